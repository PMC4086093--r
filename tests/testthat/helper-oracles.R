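# Independent oracles used to cross-check the package implementations.
# They deliberately take different computational routes than the package:
# per-start candidate filtering instead of diagonal scans, window-by-window
# substring extraction instead of vectorized column projection.

# Brute-force k-mismatch matching statistics: for each query start i, keep
# every subject start j alive and extend one character at a time, dropping
# candidates once they exceed k mismatches.
oracle_matching_stats <- function(x, y, k, symbols = c("A", "C", "G", "T")) {
    cx <- strsplit(x, "", fixed = TRUE)[[1L]]
    cy <- strsplit(y, "", fixed = TRUE)[[1L]]
    okx <- cx %in% symbols
    oky <- cy %in% symbols
    n <- length(cx); m <- length(cy)
    out <- integer(n)
    for (i in seq_len(n)) {
        alive <- seq_len(m)
        mism <- integer(m)
        l <- 0L
        repeat {
            if (i + l > n) break
            inb <- alive + l <= m
            alive <- alive[inb]; mism <- mism[inb]
            if (length(alive) == 0L) break
            mm <- (cy[alive + l] != cx[i + l]) | !oky[alive + l] | !okx[i + l]
            mism <- mism + mm
            keep <- mism <= k
            alive <- alive[keep]; mism <- mism[keep]
            if (length(alive) == 0L) break
            l <- l + 1L
        }
        out[i] <- l
    }
    out
}

# Window-by-window spaced-word enumeration (substr per window).
oracle_spaced_words <- function(s, mask, symbols = c("A", "C", "G", "T")) {
    mp <- which(strsplit(mask, "", fixed = TRUE)[[1L]] == "1")
    l <- nchar(mask)
    nwin <- nchar(s) - l + 1L
    if (nwin < 1L) return(character(0))
    keys <- character(0)
    for (start in seq_len(nwin)) {
        win <- strsplit(substr(s, start, start + l - 1L), "", fixed = TRUE)[[1L]]
        key <- win[mp]
        if (all(key %in% symbols))
            keys <- c(keys, paste(key, collapse = ""))
    }
    keys
}

# Dense frequency vector over all |symbols|^w words from an oracle key list.
oracle_dense_freqs <- function(keys, w, symbols = c("A", "C", "G", "T")) {
    all_words <- do.call(paste0, rev(expand.grid(
        rep(list(symbols), w), stringsAsFactors = FALSE)))
    counts <- table(factor(keys, levels = sort(all_words)))
    as.numeric(counts) / length(keys)
}

random_dna <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Euclidean / Jensen-Shannon on dense frequency vectors (closed formulas).
dense_euclid <- function(fa, fb) sqrt(sum((fa - fb)^2))
dense_js <- function(fa, fb) {
    h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    h((fa + fb) / 2) - (h(fa) + h(fb)) / 2
}

# Path to the installed command-line front end plus the Rscript binary.
afdist_cli <- function() {
    path <- system.file("exec", "afdist.R", package = "afdist")
    if (!nzchar(path)) path <- system.file("..", "exec", "afdist.R",
                                           package = "afdist")
    path
}

run_cli <- function(...) {
    rscript <- file.path(R.home("bin"), "Rscript")
    out <- suppressWarnings(system2(rscript, c(afdist_cli(), ...),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    list(status = if (is.null(status)) 0L else status, output = out)
}
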
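#' Extract spaced words from a sequence
#'
#' Slides the pattern over every window of the sequence, left to right, and
#' records the characters at the pattern's match positions. A window whose
#' match positions contain a character outside the alphabet (an ambiguity
#' code such as `N` or `X`) is skipped; don't-care positions may hold
#' anything. For the sequence `ATTATGCTAG` and the pattern `11001` this
#' yields the six spaced words `AT**T, TT**G, TA**C, AT**T, TG**A, GC**G`,
#' keyed by their match characters `ATT, TTG, TAC, ATT, TGA, GCG`.
#'
#' @param seq one sequence: a length-1 (optionally named) character vector
#'   or single-element [Biostrings::XStringSet].
#' @param pattern a [Pattern] or mask string.
#' @param alphabet `"DNA"` or `"PROTEIN"`; `NULL` auto-detects.
#' @return character vector of spaced-word keys, one per counted window, in
#'   sequence order (empty when the sequence is shorter than the pattern).
#' @examples
#' extractSpacedWords("ATTATGCTAG", "11001")
#' @export
extractSpacedWords <- function(seq, pattern, alphabet = NULL) {
    s <- seqStrings(seq)
    stopifnot(length(s) == 1L)
    if (is.character(pattern)) pattern <- parsePattern(pattern)
    if (is.null(alphabet)) alphabet <- detectAlphabet(s)
    symbols <- alphabetSymbols(alphabet)
    chars <- strsplit(s[[1L]], "", fixed = TRUE)[[1L]]
    l <- patternLength(pattern)
    nwin <- length(chars) - l + 1L
    if (nwin < 1L) return(character(0))
    mp <- matchPositions(pattern)
    cols <- lapply(mp, function(d) chars[seq_len(nwin) + d - 1L])
    ok <- Reduce(`&`, lapply(cols, function(cc) cc %in% symbols))
    keys <- do.call(paste0, cols)
    keys[ok]
}

#' Spaced-word frequency profile of a sequence
#'
#' Aggregates [extractSpacedWords()] output into occurrence counts; relative
#' frequencies (`wordFrequencies()`) are counts over the number of counted
#' windows and sum to 1. Only observed words are stored (the profile is
#' sparse); unobserved spaced words have frequency 0.
#'
#' @inheritParams extractSpacedWords
#' @return a [SpacedWordProfile].
#' @examples
#' p <- spacedWordProfile("ATTATGCTAG", "11001")
#' wordFrequencies(p)     # ATT has frequency 2/6, four others 1/6
#' @export
spacedWordProfile <- function(seq, pattern, alphabet = NULL) {
    s <- seqStrings(seq)
    if (is.character(pattern)) pattern <- parsePattern(pattern)
    keys <- extractSpacedWords(s, pattern, alphabet)
    if (length(keys) == 0L)
        stop("sequence too short for pattern ", patternMask(pattern),
             ": ", names(s)[1L])
    tab <- table(keys)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    new("SpacedWordProfile", pattern = pattern, counts = counts,
        total = length(keys))
}

# frequencies of two profiles aligned on the union of their keys
.alignedFreqs <- function(a, b) {
    if (patternMask(a@pattern) != patternMask(b@pattern))
        stop("profiles were built under different patterns: ",
             patternMask(a@pattern), " vs ", patternMask(b@pattern))
    keys <- union(names(a@counts), names(b@counts))
    fa <- fb <- numeric(length(keys))
    names(fa) <- names(fb) <- keys
    fa[names(a@counts)] <- a@counts / a@total
    fb[names(b@counts)] <- b@counts / b@total
    list(a = fa, b = fb)
}

#' Euclidean distance between spaced-word profiles
#'
#' Square root of the summed squared frequency differences over the union
#' of observed spaced words (absent words contribute frequency 0). Both
#' profiles must have been built under the same pattern.
#'
#' @param a,b [SpacedWordProfile]s under the same pattern.
#' @return non-negative numeric distance.
#' @export
euclideanDistance <- function(a, b) {
    f <- .alignedFreqs(a, b)
    sqrt(sum((f$a - f$b)^2))
}

#' Jensen-Shannon distance between spaced-word profiles
#'
#' The Jensen-Shannon divergence of the two frequency distributions,
#' computed with base-2 entropy so the value lies in `[0, 1]`:
#' `JS(A,B) = H((A+B)/2) - (H(A)+H(B))/2` with `0 log 0 := 0`. By default
#' the divergence itself is returned; `sqrt = TRUE` returns its square
#' root, which satisfies the triangle inequality.
#'
#' @inheritParams euclideanDistance
#' @param sqrt return the square-root (metric) variant.
#' @return numeric in `[0, 1]`.
#' @export
jensenShannonDistance <- function(a, b, sqrt = FALSE) {
    f <- .alignedFreqs(a, b)
    h <- function(p) {
        p <- p[p > 0]
        -sum(p * log2(p))
    }
    js <- h((f$a + f$b) / 2) - (h(f$a) + h(f$b)) / 2
    js <- min(max(js, 0), 1)  # clip floating-point residue at the bounds
    if (sqrt) base::sqrt(js) else js
}

#' Spaced-word distance between two sequences
#'
#' Builds both sequences' profiles under every pattern of the set and
#' returns the arithmetic mean of the per-pattern distances. Averaging over
#' several patterns stabilizes the estimate compared to a single pattern.
#'
#' @param x,y sequences (length-1 character or single-element
#'   [Biostrings::XStringSet]).
#' @param patterns a [PatternSet], [Pattern], or character vector of masks.
#' @param metric `"euclidean"` or `"js"` (Jensen-Shannon).
#' @param alphabet `"DNA"` or `"PROTEIN"`; `NULL` auto-detects from both
#'   sequences.
#' @param jsSqrt use the square-root variant of the Jensen-Shannon
#'   distance.
#' @return non-negative numeric distance.
#' @examples
#' spacedWordDistance("ATTATGCTAG", "ATTATGCTAA", "11001")
#' @export
spacedWordDistance <- function(x, y, patterns,
                               metric = c("euclidean", "js"),
                               alphabet = NULL, jsSqrt = FALSE) {
    metric <- match.arg(metric)
    ps <- .asPatternSet(patterns)
    sx <- seqStrings(x); sy <- seqStrings(y)
    if (is.null(alphabet)) alphabet <- detectAlphabet(c(sx, sy))
    mean(vapply(ps@patterns, function(p) {
        .profileDistance(spacedWordProfile(sx, p, alphabet),
                         spacedWordProfile(sy, p, alphabet),
                         metric, jsSqrt)
    }, numeric(1)))
}

.profileDistance <- function(pa, pb, metric, jsSqrt) {
    if (metric == "euclidean") euclideanDistance(pa, pb)
    else jensenShannonDistance(pa, pb, sqrt = jsSqrt)
}

.asPatternSet <- function(patterns) {
    if (is(patterns, "PatternSet")) return(patterns)
    if (is(patterns, "Pattern")) return(new("PatternSet",
                                            patterns = list(patterns)))
    patternSet(patterns)
}

#' Pairwise spaced-word distance matrix
#'
#' Computes every profile once per pattern, then fills the symmetric matrix
#' of pairwise distances (zero diagonal).
#'
#' @param seqs sequences: named character vector or
#'   [Biostrings::XStringSet] of length >= 2.
#' @inheritParams spacedWordDistance
#' @return a [DistanceMatrix].
#' @examples
#' seqs <- c(a = "ATTATGCTAGATTATGCTAG", b = "ATTATGCAAGATTATGCAAG",
#'           c = "TGCATGCATGCATGCATGCA")
#' spacedWordDistanceMatrix(seqs, patternSet("11001"))
#' @export
spacedWordDistanceMatrix <- function(seqs, patterns,
                                     metric = c("euclidean", "js"),
                                     alphabet = NULL, jsSqrt = FALSE) {
    metric <- match.arg(metric)
    ps <- .asPatternSet(patterns)
    s <- seqStrings(seqs)
    if (length(s) < 2L) stop("need at least 2 sequences")
    if (is.null(alphabet)) alphabet <- detectAlphabet(s)
    n <- length(s)
    profiles <- lapply(ps@patterns, function(p)
        lapply(seq_len(n), function(i) spacedWordProfile(s[i], p, alphabet)))
    d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            dij <- mean(vapply(profiles, function(pp)
                .profileDistance(pp[[i]], pp[[j]], metric, jsSqrt),
                numeric(1)))
            d[i, j] <- d[j, i] <- dij
        }
    }
    distanceMatrix(d)
}

#' Display a spaced word with wildcards
#'
#' Renders a spaced-word key in the conventional wildcard notation, e.g.
#' key `ATT` under pattern `11001` becomes `AT**T`.
#'
#' @param key spaced-word key (match-position characters).
#' @param pattern a [Pattern] or mask string.
#' @return character string with `*` at don't-care positions.
#' @examples
#' formatSpacedWord("ATT", "11001")
#' @export
formatSpacedWord <- function(key, pattern) {
    if (is.character(pattern)) pattern <- parsePattern(pattern)
    mp <- matchPositions(pattern)
    vapply(key, function(kk) {
        stopifnot(nchar(kk) == length(mp))
        out <- rep("*", patternLength(pattern))
        out[mp] <- strsplit(kk, "", fixed = TRUE)[[1L]]
        paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}
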
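#' Parse a single match/don't-care pattern
#'
#' A pattern is a string over `{'1','0'}`: `1` marks a match position, `0` a
#' don't-care position. Leading `0`s only shift the extraction window
#' without changing the induced spaced-word multiset, so they are removed
#' with a warning. An all-`0` mask has zero weight and is rejected.
#'
#' @param mask pattern string, e.g. `"11001"`.
#' @return a [Pattern].
#' @examples
#' parsePattern("11001")   # weight 3, length 5
#' @export
parsePattern <- function(mask) {
    if (!is.character(mask) || length(mask) != 1L || !nzchar(mask))
        stop("pattern mask must be a single non-empty string")
    if (!grepl("^[01]+$", mask))
        stop("pattern may only contain '0' and '1': ", mask)
    if (!grepl("1", mask, fixed = TRUE))
        stop("pattern has zero weight: ", mask)
    canon <- sub("^0+", "", mask)
    if (canon != mask)
        warning("leading don't-care positions removed: ", mask,
                " -> ", canon)
    new("Pattern", mask = canon)
}

#' Build a pattern set from masks
#'
#' @param masks character vector of pattern masks, or a list of [Pattern]s.
#' @return a [PatternSet].
#' @examples
#' patternSet(c("11001", "101"))
#' @export
patternSet <- function(masks) {
    pats <- if (is.list(masks)) masks else lapply(masks, parsePattern)
    new("PatternSet", patterns = pats)
}

#' Generate a random pattern set
#'
#' Draws `count` distinct patterns of identical weight and length
#' (`weight + dontCare`). The first and last mask characters are fixed to
#' `1` — leading or trailing don't-cares only shift the window, so fixing
#' the ends removes redundant duplicates — and the remaining `weight - 2`
#' match positions are placed uniformly at random among the interior
#' positions. Deterministic for a given `seed`.
#'
#' @param weight number of match positions per pattern (>= 2).
#' @param dontCare number of don't-care positions per pattern (>= 0).
#' @param count number of patterns (default 10, the conventional default;
#'   accuracy tends to saturate around 50-70 patterns at higher cost).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [PatternSet] of `count` distinct patterns.
#' @examples
#' randomPatterns(4, 4, count = 3, seed = 1)
#' @export
randomPatterns <- function(weight, dontCare, count = 10L, seed = NULL) {
    weight <- as.integer(weight); dontCare <- as.integer(dontCare)
    count <- as.integer(count)
    stopifnot(weight >= 2L, dontCare >= 0L, count >= 1L)
    if (!is.null(seed)) set.seed(as.integer(seed))
    len <- weight + dontCare
    interior <- len - 2L
    maxDistinct <- choose(interior, weight - 2L)
    if (count > maxDistinct)
        stop("cannot draw ", count, " distinct patterns of weight ", weight,
             " and length ", len, ": at most ", maxDistinct, " exist")
    masks <- character(0)
    while (length(masks) < count) {
        bits <- rep("0", len)
        bits[c(1L, len)] <- "1"
        if (weight > 2L)
            bits[1L + sample.int(interior, weight - 2L)] <- "1"
        mask <- paste(bits, collapse = "")
        if (!mask %in% masks) masks <- c(masks, mask)
    }
    patternSet(masks)
}

#' Default spaced-word parameters for a sequence set
#'
#' Chooses the pattern weight from the mean input length so that a random
#' spaced word is expected to occur about once by chance: roughly
#' `log_|alphabet|(L)` match positions, plus a margin. For DNA the weight is
#' `ceil(log4(L)) + 2` clamped to `[4, 14]`; for proteins
#' `ceil(log20(L)) + 1` clamped to `[2, 6]`. The number of don't-care
#' positions equals the weight (patterns of length `2 * weight`) and 10
#' patterns are drawn.
#'
#' @param seqs sequences (named character vector or
#'   [Biostrings::XStringSet]).
#' @param alphabet `"DNA"` or `"PROTEIN"`; `NULL` auto-detects.
#' @return list with elements `weight`, `dontCare`, `count`.
#' @examples
#' defaultPatternParams(c(a = paste(rep("ACGT", 2500), collapse = "")))
#' @export
defaultPatternParams <- function(seqs, alphabet = NULL) {
    s <- seqStrings(seqs)
    if (is.null(alphabet)) alphabet <- detectAlphabet(s)
    alphabet <- match.arg(toupper(alphabet), c("DNA", "PROTEIN"))
    lavg <- mean(nchar(s))
    # epsilon inside ceil(): log(L)/log(base) can overshoot an integer by 1 ulp
    logb <- function(x, base) ceiling(log(x) / log(base) - 1e-9)
    w <- if (alphabet == "DNA") min(max(logb(lavg, 4) + 2L, 4L), 14L)
         else min(max(logb(lavg, 20) + 1L, 2L), 6L)
    list(weight = as.integer(w), dontCare = as.integer(w), count = 10L)
}
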
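# Encode characters outside the alphabet as a sentinel byte so they can
# never match anything (distinct sentinels for the two sequences make an
# N-vs-N comparison a mismatch too).
.encodeForMatch <- function(s, symbols, sentinel) {
    r <- charToRaw(s)
    ok <- r %in% charToRaw(paste(symbols, collapse = ""))
    r[!ok] <- as.raw(sentinel)
    rawToChar(r)
}

#' k-mismatch matching statistics of one sequence against another
#'
#' For each position i of the query `x`, the length of the longest
#' substring of `x` starting at i that matches some substring of the
#' subject `y` with at most `k` Hamming mismatches.
#'
#' Two computation modes are available. `"exact"` scans every
#' query/subject diagonal to the (k+1)-th mismatch and keeps the
#' per-position maximum — the literal definition, quadratic in sequence
#' length. `"heuristic"` first finds the longest exact match per position,
#' then chains longest-common-extension steps across up to `k` mismatches
#' from the best exact-match positions (at most `maxCandidates` of them).
#' The heuristic never exceeds the exact statistic and coincides with it at
#' `k = 0`.
#'
#' Characters outside the alphabet (N, X, ...) never match any character,
#' not even themselves.
#'
#' @param x,y query and subject sequences (length-1 character, optionally
#'   named, or single-element [Biostrings::XStringSet]).
#' @param k allowed mismatches, 0 to 100.
#' @param mode `"exact"` or `"heuristic"`.
#' @param alphabet `"DNA"` or `"PROTEIN"`; `NULL` auto-detects.
#' @param maxCandidates cap on exact-match positions extended per query
#'   position in heuristic mode (keeps the worst case near-linearithmic).
#' @return a [MatchingStatistics].
#' @examples
#' msLengths(matchingStatistics("ACGT", "ACGT", k = 0))   # 4 3 2 1
#' @export
matchingStatistics <- function(x, y, k = 5L, mode = c("exact", "heuristic"),
                               alphabet = NULL, maxCandidates = 50L) {
    mode <- match.arg(mode)
    k <- as.integer(k)
    if (is.na(k) || k < 0L || k > 100L)
        stop("k must be between 0 and 100")
    sx <- seqStrings(x); sy <- seqStrings(y)
    stopifnot(length(sx) == 1L, length(sy) == 1L)
    if (is.null(alphabet)) alphabet <- detectAlphabet(c(sx, sy))
    symbols <- alphabetSymbols(alphabet)
    ex <- .encodeForMatch(sx[[1L]], symbols, 1L)
    ey <- .encodeForMatch(sy[[1L]], symbols, 2L)
    lengths <- if (mode == "exact") .exact_ms_cpp(ex, ey, k)
               else .heuristic_ms_cpp(ex, ey, k, as.integer(maxCandidates))
    new("MatchingStatistics", query = names(sx)[1L], subject = names(sy)[1L],
        k = k, lengths = as.integer(lengths))
}

#' k-mismatch average common substring (kmacs) distance
#'
#' The mean matching-statistic length `L(x, y)` measures similarity; it is
#' turned into a distance by the average-common-substring log-length
#' normalization: the directed distance is
#' `d(x, y) = ln(|y|) / L(x, y) - ln(|x|) / L(x, x)`, where the
#' self-similarity is the analytic `L(x, x) = (|x| + 1) / 2` (the mean of
#' the suffix lengths), so `d(x, x) = 0` exactly. The returned value is the
#' symmetrized `(d(x, y) + d(y, x)) / 2`. With `k = 0` this is the classic
#' average common substring distance.
#'
#' If no character of one sequence occurs in the other, `L = 0`; the
#' distance is then capped at `2 * ln(max(|x|, |y|))` with a warning.
#'
#' @inheritParams matchingStatistics
#' @return non-negative numeric distance; 0 for identical sequences.
#' @examples
#' kmacsDistance("ACGTACGTACGT", "ACGTACGAACGT", k = 1)
#' @export
kmacsDistance <- function(x, y, k = 5L, mode = c("exact", "heuristic"),
                          alphabet = NULL, maxCandidates = 50L) {
    mode <- match.arg(mode)
    sx <- seqStrings(x); sy <- seqStrings(y)
    if (is.null(alphabet)) alphabet <- detectAlphabet(c(sx, sy))
    n <- nchar(sx[[1L]]); m <- nchar(sy[[1L]])
    if (n < 2L || m < 2L) stop("sequences must have length >= 2")
    lxy <- mean(msLengths(matchingStatistics(sx, sy, k, mode, alphabet,
                                             maxCandidates)))
    lyx <- mean(msLengths(matchingStatistics(sy, sx, k, mode, alphabet,
                                             maxCandidates)))
    if (lxy == 0 || lyx == 0) {
        warning("no common substring between ", names(sx)[1L], " and ",
                names(sy)[1L], "; distance capped")
        return(2 * log(max(n, m)))
    }
    dxy <- log(m) / lxy - log(n) / ((n + 1) / 2)
    dyx <- log(n) / lyx - log(m) / ((m + 1) / 2)
    (dxy + dyx) / 2
}

#' Pairwise kmacs distance matrix
#'
#' @param seqs sequences: named character vector or
#'   [Biostrings::XStringSet] of length >= 2.
#' @inheritParams kmacsDistance
#' @param mode `"exact"`, `"heuristic"`, or `NULL` to pick automatically
#'   (exact below 1 Mb of total sequence, heuristic above).
#' @return a [DistanceMatrix].
#' @examples
#' seqs <- c(a = "ACGTACGTACGT", b = "ACGTACGAACGT", c = "TTGCATTGCATT")
#' kmacsDistanceMatrix(seqs, k = 1)
#' @export
kmacsDistanceMatrix <- function(seqs, k = 5L, mode = NULL,
                                alphabet = NULL, maxCandidates = 50L) {
    s <- seqStrings(seqs)
    if (length(s) < 2L) stop("need at least 2 sequences")
    if (is.null(mode))
        mode <- if (sum(nchar(s)) < 1e6) "exact" else "heuristic"
    mode <- match.arg(mode, c("exact", "heuristic"))
    if (is.null(alphabet)) alphabet <- detectAlphabet(s)
    n <- length(s)
    d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            d[i, j] <- d[j, i] <- kmacsDistance(s[i], s[j], k, mode,
                                                alphabet, maxCandidates)
        }
    }
    distanceMatrix(d)
}
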
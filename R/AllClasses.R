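#' Match/don't-care pattern
#'
#' A binary mask over \{'1','0'\}: '1' marks a match position (the character
#' there becomes part of the spaced word), '0' a don't-care position (any
#' character is accepted and ignored). The number of '1's is the pattern's
#' *weight*, the mask length its *length*. The first mask character must be
#' '1': a leading don't-care only shifts the window and changes nothing about
#' the induced word multiset, so it is canonicalized away on parsing.
#'
#' @slot mask single character string over \{'0','1'\}.
#'
#' @seealso [parsePattern()], [patternSet()], [randomPatterns()]
#' @aliases Pattern-class Pattern
#' @exportClass Pattern
setClass("Pattern", representation(mask = "character"))

setValidity("Pattern", function(object) {
    m <- object@mask
    if (length(m) != 1L || is.na(m) || !nzchar(m))
        return("mask must be a single non-empty string")
    if (!grepl("^[01]+$", m))
        return("mask may only contain '0' and '1'")
    if (!grepl("1", m, fixed = TRUE))
        return("pattern has zero weight")
    if (substr(m, 1L, 1L) != "1")
        return("mask must start with a match position ('1')")
    TRUE
})

#' Ordered set of patterns
#'
#' A non-empty ordered collection of distinct [Pattern] masks. Distances
#' computed under a pattern set are averaged over its members; patterns may
#' differ in weight and length.
#'
#' @slot patterns list of [Pattern] objects, duplicate masks forbidden.
#'
#' @seealso [patternSet()], [randomPatterns()], [readPatterns()]
#' @aliases PatternSet-class PatternSet
#' @exportClass PatternSet
setClass("PatternSet", representation(patterns = "list"))

setValidity("PatternSet", function(object) {
    p <- object@patterns
    if (length(p) == 0L)
        return("pattern set must be non-empty")
    if (!all(vapply(p, is, logical(1), class2 = "Pattern")))
        return("all elements must be Pattern objects")
    masks <- vapply(p, function(x) x@mask, character(1))
    if (anyDuplicated(masks))
        return("duplicate pattern masks are not allowed")
    TRUE
})

#' Spaced-word frequency profile
#'
#' Sparse relative-frequency profile of one sequence under one pattern:
#' counts of each observed spaced word (keyed by the characters at the
#' pattern's match positions) and the total number of counted windows.
#' Frequencies are `counts/total` and sum to 1.
#'
#' @slot pattern the [Pattern] the profile was built under.
#' @slot counts named integer vector, spaced-word key -> occurrence count.
#' @slot total integer, number of valid windows (sum of counts).
#'
#' @seealso [spacedWordProfile()], [euclideanDistance()],
#'   [jensenShannonDistance()]
#' @aliases SpacedWordProfile-class SpacedWordProfile
#' @exportClass SpacedWordProfile
setClass("SpacedWordProfile",
    representation(pattern = "Pattern", counts = "integer", total = "integer"))

setValidity("SpacedWordProfile", function(object) {
    if (length(object@total) != 1L || object@total < 1L)
        return("total must be a single positive integer")
    if (is.null(names(object@counts)) || any(!nzchar(names(object@counts))))
        return("counts must be named by spaced-word keys")
    if (any(object@counts < 0L))
        return("counts must be non-negative")
    if (sum(object@counts) != object@total)
        return("total must equal the sum of counts")
    w <- sum(strsplit(object@pattern@mask, "", fixed = TRUE)[[1L]] == "1")
    if (any(nchar(names(object@counts)) != w))
        return("every key must have length equal to the pattern weight")
    TRUE
})

#' k-mismatch matching statistics
#'
#' For each position i of the query, the length of the longest substring
#' starting at i that matches some substring of the subject with at most k
#' Hamming mismatches.
#'
#' @slot query name of the query sequence.
#' @slot subject name of the subject sequence.
#' @slot k allowed number of mismatches (>= 0).
#' @slot lengths integer vector, one entry per query position.
#'
#' @seealso [matchingStatistics()], [kmacsDistance()]
#' @aliases MatchingStatistics-class MatchingStatistics
#' @exportClass MatchingStatistics
setClass("MatchingStatistics",
    representation(query = "character", subject = "character",
                   k = "integer", lengths = "integer"))

setValidity("MatchingStatistics", function(object) {
    n <- length(object@lengths)
    if (n == 0L) return("lengths must be non-empty")
    if (object@k < 0L) return("k must be >= 0")
    i <- seq_len(n)
    if (any(object@lengths < 0L) || any(object@lengths > n - i + 1L))
        return("lengths[i] must lie in [0, |query| - i + 1]")
    TRUE
})

#' Symmetric pairwise distance matrix
#'
#' A square numeric matrix over sequence names: symmetric, zero diagonal,
#' all entries finite. Serializable to relaxed Phylip format with
#' [writePhylip()].
#'
#' @slot .Data numeric matrix with identical row and column names.
#'
#' @seealso [distanceMatrix()], [writePhylip()], [neighborJoining()]
#' @aliases DistanceMatrix-class DistanceMatrix
#' @exportClass DistanceMatrix
setClass("DistanceMatrix", contains = "matrix")

setValidity("DistanceMatrix", function(object) {
    m <- object@.Data
    if (!is.numeric(m) || nrow(m) != ncol(m))
        return("must be a square numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        return("row and column names must be present and identical")
    if (anyDuplicated(rownames(m)))
        return("sequence names must be unique")
    if (any(!is.finite(m)))
        return("all entries must be finite")
    if (any(abs(diag(m)) > 0))
        return("diagonal must be zero")
    if (!isSymmetric(unname(m), tol = 0))
        return("matrix must be symmetric")
    TRUE
})
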
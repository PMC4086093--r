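#' @rdname Pattern-class
#' @param object,x a `Pattern` or `PatternSet`.
#' @export
setGeneric("patternMask", function(x) standardGeneric("patternMask"))

#' @rdname Pattern-class
#' @export
setMethod("patternMask", "Pattern", function(x) x@mask)

#' @rdname Pattern-class
#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @rdname Pattern-class
#' @export
setMethod("patternWeight", "Pattern", function(x)
    sum(strsplit(x@mask, "", fixed = TRUE)[[1L]] == "1"))

#' @rdname Pattern-class
#' @export
setGeneric("patternLength", function(x) standardGeneric("patternLength"))

#' @rdname Pattern-class
#' @export
setMethod("patternLength", "Pattern", function(x) nchar(x@mask))

# 1-based match positions of the mask
matchPositions <- function(p)
    which(strsplit(p@mask, "", fixed = TRUE)[[1L]] == "1")

#' @rdname Pattern-class
#' @export
setMethod("show", "Pattern", function(object) {
    cat(sprintf("Pattern: %s (weight %d, length %d)\n", object@mask,
                patternWeight(object), patternLength(object)))
    invisible(object)
})

#' @rdname PatternSet-class
#' @param x,object a `PatternSet`.
#' @export
setGeneric("patternMasks", function(x) standardGeneric("patternMasks"))

#' @rdname PatternSet-class
#' @export
setMethod("patternMasks", "PatternSet", function(x)
    vapply(x@patterns, function(p) p@mask, character(1)))

#' @rdname PatternSet-class
#' @export
setMethod("length", "PatternSet", function(x) length(x@patterns))

#' @rdname PatternSet-class
#' @param i index of the pattern to extract.
#' @export
setMethod("[[", "PatternSet", function(x, i) x@patterns[[i]])

#' @rdname PatternSet-class
#' @export
setMethod("show", "PatternSet", function(object) {
    masks <- patternMasks(object)
    cat(sprintf("PatternSet of %d pattern(s):\n", length(masks)))
    shown <- head(masks, 10L)
    cat(paste0("  ", shown, collapse = "\n"), "\n")
    if (length(masks) > 10L)
        cat(sprintf("  ... and %d more\n", length(masks) - 10L))
    invisible(object)
})

#' @rdname SpacedWordProfile-class
#' @param x,object a `SpacedWordProfile`.
#' @export
setGeneric("wordFrequencies", function(x) standardGeneric("wordFrequencies"))

#' @rdname SpacedWordProfile-class
#' @export
setMethod("wordFrequencies", "SpacedWordProfile", function(x)
    x@counts / x@total)

#' @rdname SpacedWordProfile-class
#' @export
setMethod("show", "SpacedWordProfile", function(object) {
    cat(sprintf(
        "SpacedWordProfile under pattern %s: %d distinct word(s), %d window(s)\n",
        object@pattern@mask, length(object@counts), object@total))
    invisible(object)
})

#' @rdname MatchingStatistics-class
#' @param x,object a `MatchingStatistics`.
#' @export
setGeneric("msLengths", function(x) standardGeneric("msLengths"))

#' @rdname MatchingStatistics-class
#' @export
setMethod("msLengths", "MatchingStatistics", function(x) x@lengths)

#' @rdname MatchingStatistics-class
#' @export
setMethod("show", "MatchingStatistics", function(object) {
    cat(sprintf(
        "MatchingStatistics %s vs %s (k = %d): %d positions, mean length %.3f\n",
        object@query, object@subject, object@k, length(object@lengths),
        mean(object@lengths)))
    invisible(object)
})

#' Construct a DistanceMatrix
#'
#' Validates and wraps a square symmetric numeric matrix with a zero
#' diagonal. Row/column names are taken from `names` if given, otherwise
#' from the matrix dimnames.
#'
#' @param values square numeric matrix.
#' @param names optional character vector of sequence names.
#' @return a [DistanceMatrix].
#' @examples
#' m <- matrix(c(0, .2, .2, 0), 2, 2)
#' distanceMatrix(m, c("a", "b"))
#' @export
distanceMatrix <- function(values, names = NULL) {
    values <- as.matrix(values)
    if (!is.null(names)) {
        if (length(names) != nrow(values))
            stop("'names' must have one entry per row")
        dimnames(values) <- list(names, names)
    }
    # symmetrize away floating-point asymmetry below 1e-12 before validating
    if (nrow(values) == ncol(values) &&
        isSymmetric(unname(values), tol = 1e-12)) {
        values[] <- (values + t(values)) / 2
    }
    new("DistanceMatrix", values)
}

#' @rdname DistanceMatrix-class
#' @param object a `DistanceMatrix`.
#' @export
setMethod("show", "DistanceMatrix", function(object) {
    cat(sprintf("DistanceMatrix over %d sequences\n", nrow(object)))
    print(round(object@.Data, 6))
    invisible(object)
})

#' @rdname DistanceMatrix-class
#' @param ... unused.
#' @export
setMethod("labels", "DistanceMatrix",
    function(object, ...) rownames(object@.Data))
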
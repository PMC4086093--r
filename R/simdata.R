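#' Simulate random sequences
#'
#' Draws `n` i.i.d. uniform sequences over the chosen alphabet, named
#' `sim_1` ... `sim_n`. Deterministic for a given seed.
#'
#' @param n number of sequences.
#' @param length sequence length (recycled across sequences).
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' simulateSequences(2, 12, seed = 1)
#' @export
simulateSequences <- function(n, length, alphabet = "DNA", seed = NULL) {
    stopifnot(n >= 1L, all(length >= 1L))
    alphabet <- match.arg(toupper(alphabet), c("DNA", "PROTEIN"))
    if (!is.null(seed)) set.seed(as.integer(seed))
    symbols <- alphabetSymbols(alphabet)
    lens <- rep_len(length, n)
    s <- vapply(lens, function(L)
        paste(sample(symbols, L, replace = TRUE), collapse = ""),
        character(1))
    names(s) <- paste0("sim_", seq_len(n))
    if (alphabet == "DNA") Biostrings::DNAStringSet(s)
    else Biostrings::AAStringSet(s)
}

#' Mutate a sequence under a simple substitution model
#'
#' Each site is independently replaced, with probability `rate`, by a
#' residue drawn uniformly from the other alphabet symbols (never the
#' original, so `rate` is the expected Hamming fraction). Optionally each
#' site is then deleted independently with probability `deletionRate`,
#' which produces unaligned sequences of different lengths; the default 0
#' keeps a substitution-only model.
#'
#' @param seq one sequence (length-1 character or single-element
#'   [Biostrings::XStringSet]).
#' @param rate per-site substitution probability in `[0, 1]`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param deletionRate per-site deletion probability in `[0, 1)`.
#' @param alphabet `"DNA"` or `"PROTEIN"`; `NULL` auto-detects.
#' @return named character vector of length 1 (name suffixed `_mut`).
#' @examples
#' mutateSequence(c(a = "ACGTACGT"), rate = 0.5, seed = 1)
#' @export
mutateSequence <- function(seq, rate, seed = NULL, deletionRate = 0,
                           alphabet = NULL) {
    stopifnot(rate >= 0, rate <= 1, deletionRate >= 0, deletionRate < 1)
    s <- seqStrings(seq)
    stopifnot(length(s) == 1L)
    if (is.null(alphabet)) alphabet <- detectAlphabet(s)
    symbols <- alphabetSymbols(alphabet)
    if (!is.null(seed)) set.seed(as.integer(seed))
    chars <- strsplit(s[[1L]], "", fixed = TRUE)[[1L]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
        # draw a uniform *different* symbol: offset 1..(|alphabet|-1) from
        # the original's index, modulo the alphabet size
        cur <- match(chars[hit], symbols)
        off <- sample.int(length(symbols) - 1L, sum(hit), replace = TRUE)
        chars[hit] <- symbols[((cur - 1L + off) %% length(symbols)) + 1L]
    }
    if (deletionRate > 0)
        chars <- chars[runif(length(chars)) >= deletionRate]
    out <- paste(chars, collapse = "")
    names(out) <- paste0(names(s)[1L], "_mut")
    out
}

#' Random additive distance matrix with its generating tree
#'
#' Builds a random binary topology over `n` leaves (random sequential pair
#' joins), assigns every edge a length uniform in `(0.1, 2.0)`, and returns
#' the matrix of leaf-to-leaf path lengths together with the tree. By
#' construction the matrix is additive (satisfies the four-point
#' condition), so Neighbour Joining recovers the tree from it exactly —
#' the canonical consistency fixture.
#'
#' @param n number of leaves (>= 4), named `t1` ... `tn`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with elements `matrix` (a [DistanceMatrix]) and `tree`
#'   (an [ape::phylo]).
#' @examples
#' fx <- randomAdditiveMatrix(5, seed = 1)
#' fx$matrix
#' @export
randomAdditiveMatrix <- function(n, seed = NULL) {
    stopifnot(n >= 4L)
    if (!is.null(seed)) set.seed(as.integer(seed))
    frag <- paste0("t", seq_len(n))
    el <- function() runif(1L, 0.1, 2.0)
    while (length(frag) > 2L) {
        pick <- sample.int(length(frag), 2L)
        frag <- c(frag[-pick],
                  sprintf("(%s:%.15g,%s:%.15g)", frag[pick[1L]], el(),
                          frag[pick[2L]], el()))
    }
    txt <- sprintf("(%s:%.15g,%s:%.15g);", frag[1L], el(), frag[2L], el())
    tree <- ape::read.tree(text = txt)
    pd <- ape::cophenetic.phylo(tree)
    ord <- paste0("t", seq_len(n))
    list(matrix = distanceMatrix(pd[ord, ord]), tree = tree)
}
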
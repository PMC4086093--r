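.DNA_SYMBOLS <- c("A", "C", "G", "T")
.PROTEIN_SYMBOLS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Residue alphabets
#'
#' The two alphabets the distance methods operate on: the four nucleotides
#' for DNA and the twenty standard amino acids for proteins. Characters
#' outside the alphabet (ambiguity codes such as N or X) are never counted
#' as matches: spaced-word windows with such a character at a match position
#' are skipped, and kmacs treats them as mismatching every character.
#'
#' @param kind `"DNA"` or `"PROTEIN"`.
#' @return `alphabetSymbols()`: character vector of residue symbols.
#' @examples
#' alphabetSymbols("DNA")
#' @export
alphabetSymbols <- function(kind) {
    kind <- match.arg(toupper(kind), c("DNA", "PROTEIN"))
    if (kind == "DNA") .DNA_SYMBOLS else .PROTEIN_SYMBOLS
}

#' @rdname alphabetSymbols
#'
#' @details `detectAlphabet()` classifies a sequence set as DNA when at
#' least 95% of residues, ignoring the ambiguity codes N and X, are
#' A/C/G/T, and as protein otherwise. Supply an explicit alphabet to any
#' downstream function to override the guess.
#'
#' @param seqs sequences: a named character vector or a
#'   [Biostrings::XStringSet].
#' @return `detectAlphabet()`: `"DNA"` or `"PROTEIN"`.
#' @examples
#' detectAlphabet(c(a = "ACGTACGT"))
#' detectAlphabet(c(a = "MKVLW"))
#' @export
detectAlphabet <- function(seqs) {
    s <- seqStrings(seqs)
    chars <- strsplit(paste(s, collapse = ""), "", fixed = TRUE)[[1L]]
    chars <- chars[!chars %in% c("N", "X")]
    if (length(chars) == 0L) return("DNA")
    if (mean(chars %in% .DNA_SYMBOLS) >= 0.95) "DNA" else "PROTEIN"
}

# Coerce any supported sequence container to a named uppercase character
# vector. Accepts a single unnamed string (named "seq" then).
seqStrings <- function(seqs) {
    if (methods::is(seqs, "XStringSet")) {
        s <- as.character(seqs)
    } else if (is.character(seqs)) {
        s <- seqs
    } else {
        stop("sequences must be a character vector or an XStringSet")
    }
    if (length(s) == 0L) stop("empty sequence set")
    if (any(!nzchar(s))) stop("empty sequence in input")
    s <- toupper(s)
    if (is.null(names(s)))
        names(s) <- if (length(s) == 1L) "seq" else paste0("seq_", seq_along(s))
    s
}
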
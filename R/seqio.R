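#' Read sequences from a FASTA file or string
#'
#' Reads a multi-FASTA input into a named [Biostrings::BStringSet]. Residues
#' are uppercased; alignment gap characters (`-`, `.`) and stop symbols
#' (`*`) are stripped — the distance methods are alignment-free, so
#' alignment mark-up is noise. Names are the header up to the first
#' whitespace; duplicates are uniquified by appending `_2`, `_3`, ... with a
#' warning.
#'
#' @param input path to a FASTA file, or FASTA text itself (recognized by a
#'   leading `>`).
#' @return a [Biostrings::BStringSet] with one element per record.
#' @examples
#' readFasta(">a\nacgt\n>b\nTTTT")
#' @export
readFasta <- function(input) {
    stopifnot(is.character(input), length(input) == 1L)
    if (!nzchar(trimws(paste(input, collapse = ""))))
        stop("empty FASTA input")
    if (grepl("^\\s*>", input)) {
        path <- tempfile(fileext = ".fa")
        on.exit(unlink(path))
        writeLines(input, path)
    } else {
        path <- input
        if (!file.exists(path))
            stop("FASTA input is neither an existing file nor FASTA text ",
                 "(no '>' header): ", substr(input, 1L, 40L))
        first <- readLines(path, n = 1L)
        if (length(first) == 0L) stop("empty FASTA input: ", path)
        if (!grepl("^\\s*>", first))
            stop("not FASTA (no '>' header): ", path)
    }
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty FASTA input")
    nm <- sub("\\s.*$", "", names(set))
    if (any(!nzchar(nm))) stop("FASTA record with empty name")
    seqs <- toupper(gsub("[-.*]", "", as.character(set)))
    empty <- !nzchar(seqs)
    if (any(empty))
        stop("empty sequence: ", paste(nm[empty], collapse = ", "))
    if (anyDuplicated(nm)) {
        for (d in unique(nm[duplicated(nm)])) {
            idx <- which(nm == d)
            nm[idx[-1L]] <- paste0(d, "_", seq_along(idx)[-1L] + 0L)
        }
        warning("duplicate sequence names uniquified: ",
                paste(unique(nm[duplicated(sub("_[0-9]+$", "", nm))]),
                      collapse = ", "))
    }
    names(seqs) <- nm
    Biostrings::BStringSet(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector or [Biostrings::XStringSet].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFasta <- function(seqs, file) {
    s <- seqStrings(seqs)
    Biostrings::writeXStringSet(Biostrings::BStringSet(s), file)
    invisible(file)
}

#' Write a distance matrix in relaxed Phylip format
#'
#' The first line holds the number of sequences; each following line holds a
#' name (spaces replaced by `_`, padded to at least 10 characters) and the
#' full row of distances with 6 decimal places. Relaxed means names longer
#' than 10 characters are written in full, which modern tree builders
#' accept.
#'
#' @param m a [DistanceMatrix] (or plain symmetric matrix with dimnames).
#' @param file optional output path; if `NULL` the text is returned.
#' @return the Phylip text (invisibly when `file` is given).
#' @examples
#' m <- distanceMatrix(matrix(0, 2, 2), c("a", "b"))
#' cat(writePhylip(m))
#' @export
writePhylip <- function(m, file = NULL) {
    if (!is(m, "DistanceMatrix")) m <- distanceMatrix(m)
    nm <- gsub("[[:space:]]+", "_", labels(m))
    if (anyDuplicated(nm))
        stop("duplicate names after space replacement: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    rows <- vapply(seq_len(nrow(m)), function(i) {
        paste0(formatC(nm[i], width = -10L),
               " ", paste(sprintf("%.6f", m[i, ]), collapse = " "))
    }, character(1))
    txt <- paste0(paste(c(nrow(m), rows), collapse = "\n"), "\n")
    if (is.null(file)) return(txt)
    cat(txt, file = file)
    invisible(txt)
}

#' @rdname writePhylip
#'
#' @details `readPhylip()` parses the square relaxed dialect written by
#' `writePhylip()` (and by the classic interleaved-free square format):
#' count line, then one `name value...value` row per sequence.
#'
#' @param input path to a Phylip matrix file, or its text.
#' @return `readPhylip()`: a [DistanceMatrix].
#' @export
readPhylip <- function(input) {
    lines <- if (length(input) == 1L && !grepl("\n", input) &&
                 file.exists(input)) readLines(input)
             else strsplit(paste(input, collapse = "\n"), "\n")[[1L]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("not a Phylip distance matrix")
    n <- suppressWarnings(as.integer(trimws(lines[1L])))
    if (is.na(n) || length(lines) != n + 1L)
        stop("Phylip matrix header does not match the number of rows")
    nm <- character(n)
    vals <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        tok <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
        if (length(tok) != n + 1L)
            stop("row ", i, " has ", length(tok) - 1L,
                 " values, expected ", n)
        nm[i] <- tok[1L]
        vals[i, ] <- as.numeric(tok[-1L])
    }
    distanceMatrix(vals, nm)
}

#' Read and write pattern files
#'
#' A pattern file holds one binary `0`/`1` mask per line; blank lines and
#' lines starting with `#` are ignored. Patterns in a file may differ in
#' weight and length.
#'
#' @param input path to a pattern file, or its text.
#' @return `readPatterns()`: a [PatternSet].
#' @examples
#' readPatterns("# two patterns\n11001\n101\n")
#' @export
readPatterns <- function(input) {
    stopifnot(is.character(input), length(input) >= 1L)
    lines <- if (length(input) == 1L && !grepl("\n", input) &&
                 !grepl("^\\s*[01#]", input) && file.exists(input))
                 readLines(input)
             else strsplit(paste(input, collapse = "\n"), "\n")[[1L]]
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    idx <- which(keep)
    if (length(idx) == 0L) stop("no patterns found in input")
    pats <- vector("list", length(idx))
    for (j in seq_along(idx)) {
        mask <- trimws(lines[idx[j]])
        if (!grepl("^[01]+$", mask))
            stop("invalid pattern character at line ", idx[j])
        pats[[j]] <- parsePattern(mask)
    }
    masks <- vapply(pats, patternMask, character(1))
    if (anyDuplicated(masks)) {
        warning("duplicate patterns dropped")
        pats <- pats[!duplicated(masks)]
    }
    new("PatternSet", patterns = pats)
}

#' @rdname readPatterns
#' @param ps a [PatternSet].
#' @param file optional output path; if `NULL` the text is returned.
#' @return `writePatterns()`: the pattern text (invisibly when writing).
#' @export
writePatterns <- function(ps, file = NULL) {
    stopifnot(is(ps, "PatternSet"))
    txt <- paste0(paste(patternMasks(ps), collapse = "\n"), "\n")
    if (is.null(file)) return(txt)
    cat(txt, file = file)
    invisible(txt)
}

#' Write a tree in Newick format
#'
#' Serializes an [ape::phylo] tree (as produced by [neighborJoining()]) to a
#' Newick string with branch lengths printed to 6 decimal places and a
#' terminating `;`. Spaces in leaf names are replaced by `_`.
#'
#' @param tree an `ape` `phylo` object.
#' @param file optional output path; if `NULL` the text is returned.
#' @return the Newick text (invisibly when `file` is given).
#' @export
writeNewick <- function(tree, file = NULL) {
    stopifnot(inherits(tree, "phylo"))
    ntip <- length(tree$tip.label)
    labs <- gsub("[[:space:]]+", "_", tree$tip.label)
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
    len <- tree$edge.length
    if (is.null(len)) len <- rep(0, nrow(tree$edge))
    rec <- function(node) {
        es <- kids[[as.character(node)]]
        parts <- vapply(es, function(e) {
            child <- tree$edge[e, 2L]
            lab <- if (child <= ntip) labs[child] else rec(child)
            sprintf("%s:%.6f", lab, len[e])
        }, character(1))
        paste0("(", paste(parts, collapse = ","), ")")
    }
    txt <- paste0(rec(ntip + 1L), ";")
    if (is.null(file)) return(txt)
    writeLines(txt, file)
    invisible(txt)
}
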
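#' Neighbour-Joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration with the Studier-Keppler Q-criterion:
#' repeatedly joins the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` (`R` = row sums, `r` = active
#' nodes) until three nodes remain, which are attached to a trifurcating
#' root — the output is the unrooted NJ topology in the convention of
#' Phylip's `neighbor`. Two sequences give a single edge split evenly.
#' Ties in Q are broken by the lexicographically smallest index pair, so
#' the output is deterministic; negative branch-length estimates are
#' clamped to zero.
#'
#' On an additive (tree-like) matrix, NJ recovers the generating topology
#' and branch lengths exactly.
#'
#' @param m a [DistanceMatrix], or a square symmetric numeric matrix with
#'   dimnames and zero diagonal.
#' @return an [ape::phylo] tree with branch lengths; serialize with
#'   [writeNewick()].
#' @examples
#' d <- matrix(c(0, 3, 5, 6,
#'               3, 0, 6, 7,
#'               5, 6, 0, 7,
#'               6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' writeNewick(neighborJoining(distanceMatrix(d)))
#' @export
neighborJoining <- function(m) {
    if (!is(m, "DistanceMatrix")) m <- distanceMatrix(m)
    D <- m@.Data
    n <- nrow(D)
    if (n < 2L) stop("need at least 2 sequences")
    frag <- rownames(D)   # newick fragment per active node

    clamp <- function(l) {
        if (any(l < 0)) message("negative branch length estimate clamped to 0")
        pmax(l, 0)
    }
    bl <- function(l) sprintf("%.15g", l)

    if (n == 2L) {
        half <- clamp(rep(D[1L, 2L] / 2, 2L))
        txt <- sprintf("(%s:%s,%s:%s);", frag[1L], bl(half[1L]),
                       frag[2L], bl(half[2L]))
        return(ape::read.tree(text = txt))
    }

    while (nrow(D) > 3L) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, `+`)
        diag(Q) <- Inf
        Q[lower.tri(Q)] <- Inf
        hits <- which(Q == min(Q), arr.ind = TRUE)
        hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
        i <- hit[[1L]]; j <- hit[[2L]]
        li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        ll <- clamp(c(li, lj))
        newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(ll[1L]),
                           frag[j], bl(ll[2L]))
        du <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                    c(du[keep], 0))
        rn <- c(rownames(D)[keep], sprintf("node%d", r))
        dimnames(D2) <- list(rn, rn)
        D <- D2
        frag <- c(frag[keep], newFrag)
    }

    d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
    l <- clamp(c((d12 + d13 - d23) / 2,
                 (d12 + d23 - d13) / 2,
                 (d13 + d23 - d12) / 2))
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   frag[1L], bl(l[1L]), frag[2L], bl(l[2L]),
                   frag[3L], bl(l[3L]))
    ape::read.tree(text = txt)
}
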
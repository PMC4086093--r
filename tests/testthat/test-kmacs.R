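test_that("exact matching statistics reproduce hand-checked cases", {
    expect_equal(msLengths(matchingStatistics("ACGT", "ACGT", k = 0)),
                 c(4L, 3L, 2L, 1L))
    # any length-2 window of AAAA vs TTTT has 2 mismatches
    expect_equal(msLengths(matchingStatistics("AAAA", "TTTT", k = 1)),
                 rep(1L, 4))
    # only the final T of ACGT occurs in TTTT
    expect_equal(msLengths(matchingStatistics("ACGT", "TTTT", k = 0)),
                 c(0L, 0L, 0L, 1L))
    expect_error(matchingStatistics("ACGT", "ACGT", k = -1), "between 0")
    expect_error(matchingStatistics("ACGT", "ACGT", k = 101), "between 0")
})

test_that("exact statistics agree with the brute-force oracle", {
    set.seed(41)
    for (rep in 1:25) {
        x <- random_dna(sample(20:80, 1))
        y <- random_dna(sample(20:80, 1))
        for (k in c(0L, 1L, 3L)) {
            expect_equal(msLengths(matchingStatistics(x, y, k, "exact")),
                         oracle_matching_stats(x, y, k))
        }
    }
})

test_that("exact lengths are monotone non-decreasing in k", {
    set.seed(43)
    for (rep in 1:10) {
        x <- random_dna(100); y <- random_dna(100)
        prev <- msLengths(matchingStatistics(x, y, 0, "exact"))
        for (k in 1:4) {
            cur <- msLengths(matchingStatistics(x, y, k, "exact"))
            expect_true(all(cur >= prev))
            prev <- cur
        }
    }
})

test_that("heuristic equals exact at k = 0 and for self-comparison", {
    set.seed(47)
    for (rep in 1:15) {
        x <- random_dna(sample(50:200, 1))
        y <- random_dna(sample(50:200, 1))
        expect_equal(msLengths(matchingStatistics(x, y, 0, "heuristic")),
                     msLengths(matchingStatistics(x, y, 0, "exact")))
    }
    x <- random_dna(150)
    for (k in c(0L, 3L)) {
        expect_equal(msLengths(matchingStatistics(x, x, k, "heuristic")),
                     rev(seq_len(150)))
        expect_equal(msLengths(matchingStatistics(x, x, k, "exact")),
                     rev(seq_len(150)))
    }
})

test_that("heuristic lengths never exceed exact lengths", {
    set.seed(53)
    for (rep in 1:20) {
        x <- random_dna(200); y <- random_dna(200)
        for (k in c(1L, 5L)) {
            h <- msLengths(matchingStatistics(x, y, k, "heuristic"))
            e <- msLengths(matchingStatistics(x, y, k, "exact"))
            expect_true(all(h <= e))
        }
    }
})

test_that("ambiguity codes never match, not even themselves", {
    # the N runs must break every match in both modes
    e <- msLengths(matchingStatistics("ANG", "ANG", k = 0, alphabet = "DNA"))
    expect_equal(e, c(1L, 0L, 1L))
    e1 <- msLengths(matchingStatistics("ANG", "ANG", k = 1, alphabet = "DNA"))
    expect_equal(e1, c(3L, 2L, 1L))
    h <- msLengths(matchingStatistics("ANG", "ANG", k = 0, mode = "heuristic",
                                      alphabet = "DNA"))
    expect_equal(h, c(1L, 0L, 1L))
})

test_that("kmacs distance is zero on identity, symmetric, and capped", {
    x <- random_dna(100)
    expect_equal(kmacsDistance(x, x, k = 0), 0)
    expect_equal(kmacsDistance(x, x, k = 5), 0)
    y <- random_dna(120)
    expect_equal(kmacsDistance(x, y, k = 2), kmacsDistance(y, x, k = 2))
    # disjoint alphabets: no common substring, distance capped with warning
    expect_warning(dcap <- kmacsDistance("AAAAAA", "TTTTTT", k = 0),
                   "capped")
    expect_equal(dcap, 2 * log(6))
})

test_that("kmacs distance matrix is consistent with pairwise calls", {
    set.seed(59)
    seqs <- c(a = random_dna(80), b = random_dna(80), c = random_dna(80))
    m <- kmacsDistanceMatrix(seqs, k = 2)
    expect_s4_class(m, "DistanceMatrix")
    expect_equal(unclass(m), t(unclass(m)))
    expect_equal(diag(unclass(m)), c(a = 0, b = 0, c = 0))
    expect_equal(m["a", "c"], kmacsDistance(seqs["a"], seqs["c"], k = 2))
    # duplicated residues give a zero matrix
    z <- kmacsDistanceMatrix(c(s1 = seqs[["a"]], s2 = seqs[["a"]]), k = 5)
    expect_true(all(unclass(z) == 0))
    # default k is 5
    expect_equal(unclass(kmacsDistanceMatrix(seqs)),
                 unclass(kmacsDistanceMatrix(seqs, k = 5)))
})

test_that("kmacs distance grows with simulated divergence", {
    anc <- as.character(simulateSequences(1, 2000, "DNA", seed = 61))
    rates <- c(0.05, 0.15, 0.30)
    d <- vapply(seq_along(rates), function(i) {
        mut <- mutateSequence(anc, rates[i], seed = 1000 + i)
        kmacsDistance(anc, mut, k = 5)
    }, numeric(1))
    expect_true(all(diff(d) > 0))
})
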
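test_that("spaced-word extraction matches the hand-worked ATTATGCTAG case", {
    keys <- extractSpacedWords("ATTATGCTAG", "11001")
    expect_identical(keys, c("ATT", "TTG", "TAC", "ATT", "TGA", "GCG"))
    expect_identical(formatSpacedWord(keys, "11001"),
                     c("AT**T", "TT**G", "TA**C", "AT**T", "TG**A", "GC**G"))
    expect_identical(extractSpacedWords("ACG", "11001"), character(0))
})

test_that("windows with ambiguity codes at match positions are skipped", {
    expect_identical(extractSpacedWords("ANAT", "11", alphabet = "DNA"), "AT")
    # don't-care positions may hold anything
    expect_identical(extractSpacedWords("ANT", "101", alphabet = "DNA"), "AT")
})

test_that("extraction agrees with window-by-window enumeration", {
    set.seed(21)
    for (rep in 1:20) {
        s <- random_dna(sample(10:60, 1))
        mask <- patternMasks(randomPatterns(3, sample(0:4, 1), 1))
        expect_identical(extractSpacedWords(s, mask, "DNA"),
                         oracle_spaced_words(s, mask))
    }
})

test_that("profile frequencies reproduce the worked example and sum to 1", {
    pr <- spacedWordProfile("ATTATGCTAG", "11001")
    f <- wordFrequencies(pr)
    expect_equal(f[["ATT"]], 2 / 6)
    expect_equal(unname(f[c("TTG", "TAC", "TGA", "GCG")]), rep(1 / 6, 4))
    expect_equal(sum(f), 1)
    expect_equal(pr@total, 6L)

    expect_equal(wordFrequencies(spacedWordProfile("AAAA", "11")),
                 c(AA = 1))
    expect_error(spacedWordProfile(c(s = "AC"), "11001"), "too short")
})

test_that("profile totals equal the window count on clean sequences", {
    set.seed(3)
    for (rep in 1:10) {
        s <- random_dna(sample(30:80, 1))
        mask <- "110101"
        pr <- spacedWordProfile(s, mask, "DNA")
        expect_equal(pr@total, nchar(s) - nchar(mask) + 1L)
    }
})

test_that("Euclidean distance: identity, disjoint masses, oracle value", {
    a <- spacedWordProfile("ATTATGCTAG", "11001")
    expect_equal(euclideanDistance(a, a), 0)

    pa <- spacedWordProfile("AAAA", "11")
    pb <- spacedWordProfile("CCCC", "11")
    expect_equal(euclideanDistance(pa, pb), sqrt(2))

    b <- spacedWordProfile("ATTATGCTAA", "11001")
    fa <- oracle_dense_freqs(oracle_spaced_words("ATTATGCTAG", "11001"), 3)
    fb <- oracle_dense_freqs(oracle_spaced_words("ATTATGCTAA", "11001"), 3)
    expect_equal(euclideanDistance(a, b), dense_euclid(fa, fb))

    expect_error(euclideanDistance(a, spacedWordProfile("ATTATGCTAG", "111")),
                 "different patterns")
})

test_that("Jensen-Shannon distance: bounds, closed form, sqrt variant", {
    a <- spacedWordProfile("ATTATGCTAG", "11001")
    expect_equal(jensenShannonDistance(a, a), 0)

    pa <- spacedWordProfile("AAAA", "11")
    pb <- spacedWordProfile("CCCC", "11")
    expect_equal(jensenShannonDistance(pa, pb), 1)

    # A = (1, 0) vs B = (1/2, 1/2): JS = H(3/4, 1/4) - 1/2 in bits
    pA <- spacedWordProfile("AAA", "11")        # {AA: 1}
    pHalf <- spacedWordProfile("AAC", "11")     # {AA: 1/2, AC: 1/2}
    expect_equal(wordFrequencies(pHalf)[c("AA", "AC")],
                 c(AA = 0.5, AC = 0.5))
    closed <- -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 1 / 2
    expect_equal(jensenShannonDistance(pA, pHalf), closed)
    expect_equal(dense_js(c(1, 0), c(0.5, 0.5)), closed)
    expect_equal(jensenShannonDistance(pA, pHalf, sqrt = TRUE), sqrt(closed))
})

test_that("JS lies in [0,1] and is symmetric on random profiles", {
    set.seed(17)
    profs <- lapply(1:12, function(i)
        spacedWordProfile(random_dna(40), "1101", "DNA"))
    for (rep in 1:30) {
        ij <- sample(12, 2)
        a <- profs[[ij[1]]]; b <- profs[[ij[2]]]
        js <- jensenShannonDistance(a, b)
        expect_gte(js, 0); expect_lte(js, 1)
        expect_equal(js, jensenShannonDistance(b, a))
    }
})

test_that("contiguous all-'1' patterns reproduce plain k-mer distances", {
    set.seed(31)
    for (rep in 1:5) {
        x <- random_dna(120); y <- random_dna(120)
        for (w in c(2L, 3L)) {
            mask <- strrep("1", w)
            px <- spacedWordProfile(x, mask, "DNA")
            py <- spacedWordProfile(y, mask, "DNA")
            # independent route: Biostrings' k-mer counter
            fx <- as.numeric(Biostrings::oligonucleotideFrequency(
                Biostrings::DNAString(x), w, as.prob = TRUE))
            fy <- as.numeric(Biostrings::oligonucleotideFrequency(
                Biostrings::DNAString(y), w, as.prob = TRUE))
            expect_equal(euclideanDistance(px, py), dense_euclid(fx, fy),
                         tolerance = 1e-12)
            expect_equal(jensenShannonDistance(px, py), dense_js(fx, fy),
                         tolerance = 1e-12)
        }
    }
})

test_that("multi-pattern distance is the mean of per-pattern distances", {
    set.seed(5)
    x <- random_dna(60); y <- random_dna(60)
    m1 <- "1101"; m2 <- "11011"
    d1 <- euclideanDistance(spacedWordProfile(x, m1, "DNA"),
                            spacedWordProfile(y, m1, "DNA"))
    d2 <- euclideanDistance(spacedWordProfile(x, m2, "DNA"),
                            spacedWordProfile(y, m2, "DNA"))
    ps <- patternSet(c(m1, m2))
    expect_equal(spacedWordDistance(x, y, ps), (d1 + d2) / 2)
    # singleton set equals the single-pattern distance
    expect_equal(spacedWordDistance(x, y, patternSet(m1)), d1)
    # identical sequences are at distance zero under any set
    expect_equal(spacedWordDistance(x, x, ps), 0)
    # shuffling the pattern set leaves the distance unchanged
    expect_equal(spacedWordDistance(x, y, patternSet(c(m2, m1))),
                 spacedWordDistance(x, y, ps))
})

test_that("distance matrices are symmetric, zero-diagonal, order-equivariant", {
    set.seed(9)
    seqs <- c(a = random_dna(80), b = random_dna(80), c = random_dna(80))
    ps <- randomPatterns(3, 3, count = 4, seed = 2)
    for (metric in c("euclidean", "js")) {
        m <- spacedWordDistanceMatrix(seqs, ps, metric)
        expect_s4_class(m, "DistanceMatrix")
        expect_equal(unclass(m), t(unclass(m)))
        expect_equal(diag(unclass(m)), c(a = 0, b = 0, c = 0))
        # entries agree with pairwise calls
        expect_equal(m["a", "b"],
                     spacedWordDistance(seqs["a"], seqs["b"], ps, metric))
        expect_equal(m["b", "c"],
                     spacedWordDistance(seqs["b"], seqs["c"], ps, metric))
        # permuting the input permutes rows/columns identically
        perm <- spacedWordDistanceMatrix(seqs[c(3, 1, 2)], ps, metric)
        expect_equal(unclass(perm)[names(seqs), names(seqs)], unclass(m))
    }
    # three copies of the same residues -> zero matrix
    dup <- c(s1 = seqs[["a"]], s2 = seqs[["a"]], s3 = seqs[["a"]])
    z <- spacedWordDistanceMatrix(dup, ps)
    expect_true(all(unclass(z) == 0))
})

test_that("Euclidean profile distance satisfies the triangle inequality", {
    set.seed(13)
    profs <- lapply(1:15, function(i)
        spacedWordProfile(random_dna(50), "1011", "DNA"))
    for (rep in 1:60) {
        ijk <- sample(15, 3)
        dab <- euclideanDistance(profs[[ijk[1]]], profs[[ijk[2]]])
        dbc <- euclideanDistance(profs[[ijk[2]]], profs[[ijk[3]]])
        dac <- euclideanDistance(profs[[ijk[1]]], profs[[ijk[3]]])
        expect_lte(dac, dab + dbc + 1e-12)
    }
})
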
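## Segmentation, property means, molecular weight, pair canonicalisation.

test_that("20/60/20 segmentation follows the floor rule", {
    s100 <- randomSequence(100, seed = 1)
    seg <- splitSegments(s100)
    expect_identical(unname(nchar(seg)), c(20L, 60L, 20L))
    expect_identical(paste(seg, collapse = ""), s100)

    s7 <- randomSequence(7, seed = 2)
    expect_identical(unname(nchar(splitSegments(s7))), c(1L, 5L, 1L))

    ## concatenation restores the input across lengths
    for (L in c(5, 9, 23, 64)) {
        s <- randomSequence(L, seed = L)
        expect_identical(paste(splitSegments(s), collapse = ""), s)
    }
    expect_error(splitSegments("ACDE"), "degenerate")
    expect_error(splitSegments("ACDB"), "disallowed")
})

test_that("property means skip X and U from numerator and denominator", {
    prop <- stats::setNames(rep(0, 20), sort(AA20h))
    prop["A"] <- 1; prop["C"] <- 4
    expect_identical(propertyMean("ACXA", prop), 2.0)
    expect_identical(propertyMean("AAAA", prop), 1.0)   # homopolymer identity
    expect_error(propertyMean("XXU", prop), "undefined mean")
})

test_that("TF vectors are 3P long, segment-major, and match a per-position oracle", {
    tab <- genPropertyTable(6, seed = 4)
    P <- length(tab)
    s <- randomSequence(30, seed = 7)
    v <- featurizeTF(s, tab)
    expect_length(v, 3L * P)
    expect_equal(unname(v), oracleFeaturizeTF(s, propertyValues(tab)))

    ## with X/U present the oracle still agrees
    sx <- paste0(substr(s, 1, 10), "XU", substr(s, 13, 30))
    expect_equal(unname(featurizeTF(sx, tab)),
                 oracleFeaturizeTF(sx, propertyValues(tab)))

    ## homopolymer: three identical blocks equal to the per-A column
    h <- featurizeTF(strrep("A", 10), tab)
    expect_equal(unname(h),
                 rep(unname(propertyValues(tab)[, "A"]), 3))

    ## values bounded by each property's range over the residues
    lo <- apply(propertyValues(tab), 1, min)
    hi <- apply(propertyValues(tab), 1, max)
    for (seed in 1:5) {
        vv <- matrix(featurizeTF(randomSequence(40, seed = seed), tab),
                     nrow = P)
        expect_true(all(vv >= lo - 1e-12 & vv <= hi + 1e-12))
    }
})

test_that("featurizeTF errors carry the record id", {
    tab <- genPropertyTable(2, seed = 1)
    expect_error(featurizeTF("ACD", tab, id = "TF_SHORT"), "TF_SHORT")
})

test_that("molecular weight uses standard average masses plus one water", {
    expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4)
    expect_equal(molecularWeight("GG"), 132.12, tolerance = 1e-4)
    ## appending any residue strictly increases the weight (X adds zero,
    ## so every real residue must add its positive mass)
    s <- "GAV"
    for (aa in sort(AA20h))
        expect_gt(molecularWeight(paste0(s, aa)), molecularWeight(s))
})

test_that("canonical pair ordering is weight-then-id and symmetric", {
    seqs <- c(HEAVY = strrep("W", 10), LIGHT = strrep("A", 10),
              B = strrep("C", 8), A = strrep("C", 8))
    expect_identical(canonicalPair("HEAVY", "LIGHT", seqs),
                     c("LIGHT", "HEAVY"))
    ## exact tie: lexicographic id
    expect_identical(canonicalPair("B", "A", seqs), c("A", "B"))
    expect_identical(canonicalPair("A", "B", seqs),
                     canonicalPair("B", "A", seqs))
})

test_that("pair vectors are 6P long and bitwise symmetric in argument order", {
    tab <- genPropertyTable(5, seed = 2)
    seqs <- c(TFA = randomSequence(40, seed = 11),
              TFB = randomSequence(60, seed = 12))
    v1 <- featurizePair("TFA", "TFB", seqs, tab)
    v2 <- featurizePair("TFB", "TFA", seqs, tab)
    expect_length(v1, 6L * length(tab))
    expect_identical(unname(v1), unname(v2))
    expect_identical(attr(v1, "first_id"), attr(v2, "first_id"))

    ## two homopolymers: the lighter (A) block comes first
    seqs2 <- c(PA = strrep("A", 5), PW = strrep("W", 5))
    vp <- featurizePair("PW", "PA", seqs2, tab)
    expect_equal(unname(vp[seq_len(3 * length(tab))]),
                 rep(unname(propertyValues(tab)[, "A"]), 3))
    expect_equal(unname(vp[3 * length(tab) + seq_len(3 * length(tab))]),
                 rep(unname(propertyValues(tab)[, "W"]), 3))
    expect_identical(attr(vp, "first_id"), "PA")
})

test_that("with P = 531 a TF vector has 1593 features and a pair 3186", {
    tab <- genPropertyTable(531, seed = 8)
    v <- featurizeTF(randomSequence(50, seed = 3), tab)
    expect_identical(length(v), 1593L)
    seqs <- c(T1 = randomSequence(50, seed = 4),
              T2 = randomSequence(70, seed = 5))
    expect_identical(length(featurizePair("T1", "T2", seqs, tab)), 3186L)
})

test_that("featurizePairs matches featurizePair row by row", {
    tab <- genPropertyTable(4, seed = 3)
    seqs <- c(Q1 = randomSequence(30, seed = 21),
              Q2 = randomSequence(45, seed = 22),
              Q3 = randomSequence(60, seed = 23))
    pairs <- data.frame(first_id = c("Q1", "Q3"), second_id = c("Q2", "Q1"))
    X <- featurizePairs(pairs, seqs, tab)
    expect_identical(dim(X), c(2L, 24L))
    expect_equal(unname(X[1, ]),
                 unname(as.numeric(featurizePair("Q1", "Q2", seqs, tab))))
    expect_equal(unname(X[2, ]),
                 unname(as.numeric(featurizePair("Q3", "Q1", seqs, tab))))
    expect_error(featurizePairs(data.frame(first_id = "Q1",
                                           second_id = "NOPE"), seqs, tab),
                 "NOPE")
})

test_that("feature annotation decomposes column indices into triples", {
    tab <- genPropertyTable(3, seed = 6)   # P = 3, pair vector length 18
    ann <- featureAnnotation(tab)
    expect_identical(nrow(ann), 18L)
    expect_identical(ann$member, rep(1:2, each = 9L))
    expect_identical(ann$segment, rep(rep(c("n", "mid", "c"), each = 3L), 2))
    expect_identical(ann$property, rep(1:3, 6L))
    ## spot-check: column P + 2 is member 1, mid segment, property 2
    one <- featureAnnotation(tab, 5L)
    expect_identical(one$member, 1L)
    expect_identical(one$segment, "mid")
    expect_identical(one$property, 2L)
})
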
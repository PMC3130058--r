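## MI-type filtering, negative generation, identity, redundancy filter.

test_that("the PSI-MI type filter keeps only allowed evidence codes", {
    df <- data.frame(first_id = c("A", "B", "C", "D"),
                     second_id = c("E", "F", "G", "H"),
                     mi_type = c("MI:0407", "MI:0914", NA, "MI:0195"))
    kept <- filterByMIType(df)
    expect_identical(kept$mi_type, c("MI:0407", "MI:0195"))
    expect_identical(nrow(filterByMIType(df[0, ])), 0L)
    ## records without annotation are dropped when filtering is on
    expect_identical(nrow(filterByMIType(df[3, ])), 0L)
})

test_that("generated negatives satisfy their class constraint (exhaustive check)", {
    ## 6 TFs, 2 known interactions: TF1-TF2 and TF3 with an external protein
    universe <- paste0("TF", 1:6)
    kp <- list(TF1 = "TF2", TF2 = "TF1", TF3 = "PEXT")
    interacting <- c("TF1", "TF2", "TF3")
    for (cls in c("absolute", "partial", "ppi")) {
        maxN <- nrow(TFIpred:::eligibleNegativePairs(universe, kp, cls))
        got <- generateNegatives(universe, kp, cls, maxN, seed = 1)
        expect_identical(nrow(got), maxN)
        for (r in seq_len(nrow(got))) {
            a <- got$first_id[r]; b <- got$second_id[r]
            expect_true(a < b)                       # ordered, no self-pair
            ok <- switch(cls,
                absolute = !(a %in% interacting) && !(b %in% interacting),
                partial = xor(a %in% interacting, b %in% interacting),
                ppi = (a %in% interacting) && (b %in% interacting) &&
                      !(b %in% kp[[a]]))
            expect_true(ok)
        }
    }
    ## brute-force capacities over all 15 unordered pairs
    expect_identical(nrow(TFIpred:::eligibleNegativePairs(universe, kp,
                                                          "absolute")), 3L)
    expect_identical(nrow(TFIpred:::eligibleNegativePairs(universe, kp,
                                                          "partial")), 9L)
    expect_identical(nrow(TFIpred:::eligibleNegativePairs(universe, kp,
                                                          "ppi")), 2L)
})

test_that("negative generation is seeded, capped, and disjoint from positives", {
    universe <- paste0("TF", 1:10)
    kp <- list(TF1 = c("TF2", "TF3"), TF2 = "TF1", TF3 = "TF1")
    expect_identical(nrow(generateNegatives(universe, kp, "ppi", 0, 1)), 0L)
    expect_error(generateNegatives(universe, kp, "absolute", 1000, 1),
                 "only [0-9]+ eligible")
    a <- generateNegatives(universe, kp, "partial", 5, seed = 42)
    b <- generateNegatives(universe, kp, "partial", 5, seed = 42)
    expect_identical(a, b)
    ## across seeds: duplicate-free and never a known positive
    posKeys <- c("TF1\rTF2", "TF1\rTF3")
    for (s in 1:20) {
        g <- generateNegatives(universe, kp, "ppi", 1, seed = s)
        keys <- paste(g$first_id, g$second_id, sep = "\r")
        expect_false(any(keys %in% posKeys))
        expect_false(anyDuplicated(keys) > 0)
    }
})

test_that("412 pairs per class merge into 1236 distinct negatives", {
    universe <- sprintf("TF%03d", 1:70)
    ## first 35 TFs interact with an external decoy protein each
    kp <- stats::setNames(
        c(lapply(1:35, function(i) sprintf("EXT%03d", i)),
          lapply(36:70, function(i) character(0))), universe)
    neg <- makeNegativeSet(universe, kp, 412, seed = 99)
    expect_identical(nrow(neg), 1236L)
    keys <- paste(neg$first_id, neg$second_id, sep = "\r")
    expect_identical(anyDuplicated(keys), 0L)
    expect_equal(as.integer(table(neg$neg_class)[c("absolute", "partial",
                                                   "ppi")]),
                 rep(412L, 3))
})

test_that("sequence identity matches a Smith-Waterman oracle on toy strings", {
    expect_equal(sequenceIdentity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
    sub <- TFIpred:::blosum62()
    set.seed(31)
    for (i in 1:25) {
        a <- randomSequence(sample(4:10, 1))
        b <- randomSequence(sample(4:10, 1))
        orc <- oracleLocalAlign(a, b, sub)
        if (orc$score <= 0) next   # no positive-scoring local alignment
        al <- Biostrings::pairwiseAlignment(a, b, type = "local",
            substitutionMatrix = sub, gapOpening = 11, gapExtension = 1)
        expect_equal(Biostrings::score(al), orc$score)
        ## symmetry of the exposed identity
        expect_equal(sequenceIdentity(a, b), sequenceIdentity(b, a))
    }
    ## identity on a gapped case whose optimal alignment is unique
    ## (ACDWWW/AC-WWW scores 34; the runner-up, WWW/WWW, scores 33);
    ## ambiguous score ties are excluded because co-optimal alignments
    ## may legitimately differ in identity between engines
    orc <- oracleLocalAlign("ACDWWW", "ACWWW", sub)
    expect_equal(orc$identity, 5 / 6)
    expect_equal(sequenceIdentity("ACDWWW", "ACWWW"), orc$identity)
    ## selenocysteine is tolerated
    expect_equal(sequenceIdentity("ACDEFGHIKU", "ACDEFGHIKU"), 1.0)
})

test_that("the redundancy filter drops exactly one of a duplicated interaction", {
    ## A and Aprime identical in sequence, both interacting with B
    seqs <- c(A = randomSequence(60, seed = 51),
              Aprime = randomSequence(60, seed = 51),
              B = randomSequence(80, seed = 52))
    pos <- data.frame(first_id = c("A", "Aprime"), second_id = c("B", "B"),
                      label = "positive", stringsAsFactors = FALSE)
    out <- redundancyFilter(pos, seqs)
    expect_identical(nrow(out$retained), 1L)
    expect_identical(out$retained$first_id, "A")      # lexicographic keeper
    expect_identical(nrow(out$removed), 1L)
    expect_identical(out$removed$tf_removed, "Aprime")
    expect_identical(out$removed$common_partner, "B")
    expect_gt(out$removed$identity, 0.8)

    ## idempotence
    again <- redundancyFilter(out$retained, seqs)
    expect_identical(again$retained, out$retained)
    expect_identical(nrow(again$removed), 0L)

    ## input order invariance
    out2 <- redundancyFilter(pos[2:1, ], seqs)
    expect_identical(out2$retained$first_id, out$retained$first_id)
    expect_identical(out2$retained$second_id, out$retained$second_id)
})

test_that("similar TFs without a common partner trigger no removal", {
    seqs <- c(A = randomSequence(60, seed = 53),
              Aprime = randomSequence(60, seed = 53),
              B = randomSequence(70, seed = 54),
              C = randomSequence(70, seed = 55))
    pos <- data.frame(first_id = c("A", "Aprime"), second_id = c("B", "C"),
                      label = "positive", stringsAsFactors = FALSE)
    out <- redundancyFilter(pos, seqs)
    expect_identical(nrow(out$retained), 2L)
    expect_identical(nrow(out$removed), 0L)
})

test_that("redundancy removal is monotone in the threshold", {
    seqs <- c(A = randomSequence(60, seed = 56),
              Aprime = randomSequence(60, seed = 56),
              B = randomSequence(80, seed = 57))
    pos <- data.frame(first_id = c("A", "Aprime"), second_id = c("B", "B"),
                      label = "positive", stringsAsFactors = FALSE)
    ## above 1: nothing is ever removed
    expect_identical(nrow(redundancyFilter(pos, seqs, 1.0)$retained), 2L)
    ## at 0 every common-partner duplicate group collapses to one record
    expect_identical(nrow(redundancyFilter(pos, seqs, 0)$retained), 1L)
    expect_error(redundancyFilter(pos, seqs[-1]), "A")
})

test_that("interaction sets enforce ordering, uniqueness and class labels", {
    df <- data.frame(first_id = c("T2", "T1"), second_id = c("T1", "T3"),
                     label = c("positive", "negative"),
                     neg_class = c("none", "ppi"),
                     stringsAsFactors = FALSE)
    set <- makeInteractionSet(df)
    p <- interactionPairs(set)
    expect_true(all(p$first_id <= p$second_id))
    ## duplicates across labels are rejected
    dup <- data.frame(first_id = c("T1", "T2"), second_id = c("T2", "T1"),
                      label = c("positive", "negative"),
                      neg_class = c("none", "ppi"))
    expect_error(makeInteractionSet(dup), "duplicate")
    ## neg_class must track the label
    bad <- data.frame(first_id = "T1", second_id = "T2",
                      label = "positive", neg_class = "ppi")
    expect_error(makeInteractionSet(bad), "neg_class")
})
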
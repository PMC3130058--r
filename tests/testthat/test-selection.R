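## Stratified folds, cross-validated evaluation, wrapper forward selection.

test_that("stratified folds balance classes exactly when they divide evenly", {
    y <- rep(c("positive", "negative"), each = 10)
    fa <- makeStratifiedFolds(y, 10, seed = 3)
    for (i in 1:10) {
        expect_identical(sum(foldIndices(fa) == i & y == "positive"), 1L)
        expect_identical(sum(foldIndices(fa) == i & y == "negative"), 1L)
    }
})

test_that("fold assignment is deterministic and validates its inputs", {
    y <- rep(c("positive", "negative"), c(23, 31))
    a <- makeStratifiedFolds(y, 5, seed = 17)
    b <- makeStratifiedFolds(y, 5, seed = 17)
    expect_identical(foldIndices(a), foldIndices(b))
    expect_false(identical(foldIndices(a),
                           foldIndices(makeStratifiedFolds(y, 5, seed = 18))))
    ## per-class and overall size balance within 1
    for (cl in unique(y)) {
        sz <- tabulate(foldIndices(a)[y == cl], 5)
        expect_lte(max(sz) - min(sz), 1L)
    }
    expect_lte(max(tabulate(foldIndices(a), 5)) -
               min(tabulate(foldIndices(a), 5)), 1L)
    expect_error(makeStratifiedFolds(y, 1, seed = 1), "stratification")
    expect_error(makeStratifiedFolds(rep(c("p", "n"), c(3, 50)), 5, 1),
                 "smaller than k")
})

test_that("cv evaluation is deterministic and perfect on a separable feature", {
    set.seed(23)
    n <- 60
    X <- cbind(c(rnorm(n, -5, 0.3), rnorm(n, 5, 0.3)),
               rnorm(2 * n))
    y <- rep(c("negative", "positive"), each = n)
    folds <- makeStratifiedFolds(y, 5, seed = 2)
    r <- cvEvaluate(X, y, 1L, folds)
    expect_equal(r$mean[["accuracy"]], 100)
    r2 <- cvEvaluate(X, y, 1L, folds)
    expect_identical(r$perFold, r2$perFold)   # bitwise determinism
    expect_error(cvEvaluate(X, y, integer(0), folds), "non-empty")
})

test_that("destroyed labels give chance-level cv accuracy", {
    set.seed(29)
    n <- 250
    X <- matrix(rnorm(2 * n * 3), 2 * n, 3)
    y <- withr::with_seed(77, sample(rep(c("positive", "negative"), each = n)))
    folds <- makeStratifiedFolds(y, 10, seed = 5)
    r <- cvEvaluate(X, y, 1:3, folds)
    band <- 100 * qbinom(c(0.005, 0.995), 2 * n, 0.5) / (2 * n)
    expect_gte(r$mean[["accuracy"]], band[1])
    expect_lte(r$mean[["accuracy"]], band[2])
})

test_that("a dominant feature is selected first", {
    set.seed(37)
    n <- 40
    X <- cbind(matrix(rnorm(2 * n * 5), 2 * n, 5),
               c(rnorm(n, -6, 0.3), rnorm(n, 6, 0.3)))
    y <- rep(c("negative", "positive"), each = n)
    folds <- makeStratifiedFolds(y, 5, seed = 7)
    tr <- forwardSelect(X, y, folds, maxFeatures = 2)
    expect_identical(selectedFeatures(tr)[1], 6L)
})

test_that("step 1 equals the argmax of an exhaustive single-feature scan", {
    study <- smallStudy(seed = 13)
    X <- featurizePairs(study$interactions, study$sequences,
                        study$properties)
    y <- interactionPairs(study$interactions)$label
    folds <- makeStratifiedFolds(y, 5, seed = 11)
    pool <- seq_len(ncol(X))
    tr <- suppressWarnings(forwardSelect(X, y, folds, maxFeatures = 1,
                                         pool = pool))
    accs <- vapply(pool, function(f)
        suppressWarnings(cvEvaluate(X, y, f, folds))$mean[["accuracy"]],
        numeric(1))
    expect_identical(selectedFeatures(tr)[1], pool[which.max(accs)])
    expect_equal(tr@steps[[1]]$mean[["accuracy"]], max(accs))
})

test_that("trace metrics are bitwise reproducible from the recorded prefix", {
    study <- smallStudy(seed = 19)
    X <- featurizePairs(study$interactions, study$sequences,
                        study$properties)
    y <- interactionPairs(study$interactions)$label
    folds <- makeStratifiedFolds(y, 5, seed = 23)
    tr <- suppressWarnings(forwardSelect(X, y, folds, maxFeatures = 4,
                                         pool = seq_len(24)))
    sel <- selectedFeatures(tr)
    expect_identical(anyDuplicated(sel), 0L)
    for (t in seq_along(sel)) {
        re <- suppressWarnings(cvEvaluate(X, y, sel[seq_len(t)], folds))
        expect_identical(re$perFold, tr@steps[[t]]$perFold)
    }
    ## every step was evaluated under the identical fold partition
    expect_true(all(vapply(tr@steps, function(s) s$foldHash, character(1))
                    == folds@hash))
})

test_that("the best subset is the shortest maximal-accuracy prefix", {
    mkTrace <- function(accs) {
        steps <- lapply(seq_along(accs), function(i) {
            mn <- rep(NA_real_, 6)
            names(mn) <- TFIpred:::METRIC_NAMES
            mn[["accuracy"]] <- accs[i]
            list(feature = i * 10L, perFold = matrix(numeric(0), 0, 6),
                 mean = mn, foldHash = "h")
        })
        new("SelectionTrace", steps = steps,
            folds = makeStratifiedFolds(rep(c("a", "b"), each = 4), 2, 1),
            ridge = 1e-6,
            candidatePool = as.integer(seq_along(accs) * 10L),
            criterion = "accuracy",
            failedFits = data.frame())
    }
    expect_identical(bestSubset(mkTrace(c(70, 80, 90))), c(10L, 20L, 30L))
    expect_identical(bestSubset(mkTrace(c(80, 85, 85))), c(10L, 20L))
    set.seed(3)
    accs <- round(runif(8, 60, 95), 1)
    best <- bestSubset(mkTrace(accs))
    ## exhaustive prefix scan
    prefixBest <- which(accs == max(accs))[1]
    expect_identical(best, (seq_len(prefixBest)) * 10L)
})

test_that("trace export mirrors the per-step layout", {
    study <- smallStudy(seed = 29)
    X <- featurizePairs(study$interactions, study$sequences,
                        study$properties)
    y <- interactionPairs(study$interactions)$label
    folds <- makeStratifiedFolds(y, 5, seed = 31)
    tr <- suppressWarnings(forwardSelect(X, y, folds, maxFeatures = 2,
                                         pool = seq_len(12)))
    f <- withr::local_tempfile(fileext = ".tsv")
    fj <- withr::local_tempfile(fileext = ".json")
    writeTrace(tr, f, table = study$properties, jsonFile = fj)
    df <- read.delim(f)
    expect_identical(nrow(df), 2L)
    expect_identical(df$feature, selectedFeatures(tr))
    expect_true(all(c("member", "segment", "accession", "mean") %in%
                    names(df)))
    js <- jsonlite::read_json(fj, simplifyVector = TRUE)
    expect_identical(as.integer(js$steps$feature), selectedFeatures(tr))
})
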
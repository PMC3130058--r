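#' Deterministic stratified k-fold assignment
#'
#' Within every class the (shuffled) samples are dealt round-robin over the
#' k folds, and each class starts dealing where the previous class's
#' remainder stopped, so fold sizes differ by at most one both per class
#' and overall. The assignment is a pure function of (labels, k, seed).
#'
#' @param labels class label vector.
#' @param k number of folds (>= 2; every class must have at least k
#'   samples).
#' @param seed integer seed.
#' @return a \code{\linkS4class{FoldAssignment}}.
#' @examples
#' foldIndices(makeStratifiedFolds(rep(c("p", "n"), each = 10), 10, 1))
#' @export
makeStratifiedFolds <- function(labels, k, seed) {
    labels <- as.character(labels)
    if (length(k) != 1L || k < 2L)
        stop("stratification error: k must be a single integer >= 2")
    k <- as.integer(k)
    classes <- sort(unique(labels))
    sizes <- table(labels)
    small <- names(sizes)[sizes < k]
    if (length(small))
        stop("stratification error: class(es) smaller than k: ",
             paste(small, collapse = ", "))
    fold <- integer(length(labels))
    offset <- 0L
    withSeed(seed, {
        for (cl in classes) {
            idx <- which(labels == cl)
            idx <- idx[sample.int(length(idx))]
            fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
            offset <- (offset + length(idx)) %% k
        }
    })
    new("FoldAssignment", fold = fold, k = k, seed = as.integer(seed),
        hash = foldHash(fold, k, seed))
}

foldHash <- function(fold, k, seed) {
    ## compact deterministic fingerprint of the partition
    x <- c(k, seed, fold)
    sprintf("%d:%d:%.0f:%.0f", k, as.integer(seed),
            sum(x * seq_along(x)) %% 1e9,
            sum(x * rev(seq_along(x))) %% 1e9)
}

#' Cross-validated evaluation of one feature subset
#'
#' For every fold, fits QDA on the out-of-fold samples restricted to the
#' given feature columns and computes the six performance measures on the
#' held-out fold. Entirely deterministic given its inputs.
#'
#' @param X numeric matrix, samples x features (full pair-vector matrix).
#' @param y binary label vector ("positive"/"negative" by convention; the
#'   label named by \code{positive} is scored as the positive class).
#' @param features integer column indices of the subset to evaluate.
#' @param folds a \code{\linkS4class{FoldAssignment}} covering the rows of
#'   \code{X}.
#' @param ridge relative covariance regularization passed to
#'   \code{\link{fitQDA}}.
#' @param positive the positive-class label.
#' @return list with \code{perFold} (k x 6 metric matrix) and \code{mean}
#'   (named numeric: component-wise fold mean, undefined values excluded
#'   with a warning).
#' @export
cvEvaluate <- function(X, y, features, folds, ridge = 1e-6,
                       positive = "positive") {
    stopifnot(is(folds, "FoldAssignment"))
    if (length(features) == 0L) stop("feature subset must be non-empty")
    if (length(foldIndices(folds)) != nrow(X))
        stop("fold assignment does not cover the samples")
    y <- as.character(y)
    k <- foldCount(folds)
    fold <- foldIndices(folds)
    perFold <- matrix(NA_real_, k, length(METRIC_NAMES),
                      dimnames = list(NULL, METRIC_NAMES))
    Xs <- X[, features, drop = FALSE]
    for (i in seq_len(k)) {
        test <- fold == i
        fit <- tryCatch(
            fitQDA(Xs[!test, , drop = FALSE], y[!test], ridge = ridge),
            error = function(e)
                stop(sprintf("fold %d: %s", i, conditionMessage(e)),
                     call. = FALSE))
        pred <- predict(fit, Xs[test, , drop = FALSE])
        perFold[i, ] <- metricSet(confusionCounts(y[test], pred,
                                                  positive = positive))
    }
    list(perFold = perFold, mean = foldMeanMetrics(perFold))
}

#' Wrapper forward feature selection under preserved folds
#'
#' Greedy selection: at each step every not-yet-selected candidate is
#' appended to the current feature list and scored by
#' \code{\link{cvEvaluate}} under one fixed fold partition (identical
#' across all steps and candidates); the candidate with the highest mean
#' criterion is kept, ties breaking toward the lowest column index. A
#' candidate whose QDA fit fails on any fold is scored as criterion 0 and
#' logged rather than aborting the search. Selection stops after
#' \code{maxFeatures} steps.
#'
#' @inheritParams cvEvaluate
#' @param maxFeatures maximum number of features to select (reference
#'   protocol: up to 150).
#' @param pool integer vector of candidate columns (default: all columns
#'   of \code{X}); restricting the pool keeps the quadratic-cost loop
#'   tractable.
#' @param criterion metric the wrapper maximises: "accuracy" (default) or
#'   "f_measure".
#' @return a \code{\linkS4class{SelectionTrace}}.
#' @export
forwardSelect <- function(X, y, folds, maxFeatures = 150L, ridge = 1e-6,
                          pool = seq_len(ncol(X)),
                          criterion = c("accuracy", "f_measure"),
                          positive = "positive") {
    criterion <- match.arg(criterion)
    pool <- as.integer(pool)
    stopifnot(is(folds, "FoldAssignment"))
    if (maxFeatures > length(pool))
        stop("maxFeatures exceeds the candidate pool size")
    selected <- integer(0)
    steps <- list()
    failed <- list()
    for (step in seq_len(maxFeatures)) {
        remaining <- setdiff(pool, selected)
        best <- NULL; bestScore <- -Inf; bestFeature <- NA_integer_
        for (f in remaining) {   # remaining is ascending: first max wins ties
            res <- tryCatch(
                cvEvaluate(X, y, c(selected, f), folds, ridge = ridge,
                           positive = positive),
                error = function(e) e)
            if (inherits(res, "error")) {
                ## failed fits are scored as criterion 0 and logged, not fatal
                failed[[length(failed) + 1L]] <- data.frame(
                    step = step, feature = f,
                    message = conditionMessage(res),
                    stringsAsFactors = FALSE)
                pf <- matrix(NA_real_, foldCount(folds),
                             length(METRIC_NAMES),
                             dimnames = list(NULL, METRIC_NAMES))
                mn <- rep(NA_real_, length(METRIC_NAMES))
                names(mn) <- METRIC_NAMES
                mn[[criterion]] <- 0
                res <- list(perFold = pf, mean = mn)
            }
            score <- res$mean[[criterion]]
            if (is.na(score)) score <- 0
            if (score > bestScore) {
                bestScore <- score; bestFeature <- f; best <- res
            }
        }
        selected <- c(selected, bestFeature)
        steps[[step]] <- list(feature = bestFeature, perFold = best$perFold,
                              mean = best$mean, foldHash = folds@hash)
    }
    failedDf <- if (length(failed)) do.call(rbind, failed)
        else data.frame(step = integer(0), feature = integer(0),
                        message = character(0), stringsAsFactors = FALSE)
    new("SelectionTrace", steps = steps, folds = folds, ridge = ridge,
        candidatePool = pool, criterion = criterion, failedFits = failedDf)
}

#' Best feature subset of a selection trace
#'
#' Returns the prefix of selected features whose mean cross-validation
#' criterion is maximal; among ties, the shortest prefix (the most
#' parsimonious model of equal performance).
#'
#' @param trace a \code{\linkS4class{SelectionTrace}}.
#' @return integer vector of feature columns (a prefix of
#'   \code{selectedFeatures(trace)}).
#' @export
bestSubset <- function(trace) {
    stopifnot(is(trace, "SelectionTrace"))
    if (length(trace@steps) == 0L) stop("empty selection trace")
    crit <- vapply(trace@steps, function(s) {
        v <- s$mean[[trace@criterion]]
        if (is.na(v)) 0 else v
    }, numeric(1))
    selectedFeatures(trace)[seq_len(which.max(crit))]
}

#' Export a selection trace
#'
#' Writes one TSV row per step (step number, feature column and its
#' member/segment/property triple if a table is supplied, per-fold and
#' mean criterion values), optionally plus a JSON dump of the full trace.
#'
#' @param trace a \code{\linkS4class{SelectionTrace}}.
#' @param file TSV path or connection.
#' @param table optional \code{\linkS4class{AAPropertyTable}} used to
#'   annotate feature columns.
#' @param jsonFile optional path for a JSON version.
#' @return the TSV data.frame, invisibly.
#' @export
writeTrace <- function(trace, file, table = NULL, jsonFile = NULL) {
    stopifnot(is(trace, "SelectionTrace"))
    k <- foldCount(trace@folds)
    rows <- lapply(seq_along(trace@steps), function(i) {
        s <- trace@steps[[i]]
        pf <- s$perFold[, trace@criterion]
        r <- data.frame(step = i, feature = s$feature)
        if (!is.null(table))
            r <- cbind(r, featureAnnotation(table, s$feature)[
                c("member", "segment", "property", "accession")])
        pfDf <- as.data.frame(as.list(pf))
        names(pfDf) <- paste0("fold", seq_len(k))
        cbind(r, pfDf, mean = s$mean[[trace@criterion]])
    })
    df <- do.call(rbind, rows)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(jsonFile)) {
        obj <- list(criterion = trace@criterion, ridge = trace@ridge,
                    fold_hash = trace@folds@hash,
                    candidate_pool = trace@candidatePool,
                    steps = lapply(trace@steps, function(s)
                        list(feature = s$feature,
                             per_fold = unname(s$perFold[, trace@criterion]),
                             mean = unname(s$mean))))
        jsonlite::write_json(obj, jsonFile, digits = NA, auto_unbox = TRUE)
    }
    invisible(df)
}
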
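#' Fit a quadratic discriminant analysis model
#'
#' Each class is fit as a Gaussian with its own sample mean and unbiased
#' sample covariance; priors are the empirical class frequencies. Every
#' class covariance receives the same relative ridge,
#' \code{ridge * tr(Sigma_pooled)/d}, added to the diagonal (the pooled
#' within-class covariance sets the scale, so regularization does not
#' favour the class with the smaller spread and, as the ridge grows, the
#' decision rule degrades gracefully towards nearest-class-mean-with-
#' prior). A class covariance that is not positive definite after
#' regularization raises an error naming the class.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (factor or vector); at least two classes with at
#'   least two samples each.
#' @param ridge relative regularization, nonnegative (default 1e-6).
#' @param featureIndices optional integer vector recording which
#'   pair-vector columns \code{X} holds, stored in the model.
#' @param featureAnnotation optional data.frame annotating those columns.
#' @param massConvention tag of the molecular-weight convention behind the
#'   pair ordering of the features.
#' @return a \code{\linkS4class{QDAModel}}.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' fitQDA(X, rep(c("a", "b"), each = 20))
#' @export
fitQDA <- function(X, y, ridge = 1e-6, featureIndices = integer(0),
                   featureAnnotation = data.frame(),
                   massConvention = MASS_CONVENTION) {
    X <- as.matrix(X)
    if (!is.numeric(X)) stop("X must be numeric")
    if (nrow(X) != length(y)) stop("length(y) must equal nrow(X)")
    if (ridge < 0) stop("ridge must be nonnegative")
    labels <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
    labels <- as.character(labels)
    y <- as.character(y)
    if (length(labels) < 2L) stop("need at least 2 classes")
    d <- ncol(X)
    if (d < 1L) stop("need at least one feature")
    means <- covs <- chols <- vector("list", length(labels))
    nk <- numeric(length(labels))
    for (i in seq_along(labels)) {
        Xi <- X[y == labels[i], , drop = FALSE]
        nk[i] <- nrow(Xi)
        if (nk[i] < 2L)
            stop(sprintf("class '%s' has %d sample(s); need at least 2",
                         labels[i], nk[i]))
        means[[i]] <- colMeans(Xi)
        S <- stats::cov(Xi)
        covs[[i]] <- (S + t(S)) / 2
    }
    ## shared ridge scale from the pooled within-class covariance trace
    pooledTr <- sum(vapply(seq_along(labels), function(i)
        (nk[i] - 1) * sum(diag(covs[[i]])), numeric(1))) /
        (sum(nk) - length(labels))
    for (i in seq_along(labels)) {
        S <- covs[[i]]
        if (ridge > 0)
            S <- S + diag(ridge * pooledTr / d, d)
        R <- tryCatch(chol(S), error = function(e) NULL)
        ## chol can numerically succeed on a rank-deficient matrix with
        ## near-zero pivots; reject those too
        tol <- d * .Machine$double.eps * max(diag(S), 0)
        if (is.null(R) || any(diag(R)^2 <= tol))
            stop(sprintf("covariance of class '%s' is singular (n_k = %d, d = %d, ridge = %g)",
                         labels[i], nk[i], d, ridge))
        covs[[i]] <- S; chols[[i]] <- R
    }
    new("QDAModel", classLabels = labels, means = means, covariances = covs,
        chol = chols, logPriors = log(nk / sum(nk)), ridge = ridge,
        featureIndices = as.integer(featureIndices),
        featureAnnotation = featureAnnotation,
        massConvention = massConvention)
}

#' Per-class QDA discriminant scores
#'
#' For each class k returns
#' \code{-log det(Sigma_k)/2 - (x - mu_k)' Sigma_k^{-1} (x - mu_k)/2 +
#' log pi_k}, which equals the log joint density up to the class-
#' independent \code{-d log(2 pi)/2}. Computed through the stored Cholesky
#' factors (triangular solves, no explicit inverse).
#'
#' @param model a \code{\linkS4class{QDAModel}}.
#' @param X numeric vector (one sample) or matrix (samples x features)
#'   whose dimension matches the model.
#' @return numeric matrix, samples x classes, with class labels as column
#'   names.
#' @export
qdaScores <- function(model, X) {
    stopifnot(is(model, "QDAModel"))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    X <- as.matrix(X)
    d <- length(model@means[[1L]])
    if (ncol(X) != d)
        stop(sprintf("dimension mismatch: model has %d features, data has %d",
                     d, ncol(X)))
    K <- length(model@classLabels)
    out <- matrix(NA_real_, nrow(X), K,
                  dimnames = list(rownames(X), model@classLabels))
    for (k in seq_len(K)) {
        R <- model@chol[[k]]
        logdet <- 2 * sum(log(diag(R)))
        centered <- t(X) - model@means[[k]]
        z <- backsolve(R, centered, transpose = TRUE)
        maha <- colSums(z * z)
        out[, k] <- -0.5 * logdet - 0.5 * maha + model@logPriors[k]
    }
    out
}

#' Predict class labels with a QDA model
#'
#' Rows are assigned to the class with the highest discriminant score;
#' exact ties go to the earlier label in \code{classLabels}.
#'
#' @param object a \code{\linkS4class{QDAModel}}.
#' @param newdata numeric matrix or vector with matching dimension.
#' @param ... ignored.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "QDAModel", function(object, newdata, ...) {
    sc <- qdaScores(object, newdata)
    object@classLabels[max.col(sc, ties.method = "first")]
})

#' Serialize a QDA model to JSON
#'
#' Writes labels, means, covariances, log-priors, ridge, the feature
#' annotation triples and the molecular-weight convention in a fixed field
#' order at full precision; \code{readQDAModel} restores the model
#' (re-deriving the Cholesky factors).
#'
#' @param model a \code{\linkS4class{QDAModel}}.
#' @param file path for the JSON document.
#' @return \code{file}, invisibly.
#' @export
writeQDAModel <- function(model, file) {
    stopifnot(is(model, "QDAModel"))
    obj <- list(
        class_labels = model@classLabels,
        means = lapply(model@means, unname),
        covariances = lapply(model@covariances, unname),
        log_priors = unname(model@logPriors),
        ridge = model@ridge,
        feature_indices = model@featureIndices,
        feature_annotation = model@featureAnnotation,
        mass_convention = model@massConvention)
    jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
    invisible(file)
}

#' @rdname writeQDAModel
#' @export
readQDAModel <- function(file) {
    obj <- jsonlite::read_json(file, simplifyVector = TRUE)
    covs <- lapply(seq_along(obj$class_labels), function(k) {
        S <- obj$covariances
        if (is.list(S)) as.matrix(S[[k]]) else matrix(S[k, , ], dim(S)[2L])
    })
    means <- if (is.list(obj$means)) lapply(obj$means, as.numeric)
             else lapply(seq_len(nrow(obj$means)), function(i)
                 as.numeric(obj$means[i, ]))
    ann <- if (is.null(obj$feature_annotation)) data.frame()
           else as.data.frame(obj$feature_annotation)
    new("QDAModel", classLabels = obj$class_labels, means = means,
        covariances = covs, chol = lapply(covs, chol),
        logPriors = as.numeric(obj$log_priors), ridge = obj$ridge,
        featureIndices = as.integer(obj$feature_indices %||% integer(0)),
        featureAnnotation = ann,
        massConvention = obj$mass_convention)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
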
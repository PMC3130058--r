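#' AAPropertyTable: an ordered collection of amino-acid property scales
#'
#' Holds one row per AAIndex1 scale and one column per standard residue
#' (alphabetical one-letter order). Values may be \code{NA} directly after
#' parsing; \code{\link{filterComplete}} retains the scales defined for all
#' 20 residues, which is the invariant the feature machinery relies on.
#' Row order is the file order of the source and is never changed by
#' filtering, so feature indices are stable across parses.
#'
#' @slot values numeric matrix, scales x 20 residues; rownames are the
#'   accessions, colnames the one-letter residue codes.
#' @slot description character vector of free-text scale descriptions,
#'   parallel to the rows of \code{values}.
#'
#' @seealso \code{\link{parseAAIndex1}}, \code{\link{filterComplete}},
#'   \code{\link{genPropertyTable}}
#' @export
setClass("AAPropertyTable",
    representation(values = "matrix", description = "character"))

setValidity("AAPropertyTable", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if (ncol(v) != 20L || !identical(colnames(v), AA20))
        msg <- c(msg, "values must have the 20 standard residues as columns")
    acc <- rownames(v)
    if (nrow(v) > 0L && (is.null(acc) || any(!nzchar(acc))))
        msg <- c(msg, "every entry needs a non-empty accession")
    if (anyDuplicated(acc))
        msg <- c(msg, "accessions must be unique")
    if (length(object@description) != nrow(v))
        msg <- c(msg, "description must be parallel to the entries")
    if (length(msg)) msg else TRUE
})

#' TFInteractionSet: a labelled, duplicate-free set of TF pairs
#'
#' Records positive (known) and negative (presumed non-interacting) TF
#' pairs over a universe of TF identifiers with available sequences. Pair
#' records are stored with the lexicographically smaller identifier first,
#' which makes duplicate detection and positive/negative disjointness
#' well-defined; the molecular-weight ordering that makes the *feature*
#' representation of a pair unique is applied later, by
#' \code{\link{featurizePair}}.
#'
#' @slot pairs data.frame with columns \code{first_id}, \code{second_id},
#'   \code{label} ("positive"/"negative"), \code{neg_class} ("none",
#'   "absolute", "partial", "ppi") and \code{mi_type} (PSI-MI code or
#'   \code{NA}).
#' @slot universe character vector of TF identifiers the records may draw
#'   from.
#'
#' @seealso \code{\link{generateNegatives}}, \code{\link{redundancyFilter}}
#' @export
setClass("TFInteractionSet",
    representation(pairs = "data.frame", universe = "character"))

setValidity("TFInteractionSet", function(object) {
    p <- object@pairs
    msg <- character()
    need <- c("first_id", "second_id", "label", "neg_class", "mi_type")
    if (!all(need %in% names(p)))
        return(paste("pairs must have columns:", paste(need, collapse = ", ")))
    if (!all(p$label %in% c("positive", "negative")))
        msg <- c(msg, "label must be 'positive' or 'negative'")
    if (!all(p$neg_class %in% c("none", "absolute", "partial", "ppi")))
        msg <- c(msg, "unknown neg_class value")
    if (any((p$neg_class == "none") != (p$label == "positive")))
        msg <- c(msg, "neg_class must be 'none' exactly for positives")
    ids <- unique(c(p$first_id, p$second_id))
    if (!all(ids %in% object@universe))
        msg <- c(msg, "all pair members must belong to the universe")
    if (any(p$first_id > p$second_id))
        msg <- c(msg, "records must be ordered first_id <= second_id")
    if (anyDuplicated(pairKey(p$first_id, p$second_id)))
        msg <- c(msg, "duplicate canonical pairs are not allowed")
    if (length(msg)) msg else TRUE
})

#' FoldAssignment: a preserved stratified cross-validation partition
#'
#' A deterministic function of (labels, k, seed): within every class the
#' samples are spread across the k folds as evenly as possible, and class
#' remainders are rotated so overall fold sizes also differ by at most one.
#' The same object is reused for every candidate evaluation during wrapper
#' selection, so all candidates are compared on identical partitions.
#'
#' @slot fold integer vector, fold index in 1..k per sample.
#' @slot k integer fold count.
#' @slot seed integer seed the assignment was drawn with.
#' @slot hash character fingerprint of (k, seed, fold), recorded into every
#'   selection step to assert fold preservation.
#'
#' @seealso \code{\link{makeStratifiedFolds}}, \code{\link{forwardSelect}}
#' @export
setClass("FoldAssignment",
    representation(fold = "integer", k = "integer", seed = "integer",
                   hash = "character"))

setValidity("FoldAssignment", function(object) {
    msg <- character()
    if (length(object@k) != 1L || object@k < 2L)
        msg <- c(msg, "k must be a single integer >= 2")
    if (any(object@fold < 1L) || any(object@fold > object@k))
        msg <- c(msg, "fold indices must lie in 1..k")
    sizes <- tabulate(object@fold, nbins = object@k)
    if (max(sizes) - min(sizes) > 1L)
        msg <- c(msg, "fold sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' QDAModel: per-class Gaussian fit for quadratic discriminant analysis
#'
#' Class k is modelled as N(mu_k, Sigma_k) with empirical prior pi_k;
#' scoring uses log pi_k - (log det Sigma_k)/2 - Mahalanobis^2/2 via a
#' Cholesky solve. Covariances carry a relative ridge
#' (\code{ridge * tr(Sigma)/d} added to the diagonal) so near-singular
#' folds remain classifiable.
#'
#' @slot classLabels character, class order (ties in prediction break
#'   toward the earlier label).
#' @slot means list of per-class mean vectors (length d).
#' @slot covariances list of per-class regularized d x d covariances.
#' @slot chol list of upper-triangular Cholesky factors of the covariances.
#' @slot logPriors numeric per-class log prior probabilities.
#' @slot ridge numeric, relative ridge used at fit time.
#' @slot featureIndices integer, the pair-vector columns the model was fit
#'   on (empty means plain column order of the training matrix).
#' @slot featureAnnotation data.frame annotating those columns (member,
#'   segment, property accession), possibly with zero rows.
#' @slot massConvention character tag naming the molecular-weight table
#'   used for pair ordering when the features were built.
#'
#' @seealso \code{\link{fitQDA}}, \code{\link{qdaScores}}
#' @export
setClass("QDAModel",
    representation(classLabels = "character", means = "list",
                   covariances = "list", chol = "list",
                   logPriors = "numeric", ridge = "numeric",
                   featureIndices = "integer",
                   featureAnnotation = "data.frame",
                   massConvention = "character"))

setValidity("QDAModel", function(object) {
    K <- length(object@classLabels)
    msg <- character()
    if (K < 2L) msg <- c(msg, "need at least 2 classes")
    if (length(object@means) != K || length(object@covariances) != K ||
        length(object@logPriors) != K)
        msg <- c(msg, "means, covariances and logPriors must be per-class")
    if (abs(sum(exp(object@logPriors)) - 1) > 1e-8)
        msg <- c(msg, "exp(logPriors) must sum to 1")
    for (S in object@covariances) {
        if (!isSymmetric(unname(S), tol = 1e-8)) {
            msg <- c(msg, "covariances must be symmetric")
            break
        }
    }
    if (length(object@ridge) != 1L || object@ridge < 0)
        msg <- c(msg, "ridge must be a single nonnegative number")
    if (length(msg)) msg else TRUE
})

#' SelectionTrace: the ordered record of wrapper forward selection
#'
#' One element of \code{steps} per accepted feature: the feature (pair-
#' vector column), its per-fold metric sets and their component-wise mean,
#' and the fold-assignment fingerprint under which it was evaluated. The
#' trace never repeats a feature and is capped at the configured maximum.
#'
#' @slot steps list; each element has \code{feature} (integer column),
#'   \code{perFold} (k x 6 metric matrix), \code{mean} (named numeric of 6)
#'   and \code{foldHash} (character).
#' @slot folds the \code{\linkS4class{FoldAssignment}} shared by all steps.
#' @slot ridge numeric ridge used for every candidate fit.
#' @slot candidatePool integer, the columns that were eligible.
#' @slot criterion character, the metric the wrapper maximised.
#' @slot failedFits data.frame logging candidates whose QDA fit failed
#'   (scored as criterion 0, never fatal).
#'
#' @seealso \code{\link{forwardSelect}}, \code{\link{bestSubset}}
#' @export
setClass("SelectionTrace",
    representation(steps = "list", folds = "FoldAssignment",
                   ridge = "numeric", candidatePool = "integer",
                   criterion = "character", failedFits = "data.frame"))

setValidity("SelectionTrace", function(object) {
    feats <- vapply(object@steps, function(s) s$feature, integer(1))
    msg <- character()
    if (anyDuplicated(feats))
        msg <- c(msg, "a feature may not be selected twice")
    if (!all(feats %in% object@candidatePool))
        msg <- c(msg, "selected features must come from the candidate pool")
    if (length(msg)) msg else TRUE
})
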
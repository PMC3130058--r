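#' @rdname AAPropertyTable-class
#' @param object,x an object of the documented class
#' @export
setGeneric("accessions", function(object) standardGeneric("accessions"))

#' @rdname AAPropertyTable-class
#' @export
setMethod("accessions", "AAPropertyTable",
    function(object) rownames(object@values))

#' @rdname AAPropertyTable-class
#' @export
setGeneric("descriptions", function(object) standardGeneric("descriptions"))

#' @rdname AAPropertyTable-class
#' @export
setMethod("descriptions", "AAPropertyTable", function(object) {
    d <- object@description
    names(d) <- rownames(object@values)
    d
})

#' @rdname AAPropertyTable-class
#' @export
setGeneric("propertyValues", function(object) standardGeneric("propertyValues"))

#' @rdname AAPropertyTable-class
#' @export
setMethod("propertyValues", "AAPropertyTable", function(object) object@values)

#' @rdname AAPropertyTable-class
#' @export
setMethod("length", "AAPropertyTable", function(x) nrow(x@values))

#' @rdname AAPropertyTable-class
#' @param i index (integer, logical or accession character) of scales to keep
#' @param j,...,drop ignored
#' @export
setMethod("[", "AAPropertyTable", function(x, i, j, ..., drop = FALSE) {
    new("AAPropertyTable", values = x@values[i, , drop = FALSE],
        description = x@description[if (is.character(i))
            match(i, rownames(x@values)) else i])
})

#' @rdname AAPropertyTable-class
#' @export
setMethod("show", "AAPropertyTable", function(object) {
    n <- nrow(object@values)
    nc <- sum(stats::complete.cases(object@values))
    cat("AAPropertyTable with", n, "scales (", nc, "complete )\n")
    if (n > 0L)
        cat("  accessions:", paste(head(rownames(object@values), 4L),
            collapse = ", "), if (n > 4L) "..." else "", "\n")
})

#' @rdname TFInteractionSet-class
#' @param object,x a \code{TFInteractionSet}
#' @export
setGeneric("interactionPairs",
    function(object) standardGeneric("interactionPairs"))

#' @rdname TFInteractionSet-class
#' @export
setMethod("interactionPairs", "TFInteractionSet", function(object) object@pairs)

#' @rdname TFInteractionSet-class
#' @export
setGeneric("universe", function(object) standardGeneric("universe"))

#' @rdname TFInteractionSet-class
#' @export
setMethod("universe", "TFInteractionSet", function(object) object@universe)

#' @rdname TFInteractionSet-class
#' @export
setMethod("length", "TFInteractionSet", function(x) nrow(x@pairs))

#' @rdname TFInteractionSet-class
#' @export
setMethod("show", "TFInteractionSet", function(object) {
    p <- object@pairs
    cat("TFInteractionSet:", nrow(p), "pairs over",
        length(object@universe), "TFs\n")
    cat("  positives:", sum(p$label == "positive"), "\n")
    neg <- table(factor(p$neg_class[p$label == "negative"],
                        levels = c("absolute", "partial", "ppi")))
    cat("  negatives:", sum(p$label == "negative"),
        sprintf("(absolute %d, partial %d, ppi %d)\n",
                neg[["absolute"]], neg[["partial"]], neg[["ppi"]]))
})

#' @rdname FoldAssignment-class
#' @param object,x a \code{FoldAssignment}
#' @export
setGeneric("foldIndices", function(object) standardGeneric("foldIndices"))

#' @rdname FoldAssignment-class
#' @export
setMethod("foldIndices", "FoldAssignment", function(object) object@fold)

#' @rdname FoldAssignment-class
#' @export
setGeneric("foldCount", function(object) standardGeneric("foldCount"))

#' @rdname FoldAssignment-class
#' @export
setMethod("foldCount", "FoldAssignment", function(object) object@k)

#' @rdname FoldAssignment-class
#' @export
setMethod("show", "FoldAssignment", function(object) {
    cat("FoldAssignment:", length(object@fold), "samples in", object@k,
        "folds (seed", paste0(object@seed, ")"), "\n")
})

#' @rdname QDAModel-class
#' @param object,x a \code{QDAModel}
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname QDAModel-class
#' @export
setMethod("classLabels", "QDAModel", function(object) object@classLabels)

#' @rdname QDAModel-class
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))

#' @rdname QDAModel-class
#' @export
setMethod("classMeans", "QDAModel", function(object) object@means)

#' @rdname QDAModel-class
#' @export
setGeneric("classCovariances",
    function(object) standardGeneric("classCovariances"))

#' @rdname QDAModel-class
#' @export
setMethod("classCovariances", "QDAModel", function(object) object@covariances)

#' @rdname QDAModel-class
#' @export
setGeneric("featureIndices", function(object) standardGeneric("featureIndices"))

#' @rdname QDAModel-class
#' @export
setMethod("featureIndices", "QDAModel", function(object) object@featureIndices)

#' @rdname QDAModel-class
#' @export
setMethod("show", "QDAModel", function(object) {
    cat("QDAModel:", length(object@classLabels), "classes, dimension",
        length(object@means[[1L]]), "\n")
    cat("  classes:", paste(object@classLabels, collapse = ", "),
        " priors:", paste(signif(exp(object@logPriors), 3), collapse = ", "),
        "\n")
    cat("  ridge:", object@ridge, "\n")
})

#' @rdname SelectionTrace-class
#' @param object,x a \code{SelectionTrace}
#' @export
setGeneric("selectedFeatures",
    function(object) standardGeneric("selectedFeatures"))

#' @rdname SelectionTrace-class
#' @export
setMethod("selectedFeatures", "SelectionTrace", function(object)
    vapply(object@steps, function(s) s$feature, integer(1)))

#' @rdname SelectionTrace-class
#' @export
setGeneric("traceTable", function(object) standardGeneric("traceTable"))

#' Flatten a selection trace to one row per step
#'
#' @return data.frame with the step number, the selected feature column and
#'   the mean cross-validation metrics after adding it.
#' @rdname SelectionTrace-class
#' @export
setMethod("traceTable", "SelectionTrace", function(object) {
    if (length(object@steps) == 0L)
        return(data.frame(step = integer(), feature = integer()))
    means <- do.call(rbind, lapply(object@steps, function(s) s$mean))
    data.frame(step = seq_along(object@steps),
               feature = selectedFeatures(object), means,
               row.names = NULL)
})

#' @rdname SelectionTrace-class
#' @export
setMethod("length", "SelectionTrace", function(x) length(x@steps))

#' @rdname SelectionTrace-class
#' @export
setMethod("show", "SelectionTrace", function(object) {
    cat("SelectionTrace:", length(object@steps), "steps over a pool of",
        length(object@candidatePool), "features (criterion:",
        paste0(object@criterion, ")"), "\n")
    if (length(object@steps)) {
        acc <- vapply(object@steps, function(s) s$mean[[object@criterion]],
                      numeric(1))
        cat("  best mean", object@criterion, ":", sprintf("%.2f", max(acc)),
            "at step", which.max(acc), "\n")
    }
})
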
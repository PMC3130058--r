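#' Featurize a pair table into matrix files
#'
#' Reads the pair table, sequences and property file (or takes the
#' corresponding in-memory objects), builds the pair feature matrix under
#' canonical molecular-weight ordering, and writes it as TSV with a
#' sidecar JSON of the feature annotation.
#'
#' @param pairs data.frame / \code{TFInteractionSet} or path to a pair
#'   TSV (see \code{\link{readPairTable}}).
#' @param sequences named \code{AAStringSet} / character vector or path to
#'   a FASTA file.
#' @param properties \code{\linkS4class{AAPropertyTable}} or path to an
#'   AAIndex1 file (incomplete scales are dropped).
#' @param outPrefix path prefix; writes \code{<prefix>_features.tsv} and
#'   \code{<prefix>_annotation.json}. \code{NULL} skips writing.
#' @return list with \code{X} (pairs x 6P matrix), \code{annotation}
#'   (data.frame) and \code{files} (written paths, if any).
#' @export
runFeaturize <- function(pairs, sequences, properties, outPrefix = NULL) {
    if (is.character(pairs)) pairs <- readPairTable(pairs)
    if (is(pairs, "TFInteractionSet")) pairs <- interactionPairs(pairs)
    sequences <- asSequences(sequences)
    if (is.character(properties))
        properties <- filterComplete(parseAAIndex1(properties))
    X <- featurizePairs(pairs, sequences, properties)
    ann <- featureAnnotation(properties)
    files <- character(0)
    if (!is.null(outPrefix)) {
        ftsv <- paste0(outPrefix, "_features.tsv")
        fjson <- paste0(outPrefix, "_annotation.json")
        write.table(data.frame(pair = rownames(X), X, check.names = FALSE),
                    ftsv, sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(ann, fjson, digits = NA, auto_unbox = TRUE)
        files <- c(features = ftsv, annotation = fjson)
    }
    list(X = X, annotation = ann, files = files)
}

#' Read protein sequences from FASTA
#'
#' Names are truncated at the first whitespace (the id token).
#'
#' @param file FASTA path.
#' @return named \code{AAStringSet}.
#' @export
readSequences <- function(file) {
    s <- Biostrings::readAAStringSet(file)
    names(s) <- sub("[[:space:]].*$", "", names(s))
    s
}

## Accept sequences as a FASTA path, a named character vector, or an
## AAStringSet; a length-1 unnamed character that names an existing file
## is treated as a path.
asSequences <- function(x) {
    if (is.character(x)) {
        if (length(x) == 1L && is.null(names(x)) && file.exists(x))
            return(readSequences(x))
        if (is.null(names(x)))
            stop("character sequences must be named by TF id")
        return(Biostrings::AAStringSet(x))
    }
    x
}

#' Run the full training pipeline
#'
#' Stages, each logged with input/output counts: PSI-MI type filter on the
#' positive records; sequence-identity redundancy filter on the positives;
#' merge with the negative records; featurization; stratified split into
#' k + 1 groups, the last held out as a completely blind set; wrapper
#' forward selection with 10-fold (k-fold) cross-validation on the other
#' k groups under one preserved fold partition; final QDA fit on all k
#' groups restricted to the best subset; evaluation on the blind group.
#'
#' @inheritParams runFeaturize
#' @param interactions labelled pairs: \code{TFInteractionSet}, data.frame
#'   (columns \code{first_id}, \code{second_id}, \code{label}, optional
#'   \code{neg_class}, \code{mi_type}) or TSV path.
#' @param allowedMITypes PSI-MI codes admissible for positive records;
#'   \code{NULL} disables the type filter (negatives are never filtered:
#'   they carry no evidence code by construction).
#' @param identityThreshold redundancy-filter identity threshold;
#'   \code{NULL} disables the filter.
#' @param k cross-validation fold count (default 10; the data are split
#'   into k + 1 groups).
#' @param maxFeatures wrapper step cap (default 150, reduced automatically
#'   to the pool size).
#' @param ridge QDA covariance regularization.
#' @param pool optional integer vector restricting the candidate feature
#'   columns; \code{poolSize} instead draws that many columns at random
#'   (seeded) from all 6P.
#' @param poolSize optional size of a random candidate pool.
#' @param criterion wrapper selection metric ("accuracy" or "f_measure").
#' @param seed integer root seed (fold split and pool draw).
#' @param outDir optional directory: writes the trace TSV/JSON, the model
#'   JSON, the per-fold metrics report, the blind-set report and the
#'   effective configuration.
#' @return list: \code{trace} (\code{\linkS4class{SelectionTrace}}),
#'   \code{model} (final \code{\linkS4class{QDAModel}}), \code{features}
#'   (best subset columns), \code{cvMetrics} (per-fold matrix at the best
#'   subset), \code{blindMetrics} (named metric vector),
#'   \code{blindConfusion}, \code{counts} (stage log), \code{config}.
#' @export
tfiPipeline <- function(interactions, sequences, properties,
                        allowedMITypes = DEFAULT_MI_TYPES,
                        identityThreshold = 0.8, k = 10L,
                        maxFeatures = 150L, ridge = 1e-6, pool = NULL,
                        poolSize = NULL,
                        criterion = c("accuracy", "f_measure"),
                        seed = 1L, outDir = NULL) {
    criterion <- match.arg(criterion)
    if (is.character(interactions)) {
        interactions <- readPairTable(interactions)
        names(interactions)[names(interactions) == "id_a"] <- "first_id"
        names(interactions)[names(interactions) == "id_b"] <- "second_id"
    }
    if (is(interactions, "TFInteractionSet"))
        interactions <- interactionPairs(interactions)
    sequences <- asSequences(sequences)
    if (is.character(properties))
        properties <- filterComplete(parseAAIndex1(properties))
    if (anyNA(propertyValues(properties)))
        properties <- filterComplete(properties)

    counts <- list()
    log1 <- function(stage, n) {
        counts[[stage]] <<- n
        message(sprintf("[%s] %d records", stage, n))
    }

    pos <- interactions[interactions$label == "positive", , drop = FALSE]
    neg <- interactions[interactions$label == "negative", , drop = FALSE]
    log1("positives_extracted", nrow(pos))
    if (!is.null(allowedMITypes) && "mi_type" %in% names(pos)) {
        pos <- filterByMIType(pos, allowedMITypes)
        log1("positives_mi_filtered", nrow(pos))
    }
    if (!is.null(identityThreshold)) {
        rf <- redundancyFilter(pos, sequences, threshold = identityThreshold)
        pos <- rf$retained
        log1("positives_retained", nrow(pos))
    } else rf <- NULL
    log1("negatives", nrow(neg))
    labelled <- rbind(pos[intersect(names(pos), names(neg))],
                      neg[intersect(names(pos), names(neg))])
    log1("labelled_total", nrow(labelled))

    X <- featurizePairs(labelled, sequences, properties)
    y <- labelled$label
    log1("featurized", nrow(X))

    ## k + 1 stratified groups; group k + 1 is the blind set
    groups <- makeStratifiedFolds(y, k + 1L, subSeed(seed, "folds"))
    blind <- foldIndices(groups) == (k + 1L)
    cvFold <- foldIndices(groups)[!blind]
    folds <- new("FoldAssignment", fold = as.integer(cvFold),
                 k = as.integer(k), seed = as.integer(seed),
                 hash = foldHash(cvFold, k, seed))
    log1("cv_samples", sum(!blind))
    log1("blind_samples", sum(blind))

    allCols <- seq_len(ncol(X))
    if (is.null(pool))
        pool <- if (is.null(poolSize)) allCols
                else sort(withSeed(subSeed(seed, "pool"),
                                   sample(allCols, poolSize)))
    pool <- as.integer(pool)
    maxFeatures <- min(maxFeatures, length(pool))

    trace <- forwardSelect(X[!blind, , drop = FALSE], y[!blind], folds,
                           maxFeatures = maxFeatures, ridge = ridge,
                           pool = pool, criterion = criterion)
    feats <- bestSubset(trace)
    cvPerFold <- trace@steps[[length(feats)]]$perFold

    model <- fitQDA(X[!blind, feats, drop = FALSE], y[!blind],
                    ridge = ridge, featureIndices = feats,
                    featureAnnotation = featureAnnotation(properties, feats))
    pred <- predict(model, X[blind, feats, drop = FALSE])
    cm <- confusionCounts(y[blind], pred)
    blindMetrics <- metricSet(cm)
    message(sprintf("[blind] accuracy %.2f%% on %d samples",
                    blindMetrics[["accuracy"]], sum(blind)))

    config <- list(allowed_mi_types = allowedMITypes,
                   identity_threshold = identityThreshold, k = k,
                   max_features = maxFeatures, ridge = ridge,
                   criterion = criterion, seed = as.integer(seed),
                   pool_size = length(pool),
                   mass_convention = MASS_CONVENTION)
    out <- list(trace = trace, model = model, features = feats,
                cvMetrics = cvPerFold, blindMetrics = blindMetrics,
                blindConfusion = cm, removed = rf$removed,
                counts = counts, config = config)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeTrace(trace, file.path(outDir, "selection_trace.tsv"),
                   table = properties,
                   jsonFile = file.path(outDir, "selection_trace.json"))
        writeQDAModel(model, file.path(outDir, "model.json"))
        writeMetricsReport(cvPerFold, file.path(outDir, "cv_metrics.tsv"))
        jsonlite::write_json(
            list(config = config, counts = counts,
                 blind_metrics = as.list(blindMetrics),
                 blind_confusion = as.list(cm)),
            file.path(outDir, "run.json"), digits = NA, auto_unbox = TRUE)
    }
    out
}

#' Predict interaction labels for new TF pairs
#'
#' Refuses to predict when the supplied property table does not match the
#' accessions recorded in the model's feature annotation or when the
#' molecular-weight convention differs, which would silently misalign
#' features.
#'
#' @param model a \code{\linkS4class{QDAModel}} or path to a model JSON.
#' @param pairs data.frame / TSV path of pairs to score.
#' @param sequences named \code{AAStringSet} / character vector or FASTA
#'   path.
#' @param properties \code{\linkS4class{AAPropertyTable}} or AAIndex1
#'   path.
#' @param file optional TSV output path.
#' @return data.frame: canonical pair ids, predicted label and per-class
#'   scores.
#' @export
runPredict <- function(model, pairs, sequences, properties, file = NULL) {
    if (is.character(model)) model <- readQDAModel(model)
    if (is.character(pairs)) pairs <- readPairTable(pairs)
    if (is(pairs, "TFInteractionSet")) pairs <- interactionPairs(pairs)
    sequences <- asSequences(sequences)
    if (is.character(properties))
        properties <- filterComplete(parseAAIndex1(properties))
    ann <- model@featureAnnotation
    if (nrow(ann)) {
        want <- accessions(properties)[ann$property]
        if (any(is.na(want)) || !identical(as.character(ann$accession), want))
            stop("property table does not match the model's feature annotation; refusing to predict")
        if (!is.null(ann$fingerprint)) {
            cur <- featureAnnotation(properties, ann$column)$fingerprint
            if (any(abs(cur - ann$fingerprint) > 1e-9))
                stop("property table values differ from those the model was fit on; refusing to predict")
        }
    }
    if (length(model@massConvention) &&
        !identical(model@massConvention, MASS_CONVENTION))
        stop("molecular-weight convention mismatch; refusing to predict")
    X <- featurizePairs(pairs, sequences, properties)
    feats <- model@featureIndices
    if (length(feats) == 0L) feats <- seq_len(length(model@means[[1L]]))
    sc <- qdaScores(model, X[, feats, drop = FALSE])
    pred <- model@classLabels[max.col(sc, ties.method = "first")]
    ids <- do.call(rbind, strsplit(rownames(X), "|", fixed = TRUE))
    out <- data.frame(first_id = ids[, 1L], second_id = ids[, 2L],
                      prediction = pred, sc, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out)[seq(4L, length.out = ncol(sc))] <-
        paste0("score_", model@classLabels)
    if (!is.null(file))
        write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    out
}
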
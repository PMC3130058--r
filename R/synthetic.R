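#' Generate a complete synthetic property table
#'
#' Scales with values drawn uniformly in [-1, 1], complete over the 20
#' residues, deterministic per seed, and serializable in AAIndex1 dialect
#' (round-trippable through \code{\link{parseAAIndex1}}).
#'
#' @param nProperties number of scales.
#' @param seed integer seed.
#' @return an \code{\linkS4class{AAPropertyTable}}.
#' @export
genPropertyTable <- function(nProperties, seed) {
    stopifnot(nProperties >= 1L)
    m <- withSeed(seed,
        matrix(runif(nProperties * 20L, -1, 1), nProperties, 20L))
    colnames(m) <- AA20
    rownames(m) <- sprintf("SYNP%04d", seq_len(nProperties))
    new("AAPropertyTable", values = m,
        description = sprintf("Synthetic amino-acid scale %d (seed %d)",
                              seq_len(nProperties), as.integer(seed)))
}

#' Generate an AAIndex1-format text fixture
#'
#' Produces \code{nEntries} records of which exactly \code{nIncomplete}
#' contain at least one \code{NA} value (positions seeded), so that
#' parse-plus-\code{\link{filterComplete}} retains
#' \code{nEntries - nIncomplete} scales.
#'
#' @param nEntries total number of records.
#' @param nIncomplete how many records carry missing values.
#' @param seed integer seed.
#' @return character vector of AAIndex1 file lines.
#' @examples
#' length(filterComplete(parseAAIndex1(genAAIndexFile(5, 2, seed = 1))))  # 3
#' @export
genAAIndexFile <- function(nEntries, nIncomplete, seed) {
    stopifnot(nIncomplete >= 0L, nIncomplete <= nEntries)
    tab <- genPropertyTable(nEntries, seed)
    v <- propertyValues(tab)
    withSeed(seed + 1L, {
        which_inc <- if (nIncomplete > 0L)
            sample.int(nEntries, nIncomplete) else integer(0)
        for (r in which_inc)
            v[r, sample.int(20L, sample(1:3, 1L))] <- NA_real_
    })
    writeAAIndex1(new("AAPropertyTable", values = v,
                      description = tab@description))
}

#' Generate a synthetic TF-interaction study with planted class signal
#'
#' Builds everything the pipeline consumes: a property table, protein
#' sequences, and a labelled pair set with all three negative classes,
#' where a known subset of properties carries class signal. Members of
#' positive pairs draw their residues from compositions shifted
#' additively along the informative properties' orthogonalised (centred,
#' normalised) value vectors; the shift magnitude is calibrated so each
#' informative pair-feature mean moves by \code{effectSize} within-class
#' standard deviations relative to negative pairs (the sd includes both
#' between-TF composition variance and within-segment sampling noise of
#' the shortest, noisiest segment). The shift is exactly orthogonal to
#' every non-informative property row, so those features carry no
#' composition-level signal.
#' Negative-pair members come from a separate baseline-composition pool,
#' half of which are marked as interacting via decoy (non-TF) partners so
#' the absolute/partial/ppi classes are all populated without leaking
#' signal into the ppi class.
#'
#' All randomness flows from the root seed through named substreams
#' (properties, compositions, sequences, pairing, negatives), so the same
#' call is bitwise-reproducible.
#'
#' @param nProperties number of property scales (default 20).
#' @param nPositive number of positive pairs (default 200).
#' @param nNegativePerClass negatives per class (default 67).
#' @param nDecoyTFs size of the baseline-composition pool negatives are
#'   drawn from (default 90; half are flagged as interacting).
#' @param lengthRange integer (min, max) sequence length (default
#'   c(600, 1400), typical of human TF chain lengths; minimum must be
#'   >= 5).
#' @param informativeProperties indices of the scales that carry signal
#'   (default 1:5).
#' @param effectSize planted class-mean shift in within-class standard
#'   deviations (>= 0; 0 plants no signal at all).
#' @param seed integer root seed.
#' @param xRate rate at which residues are replaced by X (and half as
#'   often U) to exercise the averaging skip rule (default 0.002).
#' @return list with \code{sequences} (named \code{AAStringSet}),
#'   \code{properties} (\code{\linkS4class{AAPropertyTable}}),
#'   \code{interactions} (\code{\linkS4class{TFInteractionSet}}) and
#'   \code{groundTruth} (informative properties, the 6 pair-vector columns
#'   each one occupies, calibrated tilts, seeds).
#' @examples
#' study <- genInteractionStudy(nPositive = 12, nNegativePerClass = 4,
#'                              nDecoyTFs = 20, seed = 1)
#' study$interactions
#' @export
genInteractionStudy <- function(nProperties = 20L, nPositive = 200L,
                                nNegativePerClass = 67L, nDecoyTFs = 90L,
                                lengthRange = c(600L, 1400L),
                                informativeProperties = 1:5,
                                effectSize = 2, seed = 1L,
                                xRate = 0.002) {
    stopifnot(nProperties >= 1L, nPositive >= 1L, nNegativePerClass >= 0L,
              lengthRange[1L] >= 5L, lengthRange[2L] >= lengthRange[1L],
              effectSize >= 0)
    if (length(informativeProperties) &&
        (max(informativeProperties) > nProperties ||
         min(informativeProperties) < 1L))
        stop("informativeProperties must index into 1..nProperties")
    nInt <- nDecoyTFs %/% 2L
    nNon <- nDecoyTFs - nInt
    if (nNegativePerClass > 0L &&
        (choose(nNon, 2L) < nNegativePerClass ||
         choose(nInt, 2L) < nNegativePerClass ||
         nInt * nNon < nNegativePerClass))
        stop("nDecoyTFs too small for the requested negatives per class")

    tab <- genPropertyTable(nProperties, subSeed(seed, "properties"))
    V <- propertyValues(tab)

    ## Decorrelate the planted directions: informative rows are
    ## Gram-Schmidt-orthogonalised against each other in centred space
    ## (so each tilt moves exactly one informative feature), and
    ## non-informative rows are projected out of their span (so tilting
    ## leaves them signal-free up to the softmax nonlinearity).
    if (length(informativeProperties)) {
        Q <- NULL
        for (p in informativeProperties) {
            cv <- V[p, ] - mean(V[p, ])
            len <- sqrt(sum(cv^2))
            if (!is.null(Q)) cv <- cv - Q %*% crossprod(Q, cv)
            cv <- as.numeric(cv)
            cv <- cv / sqrt(sum(cv^2))
            V[p, ] <- mean(V[p, ]) + len * cv
            Q <- cbind(Q, cv)
        }
        for (p in setdiff(seq_len(nProperties), informativeProperties)) {
            cv <- V[p, ] - mean(V[p, ])
            V[p, ] <- mean(V[p, ]) + as.numeric(cv - Q %*% crossprod(Q, cv))
        }
        tab <- new("AAPropertyTable", values = V,
                   description = tab@description)
    }

    tau <- 0.1       # sd of baseline composition logits
    eps <- 0.0125    # uniform floor mixed into every composition
    baseComposition <- function(z) (1 - 20 * eps) * softmax(z) + eps

    ## Calibrate the additive composition shift Delta = Q %*% coef so each
    ## informative middle-segment feature moves by effectSize within-class
    ## standard deviations. The sd is simulated from baseline compositions
    ## and includes the multinomial sampling noise of a typical middle
    ## segment (60% of the mean length); the shorter terminal segments are
    ## noisier and end up with a somewhat smaller standardized shift.
    ## Delta lies in span(Q), so it sums to zero and is exactly
    ## orthogonal to every non-informative (projected) property row:
    ## non-informative features carry no composition-level signal at all.
    coefs <- numeric(length(informativeProperties))
    if (effectSize > 0 && length(informativeProperties)) {
        zCal <- withSeed(subSeed(seed, "calibration"),
            matrix(rnorm(400L * 20L, 0, tau), 400L, 20L))
        wCal <- t(apply(zCal, 1L, baseComposition))
        nSegCal <- max(1L, floor(0.6 * mean(lengthRange)))
        for (j in seq_along(informativeProperties)) {
            v <- V[informativeProperties[j], ]
            wv <- as.numeric(wCal %*% v)
            wvar <- mean(as.numeric(wCal %*% v^2) - wv^2)
            sdTot <- sqrt(stats::var(wv) + wvar / nSegCal)
            len <- sqrt(sum((v - mean(v))^2))
            coefs[j] <- effectSize * sdTot / len
        }
    }
    delta <- if (length(informativeProperties) && effectSize > 0)
        as.numeric(Q %*% coefs) else rep(0, 20L)

    nSignal <- 2L * nPositive
    idsSignal <- sprintf("TFP%04d", seq_len(nSignal))
    idsInt <- if (nInt) sprintf("TFI%04d", seq_len(nInt)) else character(0)
    idsNon <- if (nNon) sprintf("TFN%04d", seq_len(nNon)) else character(0)
    ids <- c(idsSignal, idsInt, idsNon)

    Z <- withSeed(subSeed(seed, "compositions"),
        matrix(rnorm(length(ids) * 20L, 0, tau), length(ids), 20L))
    W <- t(apply(Z, 1L, baseComposition))
    if (any(delta != 0)) {
        W[seq_len(nSignal), ] <- sweep(W[seq_len(nSignal), , drop = FALSE],
                                       2L, delta, `+`)
        if (min(W) < 0)
            stop("infeasible planted signal: the requested shift drives residue frequencies negative; use a smaller effectSize")
    }

    seqs <- withSeed(subSeed(seed, "sequences"), {
        lens <- sample(lengthRange[1L]:lengthRange[2L], length(ids),
                       replace = TRUE)
        vapply(seq_along(ids), function(i) {
            w <- W[i, ]
            chars <- sample(AA20, lens[i], replace = TRUE, prob = w)
            if (xRate > 0) {
                hit <- runif(lens[i]) < xRate
                ## never blank out a whole terminal segment
                t0 <- floor(0.2 * lens[i])
                if (sum(hit[seq_len(t0)]) >= t0) hit[1L] <- FALSE
                if (sum(hit[(lens[i] - t0 + 1L):lens[i]]) >= t0)
                    hit[lens[i]] <- FALSE
                chars[hit] <- sample(c("X", "U"), sum(hit), replace = TRUE,
                                     prob = c(2, 1))
            }
            paste(chars, collapse = "")
        }, character(1))
    })
    names(seqs) <- ids
    sequences <- Biostrings::AAStringSet(seqs)

    positives <- withSeed(subSeed(seed, "pairing"), {
        perm <- sample(idsSignal)
        data.frame(first_id = perm[seq(1L, nSignal, by = 2L)],
                   second_id = perm[seq(2L, nSignal, by = 2L)],
                   label = "positive", neg_class = "none",
                   mi_type = sample(DEFAULT_MI_TYPES, nPositive,
                                    replace = TRUE, prob = c(1, 4, 5)),
                   stringsAsFactors = FALSE)
    })

    knownPartners <- c(
        lapply(seq_len(nInt), function(i) sprintf("XDECOY%04d", i)),
        lapply(seq_len(nNon), function(i) character(0)))
    names(knownPartners) <- c(idsInt, idsNon)
    negatives <- if (nNegativePerClass > 0L)
        makeNegativeSet(c(idsInt, idsNon), knownPartners,
                        nNegativePerClass, subSeed(seed, "negatives"))
    else positives[0L, ]

    interactions <- makeInteractionSet(rbind(positives, negatives),
                                       universe = ids)

    P <- nProperties
    informativeColumns <- if (length(informativeProperties))
        sort(as.integer(outer(informativeProperties,
                              (seq_len(6L) - 1L) * P, `+`)))
        else integer(0)
    ## the mid-segment columns are the ones the shift was calibrated on:
    ## member-major layout, segment order n/mid/c within a member
    plantedColumns <- if (length(informativeProperties))
        sort(as.integer(outer(informativeProperties,
                              c(1L, 4L) * P, `+`)))
        else integer(0)
    groundTruth <- list(
        informative_properties = as.integer(informativeProperties),
        informative_columns = informativeColumns,
        planted_columns = plantedColumns,
        effect_size = effectSize,
        shift_coefficients = coefs,
        composition_shift = delta,
        composition_logit_sd = tau,
        seed = as.integer(seed),
        n_positive = as.integer(nPositive),
        n_negative_per_class = as.integer(nNegativePerClass))

    list(sequences = sequences, properties = tab,
         interactions = interactions, groundTruth = groundTruth)
}

#' Write a synthetic study to disk in the package's own input formats
#'
#' Emits FASTA sequences, an AAIndex1 property file, a labelled pair TSV
#' and the ground-truth JSON into a directory.
#'
#' @param study result of \code{\link{genInteractionStudy}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "sequences.fasta"),
               aaindex = file.path(dir, "properties.aaindex1"),
               pairs = file.path(dir, "pairs.tsv"),
               truth = file.path(dir, "ground_truth.json"))
    Biostrings::writeXStringSet(study$sequences, paths[["fasta"]])
    writeAAIndex1(study$properties, paths[["aaindex"]])
    writePairTable(study$interactions, paths[["pairs"]])
    jsonlite::write_json(study$groundTruth, paths[["truth"]],
                         digits = NA, auto_unbox = TRUE)
    invisible(paths)
}
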
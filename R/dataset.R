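DEFAULT_MI_TYPES <- c("MI:0195", "MI:0407", "MI:0915")

#' Read a tab-separated interaction pair table
#'
#' Expects a header with columns \code{id_a} and \code{id_b}; optional
#' columns \code{mi_type} (PSI-MI code) and \code{label}
#' ("positive"/"negative") are carried through when present.
#'
#' @param file path or connection.
#' @return data.frame with columns \code{first_id}, \code{second_id} and,
#'   when present in the input, \code{mi_type} and \code{label}.
#' @export
readPairTable <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b") %in% names(df)))
        stop("pair table needs columns 'id_a' and 'id_b'")
    out <- data.frame(first_id = as.character(df$id_a),
                      second_id = as.character(df$id_b),
                      stringsAsFactors = FALSE)
    if ("mi_type" %in% names(df)) out$mi_type <- as.character(df$mi_type)
    if ("label" %in% names(df)) out$label <- as.character(df$label)
    out
}

#' Filter interaction records by PSI-MI interaction type
#'
#' Only evidence types that can support formation of a protein complex are
#' kept for training; the defaults are covalent binding (MI:0195), direct
#' interaction (MI:0407) and physical association (MI:0915). Records with
#' no type annotation are dropped.
#'
#' @param pairs data.frame with a \code{mi_type} column (records lacking
#'   the column, or with \code{NA}/empty type, are treated as unannotated
#'   and dropped).
#' @param allowed character vector of admissible MI codes.
#' @return the retained rows of \code{pairs}.
#' @export
filterByMIType <- function(pairs, allowed = DEFAULT_MI_TYPES) {
    if (nrow(pairs) == 0L) return(pairs)
    mi <- if ("mi_type" %in% names(pairs)) pairs$mi_type
          else rep(NA_character_, nrow(pairs))
    keep <- !is.na(mi) & nzchar(mi) & mi %in% allowed
    pairs[keep, , drop = FALSE]
}

## Enumerate eligible unordered id pairs for one negative class,
## lexicographically ordered within the pair and across rows.
eligibleNegativePairs <- function(universe, knownPartners, negClass) {
    universe <- sort(unique(as.character(universe)))
    partners <- knownPartners[names(knownPartners) %in% universe]
    interacting <- sort(names(partners)[lengths(partners) > 0L])
    nonInteracting <- setdiff(universe, interacting)
    posKeys <- character(0)
    for (a in names(partners)) {
        ps <- intersect(as.character(partners[[a]]), universe)
        ps <- setdiff(ps, a)
        if (length(ps)) posKeys <- c(posKeys, pairKey(a, ps))
    }
    posKeys <- unique(posKeys)
    allPairsOf <- function(ids) {
        if (length(ids) < 2L)
            return(matrix(character(0), 0L, 2L))
        t(combn(ids, 2L))
    }
    m <- switch(negClass,
        absolute = allPairsOf(nonInteracting),
        partial = {
            if (length(interacting) == 0L || length(nonInteracting) == 0L)
                matrix(character(0), 0L, 2L)
            else {
                g <- expand.grid(a = interacting, b = nonInteracting,
                                 stringsAsFactors = FALSE)
                cbind(pmin(g$a, g$b), pmax(g$a, g$b))
            }
        },
        ppi = {
            mm <- allPairsOf(interacting)
            if (nrow(mm))
                mm <- mm[!(pairKey(mm[, 1L], mm[, 2L]) %in% posKeys), ,
                         drop = FALSE]
            mm
        },
        stop("unknown negative class: ", negClass))
    if (nrow(m)) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    m
}

#' Generate random negative TF pairs of one class
#'
#' The three negative classes mirror how much interaction evidence exists
#' for the members: \emph{absolute} pairs join two TFs not known to
#' interact with any protein; \emph{partial} pairs join one TF with known
#' partners to one without; \emph{ppi} pairs join two TFs that each
#' interact with other proteins but are not known to interact with each
#' other. Self-pairs are never generated, no generated pair occurs in the
#' known positive set, and the classes are structurally disjoint.
#'
#' @param universe character vector of TF identifiers to draw from.
#' @param knownPartners named list mapping a TF id to the identifiers of
#'   its known interaction partners (TF or not); ids absent from the list
#'   or mapped to an empty vector count as "not known to interact".
#' @param negClass one of \code{"absolute"}, \code{"partial"},
#'   \code{"ppi"}.
#' @param n number of distinct pairs to draw.
#' @param seed integer; the draw is reproducible per seed and leaves the
#'   caller's RNG state untouched.
#' @return data.frame with columns \code{first_id}, \code{second_id}
#'   (lexicographic within the pair), \code{label} ("negative"),
#'   \code{neg_class}, \code{mi_type} (\code{NA}).
#' @examples
#' kp <- list(TF1 = "TF2", TF2 = "TF1")
#' generateNegatives(paste0("TF", 1:6), kp, "absolute", 3, seed = 7)
#' @export
generateNegatives <- function(universe, knownPartners,
                              negClass = c("absolute", "partial", "ppi"),
                              n, seed) {
    negClass <- match.arg(negClass)
    stopifnot(n >= 0L)
    elig <- eligibleNegativePairs(universe, knownPartners, negClass)
    if (n > nrow(elig))
        stop(sprintf("cannot draw %d distinct '%s' negatives: only %d eligible pairs exist",
                     n, negClass, nrow(elig)))
    idx <- if (n > 0L) withSeed(seed, sample.int(nrow(elig), n)) else integer(0)
    idx <- sort(idx)
    data.frame(first_id = elig[idx, 1L], second_id = elig[idx, 2L],
               label = rep("negative", n), neg_class = rep(negClass, n),
               mi_type = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Generate the merged three-class negative set
#'
#' Draws \code{nPerClass} pairs from each of the absolute, partial and ppi
#' classes (disjoint by construction) and merges them.
#'
#' @inheritParams generateNegatives
#' @param nPerClass pairs per class (the reference protocol uses 412,
#'   giving 1,236 negatives in total).
#' @return data.frame as in \code{\link{generateNegatives}} with
#'   \code{3 * nPerClass} rows.
#' @export
makeNegativeSet <- function(universe, knownPartners, nPerClass, seed) {
    classes <- c("absolute", "partial", "ppi")
    out <- do.call(rbind, lapply(seq_along(classes), function(i)
        generateNegatives(universe, knownPartners, classes[i], nPerClass,
                          seed = seed + i)))
    stopifnot(!anyDuplicated(pairKey(out$first_id, out$second_id)))
    out
}

#' Sequence identity of the best local alignment
#'
#' Aligns the two sequences locally with BLOSUM62 scoring and affine gaps
#' (open 11, extend 1; the BLAST protein defaults) and reports identical
#' aligned positions divided by alignment length, a fraction in [0, 1].
#' Selenocysteine (U) is scored as X for alignment purposes.
#'
#' @param seqA,seqB amino-acid strings.
#' @return identity fraction in [0, 1]; symmetric in its arguments.
#' @examples
#' sequenceIdentity("ACDEFGHIKL", "ACDEFGHIKL")  # 1
#' @export
sequenceIdentity <- function(seqA, seqB) {
    a <- paste(seqChars(seqA), collapse = ""); b <- paste(seqChars(seqB), collapse = "")
    a <- chartr("U", "X", a); b <- chartr("U", "X", b)
    al <- Biostrings::pairwiseAlignment(a, b, type = "local",
        substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
    Biostrings::pid(al, type = "PID1") / 100
}

blosum62Cache <- new.env(parent = emptyenv())
blosum62 <- function() {
    if (is.null(blosum62Cache$m)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        blosum62Cache$m <- e$BLOSUM62
    }
    blosum62Cache$m
}

#' Remove redundant positive interactions of near-identical TFs
#'
#' TF family members are often highly similar in sequence and tend to bind
#' the same partners, which inflates cross-validation estimates. For every
#' TF pair (A, A') whose local-alignment identity exceeds the threshold
#' and that shares a common interaction partner B among the positives,
#' exactly one of A-B / A'-B is kept: the record whose similar member has
#' the lexicographically smaller id. Processing is internally sorted, so
#' the result does not depend on input record order, and the filter is
#' idempotent.
#'
#' @param positives data.frame of positive pairs (columns \code{first_id},
#'   \code{second_id}; other columns carried through) or a
#'   \code{\linkS4class{TFInteractionSet}} (only its positive records are
#'   filtered and returned).
#' @param sequences named \code{AAStringSet} or character vector with a
#'   sequence for every TF occurring in \code{positives}.
#' @param threshold identity fraction above which two TFs count as
#'   redundant (default 0.8).
#' @return list with \code{retained} (the surviving rows of
#'   \code{positives}) and \code{removed} (audit data.frame: removed pair,
#'   kept pair, the two similar TFs, their identity, the common partner).
#' @export
redundancyFilter <- function(positives, sequences, threshold = 0.8) {
    wasSet <- is(positives, "TFInteractionSet")
    df <- if (wasSet) {
        p <- interactionPairs(positives)
        p[p$label == "positive", , drop = FALSE]
    } else positives
    ids <- sort(unique(c(df$first_id, df$second_id)))
    missing <- ids[!ids %in% names(sequences)]
    if (length(missing))
        stop("no sequence for TF id(s): ", paste(missing, collapse = ", "))

    ## partner map over the positive records
    partners <- lapply(ids, function(i)
        sort(unique(c(df$second_id[df$first_id == i],
                      df$first_id[df$second_id == i]))))
    names(partners) <- ids

    ## candidate similar pairs: only TF pairs sharing >= 1 common partner
    ## can trigger a removal, so only those are aligned
    keys <- pairKey(df$first_id, df$second_id)
    removedRows <- list()
    retainedKeys <- keys
    if (length(ids) >= 2L) {
        cand <- t(combn(ids, 2L))
        common <- mapply(function(a, b)
            length(intersect(partners[[a]], partners[[b]])) > 0L,
            cand[, 1L], cand[, 2L])
        cand <- cand[common, , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
            A <- cand[r, 1L]; Ap <- cand[r, 2L]   # A < Ap lexicographically
            ident <- sequenceIdentity(as.character(sequences[[A]]),
                                      as.character(sequences[[Ap]]))
            if (ident <= threshold) next
            for (B in intersect(partners[[A]], partners[[Ap]])) {
                kA <- pairKey(A, B); kAp <- pairKey(Ap, B)
                if (kA %in% retainedKeys && kAp %in% retainedKeys) {
                    retainedKeys <- setdiff(retainedKeys, kAp)
                    removedRows[[length(removedRows) + 1L]] <- data.frame(
                        removed_a = min(Ap, B), removed_b = max(Ap, B),
                        kept_a = min(A, B), kept_b = max(A, B),
                        tf_kept = A, tf_removed = Ap,
                        identity = ident, common_partner = B,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    removed <- if (length(removedRows)) do.call(rbind, removedRows)
        else data.frame(removed_a = character(0), removed_b = character(0),
                        kept_a = character(0), kept_b = character(0),
                        tf_kept = character(0), tf_removed = character(0),
                        identity = numeric(0), common_partner = character(0),
                        stringsAsFactors = FALSE)
    retained <- df[keys %in% retainedKeys, , drop = FALSE]
    rownames(retained) <- NULL
    list(retained = retained, removed = removed)
}

#' Assemble a validated interaction set
#'
#' Orders every record lexicographically, checks for duplicates and for
#' disjointness of positives and negatives, and wraps the result in a
#' \code{\linkS4class{TFInteractionSet}}.
#'
#' @param pairs data.frame with columns \code{first_id}, \code{second_id},
#'   \code{label}; optional \code{neg_class} and \code{mi_type}.
#' @param universe character vector of available TF ids (default: the ids
#'   occurring in \code{pairs}).
#' @return a \code{TFInteractionSet}.
#' @export
makeInteractionSet <- function(pairs,
                               universe = sort(unique(c(pairs$first_id,
                                                        pairs$second_id)))) {
    swap <- pairs$first_id > pairs$second_id
    tmp <- pairs$first_id[swap]
    pairs$first_id[swap] <- pairs$second_id[swap]
    pairs$second_id[swap] <- tmp
    if (!"neg_class" %in% names(pairs))
        pairs$neg_class <- ifelse(pairs$label == "positive", "none", "ppi")
    if (!"mi_type" %in% names(pairs))
        pairs$mi_type <- NA_character_
    pairs <- pairs[order(pairs$label, pairs$first_id, pairs$second_id), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
    new("TFInteractionSet",
        pairs = pairs[, c("first_id", "second_id", "label", "neg_class",
                          "mi_type")],
        universe = sort(unique(universe)))
}

#' Write a labelled pair table as TSV
#'
#' @param x a \code{TFInteractionSet} or pairs data.frame.
#' @param file path or connection.
#' @return the written data.frame, invisibly.
#' @export
writePairTable <- function(x, file) {
    df <- if (is(x, "TFInteractionSet")) interactionPairs(x) else x
    out <- data.frame(id_a = df$first_id, id_b = df$second_id,
                      df[setdiff(names(df), c("first_id", "second_id"))],
                      stringsAsFactors = FALSE)
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}
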
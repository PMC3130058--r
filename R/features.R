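## Average residue masses (Da), Expasy convention; X contributes nothing,
## U is selenocysteine. One free water is added per chain.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
             U = 150.0388, X = 0)
WATER_MASS <- 18.0153
MASS_CONVENTION <- "average-residue-mass/expasy+water18.0153"

checkAlphabet <- function(chars, id = NULL) {
    bad <- setdiff(unique(chars), c(AA20, AA_SKIP))
    if (length(bad))
        stop(sprintf("%sdisallowed residue code(s): %s (only the 20 standard residues plus X and U are accepted)",
                     if (is.null(id)) "" else paste0(id, ": "),
                     paste(bad, collapse = ", ")))
    invisible(chars)
}

#' Split a protein sequence into N-terminal / middle / C-terminal segments
#'
#' Each terminal segment takes \code{floor(0.2 * L)} residues; the middle
#' keeps the remainder, so the three parts cover 20/60/20 of the length and
#' concatenate back to the input. Sequences shorter than 5 residues are
#' rejected because a terminal segment would be empty.
#'
#' @param sequence amino-acid string (20 standard letters plus X and U).
#' @return named character vector with elements \code{n}, \code{mid},
#'   \code{c}.
#' @examples
#' nchar(splitSegments(strrep("ACDEF", 20)))  # 20 60 20
#' @export
splitSegments <- function(sequence) {
    chars <- seqChars(sequence)
    checkAlphabet(chars)
    L <- length(chars)
    if (L < 5L)
        stop(sprintf("degenerate sequence of length %d: need at least 5 residues so both terminal segments are non-empty", L))
    t <- floor(0.2 * L)
    c(n = paste(chars[seq_len(t)], collapse = ""),
      mid = paste(chars[(t + 1L):(L - t)], collapse = ""),
      c = paste(chars[(L - t + 1L):L], collapse = ""))
}

#' Mean of one amino-acid property over a segment
#'
#' Arithmetic mean of the per-residue property values, with X and U
#' excluded from both the sum and the count (the effective segment length
#' shrinks accordingly). A segment consisting only of X/U has no defined
#' mean and raises an error.
#'
#' @param segment amino-acid string.
#' @param property named numeric vector of 20 values (names = one-letter
#'   residue codes), i.e. one row of \code{\link{propertyValues}}.
#' @return the mean property value, a single number.
#' @examples
#' tab <- genPropertyTable(1, seed = 1)
#' propertyMean("ACDE", propertyValues(tab)[1, ])
#' @export
propertyMean <- function(segment, property) {
    chars <- seqChars(segment)
    checkAlphabet(chars)
    if (!is.numeric(property) || length(property) != 20L ||
        anyNA(property) || !all(AA20 %in% names(property)))
        stop("'property' must be a complete named vector over the 20 standard residues")
    keep <- !(chars %in% AA_SKIP)
    if (!any(keep))
        stop("undefined mean: segment contains only X/U residues")
    mean(property[chars[keep]])
}

## Residue counts over AA20 for each of the three segments, X/U dropped.
segmentCounts <- function(chars) {
    L <- length(chars)
    t <- floor(0.2 * L)
    seg <- rep(2L, L)
    seg[seq_len(t)] <- 1L
    seg[(L - t + 1L):L] <- 3L
    keep <- !(chars %in% AA_SKIP)
    m <- matrix(0, 3L, 20L, dimnames = list(NULL, AA20))
    if (any(keep)) {
        tab <- table(factor(seg[keep], levels = 1:3),
                     factor(chars[keep], levels = AA20))
        m[] <- as.numeric(tab)
    }
    m
}

#' Segment-wise property-mean feature vector for a single TF
#'
#' Computes the mean of every scale of a complete property table over each
#' of the three 20/60/20 segments and concatenates them segment-major:
#' positions 1..P are the N-segment means in table order, P+1..2P the
#' middle segment, 2P+1..3P the C-segment. The result has length 3P for
#' every sequence, independent of sequence length.
#'
#' @param sequence amino-acid string, or a named element of an
#'   \code{AAStringSet}.
#' @param table a complete \code{\linkS4class{AAPropertyTable}} (see
#'   \code{\link{filterComplete}}).
#' @param id optional identifier used to annotate error messages.
#' @return numeric vector of length \code{3 * length(table)}.
#' @examples
#' tab <- genPropertyTable(4, seed = 1)
#' length(featurizeTF(strrep("ACDEFGHIKL", 3), tab))  # 12
#' @export
featurizeTF <- function(sequence, table, id = NULL) {
    stopifnot(is(table, "AAPropertyTable"))
    if (anyNA(table@values))
        stop("property table contains missing values; apply filterComplete() first")
    tag <- function(msg) if (is.null(id)) msg else sprintf("%s: %s", id, msg)
    chars <- seqChars(sequence)
    tryCatch(checkAlphabet(chars), error = function(e) stop(tag(conditionMessage(e)), call. = FALSE))
    if (length(chars) < 5L)
        stop(tag(sprintf("degenerate sequence of length %d: need at least 5 residues", length(chars))))
    counts <- segmentCounts(chars)
    nRes <- rowSums(counts)
    if (any(nRes == 0))
        stop(tag("undefined mean: a segment contains only X/U residues"))
    ## means per segment: (P x 20) %*% (20) / n, all segments at once
    means <- table@values %*% t(counts / nRes)   # P x 3
    v <- as.numeric(means)                       # segment-major by column
    names(v) <- paste(rep(c("n", "mid", "c"), each = nrow(table@values)),
                      rep(rownames(table@values), 3L), sep = ".")
    v
}

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da). X counts as
#' zero mass; U uses the selenocysteine residue mass. Only the ordering of
#' weights matters downstream (pair canonicalisation), and the convention
#' is recorded in fitted models as \code{massConvention}.
#'
#' @param sequence amino-acid string.
#' @return weight in Daltons.
#' @examples
#' molecularWeight("G")   # ~75.07
#' @export
molecularWeight <- function(sequence) {
    chars <- seqChars(sequence)
    checkAlphabet(chars)
    sum(AA_MASS[chars]) + WATER_MASS
}

#' Canonical ordering of a TF pair
#'
#' Places the member with the strictly smaller molecular weight first; on
#' an exact tie the lexicographically smaller identifier wins. The result
#' is the same whichever way the arguments are given, which is what makes
#' the pair feature representation unique.
#'
#' @param idA,idB member identifiers.
#' @param sequences named \code{AAStringSet} or named character vector
#'   containing both members.
#' @return character vector \code{c(first, second)}.
#' @export
canonicalPair <- function(idA, idB, sequences) {
    sa <- as.character(sequences[[idA]])
    sb <- as.character(sequences[[idB]])
    wa <- molecularWeight(sa); wb <- molecularWeight(sb)
    if (wa < wb || (wa == wb && idA <= idB)) c(idA, idB) else c(idB, idA)
}

#' Feature vector for a TF pair
#'
#' Concatenates the two members' segment-wise property-mean vectors with
#' the lighter member (by \code{\link{molecularWeight}}) first, giving a
#' vector of length 6P that is identical for (a, b) and (b, a).
#'
#' @param idA,idB member identifiers.
#' @param sequences named \code{AAStringSet} or named character vector.
#' @param table a complete \code{\linkS4class{AAPropertyTable}}.
#' @return numeric vector of length \code{6 * length(table)} with
#'   attributes \code{first_id} and \code{second_id} recording the
#'   canonical member order.
#' @export
featurizePair <- function(idA, idB, sequences, table) {
    ord <- canonicalPair(idA, idB, sequences)
    v <- c(featurizeTF(as.character(sequences[[ord[1L]]]), table, id = ord[1L]),
           featurizeTF(as.character(sequences[[ord[2L]]]), table, id = ord[2L]))
    names(v) <- paste(rep(c("tf1", "tf2"), each = 3L * length(table)),
                      names(v), sep = ".")
    attr(v, "first_id") <- ord[1L]
    attr(v, "second_id") <- ord[2L]
    v
}

#' Annotation of pair-vector feature columns
#'
#' Decomposes each 1-based column index of a pair vector into its (member,
#' segment, property) triple, the exported naming scheme for selected
#' features.
#'
#' @param table a complete \code{\linkS4class{AAPropertyTable}}.
#' @param columns integer column indices (default: all 6P).
#' @return data.frame with columns \code{column}, \code{member} (1 =
#'   lighter TF, 2 = heavier), \code{segment} ("n", "mid", "c"),
#'   \code{property} (index into the table), \code{accession} and
#'   \code{fingerprint} (a scalar projection of the scale's 20 values;
#'   lets consumers detect a table whose accessions match but whose
#'   values differ).
#' @export
featureAnnotation <- function(table, columns = seq_len(6L * length(table))) {
    P <- length(table)
    stopifnot(all(columns >= 1L), all(columns <= 6L * P))
    k <- as.integer(columns) - 1L
    member <- k %/% (3L * P) + 1L
    segment <- (k %% (3L * P)) %/% P + 1L
    property <- k %% P + 1L
    fp <- as.numeric(propertyValues(table) %*% (seq_len(20L) / 10))
    data.frame(column = as.integer(columns), member = member,
               segment = c("n", "mid", "c")[segment], property = property,
               accession = accessions(table)[property],
               fingerprint = fp[property],
               row.names = NULL)
}

#' Feature matrix for a set of TF pairs
#'
#' Featurizes every TF once and assembles one row per pair under canonical
#' molecular-weight ordering.
#'
#' @param pairs data.frame with columns \code{first_id}, \code{second_id}
#'   (any order; canonicalisation is applied per pair), or a
#'   \code{\linkS4class{TFInteractionSet}}.
#' @param sequences named \code{AAStringSet} or named character vector
#'   covering every id in \code{pairs}.
#' @param table a complete \code{\linkS4class{AAPropertyTable}}.
#' @return numeric matrix, pairs x 6P, with rownames
#'   \code{"first|second"} in canonical order.
#' @export
featurizePairs <- function(pairs, sequences, table) {
    if (is(pairs, "TFInteractionSet")) pairs <- interactionPairs(pairs)
    ids <- unique(c(pairs$first_id, pairs$second_id))
    missing <- setdiff(ids, names(sequences))
    if (length(missing))
        stop("no sequence for id(s): ", paste(missing, collapse = ", "))
    seqs <- vapply(ids, function(i) as.character(sequences[[i]]), character(1))
    tfv <- t(vapply(seq_along(ids),
                    function(i) featurizeTF(seqs[i], table, id = ids[i]),
                    numeric(3L * length(table))))
    rownames(tfv) <- ids
    w <- vapply(seqs, molecularWeight, numeric(1))
    names(w) <- ids
    n <- nrow(pairs)
    X <- matrix(NA_real_, n, 6L * length(table))
    rn <- character(n)
    for (r in seq_len(n)) {
        a <- pairs$first_id[r]; b <- pairs$second_id[r]
        if (w[a] < w[b] || (w[a] == w[b] && a <= b)) ord <- c(a, b)
        else ord <- c(b, a)
        X[r, ] <- c(tfv[ord[1L], ], tfv[ord[2L], ])
        rn[r] <- paste(ord, collapse = "|")
    }
    rownames(X) <- rn
    colnames(X) <- paste(rep(c("tf1", "tf2"), each = 3L * length(table)),
                         rep(colnames(tfv), 2L), sep = ".")
    X
}
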
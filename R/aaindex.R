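#' Parse an AAIndex1 flat file
#'
#' Reads the AAIndex1 dialect: records separated by \code{//}, with
#' \code{H} giving the accession, \code{D} the description (continuation
#' lines indented), and \code{I} a residue header of ten \code{X/Y} column
#' pairs followed by two rows of ten numeric fields (\code{NA} marks a
#' value missing for that residue). The residue order is taken from the
#' header line itself, not assumed. Correlation and reference blocks
#' (\code{R}, \code{A}, \code{T}, \code{J}, \code{C}) are skipped.
#'
#' @param stream path to an AAIndex1 file, a connection, or a character
#'   vector of lines (a single string may contain embedded newlines).
#' @return an \code{\linkS4class{AAPropertyTable}} with one row per record
#'   in file order; residues absent from a record are \code{NA}. Apply
#'   \code{\link{filterComplete}} to keep only fully defined scales.
#' @examples
#' txt <- genAAIndexFile(3, 1, seed = 1)
#' tab <- parseAAIndex1(txt)
#' length(filterComplete(tab))
#' @export
parseAAIndex1 <- function(stream) {
    if (is.character(stream) && length(stream) == 1L &&
        !grepl("\n", stream, fixed = TRUE) && file.exists(stream))
        lines <- readLines(stream)
    else if (is.character(stream))
        lines <- unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
    else
        lines <- readLines(stream)

    nonblank <- lines[nzchar(trimws(lines))]
    if (length(nonblank) == 0L)
        return(new("AAPropertyTable",
                   values = matrix(numeric(0), 0L, 20L,
                                   dimnames = list(NULL, AA20)),
                   description = character(0)))

    recEnd <- grep("^//", lines)
    if (length(recEnd) == 0L)
        stop("not an AAIndex1 stream: no '//' record terminator found")
    recStart <- c(1L, head(recEnd, -1L) + 1L)

    vals <- list(); accs <- character(0); descs <- character(0)
    for (r in seq_along(recEnd)) {
        block <- lines[recStart[r]:(recEnd[r] - 1L)]
        offset <- recStart[r] - 1L
        acc <- NA_character_; desc <- ""; inD <- FALSE
        iAt <- NA_integer_
        for (li in seq_along(block)) {
            ln <- block[li]
            key <- substr(ln, 1L, 1L)
            if (key == "H") {
                acc <- trimws(substring(ln, 2L)); inD <- FALSE
            } else if (key == "D") {
                desc <- trimws(substring(ln, 2L)); inD <- TRUE
            } else if (key == " " && inD) {
                desc <- paste(desc, trimws(ln))
            } else if (key == "I") {
                iAt <- li; break
            } else inD <- FALSE
        }
        label <- if (is.na(acc)) sprintf("record %d", r) else acc
        if (is.na(acc) || !nzchar(acc))
            stop(sprintf("record %d (line %d): missing H (accession) line",
                         r, recStart[r]))
        if (is.na(iAt))
            stop(sprintf("%s: missing I (value) block", label))

        header <- strsplit(trimws(substring(block[iAt], 2L)), "[[:space:]]+")[[1L]]
        if (length(header) != 10L || !all(grepl("^[A-Z]/[A-Z]$", header)))
            stop(sprintf("%s (line %d): malformed I header line",
                         label, offset + iAt))
        row1aa <- substr(header, 1L, 1L)
        row2aa <- substr(header, 3L, 3L)
        if (!setequal(c(row1aa, row2aa), AA20))
            stop(sprintf("%s (line %d): I header does not cover the 20 standard residues",
                         label, offset + iAt))
        if (length(block) < iAt + 2L)
            stop(sprintf("%s: I block truncated (need two value rows)", label))

        v <- rep(NA_real_, 20L); names(v) <- AA20
        for (rowi in 1:2) {
            ln <- block[iAt + rowi]
            fields <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
            if (length(fields) != 10L)
                stop(sprintf("%s (line %d): expected 10 fields, found %d",
                             label, offset + iAt + rowi, length(fields)))
            aa <- if (rowi == 1L) row1aa else row2aa
            for (f in seq_len(10L)) {
                if (fields[f] == "NA") next
                num <- suppressWarnings(as.numeric(fields[f]))
                if (is.na(num))
                    stop(sprintf("%s (line %d): non-numeric field '%s'",
                                 label, offset + iAt + rowi, fields[f]))
                v[aa[f]] <- num
            }
        }
        vals[[r]] <- v; accs[r] <- acc; descs[r] <- desc
    }
    if (anyDuplicated(accs))
        stop("duplicate accession(s): ",
             paste(unique(accs[duplicated(accs)]), collapse = ", "))
    m <- do.call(rbind, vals)
    rownames(m) <- accs
    new("AAPropertyTable", values = m, description = descs)
}

#' Retain only property scales defined for all 20 residues
#'
#' Keeps the rows with no missing value, preserving input order. The
#' operation is idempotent and never reorders scales.
#'
#' @param table an \code{\linkS4class{AAPropertyTable}} (possibly with
#'   \code{NA} values, e.g. fresh from \code{\link{parseAAIndex1}}).
#' @return an \code{AAPropertyTable} containing the complete scales only.
#' @export
filterComplete <- function(table) {
    stopifnot(is(table, "AAPropertyTable"))
    keep <- stats::complete.cases(table@values)
    table[keep]
}

#' Write a property table in AAIndex1 dialect
#'
#' Emits H/D/I records with the standard \code{A/L R/K ...} column header
#' and full-precision values, so that write-then-parse reproduces the
#' table exactly. Missing values are written as \code{NA}.
#'
#' @param table an \code{\linkS4class{AAPropertyTable}}.
#' @param file path or connection; omit to return the lines invisibly
#'   without writing.
#' @return character vector of file lines, invisibly.
#' @export
writeAAIndex1 <- function(table, file = NULL) {
    stopifnot(is(table, "AAPropertyTable"))
    row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
    row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    header <- paste0("I    ", paste(paste(row1, row2, sep = "/"),
                                    collapse = "     "))
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    out <- character(0)
    for (r in seq_len(nrow(table@values))) {
        v <- table@values[r, ]
        out <- c(out,
                 paste("H", rownames(table@values)[r]),
                 paste("D", table@description[r]),
                 header,
                 paste0("     ", paste(fmt(v[row1]), collapse = "  ")),
                 paste0("     ", paste(fmt(v[row2]), collapse = "  ")),
                 "//")
    }
    if (!is.null(file)) writeLines(out, file)
    invisible(out)
}

#' Export a property table as TSV for inspection
#'
#' One row per scale: accession, description, then the 20 residue columns.
#'
#' @param table an \code{\linkS4class{AAPropertyTable}}.
#' @param file path or connection.
#' @return the exported data.frame, invisibly.
#' @export
writePropertyTSV <- function(table, file) {
    stopifnot(is(table, "AAPropertyTable"))
    df <- data.frame(accession = rownames(table@values),
                     description = table@description,
                     table@values, check.names = FALSE,
                     row.names = NULL)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
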
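# CSV input, matrix summaries, and the simplified NEXUS / PHYLIP / CSV
# writers. The CSV dialect is deliberately plain: one row per taxon, first
# field the taxon name, no header by default.

#' Read a character matrix from CSV
#'
#' Rows are taxa, the first field is the taxon name, remaining fields are
#' one state symbol each. Gaps (`-`), `?` and empty fields are read as
#' missing; sequence-type symbols are upper-cased.
#'
#' @param file path to a CSV file (ignored when `text` is given).
#' @param dataType declared data type (see [CharacterMatrix-class]).
#' @param text optional literal CSV content instead of a file.
#' @param header whether the first row is a header (dropped).
#' @param sep field separator.
#' @param missingSymbols symbols mapped to missing.
#' @param maxTaxa,maxChars size limits (defaults 5000 and 100000).
#' @return A [CharacterMatrix-class].
#' @examples
#' readCharacterMatrix(text = "A,0,1\nB,1,1\nC,1,0\nD,0,0", dataType = "binary")
#' @export
readCharacterMatrix <- function(file, dataType, text = NULL, header = FALSE,
                                sep = ",", missingSymbols = c("?", "-", ""),
                                maxTaxa = 5000L, maxChars = 100000L) {
  dataType <- match.arg(dataType, .DATA_TYPES)
  if (is.null(text)) {
    if (!file.exists(file))
      .err(sprintf("input file not found: %s", file), "tritax_io_error")
    df <- utils::read.table(file, sep = sep, header = header,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(text = text, sep = sep, header = header,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
  }
  if (!nrow(df) || ncol(df) < 2L)
    .err("CSV must contain at least one taxon row and one character column",
         "tritax_parse_error")
  taxa <- trimws(df[[1L]])
  if (anyDuplicated(taxa))
    .err(sprintf("duplicate taxon name(s): %s",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
         "tritax_parse_error")
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- trimws(m)
  rownames(m) <- taxa
  colnames(m) <- NULL
  if (isSequenceType(dataType)) m[] <- toupper(m)
  # locate alphabet violations before construction so the error names a cell
  alpha <- typeAlphabet(dataType)
  if (!is.null(alpha)) {
    ok <- is.na(m) | m %in% c(alpha, missingSymbols)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1L, ]
      .err(sprintf("symbol \"%s\" at taxon \"%s\", character %d is not a valid %s state",
                   m[bad[1L], bad[2L]], taxa[bad[1L]], bad[2L], dataType),
           "tritax_symbol_error")
    }
  }
  characterMatrix(m, dataType, missingSymbols = missingSymbols,
                  maxTaxa = maxTaxa, maxChars = maxChars)
}

#' Summary statistics of a character matrix
#'
#' Counts taxa, characters, variable characters and parsimony-informative
#' characters. A character is parsimony-informative when at least two of its
#' states are each carried by at least two taxa; missing cells and (for
#' sequence types) ambiguity codes are excluded from the tally.
#'
#' @param x a [CharacterMatrix-class].
#' @return list with `taxa`, `characters`, `variable`, `informative`.
#' @export
matrixStats <- function(x) {
  m <- stateMatrix(x)
  amb <- ambiguitySymbols(dataType(x))
  cls <- apply(m, 2L, function(col) {
    col <- col[!is.na(col) & !(col %in% amb)]
    cnt <- table(col)
    c(variable = length(cnt) >= 2L, informative = sum(cnt >= 2L) >= 2L)
  })
  list(taxa = nrow(m), characters = ncol(m),
       variable = if (ncol(m)) sum(cls["variable", ]) else 0L,
       informative = if (ncol(m)) sum(cls["informative", ]) else 0L)
}

.outSymbols <- function(x) {
  m <- stateMatrix(x)
  m[is.na(m)] <- "?"
  m
}

.nexusFormatLine <- function(x) {
  if (notation(x) == "binary")
    return("FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";")
  dt <- dataType(x)
  if (dt == "dna") return("FORMAT DATATYPE=DNA MISSING=?;")
  if (dt == "rna") return("FORMAT DATATYPE=RNA MISSING=?;")
  if (dt == "aa") return("FORMAT DATATYPE=PROTEIN MISSING=?;")
  sym <- sort(unique(as.vector(stateMatrix(x))))
  sym <- sym[!is.na(sym)]
  sprintf("FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"%s\";",
          paste(sym, collapse = ""))
}

.checkNonEmpty <- function(x) {
  if (!ncol(stateMatrix(x)))
    .err("the matrix contains no informative statements; nothing to write",
         "tritax_empty_error")
}

#' Write a three-item matrix as simplified NEXUS
#'
#' Emits a `#NEXUS` file with a DATA block (DIMENSIONS, FORMAT, MATRIX) and,
#' when weights are included, an ASSUMPTIONS block carrying a `WTSET` vector
#' with one weight per statement column (12 significant digits).
#'
#' @param x a [ThreeItemMatrix-class].
#' @param file output path; when `NULL` the text is returned invisibly.
#' @param includeWeights write the ASSUMPTIONS wtset block.
#' @return The NEXUS text, invisibly.
#' @export
writeNexus <- function(x, file = NULL, includeWeights = TRUE) {
  .checkNonEmpty(x)
  m <- .outSymbols(x)
  tn <- taxonNames(x)
  pad <- formatC(tn, width = max(nchar(tn)) + 2L, flag = "-")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    .nexusFormatLine(x),
    "MATRIX",
    paste0(pad, apply(m, 1L, paste, collapse = "")),
    ";",
    "END;")
  if (includeWeights) {
    w <- sprintf("%.12g", statementWeights(x))
    lines <- c(lines,
               "BEGIN ASSUMPTIONS;",
               sprintf("WTSET * statement_weights (VECTOR) = %s;",
                       paste(w, collapse = " ")),
               "END;")
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Write a three-item matrix in PHYLIP format
#'
#' Relaxed PHYLIP by default: taxon name, whitespace, then the full row of
#' symbols on one line. With `strict = TRUE` names are truncated/padded to
#' the classic 10 characters. PHYLIP has no weight field; weights travel in
#' the sidecar written by [writeStatementTable()].
#'
#' @inheritParams writeNexus
#' @param strict use the strict 10-character name field.
#' @return The PHYLIP text, invisibly.
#' @export
writePhylip <- function(x, file = NULL, strict = FALSE) {
  .checkNonEmpty(x)
  m <- .outSymbols(x)
  tn <- taxonNames(x)
  if (any(grepl("[[:space:]]", tn)))
    .err("taxon names must not contain whitespace in PHYLIP output",
         "tritax_io_error")
  if (strict) {
    if (any(nchar(tn) > 10L))
      warning("taxon names truncated to 10 characters for strict PHYLIP")
    tn <- formatC(substr(tn, 1L, 10L), width = 10L, flag = "-")
  } else {
    tn <- formatC(tn, width = max(nchar(tn)) + 2L, flag = "-")
  }
  lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
             paste0(tn, apply(m, 1L, paste, collapse = "")))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Write a three-item matrix as CSV
#'
#' Mirrors the input dialect: one row per taxon, first field the taxon name,
#' one field per statement column, missing as `?`. Optionally appends a
#' trailing weight row (first field `_weights_`).
#'
#' @inheritParams writeNexus
#' @param weightRow append the per-column weight row.
#' @param sep field separator.
#' @return The CSV text, invisibly.
#' @export
writeCsvMatrix <- function(x, file = NULL, weightRow = FALSE, sep = ",") {
  .checkNonEmpty(x)
  m <- .outSymbols(x)
  rows <- paste(taxonNames(x), apply(m, 1L, paste, collapse = sep), sep = sep)
  if (weightRow)
    rows <- c(rows, paste(c("_weights_", sprintf("%.12g", statementWeights(x))),
                          collapse = sep))
  txt <- paste(rows, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Write the statement provenance sidecar
#'
#' A TSV with one row per statement column: column index, source character,
#' the out-taxon, the in-pair, and the exact rational weight. This is the
#' canonical carrier of weights for formats that cannot hold them (PHYLIP).
#'
#' @inheritParams writeNexus
#' @return The TSV text, invisibly.
#' @export
writeStatementTable <- function(x, file = NULL) {
  pv <- provenance(x)
  tn <- taxonNames(x)
  df <- data.frame(index = seq_len(nrow(pv)),
                   source_char = pv$sourceChar,
                   out_taxon = tn[pv$out],
                   in1 = tn[pv$in1],
                   in2 = tn[pv$in2],
                   weight = statementWeights(x, "character"),
                   stringsAsFactors = FALSE)
  txt <- paste(c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(df, sep = "\t"))), collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
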
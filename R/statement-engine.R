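# Statement enumeration. A three-item statement x(y z) asserts that taxa y
# and z are more closely related to each other than either is to taxon x.
# Each enumerator takes one character column (character vector of state
# symbols, NA = missing, one element per taxon) and returns a StatementBlock.

# all unordered pairs of idx (integer vector), as a 2-row matrix
.pairs2 <- function(idx) {
  if (length(idx) < 2L) return(matrix(integer(), nrow = 2))
  utils::combn(idx, 2L)
}

# statements for one (p, a) state pair: every p-taxon against every a-pair
.cross <- function(outs, pairIdx, p, a) {
  np <- ncol(pairIdx)
  if (!length(outs) || !np) return(emptyStatements())
  data.frame(out = rep(unname(outs), each = np),
             in1 = rep(unname(pairIdx[1L, ]), times = length(outs)),
             in2 = rep(unname(pairIdx[2L, ]), times = length(outs)),
             p = unname(p), a = unname(a), stringsAsFactors = FALSE)
}

#' Enumerate statements from a binary character (state 0 plesiomorphic)
#'
#' Nelson-Platnick representation of a binary character: state 0 is taken as
#' plesiomorphic a priori, so each taxon scored 0 is set against every
#' unordered pair of taxa scored 1. With m zeros and n ones the block holds
#' m * n * (n - 1) / 2 statements; taxa with missing states are excluded.
#'
#' @param column character vector of states over `{"0", "1", NA}`.
#' @param sourceChar index of the source character (provenance only).
#' @return A [StatementBlock-class].
#' @examples
#' enumerateBinary(c(A = "0", B = "1", C = "1", D = "0"))
#' @export
enumerateBinary <- function(column, sourceChar = 1L) {
  zeros <- which(!is.na(column) & column == "0")
  ones <- which(!is.na(column) & column == "1")
  newBlock(sourceChar, .cross(zeros, .pairs2(ones), "0", "1"), "binary")
}

#' Enumerate statements under the general (G) representation
#'
#' The simplest three-item representation of an unordered multistate
#' character, by exhaustion of the outgroup value: every observed state is
#' taken in turn as plesiomorphic, and each taxon bearing it is set against
#' every pair of taxa sharing any single other state. Each taxon is thereby
#' represented with all of its minimal rooted relationships to the others.
#'
#' @inheritParams enumerateBinary
#' @param column character vector of single-state symbols (`NA` = missing;
#'   ambiguity codes must already be resolved or mapped to missing).
#' @return A [StatementBlock-class]; total count is
#'   sum over ordered state pairs (p, a) of n_p * n_a * (n_a - 1) / 2.
#' @examples
#' enumerateG(c(A = "0", B = "1", C = "1", D = "2", E = "2"))
#' @export
enumerateG <- function(column, sourceChar = 1L) {
  groups <- split(seq_along(column), factor(column))  # drops NA
  states <- names(groups)
  parts <- list()
  for (p in states) {
    for (a in setdiff(states, p)) {
      parts[[length(parts) + 1L]] <-
        .cross(groups[[p]], .pairs2(groups[[a]]), p, a)
    }
  }
  newBlock(sourceChar, do.call(rbind, c(parts, list(emptyStatements()))), "G")
}

#' Enumerate statements under the Williams (W) fixed-outgroup representation
#'
#' Statements are generated only relative to a fixed plesiomorphic state --
#' the state carried by the designated outgroup taxon for this character.
#' Each taxon bearing that state is set against every pair of taxa sharing
#' any single other state.
#'
#' @inheritParams enumerateG
#' @param outgroupState the symbol fixed as plesiomorphic (non-missing).
#' @return A [StatementBlock-class]; count is n_p * sum over other states a
#'   of n_a * (n_a - 1) / 2.
#' @examples
#' enumerateW(c(A = "0", B = "1", C = "1", D = "2", E = "2"), "0")
#' @export
enumerateW <- function(column, outgroupState, sourceChar = 1L) {
  stopifnot(length(outgroupState) == 1L, !is.na(outgroupState))
  groups <- split(seq_along(column), factor(column))
  outs <- groups[[outgroupState]]
  parts <- list()
  for (a in setdiff(names(groups), outgroupState)) {
    parts[[length(parts) + 1L]] <-
      .cross(outs, .pairs2(groups[[a]]), outgroupState, a)
  }
  newBlock(sourceChar, do.call(rbind, c(parts, list(emptyStatements()))), "W")
}

#' Additive (Farris) decomposition of an ordered multistate character
#'
#' Recodes an ordered character with integer levels into threshold binary
#' columns: for each observed level v above the minimum, a column scoring 1
#' where state >= v and 0 otherwise. Missing states propagate. Only observed
#' levels generate thresholds: unobserved intermediate levels would only
#' duplicate an existing threshold column.
#'
#' @param column character vector of integer state symbols (`NA` = missing).
#' @return A list of binary columns (character vectors over `{"0","1",NA}`),
#'   one per threshold, named by the threshold level; length is the number
#'   of distinct observed levels minus one.
#' @examples
#' decomposeAdditive(c(A = "0", B = "1", C = "2", D = "2"))
#' @export
decomposeAdditive <- function(column) {
  vals <- suppressWarnings(as.integer(column))
  if (any(is.na(vals) & !is.na(column)))
    .err("ordered multistate characters must have integer states",
         "tritax_symbol_error")
  lev <- sort(unique(vals[!is.na(vals)]))
  out <- lapply(lev[-1L], function(v) {
    col <- ifelse(is.na(vals), NA_character_, ifelse(vals >= v, "1", "0"))
    names(col) <- names(column)
    col
  })
  names(out) <- as.character(lev[-1L])
  out
}

#' Enumerate statements from an ordered multistate character
#'
#' Applies [enumerateBinary()] to each threshold column of the additive
#' decomposition and concatenates the blocks, reproducing the classic
#' treatment of ordered characters. With `mus = TRUE` only unique statements
#' per input character are kept: duplicates of the same (out, pair) arising
#' from different thresholds collapse to one statement.
#'
#' @inheritParams enumerateBinary
#' @param mus keep only unique statements within this character.
#' @return A [StatementBlock-class]; the `p`/`a` columns carry the 0/1 of
#'   the derived threshold columns.
#' @examples
#' enumerateOmc(c(A = "0", B = "1", C = "2", D = "2"))            # 5 statements
#' enumerateOmc(c(A = "0", B = "1", C = "2", D = "2"), mus = TRUE) # 4 unique
#' @export
enumerateOmc <- function(column, mus = FALSE, sourceChar = 1L) {
  cols <- decomposeAdditive(column)
  st <- do.call(rbind, c(lapply(cols, function(col)
    enumerateBinary(col, sourceChar)@statements), list(emptyStatements())))
  if (mus && nrow(st))
    st <- st[!duplicated(st[c("out", "in1", "in2")]), , drop = FALSE]
  newBlock(sourceChar, st, "omc")
}

#' Render one statement as a matrix column
#'
#' In binary notation the out-taxon is scored `"0"`, the in-pair `"1"` and
#' every other taxon missing (`NA`); in multistate notation the original
#' plesiomorphic and apomorphic symbols are kept instead.
#'
#' @param statement one-row statement data.frame (columns `out`, `in1`,
#'   `in2`, `p`, `a`), e.g. one row of a [StatementBlock-class]'s statements.
#' @param notation `"binary"` or `"multistate"`.
#' @param taxonCount number of rows of the output column.
#' @return Character vector of length `taxonCount` with exactly three
#'   non-missing entries.
#' @export
renderColumn <- function(statement, notation = c("binary", "multistate"),
                         taxonCount) {
  notation <- match.arg(notation)
  col <- rep(NA_character_, taxonCount)
  if (notation == "binary") {
    col[statement$out] <- "0"
    col[c(statement$in1, statement$in2)] <- "1"
  } else {
    col[statement$out] <- statement$p
    col[c(statement$in1, statement$in2)] <- statement$a
  }
  col
}
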
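# Fractional weighting of three-item statements.
#
# All weight arithmetic is carried out in exact rationals so that the
# conservation identity (sum of a character's statement weights equals its
# independent-statement count i) holds bit-exactly; decimals appear only at
# serialization.

#' Nelson-Ladiges fractional weighting of a binary character
#'
#' For a binary character scored in t taxa of which n carry the derived
#' state, the character implies s = n(n-1)(t-n)/2 statements of which only
#' i = (n-1)(t-n) are mutually independent on a cladogram; fractional
#' weighting assigns each statement the ratio i/s = 2/n so that redundant
#' statements do not overweight the character.
#'
#' @param t number of taxa scored (non-missing) for the character.
#' @param n number of taxa carrying the derived (apomorphic) state.
#' @return A list with `t`, `n`, `s`, `i` and `weight` (a length-1
#'   `rational`, or length-0 when the character implies no statements).
#' @examples
#' fwBinary(t = 4, n = 3)  # s = 3, i = 2, weight 2/3
#' @export
fwBinary <- function(t, n) {
  s <- n * (n - 1) * (t - n) / 2
  i <- (n - 1) * (t - n)
  w <- if (s > 0) rational(2, n) else rational(integer(), integer())
  list(t = t, n = n, s = s, i = i, weight = w)
}

# per-state counts of a column, missing dropped
.stateCounts <- function(column) table(column[!is.na(column)])

#' Fractional-weighting parameters under the G-representation
#'
#' Adapts the binary fractional-weighting forms to an unordered multistate
#' character by treating each ordered pair of observed states (p, a) as a
#' pseudo-binary character scored in t' = n_p + n_a taxa with n' = n_a
#' derived: each (p, a) contributes s' = n_p n_a (n_a - 1)/2 statements and
#' i' = n_p (n_a - 1) independent ones, so every statement whose in-pair
#' shares state a weighs 2/n_a. This per-pair decomposition reduces exactly
#' to the binary case when only one derived state is present.
#'
#' @param column one character column (symbols, `NA` missing).
#' @return list with `t` (taxa scored), `n` (taxa carrying informative
#'   states), `k` (number of informative states, i.e. shared by at least two
#'   taxa), `s` (total statements) and `i` (independent statements).
#' @seealso [fwBinary()], [blockWeights()]
#' @export
fwParamsG <- function(column) {
  cnt <- .stateCounts(column)
  inf <- cnt[cnt >= 2L]
  s <- 0; i <- 0
  for (p in names(cnt)) for (a in names(cnt)) {
    if (p == a) next
    s <- s + cnt[[p]] * cnt[[a]] * (cnt[[a]] - 1) / 2
    i <- i + cnt[[p]] * (cnt[[a]] - 1)
  }
  list(t = sum(cnt), n = sum(inf), k = length(inf), s = s, i = i)
}

#' Fixed-outgroup (Wt) weighting parameters
#'
#' Under the W-representation the plesiomorphic state is fixed, and the
#' optional Wt weight is the fraction i_w / s_w, where s_w is the total
#' number of statements with the outgroup value fixed and i_w the
#' corresponding independent count (per-(p,a) closed forms restricted to the
#' fixed p). An alternative variant weighs every statement 1/s_w.
#'
#' @inheritParams fwParamsG
#' @param outgroupState the fixed plesiomorphic symbol.
#' @return list with `s` (s_w), `i` (i_w), and `weight` (length-1 rational;
#'   length-0 when no statements exist).
#' @export
wtParams <- function(column, outgroupState) {
  cnt <- .stateCounts(column)
  np <- if (outgroupState %in% names(cnt)) cnt[[outgroupState]] else 0L
  s <- 0; i <- 0
  for (a in setdiff(names(cnt), outgroupState)) {
    s <- s + np * cnt[[a]] * (cnt[[a]] - 1) / 2
    i <- i + np * (cnt[[a]] - 1)
  }
  w <- if (s > 0) rational(i, s) else rational(integer(), integer())
  list(s = s, i = i, weight = w)
}

#' Per-statement weights for one statement block
#'
#' Dispatches on the block's representation and the requested weighting
#' mode; returns one exact rational weight per statement, aligned with the
#' block's statement order.
#'
#' @param block a [StatementBlock-class].
#' @param column the source character column the block was derived from.
#' @param mode `"uniform"`, `"fw"` (Nelson-Ladiges fractional), `"wt"`
#'   (fixed-outgroup fraction; W blocks only) or `"disabled"`.
#' @param wtVariant for `mode = "wt"`: `"fraction"` (i_w/s_w, default) or
#'   `"inverse"` (1/s_w).
#' @return A `rational` vector of length `nrow` of the block's statements.
#' @examples
#' col <- c(A = "0", B = "1", C = "1", D = "1")
#' blockWeights(enumerateBinary(col), col, mode = "fw")  # 2/3 each
#' @export
blockWeights <- function(block, column,
                         mode = c("uniform", "fw", "wt", "disabled"),
                         wtVariant = c("fraction", "inverse")) {
  mode <- match.arg(mode)
  wtVariant <- match.arg(wtVariant)
  st <- block@statements
  nst <- nrow(st)
  if (mode %in% c("uniform", "disabled") || nst == 0L)
    return(rational(rep(1, nst)))
  rep_ <- block@representation
  if (mode == "fw") {
    if (rep_ == "binary") {
      n <- sum(!is.na(column) & column == "1")
      return(rational(rep(2, nst), rep(n, nst)))
    }
    if (rep_ == "G") {
      cnt <- .stateCounts(column)
      na <- as.integer(cnt[st$a])
      return(rational(rep(2, nst), na))
    }
    .err(sprintf(
      "fractional weighting is not defined for the %s representation", rep_),
      "tritax_config_error")
  }
  # mode == "wt"
  if (rep_ != "W")
    .err("Wt weighting applies only to W-representation blocks",
         "tritax_config_error")
  pr <- wtParams(column, st$p[1L])
  w <- if (wtVariant == "fraction") rational(pr$i, pr$s) else rational(1, pr$s)
  rational(rep(w$num, nst), rep(w$den, nst))
}

# all resolved copies of a column, expanding IUPAC ambiguity codes.
# Returns a list of columns; length 1 when nothing is ambiguous.
.resolutions <- function(column, dataType, maxResolutions = 4096L) {
  amb <- ambiguityMap(dataType)
  hit <- which(!is.na(column) & column %in% names(amb))
  if (!length(hit)) return(list(column))
  opts <- lapply(column[hit], function(s) amb[[s]])
  nres <- prod(lengths(opts))
  if (nres > maxResolutions) {
    warning(sprintf(
      "character has %d ambiguity resolutions (> %d); treating ambiguous cells as missing",
      nres, maxResolutions))
    column[hit] <- NA_character_
    return(list(column))
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    column[hit] <- as.character(grid[r, ])
    column
  })
}

#' Average statement weights over ambiguity resolutions
#'
#' Opt-in treatment of IUPAC ambiguity codes (the default maps them to
#' missing): the character is enumerated under every resolution of its
#' ambiguous cells, and each statement receives the mean of its weights over
#' the resolutions in which it occurs, scaled by the fraction of resolutions
#' containing it -- equivalently, the sum of its per-resolution weights
#' divided by the number of resolutions. Statements absent from all
#' resolutions do not appear.
#'
#' @param column one character column, possibly containing ambiguity codes.
#' @param dataType `"dna"`, `"rna"` or `"aa"` (other types have no codes).
#' @param enumerate function(column) -> [StatementBlock-class] for one fully
#'   resolved column.
#' @param mode,wtVariant base weighting passed to [blockWeights()].
#' @param sourceChar source character index for the returned block.
#' @param maxResolutions cap on the resolution count per character; beyond
#'   it ambiguous cells fall back to missing (with a warning).
#' @return list with `block` (a [StatementBlock-class] of the union of
#'   statements, identified by out/in-pair/states) and `weights` (rational).
#' @examples
#' col <- c(A = "0", B = "1", C = "R", D = "1")
#' # treat as DNA-style {0,1} toy via a W enumerator fixing p = "0"
#' @export
ambiguityAverage <- function(column, dataType, enumerate,
                             mode = "uniform", wtVariant = "fraction",
                             sourceChar = 1L, maxResolutions = 4096L) {
  cols <- .resolutions(column, dataType, maxResolutions)
  R <- length(cols)
  acc <- new.env(parent = emptyenv())
  rows <- list()
  repr <- "G"
  for (col in cols) {
    blk <- enumerate(col)
    repr <- blk@representation
    st <- blk@statements
    if (!nrow(st)) next
    w <- blockWeights(blk, col, mode, wtVariant)
    keys <- paste(st$out, st$in1, st$in2, st$p, st$a, sep = "\r")
    for (j in seq_len(nrow(st))) {
      k <- keys[j]
      wj <- ratSubset(w, j)
      if (is.null(acc[[k]])) {
        acc[[k]] <- wj
        rows[[k]] <- st[j, , drop = FALSE]
      } else {
        acc[[k]] <- ratAdd(acc[[k]], wj)
      }
    }
  }
  if (!length(rows)) {
    blk <- newBlock(sourceChar, emptyStatements(), repr)
    return(list(block = blk, weights = rational(integer(), integer())))
  }
  st <- do.call(rbind, rows)
  totals <- lapply(names(rows), function(k) ratMul(acc[[k]], rational(1, R)))
  o <- order(st$out, st$in1, st$in2, st$p, st$a)
  st <- st[o, , drop = FALSE]; rownames(st) <- NULL
  totals <- totals[o]
  blk <- new("StatementBlock", sourceChar = as.integer(sourceChar),
             statements = st, representation = repr)
  list(block = blk, weights = do.call(ratC, totals))
}

#' Select the effective weighting mode for a matrix
#'
#' Applies the global rules: per-character deduplication (`mus`) is tied to
#' uniform weights; fractional weighting is not offered for ordered
#' multistate characters; and when every character of a sequence-type matrix
#' contains ambiguity codes, weighting is disabled altogether.
#'
#' @param x a [CharacterMatrix-class].
#' @param requested `"uniform"`, `"fw"` or `"wt"`.
#' @param mus logical, per-character unique-statement option.
#' @param representation `"binary"`, `"G"`, `"W"` or `"omc"`.
#' @return The effective mode: the request, or `"disabled"`.
#' @export
weightingPolicy <- function(x, requested = c("uniform", "fw", "wt"),
                            mus = FALSE, representation = "G") {
  requested <- match.arg(requested)
  if (mus && requested != "uniform")
    .err("the unique-statements option (-mus) implies uniform weights; fractional weighting cannot be combined with it",
         "tritax_config_error")
  if (representation == "omc" && requested != "uniform")
    .err("ordered multistate characters support uniform weighting only",
         "tritax_config_error")
  if (requested == "fw" && representation == "W")
    .err("use Wt weighting for the fixed-outgroup (W) representation",
         "tritax_config_error")
  if (requested == "wt" && representation != "W")
    .err("Wt weighting applies only to the fixed-outgroup (W) representation",
         "tritax_config_error")
  if (requested != "uniform") {
    amb <- ambiguitySymbols(dataType(x))
    if (length(amb)) {
      m <- stateMatrix(x)
      hasAmb <- vapply(seq_len(ncol(m)),
                       function(j) any(m[, j] %in% amb), logical(1))
      if (length(hasAmb) && all(hasAmb)) return("disabled")
    }
  }
  requested
}
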
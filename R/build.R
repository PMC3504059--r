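#' Build a three-item statement matrix from a character matrix
#'
#' Top-level assembly: enumerates the statements of every character under
#' the chosen representation, attaches weights, and renders the result as a
#' [ThreeItemMatrix-class] in binary or multistate notation. Per-character
#' statement blocks are concatenated in character order; within a block,
#' statements are ordered by (out-taxon index, in-pair indices), so the
#' output is fully deterministic.
#'
#' Representations: `"binary"` (state 0 plesiomorphic a priori), `"G"`
#' (exhaustion of the outgroup value over all observed states), `"W"`
#' (states polarized against the state of a fixed outgroup taxon; with
#' binary notation this is the WS form) and `"omc"` (additive threshold
#' decomposition of ordered characters). `"auto"` picks `"binary"`/`"omc"`
#' for those data types, otherwise `"W"` when an outgroup is given, else
#' `"G"`.
#'
#' @param x a [CharacterMatrix-class].
#' @param representation `"auto"`, `"binary"`, `"G"`, `"W"` or `"omc"`.
#' @param notation `"binary"` or `"multistate"` output notation.
#' @param outgroup taxon name or index fixing the plesiomorphic state per
#'   character (required for `"W"`). Characters for which the outgroup is
#'   missing or ambiguous are skipped with a warning.
#' @param mus keep only unique statements per input character (ordered
#'   multistate characters; forces uniform weights).
#' @param weighting `"uniform"`, `"fw"` (Nelson-Ladiges fractional) or
#'   `"wt"` (fixed-outgroup fraction, W only).
#' @param ambiguity `"missing"` (default: IUPAC ambiguity codes become
#'   missing data, the recommended treatment) or `"average"` (statements are
#'   averaged over all resolutions of the ambiguous cells).
#' @param wtVariant Wt flavour: `"fraction"` (i_w/s_w) or `"inverse"` (1/s_w).
#' @return A [ThreeItemMatrix-class]. Errors with a dedicated condition when
#'   no informative statement exists.
#' @examples
#' cm <- characterMatrix(rbind(A = "0", B = "1", C = "1", D = "2", E = "2"),
#'                       "umc")
#' buildThreeItemMatrix(cm)                          # G: 6 statements
#' buildThreeItemMatrix(cm, outgroup = "A")          # W/WS: 2 statements
#' @export
buildThreeItemMatrix <- function(x,
                                 representation = c("auto", "binary", "G",
                                                    "W", "omc"),
                                 notation = c("binary", "multistate"),
                                 outgroup = NULL, mus = FALSE,
                                 weighting = c("uniform", "fw", "wt"),
                                 ambiguity = c("missing", "average"),
                                 wtVariant = c("fraction", "inverse")) {
  stopifnot(is(x, "CharacterMatrix"))
  representation <- match.arg(representation)
  notation <- match.arg(notation)
  weighting <- match.arg(weighting)
  ambiguity <- match.arg(ambiguity)
  wtVariant <- match.arg(wtVariant)
  dt <- dataType(x)
  if (representation == "auto") {
    representation <- switch(dt, binary = "binary", omc = "omc",
                             if (is.null(outgroup)) "G" else "W")
  }
  if (representation == "binary" && dt != "binary")
    .err("the a-priori-polarized binary representation requires binary input",
         "tritax_config_error")
  if (representation == "omc" && dt != "omc")
    .err("additive decomposition requires ordered multistate input",
         "tritax_config_error")
  if (representation == "binary" && !is.null(outgroup))
    .err(paste("binary input fixes state 0 as plesiomorphic; an outgroup",
               "taxon would contradict it (declare the data as umc instead)"),
         "tritax_config_error")

  m <- stateMatrix(x)
  tn <- rownames(m)
  ogIdx <- NULL
  if (representation == "W") {
    if (is.null(outgroup))
      .err("the W representation requires an outgroup taxon",
           "tritax_config_error")
    ogIdx <- if (is.character(outgroup)) match(outgroup, tn)
             else as.integer(outgroup)
    if (is.na(ogIdx) || ogIdx < 1L || ogIdx > nrow(m))
      .err(sprintf("outgroup \"%s\" is not a taxon of the matrix",
                   as.character(outgroup)), "tritax_config_error")
  }

  mode <- weightingPolicy(x, weighting, mus, representation)
  amb <- ambiguitySymbols(dt)
  average <- ambiguity == "average" && length(amb) > 0L && mode != "disabled"

  blocks <- vector("list", ncol(m))
  weights <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    enum <- switch(representation,
      binary = function(cc) enumerateBinary(cc, j),
      G = function(cc) enumerateG(cc, j),
      omc = function(cc) enumerateOmc(cc, mus, j),
      W = function(cc) {
        s <- cc[ogIdx]
        if (is.na(s)) newBlock(j, emptyStatements(), "W")
        else enumerateW(cc, s, j)
      })
    if (average) {
      res <- ambiguityAverage(col, dt, enum, mode = mode,
                              wtVariant = wtVariant, sourceChar = j)
      blocks[[j]] <- res$block
      weights[[j]] <- res$weights
    } else {
      col[col %in% amb] <- NA_character_
      if (representation == "W" && is.na(col[ogIdx]) &&
          any(!is.na(col)))
        warning(sprintf(
          "character %d skipped: outgroup state is missing or ambiguous", j))
      blk <- enum(col)
      blocks[[j]] <- blk
      weights[[j]] <- blockWeights(blk, col, mode, wtVariant)
    }
  }

  sts <- lapply(blocks, slot, "statements")
  nPer <- vapply(sts, nrow, integer(1))
  total <- sum(nPer)
  if (total == 0L)
    .err("no informative statements can be derived from this matrix",
         "tritax_empty_error")
  pv <- do.call(rbind, sts)
  pv <- cbind(sourceChar = rep(seq_along(blocks), nPer), pv)
  rownames(pv) <- NULL

  out <- matrix(NA_character_, nrow = nrow(m), ncol = total,
                dimnames = list(tn, NULL))
  for (k in seq_len(total))
    out[, k] <- renderColumn(pv[k, , drop = FALSE], notation, nrow(m))

  w <- do.call(ratC, weights[nPer > 0L])
  new("ThreeItemMatrix", states = out, weights = w, notation = notation,
      dataType = dt, provenance = pv, weightingMode = mode)
}
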
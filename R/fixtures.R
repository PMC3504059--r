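# Reproducible random character matrices for property testing and demos.

.baseSymbols <- function(dataType, nStates = 4L) {
  switch(dataType,
    binary = c("0", "1"),
    omc = as.character(seq_len(nStates) - 1L),
    umc = as.character(seq_len(nStates) - 1L),
    dna = c("A", "C", "G", "T"),
    rna = c("A", "C", "G", "U"),
    aa = .AA_ONE)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a random character matrix
#'
#' Draws i.i.d. states per cell from the base alphabet of the data type,
#' then sprinkles missing cells and (for sequence types) IUPAC ambiguity
#' codes at the requested rates. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param nTaxa,nChars matrix dimensions.
#' @param dataType one of the supported data types.
#' @param stateFreqs optional named frequency vector over the base alphabet
#'   (must sum to 1); default uniform.
#' @param missingFraction,ambiguityFraction per-cell probabilities in
#'   `[0, 1]`; ambiguity codes only exist for sequence types.
#' @param nStates alphabet size for `omc`/`umc` data.
#' @param seed optional integer seed.
#' @return A [CharacterMatrix-class] with taxa named `t1`, `t2`, ...
#' @examples
#' generateMatrix(6, 10, "dna", seed = 1)
#' @export
generateMatrix <- function(nTaxa, nChars, dataType = "binary",
                           stateFreqs = NULL, missingFraction = 0,
                           ambiguityFraction = 0, nStates = 4L, seed = NULL) {
  dataType <- match.arg(dataType, .DATA_TYPES)
  stopifnot(missingFraction >= 0, missingFraction <= 1,
            ambiguityFraction >= 0, ambiguityFraction <= 1)
  base <- .baseSymbols(dataType, nStates)
  if (is.null(stateFreqs)) {
    stateFreqs <- stats::setNames(rep(1 / length(base), length(base)), base)
  } else {
    stopifnot(setequal(names(stateFreqs), base),
              abs(sum(stateFreqs) - 1) < 1e-9)
    stateFreqs <- stateFreqs[base]
  }
  amb <- ambiguitySymbols(dataType)
  if (!length(amb)) ambiguityFraction <- 0
  .withSeed(seed, {
    cells <- sample(base, nTaxa * nChars, replace = TRUE, prob = stateFreqs)
    if (ambiguityFraction > 0) {
      hit <- stats::runif(length(cells)) < ambiguityFraction
      cells[hit] <- sample(amb, sum(hit), replace = TRUE)
    }
    if (missingFraction > 0)
      cells[stats::runif(length(cells)) < missingFraction] <- NA_character_
    m <- matrix(cells, nrow = nTaxa,
                dimnames = list(paste0("t", seq_len(nTaxa)), NULL))
    characterMatrix(m, dataType)
  })
}
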
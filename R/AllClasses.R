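#' @import methods
NULL

setOldClass("rational")

.err <- function(msg, class) {
  stop(structure(class = c(class, "tritax_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' CharacterMatrix: a taxa-by-characters state grid
#'
#' Holds a conventional phylogenetic character matrix: one row per taxon, one
#' column per character, cells are single state symbols (`NA` = missing).
#' The declared data type fixes the admissible alphabet: `"binary"` (0/1,
#' state 0 plesiomorphic a priori), `"omc"` (ordered multistate, integer
#' levels 0-9), `"umc"` (unordered multistate, free alphabet of up to 25
#' symbols), and the sequence types `"dna"`, `"rna"`, `"aa"` with their
#' IUPAC alphabets including ambiguity codes.
#'
#' @slot states character matrix of state symbols; rownames are taxon names.
#' @slot dataType one of `"binary"`, `"omc"`, `"umc"`, `"dna"`, `"rna"`, `"aa"`.
#'
#' @seealso [characterMatrix()], [readCharacterMatrix()], [matrixStats()]
#' @export
setClass("CharacterMatrix",
  representation(states = "matrix", dataType = "character"))

setValidity("CharacterMatrix", function(object) {
  m <- object@states
  dt <- object@dataType
  if (length(dt) != 1L || !dt %in% .DATA_TYPES)
    return(sprintf("dataType must be one of %s",
                   paste(.DATA_TYPES, collapse = ", ")))
  if (!is.character(m)) return("states must be a character matrix")
  tn <- rownames(m)
  if (is.null(tn) || any(!nzchar(tn)) || anyNA(tn))
    return("all taxa must have non-empty names")
  if (anyDuplicated(tn)) return("taxon names must be unique")
  alpha <- typeAlphabet(dt)
  sym <- unique(m[!is.na(m)])
  if (is.null(alpha)) {  # umc: free alphabet, bounded size
    if (length(sym) > 25L)
      return("unordered multistate alphabet exceeds 25 symbols")
  } else if (length(bad <- setdiff(sym, alpha))) {
    return(sprintf("symbol(s) not in the %s alphabet: %s", dt,
                   paste(bad, collapse = " ")))
  }
  TRUE
})

#' Construct a CharacterMatrix
#'
#' @param states a character matrix (taxa as rows, rownames = taxon names) or
#'   anything coercible to one; cells `"?"`, `"-"` and `NA` are treated as
#'   missing. Symbols of sequence types are upper-cased; gaps map to missing.
#' @param dataType declared data type (see [CharacterMatrix-class]).
#' @param missingSymbols symbols mapped to `NA` on construction.
#' @param maxTaxa,maxChars size limits; the defaults mirror the converter's
#'   published bounds and can be raised by the caller.
#' @return A validated [CharacterMatrix-class] object.
#' @examples
#' m <- rbind(A = c("0", "1"), B = c("1", "1"), C = c("1", "0"), D = c("0", "0"))
#' characterMatrix(m, "binary")
#' @export
characterMatrix <- function(states, dataType,
                            missingSymbols = c("?", "-"),
                            maxTaxa = 5000L, maxChars = 100000L) {
  dataType <- match.arg(dataType, .DATA_TYPES)
  states <- as.matrix(states)
  mode(states) <- "character"
  if (nrow(states) > maxTaxa)
    .err(sprintf("matrix has %d taxa; the limit is %d", nrow(states), maxTaxa),
         "tritax_limit_error")
  if (ncol(states) > maxChars)
    .err(sprintf("matrix has %d characters; the limit is %d", ncol(states),
                 maxChars), "tritax_limit_error")
  if (isSequenceType(dataType)) states[] <- toupper(states)
  states[states %in% missingSymbols] <- NA_character_
  obj <- new("CharacterMatrix", states = states, dataType = dataType)
  msg <- validObject(obj, test = TRUE)
  if (is.character(msg)) .err(msg, "tritax_symbol_error")
  obj
}

#' StatementBlock: the three-item statements from one character
#'
#' All statements derived from a single input character under one
#' representation. Statements are stored as a data.frame with columns
#' `out` (taxon index of the outgroup item), `in1`, `in2` (sorted taxon
#' indices of the paired items), `p` (plesiomorphic symbol) and `a`
#' (apomorphic symbol), ordered by (out, in1, in2).
#'
#' @slot sourceChar index of the input character.
#' @slot statements data.frame as described above.
#' @slot representation `"binary"`, `"G"`, `"W"` or `"omc"`.
#' @export
setClass("StatementBlock",
  representation(sourceChar = "integer", statements = "data.frame",
                 representation = "character"))

setValidity("StatementBlock", function(object) {
  st <- object@statements
  need <- c("out", "in1", "in2", "p", "a")
  if (!all(need %in% names(st))) return("statements lack required columns")
  if (nrow(st)) {
    if (any(st$out == st$in1 | st$out == st$in2))
      return("out taxon must not appear in the in-pair")
    if (any(st$in1 >= st$in2))
      return("in-pair must hold two distinct taxa, indices sorted")
    if (any(st$p == st$a))
      return("plesiomorphic and apomorphic states must differ")
  }
  TRUE
})

newBlock <- function(sourceChar, statements, representation) {
  if (nrow(statements)) {
    o <- order(statements$out, statements$in1, statements$in2)
    statements <- statements[o, , drop = FALSE]
    rownames(statements) <- NULL
  }
  new("StatementBlock", sourceChar = as.integer(sourceChar),
      statements = statements, representation = representation)
}

emptyStatements <- function() {
  data.frame(out = integer(), in1 = integer(), in2 = integer(),
             p = character(), a = character(), stringsAsFactors = FALSE)
}

#' ThreeItemMatrix: a rendered three-item statement matrix
#'
#' The output of [buildThreeItemMatrix()]: one column per statement, in the
#' input taxon order, with a parallel weight vector (exact rationals) and
#' per-column provenance. In binary notation the out-taxon carries `"0"`,
#' the in-pair `"1"`, everything else `"?"` (missing); in multistate
#' notation the original plesiomorphic/apomorphic symbols are kept.
#'
#' @slot states character matrix (taxa x statements); `NA` = missing.
#' @slot weights a `rational` weight vector, one per column.
#' @slot notation `"binary"` or `"multistate"`.
#' @slot dataType data type of the source matrix.
#' @slot provenance data.frame: `sourceChar`, `out`, `in1`, `in2`, `p`, `a`
#'   (taxon columns hold indices into `taxonNames`).
#' @slot weightingMode `"uniform"`, `"fw"`, `"wt"` or `"disabled"`.
#' @export
setClass("ThreeItemMatrix",
  representation(states = "matrix", weights = "rational", notation = "character",
                 dataType = "character", provenance = "data.frame",
                 weightingMode = "character"))

setValidity("ThreeItemMatrix", function(object) {
  m <- object@states
  if (!object@notation %in% c("binary", "multistate"))
    return("notation must be binary or multistate")
  if (ratLength(object@weights) != ncol(m))
    return("weights length must equal column count")
  if (nrow(object@provenance) != ncol(m))
    return("provenance must have one row per column")
  filled <- colSums(!is.na(m))
  if (ncol(m) && any(filled != 3L))
    return("every statement column must score exactly three taxa")
  if (any(object@weights$num <= 0))
    return("all weights must be positive")
  TRUE
})

# ---- generics ----------------------------------------------------------

#' @describeIn CharacterMatrix-class taxon names, in input order.
#' @param x,object a `CharacterMatrix` or `ThreeItemMatrix`.
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))

#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @export
setGeneric("statementWeights", function(x, ...) standardGeneric("statementWeights"))

#' @export
setGeneric("notation", function(x) standardGeneric("notation"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("weightingMode", function(x) standardGeneric("weightingMode"))

#' @export
setMethod("taxonNames", "CharacterMatrix", function(x) rownames(x@states))
#' @export
setMethod("dataType", "CharacterMatrix", function(x) x@dataType)
#' @export
setMethod("stateMatrix", "CharacterMatrix", function(x) x@states)
#' @export
setMethod("dim", "CharacterMatrix", function(x) dim(x@states))

#' @export
setMethod("taxonNames", "ThreeItemMatrix", function(x) rownames(x@states))
#' @export
setMethod("stateMatrix", "ThreeItemMatrix", function(x) x@states)
#' @export
setMethod("dim", "ThreeItemMatrix", function(x) dim(x@states))
#' @export
setMethod("dataType", "ThreeItemMatrix", function(x) x@dataType)
#' @export
setMethod("notation", "ThreeItemMatrix", function(x) x@notation)
#' @export
setMethod("provenance", "ThreeItemMatrix", function(x) x@provenance)
#' @export
setMethod("weightingMode", "ThreeItemMatrix", function(x) x@weightingMode)

#' @param format `"numeric"` for doubles, `"character"` for exact fractions,
#'   `"rational"` for the internal exact representation.
#' @describeIn ThreeItemMatrix-class per-statement weights.
#' @export
setMethod("statementWeights", "ThreeItemMatrix",
  function(x, format = c("numeric", "character", "rational")) {
    format <- match.arg(format)
    switch(format,
           numeric = ratAsNumeric(x@weights),
           character = ratFormat(x@weights),
           rational = x@weights)
  })

#' @export
setMethod("show", "CharacterMatrix", function(object) {
  cat(sprintf("CharacterMatrix: %d taxa x %d characters (%s)\n",
              nrow(object@states), ncol(object@states), object@dataType))
  s <- matrixStats(object)
  cat(sprintf("  variable: %d  parsimony-informative: %d  missing cells: %d\n",
              s$variable, s$informative, sum(is.na(object@states))))
})

#' @export
setMethod("show", "ThreeItemMatrix", function(object) {
  cat(sprintf("ThreeItemMatrix: %d taxa x %d statements (%s notation, %s weights)\n",
              nrow(object@states), ncol(object@states), object@notation,
              object@weightingMode))
  if (ncol(object@states)) {
    w <- unique(ratFormat(object@weights))
    cat(sprintf("  from %d source character(s); distinct weights: %s\n",
                length(unique(object@provenance$sourceChar)),
                paste(utils::head(w, 8), collapse = " ")))
  }
})
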
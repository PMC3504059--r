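# Minimal exact rational arithmetic on parallel integer num/den vectors.
# Weight values here are tiny (numerators/denominators bounded by taxon
# counts), so plain doubles holding exact integers are safe carriers.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    r <- ifelse(b == 0, 0, a %% b)
    a <- ifelse(b == 0, a, b)   # keep finished elements untouched
    b <- r
  }
  a
}

#' Exact rational vectors
#'
#' A tiny internal representation of vectors of exact rationals, used so that
#' fractional statement weights (e.g. 2/3) sum exactly to the independent
#' statement count without floating-point error.
#'
#' @param num integer numerators.
#' @param den integer denominators (must be non-zero).
#' @return An object of class `"rational"`: a list with reduced `num` and
#'   `den` vectors (denominators positive).
#' @keywords internal
rational <- function(num, den = rep(1, length(num))) {
  if (length(den) == 1L && length(num) > 1L) den <- rep(den, length(num))
  stopifnot(length(num) == length(den), all(den != 0))
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- .gcd(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

ratLength <- function(x) length(x$num)

ratC <- function(...) {
  parts <- list(...)
  rational(unlist(lapply(parts, `[[`, "num")),
           unlist(lapply(parts, `[[`, "den")))
}

ratAdd <- function(x, y) {
  rational(x$num * y$den + y$num * x$den, x$den * y$den)
}

ratMul <- function(x, y) rational(x$num * y$num, x$den * y$den)

ratSum <- function(x) {
  out <- rational(0, 1)
  for (i in seq_len(ratLength(x)))
    out <- ratAdd(out, rational(x$num[i], x$den[i]))
  out
}

ratEq <- function(x, y) x$num * y$den == y$num * x$den

ratAsNumeric <- function(x) x$num / x$den

ratFormat <- function(x) ifelse(x$den == 1, sprintf("%d", as.integer(x$num)),
                                sprintf("%d/%d", as.integer(x$num),
                                        as.integer(x$den)))

ratSubset <- function(x, i) rational(x$num[i], x$den[i])

#' @export
print.rational <- function(x, ...) {
  cat("rational:", paste(ratFormat(x), collapse = " "), "\n")
  invisible(x)
}
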
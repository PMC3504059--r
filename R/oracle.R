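# Brute-force oracle: scans every (x, {y, z}) taxon triple of every
# character and applies the representation's admission rule directly on the
# three observed states. Deliberately shares no code with the statement
# engine (no per-state grouping, no pair expansion) so the two can serve as
# independent cross-checks in tests.

# all t * C(t-1, 2) triples, as a data.frame of (out, in1, in2), in1 < in2
.allTriples <- function(t) {
  prs <- t(utils::combn(seq_len(t), 2L))
  out <- rep(seq_len(t), each = nrow(prs))
  y <- rep(prs[, 1L], times = t)
  z <- rep(prs[, 2L], times = t)
  keep <- out != y & out != z
  data.frame(out = out[keep], in1 = y[keep], in2 = z[keep])
}

#' Brute-force enumeration of three-item statements
#'
#' Independent re-implementation of the statement enumerators by exhaustive
#' scan over all taxon triples. Intended as a test oracle: O(t^3) per
#' character, no shared code with [enumerateBinary()] and friends.
#' Ambiguity codes are treated as missing.
#'
#' @param x a [CharacterMatrix-class].
#' @param representation `"binary"`, `"G"`, `"W"` or `"omc"`.
#' @param outgroup taxon name or index (W only).
#' @param mus unique statements per character (omc only).
#' @return data.frame (`char`, `out`, `in1`, `in2`), one row per statement
#'   (duplicates repeated when `mus = FALSE`), sorted by all four columns.
#' @export
oracleEnumerate <- function(x, representation = c("binary", "G", "W", "omc"),
                            outgroup = NULL, mus = FALSE) {
  representation <- match.arg(representation)
  m <- stateMatrix(x)
  m[m %in% ambiguitySymbols(dataType(x))] <- NA_character_
  t <- nrow(m)
  tri <- .allTriples(t)
  ogIdx <- if (is.character(outgroup)) match(outgroup, rownames(m))
           else outgroup
  res <- list()
  for (j in seq_len(ncol(m))) {
    sx <- m[tri$out, j]; sy <- m[tri$in1, j]; sz <- m[tri$in2, j]
    scored <- !is.na(sx) & !is.na(sy) & !is.na(sz)
    times <- integer(nrow(tri))
    if (representation == "binary") {
      times[scored & sx == "0" & sy == "1" & sz == "1"] <- 1L
    } else if (representation == "G") {
      times[scored & sy == sz & sx != sy] <- 1L
    } else if (representation == "W") {
      og <- m[ogIdx, j]
      if (!is.na(og))
        times[scored & sx == og & sy == sz & sy != og] <- 1L
    } else {  # omc: one hit per observed threshold separating x from {y,z}
      vx <- as.integer(sx); vy <- as.integer(sy); vz <- as.integer(sz)
      lev <- sort(unique(as.integer(m[, j])))
      for (v in lev[-1L]) {
        hit <- scored & vx < v & vy >= v & vz >= v
        times[hit] <- times[hit] + 1L
      }
      if (mus) times <- pmin(times, 1L)
    }
    if (any(times > 0L)) {
      idx <- rep(seq_len(nrow(tri)), times)
      res[[length(res) + 1L]] <- cbind(char = j, tri[idx, , drop = FALSE])
    }
  }
  if (!length(res))
    return(data.frame(char = integer(), out = integer(),
                      in1 = integer(), in2 = integer()))
  df <- do.call(rbind, res)
  df <- df[order(df$char, df$out, df$in1, df$in2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Closed-form per-character statement counts
#'
#' The combinatorial identities the enumerators must satisfy: with m/n the
#' zero/one counts of a binary character, the count is m n (n-1) / 2; under
#' G it is the sum over ordered state pairs (p, a) of n_p n_a (n_a - 1) / 2;
#' under W the sum is restricted to p = the outgroup state; for omc each
#' threshold column contributes its binary count (without `mus`).
#'
#' @inheritParams oracleEnumerate
#' @return integer vector, one count per character.
#' @export
oracleCounts <- function(x, representation = c("binary", "G", "W", "omc"),
                         outgroup = NULL) {
  representation <- match.arg(representation)
  m <- stateMatrix(x)
  m[m %in% ambiguitySymbols(dataType(x))] <- NA_character_
  ogIdx <- if (is.character(outgroup)) match(outgroup, rownames(m))
           else outgroup
  vapply(seq_len(ncol(m)), function(j) {
    cnt <- table(m[!is.na(m[, j]), j])
    if (representation == "binary") {
      n <- if ("1" %in% names(cnt)) cnt[["1"]] else 0
      mm <- if ("0" %in% names(cnt)) cnt[["0"]] else 0
      return(as.integer(mm * n * (n - 1) / 2))
    }
    if (representation == "G") {
      tot <- 0
      for (p in names(cnt)) for (a in setdiff(names(cnt), p))
        tot <- tot + cnt[[p]] * cnt[[a]] * (cnt[[a]] - 1) / 2
      return(as.integer(tot))
    }
    if (representation == "W") {
      og <- m[ogIdx, j]
      if (is.na(og) || !og %in% names(cnt)) return(0L)
      tot <- 0
      for (a in setdiff(names(cnt), og))
        tot <- tot + cnt[[og]] * cnt[[a]] * (cnt[[a]] - 1) / 2
      return(as.integer(tot))
    }
    # omc
    v <- as.integer(m[, j])
    lev <- sort(unique(v[!is.na(v)]))
    tot <- 0
    for (thr in lev[-1L]) {
      n <- sum(v >= thr, na.rm = TRUE)
      mm <- sum(v < thr, na.rm = TRUE)
      tot <- tot + mm * n * (n - 1) / 2
    }
    as.integer(tot)
  }, integer(1))
}
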
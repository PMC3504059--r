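# Shared toy columns and comparison helpers.

# exact-rational internals, aliased for test readability
rational <- tritax:::rational
ratEq <- tritax:::ratEq
ratSum <- tritax:::ratSum
ratMul <- tritax:::ratMul
ratFormat <- tritax:::ratFormat
ratLength <- tritax:::ratLength

# the five-taxon unordered multistate worked example
toyUmcColumn <- function() c(A = "0", B = "1", C = "1", D = "2", E = "2")

toyUmcMatrix <- function() {
  characterMatrix(cbind(toyUmcColumn()), "umc")
}

# statement data.frame from named taxon triples, e.g. stmts("A(BC)", ...)
# against a taxon name vector; for readable expected values in tests
stmts <- function(..., taxa) {
  parts <- lapply(c(...), function(s) {
    m <- regmatches(s, regexec("^(\\w+)\\((\\w+) ?(\\w+)\\)$", s))[[1]]
    idx <- match(m[2:4], taxa)
    pair <- sort(idx[2:3])
    data.frame(out = idx[1], in1 = pair[1], in2 = pair[2])
  })
  df <- do.call(rbind, parts)
  df[order(df$out, df$in1, df$in2), , drop = FALSE]
}

# engine output as a bare (out, in1, in2) data.frame for comparison
blockTriples <- function(block) {
  st <- block@statements[c("out", "in1", "in2")]
  rownames(st) <- NULL
  st
}

expect_same_statements <- function(block, expected) {
  rownames(expected) <- NULL
  expect_equal(blockTriples(block), expected)
}

# provenance reduced to the oracle's column layout
timTriples <- function(tim) {
  pv <- provenance(tim)[c("sourceChar", "out", "in1", "in2")]
  names(pv)[1] <- "char"
  rownames(pv) <- NULL
  pv
}

oracleTriples <- function(...) {
  df <- oracleEnumerate(...)
  rownames(df) <- NULL
  df
}
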
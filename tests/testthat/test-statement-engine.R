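# Enumerators checked against hand-enumerated triples and the brute-force
# oracle; expected statement sets below were derived by scanning all
# (x, {y,z}) triples by hand for these tiny columns.

test_that("binary characters yield one statement per zero-taxon and one-pair", {
  taxa <- c("A", "B", "C", "D")
  blk <- enumerateBinary(c(A = "0", B = "1", C = "1", D = "0"))
  expect_same_statements(blk, stmts("A(BC)", "D(BC)", taxa = taxa))

  expect_identical(nrow(enumerateBinary(c("1", "1", "1"))@statements), 0L)

  taxa5 <- c("A", "B", "C", "D", "E")
  blk <- enumerateBinary(c(A = "0", B = "1", C = NA, D = "1", E = "1"))
  expect_same_statements(blk, stmts("A(BD)", "A(BE)", "A(DE)", taxa = taxa5))
  # count m * n(n-1)/2 with the missing taxon excluded
  expect_identical(nrow(blk@statements), 3L)
})

test_that("G-representation exhausts every observed state as the outgroup value", {
  taxa <- c("A", "B", "C", "D", "E")
  blk <- enumerateG(toyUmcColumn())
  expect_same_statements(blk, stmts("A(BC)", "A(DE)", "B(DE)", "C(DE)",
                                    "D(BC)", "E(BC)", taxa = taxa))

  # on a 0/1 column G runs both directions, unlike the polarized binary rule
  taxa4 <- c("A", "B", "C", "D")
  col <- c(A = "0", B = "1", C = "1", D = "0")
  blk <- enumerateG(col)
  expect_same_statements(blk, stmts("A(BC)", "B(AD)", "C(AD)", "D(BC)",
                                    taxa = taxa4))
  # the polarized binary statements are a subset of the G statements
  bin <- blockTriples(enumerateBinary(col))
  expect_true(nrow(merge(bin, blockTriples(blk))) == nrow(bin))

  expect_identical(nrow(enumerateG(c("2", "2", "2", "2"))@statements), 0L)
})

test_that("W-representation fixes the plesiomorphic state", {
  taxa <- c("A", "B", "C", "D", "E")
  blk <- enumerateW(toyUmcColumn(), "0")
  expect_same_statements(blk, stmts("A(BC)", "A(DE)", taxa = taxa))

  blk <- enumerateW(toyUmcColumn(), "1")
  expect_same_statements(blk, stmts("B(DE)", "C(DE)", taxa = taxa))

  # outgroup state unique, all other states distinct: no pair shares a state
  blk <- enumerateW(c("0", "1", "2", "3"), "0")
  expect_identical(nrow(blk@statements), 0L)

  # every W statement is also a G statement
  g <- blockTriples(enumerateG(toyUmcColumn()))
  for (s in c("0", "1", "2")) {
    w <- blockTriples(enumerateW(toyUmcColumn(), s))
    if (nrow(w)) expect_identical(nrow(merge(w, g)), nrow(w))
  }
})

test_that("additive decomposition recodes ordered levels as thresholds", {
  cols <- decomposeAdditive(c(A = "0", B = "1", C = "2", D = "2"))
  expect_identical(unname(lapply(cols, unname)),
                   list(c("0", "1", "1", "1"), c("0", "0", "1", "1")))

  expect_length(decomposeAdditive(c("1", "1", "1")), 0L)

  # unobserved intermediate levels generate no duplicate columns
  cols <- decomposeAdditive(c(A = "0", B = "2"))
  expect_identical(unname(lapply(cols, unname)), list(c("0", "1")))

  # missing propagates through every threshold column
  cols <- decomposeAdditive(c("0", NA, "2"))
  expect_true(all(vapply(cols, function(cc) is.na(cc[2]), logical(1))))

  expect_error(decomposeAdditive(c("0", "x")), class = "tritax_symbol_error")
})

test_that("ordered characters concatenate threshold statements; -mus keeps them unique", {
  taxa <- c("A", "B", "C", "D")
  col <- c(A = "0", B = "1", C = "2", D = "2")
  blk <- enumerateOmc(col)
  # thresholds >=1 and >=2 both imply A(CD): present twice without dedup
  expect_same_statements(blk, stmts("A(BC)", "A(BD)", "A(CD)", "A(CD)",
                                    "B(CD)", taxa = taxa))
  mus <- enumerateOmc(col, mus = TRUE)
  expect_same_statements(mus, stmts("A(BC)", "A(BD)", "A(CD)", "B(CD)",
                                    taxa = taxa))
  expect_false(anyDuplicated(mus@statements[c("out", "in1", "in2")]) > 0)

  # a binary-valued ordered character has one threshold: mus is a no-op
  col01 <- c(A = "0", B = "1", C = "1", D = "0")
  expect_identical(blockTriples(enumerateOmc(col01, mus = TRUE)),
                   blockTriples(enumerateBinary(col01)))

  expect_identical(nrow(enumerateOmc(c("3", "3"))@statements), 0L)
})

test_that("dedup is idempotent and independent of taxon input order", {
  col <- c(A = "0", B = "1", C = "2", D = "2", E = "1", F = "3")
  once <- enumerateOmc(col, mus = TRUE)@statements
  # idempotence: deduplicating the deduplicated set changes nothing
  expect_identical(once[!duplicated(once[c("out", "in1", "in2")]), ], once)
  # order-independence: permuting taxa permutes labels, not the set
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  shuffled <- enumerateOmc(col[perm], mus = TRUE)@statements
  back <- data.frame(out = perm[shuffled$out],
                     in1 = pmin(perm[shuffled$in1], perm[shuffled$in2]),
                     in2 = pmax(perm[shuffled$in1], perm[shuffled$in2]))
  back <- back[order(back$out, back$in1, back$in2), ]
  rownames(back) <- NULL
  expect_identical(back, blockTriples(enumerateOmc(col, mus = TRUE)))
})

test_that("rendered columns score exactly the three statement taxa", {
  st <- data.frame(out = 1L, in1 = 2L, in2 = 3L, p = "A", a = "G")
  expect_identical(renderColumn(st, "binary", 4L), c("0", "1", "1", NA))
  expect_identical(renderColumn(st, "multistate", 4L), c("A", "G", "G", NA))
  # inverse: the non-missing rows recover {out} union in-pair
  col <- renderColumn(st, "binary", 6L)
  expect_identical(which(!is.na(col)), 1:3)
  expect_identical(unname(col[st$out]), "0")
})

test_that("assembly concatenates per-character blocks deterministically", {
  m <- rbind(A = c("0", "1"), B = c("1", "0"), C = c("1", "1"),
             D = c("0", "1"), E = c("0", "0"))
  cm <- characterMatrix(m, "binary")
  tim <- buildThreeItemMatrix(cm)
  percol <- vapply(1:2, function(j)
    nrow(enumerateBinary(m[, j])@statements), integer(1))
  expect_identical(ncol(tim), sum(percol))
  expect_identical(timTriples(tim), oracleTriples(cm, "binary"))

  # permuting taxon rows relabels but preserves the statement multiset
  perm <- c(3L, 5L, 1L, 2L, 4L)
  tim2 <- buildThreeItemMatrix(characterMatrix(m[perm, ], "binary"))
  pv2 <- provenance(tim2)
  back <- data.frame(char = pv2$sourceChar, out = perm[pv2$out],
                     in1 = pmin(perm[pv2$in1], perm[pv2$in2]),
                     in2 = pmax(perm[pv2$in1], perm[pv2$in2]))
  back <- back[order(back$char, back$out, back$in1, back$in2), ]
  rownames(back) <- NULL
  expect_identical(back, timTriples(tim))

  # identical input and config give byte-identical output
  expect_identical(writeNexus(buildThreeItemMatrix(cm)),
                   writeNexus(buildThreeItemMatrix(cm)))
})

test_that("degenerate inputs raise the dedicated conditions", {
  cm <- characterMatrix(rbind(A = "0", B = "0", C = "0"), "binary")
  expect_error(buildThreeItemMatrix(cm), class = "tritax_empty_error")
  cm2 <- toyUmcMatrix()
  expect_error(buildThreeItemMatrix(cm2, outgroup = "Z"),
               class = "tritax_config_error")
  expect_error(buildThreeItemMatrix(cm2, representation = "W"),
               class = "tritax_config_error")
  bin <- characterMatrix(rbind(A = "0", B = "1", C = "1"), "binary")
  expect_error(buildThreeItemMatrix(bin, outgroup = "A"),
               class = "tritax_config_error")
})

test_that("W characters with a missing outgroup state are skipped with a warning", {
  m <- rbind(A = c(NA, "0"), B = c("1", "1"), C = c("1", "1"),
             D = c("0", "0"))
  cm <- characterMatrix(m, "umc")
  expect_warning(tim <- buildThreeItemMatrix(cm, outgroup = "A"),
                 "outgroup state is missing")
  expect_identical(unique(provenance(tim)$sourceChar), 2L)
})
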
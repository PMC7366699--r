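toy_stockholm <- function(rows, ss_cons, id = "toy") {
  list(sequences = setNames(rows, paste0("s", seq_along(rows))),
       ss_cons = ss_cons, id = id)
}

test_that("block extraction keeps maximal gap-free runs longer than five", {
  # 10 clean columns -> one block of 10
  aln <- toy_stockholm(c("GGGGAAAACC", "GGGGAAAACC"), "<<<....>>>")
  b <- extract_blocks(aln)
  expect_length(b, 1)
  expect_equal(b[[1]]$columns, 10)
  # 5 clean columns -> nothing (blocks must exceed five columns)
  aln5 <- toy_stockholm(c("GGAAC", "GGAAC"), "<...>")
  expect_length(extract_blocks(aln5), 0)
  # 6 clean, one gap column, 7 clean -> exactly two blocks of 6 and 7
  rows <- c(paste0("GGAACC", "A", "GGGAACC"),
            paste0("GGAACC", "-", "GGGAACC"))
  ss <- paste0("<<..>>", ".", "<<<.>>>")
  b2 <- extract_blocks(toy_stockholm(rows, ss))
  expect_equal(vapply(b2, `[[`, 0, "columns"), c(6, 7))
  expect_error(extract_blocks(list(sequences = rows, ss_cons = NULL)),
               "consensus")
})

test_that("block rows are re-encoded from the restricted consensus", {
  aln <- toy_stockholm(c("GGGAAACCC", "GGGAAACCC"), "<<<...>>>")
  b <- extract_blocks(aln)
  alpha <- bear_alphabet()
  want <- encode_bear(parse_dot_bracket("(((...)))", "GGGAAACCC"), alpha)$bear
  expect_identical(b[[1]]$rows, rep(want, 2))
  # canonical filtering drops consensus pairs a row cannot form
  aln2 <- toy_stockholm(c("GAAAAC", "AAAAAA"), "<....>")
  b2 <- extract_blocks(aln2, pair_filter = "canonical")
  expect_false(b2[[1]]$rows[1] == b2[[1]]$rows[2])
})

test_that("row clustering is single-linkage with inverse-size weights", {
  # identical rows at identity 80 -> one cluster, weights 1/2
  cl <- cluster_rows(c("aaaa", "aaaa"), 80)
  expect_equal(cl$cluster, c(1L, 1L))
  expect_equal(cl$weight, c(0.5, 0.5))
  # fully distinct rows stay singletons
  cl2 <- cluster_rows(c("aaaa", "bbbb"), 80)
  expect_equal(cl2$weight, c(1, 1))
  # transitive closure: A~B and B~C at 90% links A and C despite 50%
  a <- "aaaaaaaaaa"
  b <- "aaaaaaaaab"          # 90% to a
  cc <- "aaaaaaaabb"          # 80% to a, 90% to b
  cl3 <- cluster_rows(c(a, b, cc), 85)
  expect_equal(length(unique(cl3$cluster)), 1L)
  expect_equal(cl3$weight, rep(1 / 3, 3))
  # identity 100 disables redundancy removal even for duplicates
  cl4 <- cluster_rows(c("aaaa", "aaaa"), 100)
  expect_equal(cl4$weight, c(1, 1))
})

test_that("log-odds scores on the toy block match the hand computation", {
  # two rows, six columns: five a/a columns and one a/b column.
  # Hand-derived Henikoff quantities: q_aa = 5/6, q_ab = 1/6, p_a = 11/12;
  # half-bit scores round to 0 (a,a), 0 (a,b) and, through the single
  # pseudo-pair for the unseen b/b, 9.
  m <- compute_rnablosum(list(list(rows = c("aaaaaa", "aaaaab"))),
                         identity = 100)
  fr <- attr(m, "frequencies")
  expect_equal(fr$q["a", "a"], 5 / 6)
  expect_equal(2 * fr$q["a", "b"], 1 / 6)
  expect_equal(unname(fr$p["a"]), 11 / 12)
  expect_equal(unname(m$scores["a", "a"]), 0)
  expect_equal(unname(m$scores["a", "b"]), 0)
  expect_equal(unname(m$scores["b", "b"]), 9)
})

test_that("identical rows without clustering give a positive diagonal", {
  m <- compute_rnablosum(list(list(rows = c("abab", "abab"))), identity = 100)
  expect_gt(m$scores["a", "a"], 0)
  expect_gt(m$scores["b", "b"], 0)
})

test_that("the matrix is symmetric and invariant to duplicating the data", {
  set.seed(42)
  blocks <- lapply(1:4, function(k) {
    list(rows = replicate(3, paste(sample(letters[1:4], 8, TRUE),
                                   collapse = "")))
  })
  m1 <- compute_rnablosum(blocks, identity = 100)
  expect_identical(m1$scores, t(m1$scores))
  # doubling every block leaves the observed frequencies, hence the
  # observed-pair scores, unchanged
  m2 <- compute_rnablosum(c(blocks, blocks), identity = 100)
  fr1 <- attr(m1, "frequencies"); fr2 <- attr(m2, "frequencies")
  expect_equal(fr1$q, fr2$q)
  observed <- fr1$q > 0
  expect_equal(m1$scores[observed], m2$scores[observed])
})

test_that("low clustering identity down-weights redundant matches", {
  # a block dominated by near-duplicate rows: clustering at low identity
  # merges them, so the diagonal advantage must not exceed the
  # unclustered one
  rows <- c("aabbaabb", "aabbaabb", "aabbaabb", "abbbaabb", "bbaabbaa")
  m_hi <- compute_rnablosum(list(list(rows = rows)), identity = 100)
  m_lo <- compute_rnablosum(list(list(rows = rows)), identity = 60)
  expect_gte(m_hi$scores["a", "a"], m_lo$scores["a", "a"])
  expect_gte(m_hi$scores["b", "b"], m_lo$scores["b", "b"])
})

test_that("the combined scorer applies structure + bonus * nucleotide", {
  alpha <- bear_alphabet()
  chars <- alpha$char
  sm <- substitution_matrix(chars, diag(3, length(chars)))
  a <- unpaired_ss("A")
  c_ <- unpaired_ss("C")
  # bonus 0: structure term only
  s0 <- build_scorer(sm, bonus = 0)
  expect_equal(global_align(a, c_, s0)$score, 3)
  # identical nucleotides, identical structure characters, bonus 1:
  # structure diagonal + nucleotide match 5
  s1 <- build_scorer(sm, bonus = 1)
  expect_equal(global_align(a, a, s1)$score, 3 + 5)
  # mismatched nucleotides at the default bonus: + 0.2 * (-4)
  s02 <- build_scorer(sm, bonus = 0.2)
  expect_equal(global_align(a, c_, s02)$score, 3 + 0.2 * -4)
  expect_error(build_scorer(sm, bonus = -1))
  # ambiguity codes are rejected
  expect_error(global_align(unpaired_ss("AN"), a, s0), "alphabet")
})

test_that("matrix files round-trip through the NCBI text format", {
  m <- compute_rnablosum(list(list(rows = c("abcabc", "abcbca"))),
                         identity = 100)
  f <- withr::local_tempfile(fileext = ".mat")
  write_matrix(m, f)
  back <- read_matrix(f)
  expect_equal(back$scores, m$scores)
  expect_equal(back$clustering_identity, m$clustering_identity)
})

test_that("stockholm files parse including wrapped alignments", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID fam1",
               "s1 GGGAA", "s2 GGGAA",
               "#=GC SS_cons <<...",
               "s1 ACCC", "s2 ACCC",
               "#=GC SS_cons .>>.", "//"), f)
  aln <- read_stockholm(f)
  expect_equal(unname(aln$sequences), c("GGGAAACCC", "GGGAAACCC"))
  expect_equal(aln$ss_cons, "<<....>>.")
  expect_equal(aln$id, "fam1")
})
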
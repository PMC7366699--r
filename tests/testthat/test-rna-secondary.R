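test_that("dot-bracket parsing recovers the nested pair set", {
  ss <- parse_dot_bracket("((..))", "GGAACC")
  expect_equal(ss$pairs, matrix(c(1L, 2L, 6L, 5L), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(parse_dot_bracket("....", "AAAA")$pairs[, 1], integer())
  expect_error(parse_dot_bracket("((.", "GGA"), "unbalanced")
  expect_error(parse_dot_bracket("()).", "GGAA"), "unbalanced.*position 3")
  expect_error(parse_dot_bracket("(.)", "GGAA"), "length")
})

test_that("parse/render round-trips on random structures", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    # random non-crossing structure by recursive bracket insertion
    db <- random_dotbracket(n)
    seq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    ss <- parse_dot_bracket(db, seq)
    expect_identical(ss$dot_bracket, db)
    expect_identical(render_dot_bracket(ss$pairs, n), db)
    expect_equal(nchar(encode_bear(ss)$bear), n)
  }
})

test_that("CT conversion is lossless on nested input and greedy on knots", {
  recs <- data.frame(index = 1:4, base = c("G", "A", "A", "C"),
                     partner = c(4L, 0L, 0L, 1L))
  expect_identical(ct_to_dot_bracket(recs)$dot_bracket, "(..)")
  recs0 <- data.frame(index = 1:4, base = c("A", "A", "A", "A"),
                      partner = rep(0L, 4))
  expect_identical(ct_to_dot_bracket(recs0)$dot_bracket, "....")
  # crossing pairs (1,3) and (2,4): either removal leaves one valid pair,
  # so the minimum drop is one pair; the tie rule keeps the pair opening
  # earlier, i.e. (1,3)
  knot <- data.frame(index = 1:4, base = c("G", "G", "C", "C"),
                     partner = c(3L, 4L, 1L, 2L))
  ss <- ct_to_dot_bracket(knot)
  expect_identical(ss$dot_bracket, "(.).")
  expect_equal(nrow(ss$pairs), 1L)
  expect_equal(unname(attr(ss, "removed_pairs")[1, ]), c(2L, 4L))
  bad <- data.frame(index = 1:4, base = c("G", "A", "A", "C"),
                    partner = c(3L, 0L, 4L, 1L))
  expect_error(ct_to_dot_bracket(bad), "inconsistent")
})

test_that("CT round-trip preserves pair count on non-pseudoknotted input", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    ss <- parse_dot_bracket(random_dotbracket(n),
                            paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                  collapse = ""))
    partner <- integer(n)
    if (nrow(ss$pairs) > 0) {
      partner[ss$pairs[, 1]] <- ss$pairs[, 2]
      partner[ss$pairs[, 2]] <- ss$pairs[, 1]
    }
    recs <- data.frame(index = 1:n, base = strsplit(ss$sequence, "")[[1]],
                       partner = partner)
    expect_equal(nrow(ct_to_dot_bracket(recs)$pairs), nrow(ss$pairs))
  }
})

test_that("structural-alphabet encoding is element-local with capped lengths", {
  alpha <- bear_alphabet()
  # all-exterior: one element of length 4, all positions share a character
  b1 <- encode_bear(parse_dot_bracket("....", "AAAA"), alpha)$bear
  expect_equal(length(unique(strsplit(b1, "")[[1]])), 1L)
  expect_identical(substr(b1, 1, 1),
                   alpha$char[alpha$type == "exterior" & alpha$length == 4])
  # hairpin: stem of 2 pairs + loop of 3
  b2 <- encode_bear(parse_dot_bracket("((...))", "GGAAACC"), alpha)$bear
  stem_char <- alpha$char[alpha$type == "stem" & alpha$length == 2]
  loop_char <- alpha$char[alpha$type == "hairpin_loop" & alpha$length == 3]
  expect_identical(b2, paste0(strrep(stem_char, 2), strrep(loop_char, 3),
                              strrep(stem_char, 2)))
  # element lengths beyond the cap share the cap class
  long <- encode_bear(parse_dot_bracket(strrep(".", 25), strrep("A", 25)), alpha)$bear
  expect_identical(substr(long, 1, 1),
                   alpha$char[alpha$type == "exterior" & alpha$length == 9])
  # internal loop/bulge between two helices
  b3 <- encode_bear(parse_dot_bracket("((..((...))..))", "GGAAGGAAACCAACC"))$bear
  el <- decompose_elements(parse_dot_bracket("((..((...))..))", "GGAAGGAAACCAACC"))
  expect_equal(el$type[3:4], rep("internal_or_bulge", 2))
  expect_equal(el$length[3], 2L)
})

test_that("a user-supplied alphabet table drives the encoding", {
  tab <- expand.grid(type = c("stem", "hairpin_loop", "internal_or_bulge",
                              "exterior"),
                     length = 1:3, stringsAsFactors = FALSE)
  tab$char <- c(letters[1:4], LETTERS[1:4], letters[23:26])
  alpha <- bear_alphabet(mapping = tab)
  b <- encode_bear(parse_dot_bracket("(...)", "GAAAC"), alpha)$bear
  expect_identical(substr(b, 1, 1), tab$char[tab$type == "stem" & tab$length == 1])
  expect_identical(substr(b, 2, 2),
                   tab$char[tab$type == "hairpin_loop" & tab$length == 3])
  dup <- tab; dup$char[2] <- dup$char[1]
  expect_error(bear_alphabet(mapping = dup), "injective")
})

test_that("dot-bracket and CT file I/O round-trips", {
  dir <- withr::local_tempdir()
  ss <- encode_bear(parse_dot_bracket("((....))", "GGAAAACC"))
  f <- file.path(dir, "x.dbn")
  write_dbn(list(hairpin = ss), f)
  back <- read_dbn(f)
  expect_identical(back$hairpin$dot_bracket, ss$dot_bracket)
  expect_identical(back$hairpin$sequence, ss$sequence)
  fb <- file.path(dir, "x.bear")
  write_bear_fasta(list(hairpin = ss), fb)
  expect_identical(readLines(fb)[2], ss$bear)
  ctf <- file.path(dir, "x.ct")
  writeLines(c("4 toy", " 1 G 0 2 4 1", " 2 A 1 3 0 2",
               " 3 A 2 4 0 3", " 4 C 3 0 1 4"), ctf)
  expect_identical(read_ct(ctf)$dot_bracket, "(..)")
})
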
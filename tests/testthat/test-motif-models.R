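test_that("bracketed consensus parsing matches the HIPPI site structure", {
  m <- parse_consensus("AAAGA[G/C]A[A/C/T][T/G]")
  expect_identical(motif_length(m), 9L)
  expect_setequal(m$sets[[6]], c("G", "C"))
  expect_setequal(m$sets[[8]], c("A", "C", "T"))
  expect_identical(m$sets[[1]], "A")
  expect_identical(consensus_text(m), "AAAGA[G/C]A[A/C/T][T/G]")
  expect_identical(motif_length(parse_consensus("A")), 1L)
  expect_setequal(parse_consensus("[A/C/G/T]")$sets[[1]], c("A", "C", "G", "T"))
})

test_that("consensus parse errors carry an offset", {
  expect_error(parse_consensus("AC[]GT"), "empty bracket")
  expect_error(parse_consensus("AC[A/"), "unclosed")
  expect_error(parse_consensus("ACXGT"), "offset 3")
  expect_error(parse_consensus("[A/C"), "unclosed")
})

test_that("consensus expansion enumerates the Cartesian product", {
  words <- expand_consensus(hbs)
  expect_length(words, 12)
  expect_true("AAAGACATG" %in% words)
  expect_length(unique(words), 12)
  expect_identical(expand_consensus(parse_consensus("ACG")), "ACG")
  expect_setequal(expand_consensus(parse_consensus("[A/C][G/T]")),
                  c("AG", "AT", "CG", "CT"))
  expect_error(expand_consensus(parse_consensus(strrep("[A/C/G/T]", 9))),
               "bound")
})

test_that("consensus-derived PWM spreads mass evenly over allowed bases", {
  p <- consensus_to_pwm(hbs)
  expect_equal(unclass(p)[, 6], c(A = 0, C = 0.5, G = 0.5, T = 0))
  expect_equal(unclass(p)[, 8], c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  expect_equal(unclass(p)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(consensus_to_pwm(parse_consensus("A")))[, 1],
               c(A = 1, C = 0, G = 0, T = 0))
  # a motif of only uniform columns has no score contrast
  expect_error(consensus_to_pwm(parse_consensus("[A/C/G/T][A/C/G/T]")),
               "unscorable")
})

test_that("TRANSFAC blocks parse with normalization and id/name mapping", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("AC M00001", "XX", "ID V$TEST", "XX", "P0 A C G T",
               "01 10 0 0 0", "02 0 0 10 0", "//",
               "AC M00002", "P0 A C G T", "01 2 1 1 1 N", "//"), f)
  lib <- parse_transfac(f)
  expect_length(lib, 2)
  expect_identical(motif_id(lib[[1]]), "M00001")
  expect_identical(attr(lib[[1]], "name"), "V$TEST")
  expect_identical(ncol(lib[[1]]), 2L)
  expect_equal(unclass(lib[[1]])[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(lib[[2]])[, 1], c(A = 0.4, C = 0.2, G = 0.2, T = 0.2))
})

test_that("malformed TRANSFAC files are rejected with block context", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("AC M1", "P0 A C G T", "01 1 2 3"), f)
  expect_error(parse_transfac(f), "terminator|numeric fields")
  writeLines(c("AC M1", "P0 A C G T", "01 1 2 3", "//"), f)
  expect_error(parse_transfac(f), "4 numeric fields")
  writeLines(c("AC M1", "P0 A C G T", "01 0 0 0 0", "//"), f)
  expect_error(parse_transfac(f), "all-zero")
})

test_that("similarity score reproduces hand-computed values", {
  expect_identical(score_window(hbs_pwm, "AAAGACATG"), 1)
  # S = 6.83333, S_min = 0, S_max = 7.33333
  expect_equal(score_window(hbs_pwm, "AAAGAAATG"), 6.83333333 / 7.33333333,
               tolerance = 1e-6)
  acg <- consensus_to_pwm(parse_consensus("ACG"))
  expect_identical(score_window(acg, "TTT"), 0)
  expect_error(score_window(hbs_pwm, "ACGT"), "length")
})

test_that("score is 1 exactly on expansions and in [0,1] everywhere", {
  two <- parse_consensus("[A/C]G[T/G]")
  p2 <- consensus_to_pwm(two)
  words <- expand_consensus(two)
  all3 <- apply(expand.grid(rep(list(c("A","C","G","T")), 3)), 1, paste, collapse = "")
  for (w in all3) {
    sc <- score_window(p2, w)
    expect_true(sc >= 0 && sc <= 1)
    expect_identical(sc == 1, w %in% words)
  }
  # random PWMs: scores stay in [0,1]; N contributes the column minimum
  set.seed(7)
  for (i in 1:20) {
    L <- sample(3:10, 1)
    pm <- pwm(matrix(runif(4 * L), 4), motif_id = "R")
    w <- random_seq(L)
    sc <- score_window(pm, w)
    expect_true(sc >= 0 && sc <= 1)
  }
  expect_identical(score_window(hbs_pwm, "NNNNNNNNN"), 0)
})

test_that("score is invariant under a consistent base relabeling", {
  # swap A<->T and C<->G in both the matrix rows and the window
  set.seed(9)
  L <- 6
  m <- matrix(runif(4 * L), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  p1 <- pwm(m, "orig")
  m2 <- m[c(4, 3, 2, 1), ]
  rownames(m2) <- NULL  # drop labels so rows mean their new positions
  p2 <- pwm(m2, "swapped")
  for (i in 1:10) {
    w <- random_seq(L)
    w2 <- chartr("ACGT", "TGCA", w)
    expect_equal(score_window(p1, w), score_window(p2, w2))
  }
})

test_that("mixed motif libraries load from TRANSFAC plus consensus TSV", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("AC M1", "P0 A C G T", "01 5 0 0 0", "02 0 5 0 0", "//"), tf)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tpattern", "HBS\tAAAGA[G/C]A[A/C/T][T/G]"), tsv)
  lib <- read_motif_library(transfac = tf, consensus_tsv = tsv)
  expect_identical(names(lib), c("M1", "HBS"))
  expect_identical(score_window(lib$HBS, "AAAGACATG"), 1)
})
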
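test_that("single-sequence scans locate the canonical site on both strands", {
  h <- scan_sequence(hbs_pwm, "TTAAAGACATGC", cutoff = 1)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_identical(c(h$start, h$end), c(-10L, -2L))
  expect_identical(h$score, 1)

  h2 <- scan_sequence(hbs_pwm, "GCATGTCTTTAA", cutoff = 1)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$strand, "-")

  expect_identical(nrow(scan_sequence(hbs_pwm, "AAAAAAAAAAAA", cutoff = 1)), 0L)
  # motif longer than sequence: empty result, not an error
  expect_identical(nrow(scan_sequence(hbs_pwm, "ACGT", cutoff = 1)), 0L)
  expect_error(scan_sequence(hbs_pwm, "ACGTACGTACGT", cutoff = 1.2), "cutoff")
})

test_that("scanner equals exact-string matching of consensus expansions", {
  set.seed(101)
  for (i in 1:120) {
    s <- random_seq(1000)
    got <- hits_to_matrix(scan_sequence(hbs, s, cutoff = 1))
    want <- oracle_scan(hbs, s)
    expect_equal(unname(got), unname(want))
  }
})

test_that("plus hits mirror to minus hits on the reverse complement", {
  set.seed(55)
  L <- motif_length(hbs)
  for (i in 1:30) {
    s <- random_seq(300)
    M <- nchar(s)
    plus <- scan_sequence(hbs_pwm, s, cutoff = 0.85, strands = "plus")
    minus_rc <- scan_sequence(hbs_pwm, reverse_complement(s), cutoff = 0.85,
                              strands = "minus")
    # a plus hit ending at e maps to a minus hit on the reverse
    # complement starting at -(e + M + 1): the interval reflected
    # through the sequence midline
    expect_identical(sort(minus_rc$start), sort(-(plus$end) - M - 1L))
    expect_equal(sort(minus_rc$score), sort(plus$score))
  }
})

test_that("set scans summarize genes with hits and respect cutoff nesting", {
  base <- generate_promoters(10, 400, seed = 21)
  # plant in exactly 7 genes
  seqs <- unclass(base)
  words <- expand_consensus(planted12)
  for (g in 1:7) substr(seqs[g], 101, 112) <- words[1]
  set <- sequence_set(seqs, "planted")
  res <- scan_set(planted12, set, cutoff = 1)
  expect_identical(sort(res$genes_with_hit), sprintf("g%06d", 1:7))
  expect_identical(res$n_with_hit, 7L)
  expect_equal(res$percent_with_hit, 70)

  loose <- scan_set(hbs_pwm, base, cutoff = 0.9)$genes_with_hit
  strict <- scan_set(hbs_pwm, base, cutoff = 1)$genes_with_hit
  expect_true(all(strict %in% loose))
})

test_that("hit positions bin by start with dropped-hit accounting", {
  hits <- data.frame(gene_id = "g", motif_id = "m",
                     start = c(-150L, -950L, -1500L), end = c(-142L, -942L, -1492L),
                     strand = "+", score = 1)
  h <- positional_distribution(hits, n_sequences = 10)
  expect_identical(h$count, c(2L, 1L, rep(0L, 8)))
  expect_identical(attr(h, "n_dropped"), 0L)
  expect_equal(h$freq_per_kb[1], 2 / 10)
  # bin edges are inclusive TSS-relative intervals
  expect_identical(h$bin_start[1], -1000L)
  expect_identical(h$bin_end[1], -1L)

  empty <- positional_distribution(hits[0, ], n_sequences = 5)
  expect_identical(sum(empty$count), 0L)

  far <- data.frame(gene_id = "g", motif_id = "m", start = -10001L,
                    end = -9993L, strand = "+", score = 1)
  h2 <- positional_distribution(far, n_sequences = 1)
  expect_identical(attr(h2, "n_dropped"), 1L)
  expect_error(positional_distribution(hits, 10, bin_width = 300), "divide")
})

test_that("uniformly planted hits spread evenly across bins", {
  set.seed(77)
  starts <- -sample.int(10000 - 11, 100) # uniform starts within the extent
  hits <- data.frame(gene_id = "g", motif_id = "m", start = starts,
                     end = starts + 11L, strand = "+", score = 1)
  h <- positional_distribution(hits, n_sequences = 100)
  expect_identical(sum(h$count), 100L)
  # binomial 99.9% bounds around 10 per bin
  bound <- 3.29 * sqrt(100 * 0.1 * 0.9)
  expect_true(all(abs(h$count - 10) <= bound + 1))
})

test_that("order of input hits does not change the histogram", {
  set.seed(3)
  starts <- -sample.int(5000, 40)
  hits <- data.frame(gene_id = "g", motif_id = "m", start = starts,
                     end = starts + 8L, strand = "+", score = 1)
  h1 <- positional_distribution(hits, 10)
  h2 <- positional_distribution(hits[sample.int(40), ], 10)
  expect_identical(h1$count, h2$count)
})

test_that("hit tables export BED-like TSV with optional 0-based offsets", {
  set <- sequence_set(c(g1 = "TTAAAGACATGC"))
  sc <- scan_set(hbs_pwm, set, cutoff = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(sc, f, zero_based = TRUE, set = set)
  back <- read.delim(f)
  expect_identical(names(back), c("gene_id", "start", "end", "motif_id",
                                  "score", "strand", "offset_start", "offset_end"))
  expect_identical(back$offset_start, 2L)
  expect_identical(back$offset_end, 11L)
})
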
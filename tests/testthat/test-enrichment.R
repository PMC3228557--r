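test_that("hypergeometric tail matches exhaustive enumeration on small urns", {
  expect_equal(hypergeom_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_tail(2, 2, 2, 4), 1 / 6)
  expect_identical(hypergeom_tail(0, 3, 2, 10), 1)
  set.seed(2)
  for (i in 1:40) {
    N <- sample(2:9, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle_hyper(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(5, 4, 6, 10), "inconsistent")
  expect_error(hypergeom_tail(1, 4, 12, 10), "inconsistent")
})

test_that("2x2 chi-square matches the closed-form Pearson statistic", {
  r <- chi_square_2x2(20, 80, 10, 90)
  expect_equal(r$statistic, 3.9216, tolerance = 1e-4)
  expect_equal(r$p.value, 0.0477, tolerance = 1e-3)
  flat <- chi_square_2x2(10, 90, 10, 90)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chi_square_2x2(0, 0, 10, 90), "degenerate")
  expect_error(chi_square_2x2(5, 0, 9, 0), "degenerate")
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(rep(0.05, 4)), rep(0.05, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(benjamini_hochberg(p[o]), adj[o])
  }
})

test_that("whole-urn and planted motif enrichment behave as the urn model dictates", {
  set <- generate_promoters(300, 500, seed = 61)
  pg <- plant_two_group(set, 30, planted12, rate_target = 0.5,
                        rate_background = 0.1, seed = 62)
  enr <- motif_set_enrichment(pg$target_genes, pg$sequences, planted12, cutoff = 1)
  expect_s3_class(enr, "enrichment_table")
  expect_identical(enr$n, 30L)
  expect_identical(enr$N, 300L)
  expect_lt(enr$p_hypergeom, 1e-3)
  expect_true(enr$significant)
  # target = whole background: k = K, p = 1
  all_enr <- motif_set_enrichment(names(set), pg$sequences, planted12, cutoff = 1)
  expect_identical(all_enr$k, all_enr$K)
  expect_equal(all_enr$p_hypergeom, 1)
  expect_error(motif_set_enrichment(character(0), set, planted12), "empty")
})

test_that("annotation enrichment reproduces the enumerated worked example", {
  genes <- sprintf("g%02d", 1:20)
  ann <- data.frame(term_id = "T1", term_name = "covered",
                    gene_id = genes[1:10], stringsAsFactors = FALSE)
  enr <- annotation_enrichment(genes[1:5], ann, genes)
  expect_equal(enr$p_hypergeom, 252 / 15504, tolerance = 1e-9)
  expect_equal(enr$dataset_frequency, 100)
  expect_equal(enr$background_frequency, 50)
  expect_equal(enr$p_adj, enr$p_hypergeom)  # single term: m = 1
  # a disjoint term scores p = 1 and is not selected
  ann2 <- rbind(ann, data.frame(term_id = "T2", term_name = "disjoint",
                                gene_id = genes[11:14]))
  enr2 <- annotation_enrichment(genes[1:5], ann2, genes)
  t2 <- enr2[enr2$item_id == "T2", ]
  expect_identical(t2$k, 0L)
  expect_equal(t2$p_hypergeom, 1)
  expect_false(t2$selected)
  expect_error(annotation_enrichment(genes[1:5], ann[0, ], genes), "empty")
})

test_that("annotation maps read in both TSV dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tterm_name\tgene_id", "T1\tname one\tg1", "T1\tname one\tg2",
               "T2\tname two\tg3"), f)
  a <- read_annotation(f)
  expect_identical(nrow(a), 3L)
  expect_identical(a$gene_id, c("g1", "g2", "g3"))
  writeLines(c("T1\tg1,g2", "T2\tg3"), f)
  b <- read_annotation(f)
  expect_identical(b$term_id, c("T1", "T1", "T2"))
  expect_identical(b$gene_id, c("g1", "g2", "g3"))
})

test_that("differential selection applies BH and splits by fold direction", {
  tab <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    fold_change = c(rep(2, 5), rep(1, 95)),
                    p_value = c(rep(0.001, 5), rep(0.5, 95)))
  sel <- select_differential(tab, alpha = 0.05, correct = TRUE)
  expect_identical(sel$up, sprintf("g%03d", 1:5))   # 0.001*100/5 = 0.02 < 0.05
  expect_identical(sel$down, character(0))

  none <- select_differential(data.frame(gene_id = "a", fold_change = 2,
                                         p_value = 0.9))
  expect_identical(lengths(none), c(up = 0L, down = 0L))

  single <- select_differential(data.frame(gene_id = "a", fold_change = 0.5,
                                           p_value = 0.04))
  expect_identical(single$down, "a")

  neutral <- select_differential(data.frame(gene_id = "a", fold_change = 1,
                                            p_value = 0.01))
  expect_identical(attr(neutral, "n_neutral"), 1L)
  expect_identical(lengths(neutral), c(up = 0L, down = 0L))
})

test_that("the 10% diminished-response rule picks the common set", {
  a <- data.frame(gene_id = c("up1", "up2", "dn1", "dn2", "lost"),
                  fold_change = c(2.0, 2.0, 0.5, 0.5, 3.0),
                  p_value = rep(0.001, 5))
  b <- data.frame(gene_id = c("up1", "up2", "dn1", "dn2"),
                  fold_change = c(1.7, 1.95, 0.588, 0.51),
                  stringsAsFactors = FALSE)
  b$p_value <- 0.5
  cs <- select_common_set(a, b, cutoff_fraction = 0.10, correct = FALSE)
  expect_identical(cs$common_up, "up1")       # 1.7/2.0 = 0.85 <= 0.90
  expect_false("up2" %in% cs$common_up)       # 1.95/2.0 = 0.975
  expect_identical(cs$common_down, "dn1")     # 0.5/0.588 = 0.85 <= 0.90
  expect_identical(attr(cs, "n_missing"), 1L) # "lost" absent from B
})

test_that("BH keeps the null discovery count controlled", {
  set.seed(99)
  selected <- replicate(200, {
    sum(benjamini_hochberg(runif(100)) < 0.05)
  })
  expect_lte(mean(selected), 5 + 3 * stats::sd(selected) / sqrt(200) + 0.5)
})
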
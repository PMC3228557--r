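test_that("promoter generation is seeded, sized and GC-calibrated", {
  a <- generate_promoters(10, 1000, gc = 0.5, seed = 1)
  b <- generate_promoters(10, 1000, gc = 0.5, seed = 1)
  expect_identical(unclass(a)[], unclass(b)[])
  expect_identical(unname(nchar(a)), rep(1000L, 10))
  expect_identical(names(a)[1], "g000001")

  pure <- generate_promoters(3, 200, gc = 1, seed = 2)
  expect_false(any(grepl("[AT]", unclass(pure))))

  big <- generate_promoters(1, 10000, gc = 0.5, seed = 3)
  gc_frac <- mean(strsplit(unclass(big)[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_promoters(5, 100, gc = 1.5), "gc")
})

test_that("planted sites are recovered exactly by the scanner", {
  set <- generate_promoters(20, 1000, seed = 7)
  pl <- plant_motif(set, hbs, rate = 1, position_model = position_fixed(-500),
                    strand_prob = 0, seed = 8)
  sc <- scan_set(hbs, pl$sequences, cutoff = 1)
  hits500 <- sc$hits[sc$hits$start == -500 & sc$hits$strand == "+", ]
  expect_identical(sort(hits500$gene_id), sort(pl$truth$gene_id))
  expect_identical(nrow(pl$truth), 20L)
  expect_true(all(pl$truth$start == -500))

  none <- plant_motif(set, hbs, rate = 0, seed = 9)
  expect_identical(unclass(none$sequences)[], unclass(set)[])
  expect_identical(nrow(none$truth), 0L)

  minus <- plant_motif(set, planted12, rate = 1, strand_prob = 1, seed = 10)
  scm <- scan_set(planted12, minus$sequences, cutoff = 1)
  expect_true(all(scm$hits$strand == "-"))
  expect_identical(sort(unique(scm$hits$gene_id)), sort(minus$truth$gene_id))
})

test_that("scanner output is complete and sound against the planted truth", {
  set <- generate_promoters(50, 800, seed = 13)
  pl <- plant_motif(set, hbs, rate = 0.6, strand_prob = 0.5, seed = 14)
  sc <- scan_set(hbs, pl$sequences, cutoff = 1)
  key <- function(d) paste(d$gene_id, d$start, d$strand)
  # completeness: every planted site is recovered
  expect_true(all(key(pl$truth) %in% key(sc$hits)))
  # soundness: every extra hit is a true expansion of the consensus
  extra <- sc$hits[!key(sc$hits) %in% key(pl$truth), ]
  if (nrow(extra) > 0) {
    words <- expand_consensus(hbs)
    for (i in seq_len(nrow(extra))) {
      s <- unclass(pl$sequences)[[extra$gene_id[i]]]
      M <- nchar(s)
      frag <- substr(s, extra$start[i] + M + 1, extra$end[i] + M + 1)
      if (extra$strand[i] == "-") frag <- reverse_complement(frag)
      expect_true(frag %in% words)
    }
  }
})

test_that("same seed and configuration reproduce planting byte for byte", {
  set <- generate_promoters(15, 600, seed = 20)
  p1 <- plant_motif(set, hbs, rate = 0.5, strand_prob = 0.3, seed = 21)
  p2 <- plant_motif(set, hbs, rate = 0.5, strand_prob = 0.3, seed = 21)
  expect_identical(unclass(p1$sequences)[], unclass(p2$sequences)[])
  expect_identical(p1$truth, p2$truth)
})

test_that("co-occurring plants respect the window and are recovered", {
  set <- generate_promoters(60, 600, seed = 23)
  co <- plant_cooccurring(set, hbs, secondary12, anchor_rate = 1,
                          in_window_rate = 1, window = 100, seed = 24)
  expect_true(all(co$secondary_truth$gap <= 100))
  a_sc <- scan_set(hbs, co$sequences, cutoff = 1)
  s_sc <- scan_set(secondary12, co$sequences, cutoff = 1)
  recs <- find_cooccurrences(a_sc$hits, s_sc$hits, window = 100)
  expect_true(all(co$secondary_truth$gene_id %in% recs$gene_id))
  expect_true(all(recs$gap <= 100))

  co0 <- plant_cooccurring(set, hbs, secondary12, anchor_rate = 1,
                           in_window_rate = 1, window = 0, seed = 25)
  expect_true(all(co0$secondary_truth$gap == 0))

  none <- plant_cooccurring(set, hbs, secondary12, anchor_rate = 1,
                            in_window_rate = 0, window = 100, seed = 26)
  expect_identical(nrow(none$secondary_truth), 0L)
  expect_error(plant_cooccurring(generate_promoters(5, 100, seed = 1),
                                 hbs, secondary12),
               "at least")
})

test_that("chance HBS hit counts match the closed-form expectation", {
  # expected hits per sequence: 2 * (M - 8) * 12 / 4^9 in uniform sequence
  set <- generate_promoters(2000, 1000, gc = 0.5, seed = 30)
  sc <- scan_set(hbs, set, cutoff = 1)
  expected <- 2 * (1000 - 8) * 12 / 4^9 * 2000
  se <- sqrt(expected)
  expect_lt(abs(nrow(sc$hits) - expected), 3 * se)
})

test_that("annotation generation covers the designed fractions", {
  genes <- sprintf("g%06d", 1:500)
  target <- genes[1:50]
  ann <- generate_annotation(genes, n_terms = 10, target_genes = target,
                             target_fraction = 0.8, background_fraction = 0.1,
                             seed = 33)
  expect_identical(length(unique(ann$annotation$term_id)), 10L)
  enr_genes <- ann$annotation$gene_id[ann$annotation$term_id == ann$enriched_term]
  expect_identical(sum(enr_genes %in% target), 40L)
  expect_identical(sum(!enr_genes %in% target), 45L)
  one <- generate_annotation(genes, 1, target, seed = 34)
  expect_identical(unique(one$annotation$term_id), "T0001")
})

test_that("enriched annotation terms rank first with small adjusted p", {
  genes <- sprintf("g%06d", 1:1000)
  target <- genes[1:50]
  hits <- vapply(1:20, function(s) {
    ann <- generate_annotation(genes, 15, target, 0.8, 0.1, seed = 100 + s)
    enr <- annotation_enrichment(target, ann$annotation, genes)
    enr$item_id[1] == ann$enriched_term && enr$p_adj[1] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("differential tables carry truth labels and configured models", {
  de <- generate_de_table(2000, 0.05, alt_p = 1e-4, null_p = 0.5, seed = 40)
  expect_identical(sum(de$truth), 100L)
  sel <- select_differential(de, alpha = 0.05, correct = TRUE)
  expect_setequal(c(sel$up, sel$down), de$table$gene_id[de$truth])

  tiny <- generate_de_table(1, 1, seed = 41)
  expect_identical(nrow(tiny$table), 1L)

  # null-only tables stay empty after BH in most seeds
  empties <- vapply(1:40, function(s) {
    de0 <- generate_de_table(200, 0, seed = 200 + s)
    sel0 <- select_differential(de0)
    length(sel0$up) + length(sel0$down) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})
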
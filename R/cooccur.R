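# Gap between two inclusive intervals: number of bases strictly between
# them, 0 when they overlap or are adjacent.
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2) - 1L)
}

#' Find secondary-motif sites within a window of anchor-motif sites
#'
#' For every (anchor hit, secondary hit) pair in the same gene, a
#' co-occurrence is recorded when the two inclusive intervals overlap or
#' when the number of bases strictly between them (the gap) is at most
#' `window` — i.e. the secondary site lies within `window` bp on either
#' side of the anchor, boundary inclusive. A hit paired with itself
#' (same motif, interval and strand) is never reported.
#'
#' @param anchor_hits Hit data frame (TSS-relative coordinates, all starts
#'   negative) for the anchor motif.
#' @param secondary_hits Hit data frame for the secondary motif, same gene
#'   universe and coordinate convention.
#' @param window Window size W in bp on either side of the anchor
#'   (default 100).
#' @return Data frame with one row per co-occurring pair: `gene_id`,
#'   `anchor_motif`, `anchor_start`, `anchor_end`, `anchor_strand`,
#'   `secondary_motif`, `secondary_start`, `secondary_end`,
#'   `secondary_strand`, `gap`.
#' @examples
#' a <- data.frame(gene_id = "CASP1", motif_id = "HBS", start = -119L,
#'                 end = -111L, strand = "+", score = 1)
#' s <- data.frame(gene_id = "CASP1", motif_id = "P53", start = -117L,
#'                 end = -98L, strand = "+", score = 1)
#' find_cooccurrences(a, s, window = 100)  # one record, gap 0
#' @export
find_cooccurrences <- function(anchor_hits, secondary_hits, window = 100L) {
  if (inherits(anchor_hits, "mst_scan")) anchor_hits <- anchor_hits$hits
  if (inherits(secondary_hits, "mst_scan")) secondary_hits <- secondary_hits$hits
  if (!is.numeric(window) || length(window) != 1L || window < 0) {
    stop("window must be a non-negative number of base pairs")
  }
  empty <- data.frame(gene_id = character(0),
                      anchor_motif = character(0), anchor_start = integer(0),
                      anchor_end = integer(0), anchor_strand = character(0),
                      secondary_motif = character(0), secondary_start = integer(0),
                      secondary_end = integer(0), secondary_strand = character(0),
                      gap = integer(0), stringsAsFactors = FALSE)
  if (nrow(anchor_hits) == 0L || nrow(secondary_hits) == 0L) return(empty)
  if (any(anchor_hits$start >= 0) || any(secondary_hits$start >= 0)) {
    stop("hit tables mix coordinate conventions: TSS-relative starts must be negative")
  }
  common <- intersect(unique(anchor_hits$gene_id), unique(secondary_hits$gene_id))
  if (length(common) == 0L) return(empty)
  a <- anchor_hits[anchor_hits$gene_id %in% common, , drop = FALSE]
  s <- secondary_hits[secondary_hits$gene_id %in% common, , drop = FALSE]
  # all pairs within each gene
  sa <- split(seq_len(nrow(a)), a$gene_id)
  ss <- split(seq_len(nrow(s)), s$gene_id)
  recs <- lapply(common, function(g) {
    ia <- sa[[g]]; is <- ss[[g]]
    grid <- expand.grid(ia = ia, is = is, KEEP.OUT.ATTRS = FALSE)
    grid
  })
  grid <- do.call(rbind, recs)
  A <- a[grid$ia, , drop = FALSE]
  S <- s[grid$is, , drop = FALSE]
  gap <- .interval_gap(A$start, A$end, S$start, S$end)
  keep <- gap <= window &
    !(A$motif_id == S$motif_id & A$start == S$start &
        A$end == S$end & A$strand == S$strand)
  out <- data.frame(gene_id = A$gene_id[keep],
                    anchor_motif = A$motif_id[keep],
                    anchor_start = A$start[keep], anchor_end = A$end[keep],
                    anchor_strand = A$strand[keep],
                    secondary_motif = S$motif_id[keep],
                    secondary_start = S$start[keep], secondary_end = S$end[keep],
                    secondary_strand = S$strand[keep],
                    gap = as.integer(gap[keep]), stringsAsFactors = FALSE)
  out <- out[order(match(out$gene_id, common), out$anchor_start, out$secondary_start), ]
  rownames(out) <- NULL
  out
}

#' Test over-representation of secondary motifs near an anchor motif
#'
#' The matrix-combination search: genes are first anchored by scanning the
#' anchor motif; for each secondary motif in the library, a gene "carries a
#' co-occurrence" when at least one secondary site lies within `window` bp
#' of at least one anchor site. Counting is at the gene level, matching the
#' hypergeometric urn: with n/N anchored genes in the target/background and
#' k/K of them carrying a co-occurrence, the enrichment ratio is
#' `(k/n) / (K/N)` and the cumulative hypergeometric p-value is
#' `P(X >= k)` for X hypergeometric(N, K, n). A 2x2 chi-square (target vs
#' background excluding target) and Benjamini-Hochberg adjustment of the
#' hypergeometric p across the library are also reported.
#'
#' @param target Target `SequenceSet` (must be a subset of `background`'s
#'   genes), or a character vector of target gene ids.
#' @param background Background `SequenceSet`.
#' @param anchor Anchor motif (`PWM` or `ConsensusMotif`).
#' @param secondary_library List of secondary motifs (or a single motif).
#' @param anchor_cutoff Similarity cutoff for the anchor scan (default 1.0,
#'   perfect match).
#' @param secondary_cutoff Cutoff for secondary scans (default 0.9).
#' @param window Co-occurrence window W in bp (default 100).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `enrichment_table`, one row per secondary
#'   motif, sorted by `p_hypergeom`: `item_id`, `k`, `n`, `K`, `N`,
#'   `dataset_frequency`, `background_frequency`, `ratio`, `p_hypergeom`,
#'   `p_chisq`, `p_adj`, `significant`, `flagged` (TRUE when K = 0, where
#'   the ratio is undefined and p is set to 1).
#' @export
cooccurrence_enrichment <- function(target, background, anchor, secondary_library,
                                    anchor_cutoff = 1, secondary_cutoff = 0.9,
                                    window = 100L, alpha = 0.05) {
  stopifnot(inherits(background, "SequenceSet"))
  target_ids <- if (inherits(target, "SequenceSet")) names(target) else as.character(target)
  if (!all(target_ids %in% names(background))) {
    stop("target genes must be a subset of the background set")
  }
  if (inherits(secondary_library, "PWM") || inherits(secondary_library, "ConsensusMotif")) {
    secondary_library <- list(secondary_library)
  }
  anchor_scan <- scan_set(anchor, background, cutoff = anchor_cutoff)
  anchored <- anchor_scan$genes_with_hit
  anchored_target <- intersect(anchored, target_ids)
  n <- length(anchored_target)
  N <- length(anchored)
  if (n == 0L) stop("no anchored genes in the target set")
  rows <- lapply(secondary_library, function(sec) {
    sec_scan <- scan_set(sec, background, cutoff = secondary_cutoff)
    co <- find_cooccurrences(anchor_scan$hits, sec_scan$hits, window = window)
    co_genes <- unique(co$gene_id)
    K <- length(intersect(co_genes, anchored))
    k <- length(intersect(co_genes, anchored_target))
    .enrichment_row(motif_id(.as_pwm(sec)), k, n, K, N, alpha)
  })
  .finish_enrichment_table(rows, alpha)
}

# Shared row/table assembly for motif, co-occurrence and annotation
# enrichment. K = 0 rows are flagged: the ratio is undefined and the
# hypergeometric p is 1 by construction.
.enrichment_row <- function(item_id, k, n, K, N, alpha) {
  flagged <- K == 0L
  ratio <- if (flagged) NA_real_ else (k / n) / (K / N)
  p_h <- if (flagged) 1 else hypergeom_tail(k, K, n, N)
  p_c <- tryCatch(chi_square_2x2(k, n - k, K - k, (N - n) - (K - k))$p.value,
                  error = function(e) NA_real_)
  data.frame(item_id = item_id, k = k, n = n, K = K, N = N,
             dataset_frequency = 100 * k / n,
             background_frequency = 100 * K / N,
             ratio = ratio, p_hypergeom = p_h, p_chisq = p_c,
             flagged = flagged, stringsAsFactors = FALSE)
}

.finish_enrichment_table <- function(rows, alpha) {
  tab <- do.call(rbind, rows)
  tab$p_adj <- benjamini_hochberg(tab$p_hypergeom)
  tab$significant <- (tab$p_hypergeom < alpha) |
    (!is.na(tab$p_chisq) & tab$p_chisq < alpha)
  tab <- tab[order(tab$p_hypergeom, tab$item_id),
             c("item_id", "k", "n", "K", "N", "dataset_frequency",
               "background_frequency", "ratio", "p_hypergeom", "p_chisq",
               "p_adj", "significant", "flagged")]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Write a co-occurrence table as TSV
#' @param co A [find_cooccurrences()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrences_tsv <- function(co, path) {
  utils::write.table(co, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment table as TSV
#' @param tab An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
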
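#' Cumulative (upper-tail) hypergeometric probability
#'
#' `P(X >= k)` where X counts marked genes in a draw of `n` from an urn of
#' `N` genes of which `K` are marked. This is the over-representation
#' p-value for observing at least `k` motif-bearing (or term-annotated)
#' genes in a target set of size `n` drawn from a background of size `N`
#' containing `K` such genes. Computed through the log-gamma machinery of
#' [stats::phyper()], so it is stable for genome-scale counts and exact to
#' machine precision for small urns.
#'
#' @param k Observed successes in the target (0 <= k <= min(n, K)).
#' @param K Successes in the background.
#' @param n Target set size.
#' @param N Background size.
#' @return The upper-tail probability, in `[0, 1]`; `k = 0` gives 1.
#' @examples
#' hypergeom_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(!is.finite(c(k, K, n, N)))) stop("counts must be finite")
  if (k < 0 || K < 0 || n < 0 || N < 1) stop("negative or empty urn counts")
  if (n > N || K > N) stop("inconsistent counts: n and K cannot exceed N")
  if (k > min(n, K)) stop("inconsistent counts: k cannot exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The contrast is target (a = genes with the feature, b = without) versus
#' background excluding the target (c, d), keeping the two samples
#' disjoint. No continuity correction; 1 degree of freedom.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with `statistic` and `p.value`.
#' @examples
#' chi_square_2x2(20, 80, 10, 90)  # statistic 3.92, p 0.048
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) stop("cell counts must be non-negative")
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a row or column margin is zero")
  }
  # small expected counts warn about the chi-square approximation; the
  # hypergeometric is the exact companion test, so the warning is noise here
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard FDR step-up: sort ascending, multiply `p_(i)` by `m/i`, enforce
#' monotonicity from the largest rank down, cap at 1, return in input
#' order. Tied p-values share their rank block's adjusted value.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set motif enrichment against a background sequence collection
#'
#' For each motif in the library, the background set (truncated to
#' `extent` bp upstream of the TSS) is scanned at `cutoff` and genes with
#' at least one hit are counted: K in the whole background of N genes, k
#' among the n target genes. Both the cumulative hypergeometric test and
#' the 2x2 chi-square (target vs background-excluding-target) are
#' computed; a motif is called significant when either p-value falls below
#' `alpha`, and the Benjamini-Hochberg-adjusted hypergeometric p across
#' the library is reported alongside.
#'
#' @param target_genes Character vector of target gene ids (subset of the
#'   background's genes), or a target `SequenceSet`.
#' @param background Background `SequenceSet` (superset of the target).
#' @param motif_library List of `PWM`/`ConsensusMotif` objects, or one motif.
#' @param cutoff Similarity cutoff in `[0, 1]`.
#' @param extent Upstream extent in bp to scan (sequences are truncated
#'   with [truncate_to_extent()]); `NULL` scans full length.
#' @param alpha Significance level (default 0.05).
#' @return An `enrichment_table` (see [cooccurrence_enrichment()]).
#' @export
motif_set_enrichment <- function(target_genes, background, motif_library,
                                 cutoff = 1, extent = NULL, alpha = 0.05) {
  stopifnot(inherits(background, "SequenceSet"))
  target_ids <- if (inherits(target_genes, "SequenceSet")) names(target_genes)
                else as.character(target_genes)
  if (length(target_ids) == 0L) stop("empty target gene set")
  if (!all(target_ids %in% names(background))) {
    stop("target genes must be a subset of the background set")
  }
  if (inherits(motif_library, "PWM") || inherits(motif_library, "ConsensusMotif")) {
    motif_library <- list(motif_library)
  }
  if (!is.null(extent)) background <- truncate_to_extent(background, extent)
  n <- length(target_ids)
  N <- length(background)
  rows <- lapply(motif_library, function(mo) {
    sc <- scan_set(mo, background, cutoff = cutoff)
    K <- sc$n_with_hit
    k <- length(intersect(sc$genes_with_hit, target_ids))
    .enrichment_row(motif_id(.as_pwm(mo)), k, n, K, N, alpha)
  })
  .finish_enrichment_table(rows, alpha)
}

#' Annotation-term over-representation analysis
#'
#' Flat (non-hierarchical) term enrichment in the style of GO
#' over-representation tools: for each term, k = target genes annotated to
#' it, K = background genes annotated to it; the cumulative hypergeometric
#' p-value is adjusted across all tested terms with Benjamini-Hochberg,
#' and a term is selected when the adjusted p falls below `alpha`. Dataset
#' and background frequencies are reported in percent.
#'
#' @param target_genes Character vector of target gene ids.
#' @param annotation Data frame with columns `term_id`, `term_name`,
#'   `gene_id` (one gene per row), e.g. from [read_annotation()].
#' @param background_genes Character vector: the background gene universe
#'   (must contain the target and all annotated genes).
#' @param alpha Significance level for selection on the adjusted p.
#' @return An `enrichment_table` with a `term_name` column and `selected =
#'   p_adj < alpha`; `significant` mirrors `selected` here.
#' @export
annotation_enrichment <- function(target_genes, annotation, background_genes,
                                  alpha = 0.05) {
  target_genes <- unique(as.character(target_genes))
  background_genes <- unique(as.character(background_genes))
  if (!all(target_genes %in% background_genes)) {
    stop("target genes must be a subset of the background universe")
  }
  if (!is.data.frame(annotation) || nrow(annotation) == 0L) {
    stop("empty annotation map")
  }
  if (!all(c("term_id", "gene_id") %in% names(annotation))) {
    stop("annotation needs columns term_id, gene_id (and optionally term_name)")
  }
  if (!all(annotation$gene_id %in% background_genes)) {
    stop("annotation gene ids must be a subset of the background universe")
  }
  n <- length(target_genes)
  N <- length(background_genes)
  terms <- split(unique(annotation[, c("term_id", "gene_id")])$gene_id,
                 unique(annotation[, c("term_id", "gene_id")])$term_id)
  term_names <- if ("term_name" %in% names(annotation)) {
    tn <- annotation$term_name[!duplicated(annotation$term_id)]
    stats::setNames(tn, annotation$term_id[!duplicated(annotation$term_id)])
  } else stats::setNames(names(terms), names(terms))
  rows <- lapply(names(terms), function(t) {
    genes <- unique(terms[[t]])
    K <- length(genes)
    k <- length(intersect(genes, target_genes))
    .enrichment_row(t, k, n, K, N, alpha)
  })
  tab <- .finish_enrichment_table(rows, alpha)
  tab$term_name <- unname(term_names[tab$item_id])
  tab$selected <- tab$p_adj < alpha
  tab$significant <- tab$selected
  tab[, c("item_id", "term_name", setdiff(names(tab), c("item_id", "term_name")))]
}

#' Read a flat annotation map
#'
#' Two dialects are accepted: three columns `term_id`, `term_name`,
#' `gene_id` with one gene per line; or two columns `term_id` and a
#' comma-separated gene list. A header line naming the first column
#' `term_id` is skipped. Lines starting with `#` are comments.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `term_id`, `term_name`, `gene_id`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty annotation map: ", path)
  if (identical(tolower(df[1, 1]), "term_id")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) >= 3L) {
    out <- data.frame(term_id = df[[1L]], term_name = df[[2L]],
                      gene_id = df[[3L]], stringsAsFactors = FALSE)
  } else if (ncol(df) == 2L) {
    genes <- strsplit(df[[2L]], ",", fixed = TRUE)
    out <- data.frame(term_id = rep(df[[1L]], lengths(genes)),
                      term_name = rep(df[[1L]], lengths(genes)),
                      gene_id = trimws(unlist(genes)), stringsAsFactors = FALSE)
  } else {
    stop("annotation map needs 2 or 3 columns")
  }
  out
}
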
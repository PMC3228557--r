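#' Read a differential-expression table
#'
#' TSV with a header and columns `gene_id`, `fold_change`, `p_value`.
#' Fold changes are ratios (test/control; neutral = 1).
#'
#' @param path Path to the TSV.
#' @return Data frame with unique `gene_id`, numeric `fold_change` and
#'   `p_value` in `[0, 1]`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("differential table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "fold_change", "p_value")
  if (!all(need %in% names(df))) {
    stop("differential table needs columns: ", paste(need, collapse = ", "))
  }
  validate_de_table(df[, need])
}

#' @keywords internal
validate_de_table <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in differential table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$p_value)) || any(df$p_value < 0 | df$p_value > 1)) {
    stop("p_value column must lie in [0, 1]")
  }
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0)) {
    stop("fold_change must be a positive ratio (neutral = 1)")
  }
  df
}

#' Select differentially expressed genes and split by direction
#'
#' With `correct = TRUE` (the default) the p-value column is first
#' Benjamini-Hochberg adjusted, and genes with adjusted p below `alpha`
#' are kept; with `correct = FALSE` the raw p-values are thresholded.
#' Selected genes with fold change above 1 go to `up`, below 1 to `down`.
#' A selected gene at exactly the neutral fold (1) is assigned to neither
#' direction; its count is returned as the `n_neutral` attribute.
#'
#' @param table Data frame with `gene_id`, `fold_change` (ratio, neutral
#'   1) and `p_value`, e.g. from [read_de_table()] or
#'   [generate_de_table()].
#' @param alpha Significance level (default 0.05).
#' @param correct Apply Benjamini-Hochberg before thresholding.
#' @return List with character vectors `up` and `down` and attribute
#'   `n_neutral`.
#' @export
select_differential <- function(table, alpha = 0.05, correct = TRUE) {
  if (inherits(table, "de_table_sim")) table <- table$table
  table <- validate_de_table(table)
  p <- if (correct) benjamini_hochberg(table$p_value) else table$p_value
  sel <- p < alpha
  up <- table$gene_id[sel & table$fold_change > 1]
  down <- table$gene_id[sel & table$fold_change < 1]
  neutral <- sum(sel & table$fold_change == 1)
  structure(list(up = up, down = down), n_neutral = neutral)
}

#' Intersect two differential experiments under a diminished-response rule
#'
#' Genes significantly altered in experiment A whose fold change in
#' experiment B is diminished by at least `cutoff_fraction` form the
#' "common set": for up-regulated genes `fold_B / fold_A <= 1 -
#' cutoff_fraction`, and symmetrically on magnitudes for down-regulated
#' genes (`fold_A / fold_B <= 1 - cutoff_fraction`, since the magnitude of
#' a repression is the reciprocal fold). The conventional cutoff fraction
#' is 10%. Genes absent from B are excluded; their count is returned as
#' the `n_missing` attribute.
#'
#' @param table_a Differential table of the primary experiment.
#' @param table_b Differential table of the comparison experiment (shared
#'   gene universe).
#' @param cutoff_fraction Required relative diminution of the fold change
#'   (default 0.10).
#' @param alpha,correct Passed to [select_differential()] for experiment A.
#' @return List with character vectors `common_up` and `common_down` and
#'   attribute `n_missing`.
#' @export
select_common_set <- function(table_a, table_b, cutoff_fraction = 0.10,
                              alpha = 0.05, correct = TRUE) {
  if (inherits(table_a, "de_table_sim")) table_a <- table_a$table
  if (inherits(table_b, "de_table_sim")) table_b <- table_b$table
  table_a <- validate_de_table(table_a)
  table_b <- validate_de_table(table_b)
  if (!is.numeric(cutoff_fraction) || cutoff_fraction < 0 || cutoff_fraction >= 1) {
    stop("cutoff_fraction must lie in [0, 1)")
  }
  sel <- select_differential(table_a, alpha = alpha, correct = correct)
  fold_a <- stats::setNames(table_a$fold_change, table_a$gene_id)
  fold_b <- stats::setNames(table_b$fold_change, table_b$gene_id)
  present <- function(g) g[g %in% names(fold_b)]
  up_in_b <- present(sel$up)
  down_in_b <- present(sel$down)
  n_missing <- (length(sel$up) - length(up_in_b)) +
    (length(sel$down) - length(down_in_b))
  common_up <- up_in_b[fold_b[up_in_b] / fold_a[up_in_b] <= 1 - cutoff_fraction]
  common_down <- down_in_b[fold_a[down_in_b] / fold_b[down_in_b] <= 1 - cutoff_fraction]
  structure(list(common_up = unname(common_up), common_down = unname(common_down)),
            n_missing = n_missing)
}
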
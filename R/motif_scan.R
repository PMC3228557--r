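# --- encoding ---------------------------------------------------------------
# Sequences are encoded as integers 1..5 (A,C,G,T,N); 6 is an inter-gene
# separator whose score contribution is -Inf, so no window spanning two
# genes can ever reach a non-negative similarity score.

.CODE_LUT <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  lut
})
.COMP_CODE <- c(4L, 3L, 2L, 1L, 5L, 6L)

.encode_seq <- function(s) {
  code <- .CODE_LUT[utf8ToInt(s)]
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/T/N")
  code
}

# 6 x L score matrix: rows A,C,G,T then N (column minimum) then separator.
.score_matrix <- function(p, r) {
  rbind(unclass(p), r$fmin, rep(-Inf, ncol(p)))
}

# Score every window of a code vector; returns 1-based window starts passing
# the cutoff and their scores. A tiny epsilon absorbs float summation noise
# at the cutoff boundary.
.scan_code <- function(code, sm, r, cutoff) {
  L <- ncol(sm)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(list(pos = integer(0), score = numeric(0)))
  acc <- numeric(nw)
  for (j in seq_len(L)) {
    colj <- sm[, j]
    acc <- acc + colj[code[j:(j + nw - 1L)]]
  }
  sc <- (acc - r$smin) / (r$smax - r$smin)
  keep <- which(sc >= cutoff - 1e-9)
  list(pos = keep, score = pmin(sc[keep], 1))
}

.empty_hits <- function() {
  data.frame(gene_id = character(0), motif_id = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.check_cutoff <- function(cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a similarity score in [0, 1]")
  }
}

.as_pwm <- function(motif) {
  if (inherits(motif, "ConsensusMotif")) consensus_to_pwm(motif)
  else if (inherits(motif, "PWM")) motif
  else stop("motif must be a PWM or ConsensusMotif")
}

# --- scanning ---------------------------------------------------------------

#' Scan a sequence set for a motif on both strands
#'
#' The matrix search: every window position on the requested strand(s) whose
#' min-max similarity score reaches `cutoff` is reported as a hit. Hits are
#' given in TSS-relative coordinates, inclusive on both ends: a sequence of
#' length M has its last base at -1, and a hit starting at 0-based string
#' index i covers `[i - M, i - M + L - 1]`. Minus-strand windows are scored
#' on the reverse complement but reported as the interval of matched bases
#' in sense coordinates with strand `"-"`. Overlapping hits are all
#' reported; gene-level summaries deduplicate.
#'
#' @param motif A `PWM` or `ConsensusMotif`.
#' @param set A [sequence_set()].
#' @param cutoff Similarity score threshold in `[0, 1]` (1.0 accepts only
#'   perfect consensus matches; 0.9 is the conventional secondary-motif
#'   cutoff).
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return An `mst_scan` object: list with `hits` (data frame: gene_id,
#'   motif_id, start, end, strand, score), `genes_with_hit`,
#'   `n_genes`, `n_with_hit` and `percent_with_hit`.
#' @examples
#' set <- sequence_set(c(g1 = "TTAAAGACATGC"))
#' scan_set(hbs_motif(), set, cutoff = 1)$hits
#' @export
scan_set <- function(motif, set, cutoff = 1, strands = c("both", "plus", "minus")) {
  stopifnot(inherits(set, "SequenceSet"))
  strands <- match.arg(strands)
  .check_cutoff(cutoff)
  p <- .as_pwm(motif)
  L <- ncol(p)
  r <- .pwm_range(p)
  sm <- .score_matrix(p, r)
  ids <- names(set)
  m <- nchar(set)
  codes <- lapply(unclass(set), .encode_seq)

  # concatenate with single separators; any window crossing one scores -Inf
  n <- length(codes)
  glued <- vector("list", 2L * n - 1L)
  glued[seq(1L, 2L * n - 1L, by = 2L)] <- codes
  if (n > 1L) glued[seq(2L, 2L * n - 2L, by = 2L)] <- list(6L)
  cat_code <- unlist(glued, use.names = FALSE)
  gene_start <- cumsum(c(1L, m[-n] + 1L))  # global 1-based start per gene

  res <- list()
  if (strands %in% c("both", "plus")) {
    sp <- .scan_code(cat_code, sm, r, cutoff)
    if (length(sp$pos)) {
      g <- findInterval(sp$pos, gene_start)
      i0 <- sp$pos - gene_start[g]          # 0-based index within gene
      res[[length(res) + 1L]] <- data.frame(
        gene_id = ids[g], motif_id = motif_id(p),
        start = i0 - m[g], end = i0 - m[g] + L - 1L,
        strand = "+", score = sp$score, stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "minus")) {
    rc_codes <- lapply(codes, function(x) .COMP_CODE[rev(x)])
    glued[seq(1L, 2L * n - 1L, by = 2L)] <- rc_codes
    rc_cat <- unlist(glued, use.names = FALSE)
    sn <- .scan_code(rc_cat, sm, r, cutoff)
    if (length(sn$pos)) {
      g <- findInterval(sn$pos, gene_start)
      i0m <- sn$pos - gene_start[g]         # 0-based index on the RC strand
      # matched sense bases run from M - i0m - L, i.e. TSS-relative -(i0m + L)
      res[[length(res) + 1L]] <- data.frame(
        gene_id = ids[g], motif_id = motif_id(p),
        start = -(i0m + L), end = -(i0m + 1L),
        strand = "-", score = sn$score, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else .empty_hits()
  ord <- order(match(hits$gene_id, ids), hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  genes <- unique(hits$gene_id)
  structure(list(hits = hits, genes_with_hit = genes,
                 n_genes = n, n_with_hit = length(genes),
                 percent_with_hit = 100 * length(genes) / n),
            class = "mst_scan")
}

#' @export
print.mst_scan <- function(x, ...) {
  cat(sprintf("MST scan: %d hits; %d of %d genes with >= 1 hit (%.1f%%)\n",
              nrow(x$hits), x$n_with_hit, x$n_genes, x$percent_with_hit))
  invisible(x)
}

#' Scan a single upstream sequence
#'
#' @inheritParams scan_set
#' @param seq Character scalar over A, C, G, T, N, or a 1-sequence
#'   `SequenceSet`.
#' @param gene_id Identifier used in the hit table when `seq` is a bare
#'   string.
#' @return Hit data frame (gene_id, motif_id, start, end, strand, score),
#'   sorted by start. A motif longer than the sequence yields zero hits.
#' @export
scan_sequence <- function(motif, seq, cutoff = 1,
                          strands = c("both", "plus", "minus"), gene_id = "seq1") {
  strands <- match.arg(strands)
  if (!inherits(seq, "SequenceSet")) {
    seq <- sequence_set(stats::setNames(as.character(seq), gene_id))
  }
  p <- .as_pwm(motif)
  if (ncol(p) > max(nchar(seq))) {
    .check_cutoff(cutoff)
    return(.empty_hits())
  }
  hits <- scan_set(p, seq, cutoff = cutoff, strands = strands)$hits
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# --- positional distribution ------------------------------------------------

#' Bin motif hit positions upstream of the TSS
#'
#' Each hit is assigned to one bin by its start (the 5'-most base of the
#' matched interval in sense coordinates); bin j (1-based) covers
#' TSS-relative positions `[-j*bin_width, -(j-1)*bin_width - 1]`, so the
#' first bin is the `bin_width` bases immediately upstream of the TSS. Hits
#' starting beyond `extent` are dropped and counted. Counts are also
#' normalized to frequency per sequence per kb, the scale on which site
#' density near the TSS is conventionally plotted.
#'
#' @param hits Hit data frame from [scan_set()] / [scan_sequence()] (or an
#'   `mst_scan` object).
#' @param n_sequences Number of sequences scanned (the normalization
#'   denominator); taken from an `mst_scan` object automatically.
#' @param bin_width Bin width in bp; must divide `extent`.
#' @param extent Total upstream span covered by the histogram, in bp.
#' @return A `positional_histogram`: data frame with `bin_start`, `bin_end`
#'   (TSS-relative, inclusive), `count`, `freq_per_kb`, plus attributes
#'   `n_sequences` and `n_dropped`.
#' @export
positional_distribution <- function(hits, n_sequences = NULL,
                                    bin_width = 1000L, extent = 10000L) {
  if (inherits(hits, "mst_scan")) {
    if (is.null(n_sequences)) n_sequences <- hits$n_genes
    hits <- hits$hits
  }
  if (is.null(n_sequences)) stop("n_sequences is required with a bare hit table")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be positive")
  if (extent %% bin_width != 0) stop("bin_width must divide extent")
  nb <- as.integer(extent / bin_width)
  s <- hits$start
  bin <- floor((-s - 1) / bin_width) + 1L  # 1-based bin index
  dropped <- sum(bin > nb)
  counts <- tabulate(bin[bin <= nb], nbins = nb)
  df <- data.frame(
    bin_start = -(seq_len(nb)) * as.integer(bin_width),
    bin_end = -(seq_len(nb) - 1L) * as.integer(bin_width) - 1L,
    count = counts,
    freq_per_kb = counts / n_sequences / (bin_width / 1000))
  structure(df, n_sequences = n_sequences, n_dropped = dropped,
            class = c("positional_histogram", "data.frame"))
}

#' @export
print.positional_histogram <- function(x, ...) {
  cat(sprintf("Positional histogram: %d hits in %d bins over %d sequences (%d dropped beyond extent)\n",
              sum(x$count), nrow(x), attr(x, "n_sequences"), attr(x, "n_dropped")))
  print(as.data.frame(x))
  invisible(x)
}

# --- TSV output -------------------------------------------------------------

#' Write a hit table as BED-like TSV
#'
#' Columns: gene_id, start, end, motif_id, score, strand, in TSS-relative
#' inclusive coordinates. With `zero_based = TRUE` an extra pair of columns
#' gives the 0-based half-open offsets from the sequence 5' end
#' (`offset_start`, `offset_end`), which requires the sequence lengths.
#'
#' @param hits Hit data frame or `mst_scan` object.
#' @param path Output path.
#' @param zero_based Also emit 0-based half-open offsets.
#' @param set The scanned `SequenceSet` (needed for `zero_based`).
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, zero_based = FALSE, set = NULL) {
  if (inherits(hits, "mst_scan")) hits <- hits$hits
  out <- hits[, c("gene_id", "start", "end", "motif_id", "score", "strand")]
  if (zero_based) {
    if (is.null(set)) stop("zero_based offsets need the scanned SequenceSet")
    m <- nchar(set)[hits$gene_id]
    out$offset_start <- hits$start + m
    out$offset_end <- hits$end + m + 1L
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a positional histogram as TSV
#'
#' @param hist A [positional_distribution()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  utils::write.table(as.data.frame(hist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
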
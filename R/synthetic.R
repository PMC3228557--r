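# Uniform draw of one element of a vector (safe for length-1 vectors,
# unlike sample()).
.sample1 <- function(x) x[sample.int(length(x), 1L)]

# Run code under a local RNG seed, restoring the caller's RNG state.
# A NULL seed uses (and advances) the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate random promoter sequences
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`, split evenly within the
#' G/C and A/T pairs. Gene ids are `g000001`, `g000002`, ... so the same
#' seed and configuration reproduce the set byte for byte.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (every sequence ends at
#'   TSS-relative position -1).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param name Set label.
#' @param prefix Gene-id prefix.
#' @return A [sequence_set()].
#' @export
generate_promoters <- function(n, length, gc = 0.5, seed = NULL,
                               name = "synthetic", prefix = "g") {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    stop("gc must lie in [0, 1]")
  }
  stopifnot(n >= 1, length >= 1)
  .with_seed(seed, {
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
    ascii <- c(65L, 67L, 71L, 84L)
    code <- sample.int(4L, n * length, replace = TRUE, prob = prob)
    seqs <- vapply(seq_len(n), function(i) {
      intToUtf8(ascii[code[((i - 1L) * length + 1L):(i * length)]])
    }, "")
    names(seqs) <- sprintf("%s%06d", prefix, seq_len(n))
    sequence_set(seqs, name = name)
  })
}

#' Position models for motif planting
#'
#' `position_fixed(offset)` plants every site at the same TSS-relative
#' start; `position_uniform()` draws the start uniformly over the whole
#' sequence; `position_proximal(fraction, extent)` places a site within
#' `extent` bp of the TSS with probability `fraction` and uniformly
#' further upstream otherwise — the model that reproduces the
#' TSS-proximal concentration seen for real binding sites.
#'
#' @param offset TSS-relative start (negative; e.g. -500).
#' @param fraction Probability of a TSS-proximal placement.
#' @param extent Width of the proximal zone in bp (default 2000).
#' @return A position-model object understood by [plant_motif()].
#' @export
position_fixed <- function(offset) {
  stopifnot(is.numeric(offset), offset < 0)
  structure(list(model = "fixed", offset = as.integer(offset)), class = "position_model")
}

#' @rdname position_fixed
#' @export
position_uniform <- function() {
  structure(list(model = "uniform"), class = "position_model")
}

#' @rdname position_fixed
#' @export
position_proximal <- function(fraction = 0.7, extent = 2000L) {
  stopifnot(fraction >= 0, fraction <= 1, extent >= 1)
  structure(list(model = "proximal", fraction = fraction,
                 extent = as.integer(extent)), class = "position_model")
}

# Draw one 0-based start index for a site of length L in a sequence of
# length M under a position model.
.draw_position <- function(pm, M, L) {
  if (L > M) stop("motif does not fit in a sequence of length ", M)
  switch(pm$model,
    fixed = {
      i0 <- M + pm$offset
      if (i0 < 0L || i0 + L > M) {
        stop(sprintf("fixed offset %d does not fit a site of length %d in a %d bp sequence",
                     pm$offset, L, M))
      }
      i0
    },
    uniform = sample.int(M - L + 1L, 1L) - 1L,
    proximal = {
      prox <- min(M, pm$extent)
      if (M <= pm$extent || stats::runif(1) < pm$fraction) {
        # start within the proximal zone: TSS-relative start in [-prox, -L]
        M + .sample1(seq.int(-prox, -L))
      } else {
        # strictly beyond the proximal zone
        M + .sample1(seq.int(-M, -(pm$extent + 1L)))
      }
    },
    stop("unknown position model"))
}

#' Plant a motif into a sequence set with known ground truth
#'
#' Each sequence is selected independently with probability `rate`; in a
#' selected sequence one uniformly chosen expansion of the consensus
#' overwrites the bases at a position drawn from `position_model`
#' (overwriting, not inserting, so lengths and TSS anchoring are
#' unchanged), reverse-complemented with probability `strand_prob`. A
#' position colliding with a previously planted site is redrawn (up to
#' `max_retries`, then an error).
#'
#' @param set A `SequenceSet`.
#' @param motif A `ConsensusMotif` (or bracketed consensus string).
#' @param rate Planting probability per sequence, in `[0, 1]`.
#' @param position_model A [position_fixed()], [position_uniform()] or
#'   [position_proximal()] object (default uniform).
#' @param strand_prob Probability of planting the reverse complement
#'   (default 0: all sites on the plus strand).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param .occupied Internal: named list of previously planted intervals
#'   per gene, for collision checking across successive plantings.
#' @param max_retries Resampling bound on position collisions.
#' @return List with `sequences` (the modified `SequenceSet`) and `truth`
#'   (data frame: gene_id, start, end, strand, site — the motif-strand
#'   sequence planted), plus `occupied` for chaining.
#' @export
plant_motif <- function(set, motif, rate, position_model = position_uniform(),
                        strand_prob = 0, seed = NULL, .occupied = NULL,
                        max_retries = 100L) {
  stopifnot(inherits(set, "SequenceSet"))
  if (is.character(motif)) motif <- parse_consensus(motif)
  stopifnot(inherits(motif, "ConsensusMotif"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (strand_prob < 0 || strand_prob > 1) stop("strand_prob must lie in [0, 1]")
  stopifnot(inherits(position_model, "position_model"))
  words <- expand_consensus(motif)
  L <- motif_length(motif)
  .with_seed(seed, {
    seqs <- unclass(set)
    occupied <- if (is.null(.occupied)) stats::setNames(vector("list", length(set)), names(set))
                else .occupied
    chosen <- which(stats::runif(length(set)) < rate)
    truth <- vector("list", length(chosen))
    for (j in seq_along(chosen)) {
      g <- chosen[j]
      M <- nchar(seqs[g])
      occ <- occupied[[names(set)[g]]]
      i0 <- NULL
      for (try in seq_len(max_retries)) {
        cand <- .draw_position(position_model, M, L)
        clash <- FALSE
        for (iv in occ) if (cand <= iv[2L] && cand + L - 1L >= iv[1L]) { clash <- TRUE; break }
        if (!clash) { i0 <- cand; break }
      }
      if (is.null(i0)) {
        stop("could not place a site without collision in gene ", names(set)[g])
      }
      word <- words[sample.int(length(words), 1L)]
      minus <- stats::runif(1) < strand_prob
      planted <- if (minus) reverse_complement(word) else word
      substr(seqs[g], i0 + 1L, i0 + L) <- planted
      occupied[[names(set)[g]]] <- c(occ, list(c(i0, i0 + L - 1L)))
      truth[[j]] <- data.frame(gene_id = names(set)[g], motif_id = motif$motif_id,
                               start = i0 - M, end = i0 - M + L - 1L,
                               strand = if (minus) "-" else "+",
                               site = word, stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), motif_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 site = character(0), stringsAsFactors = FALSE)
    list(sequences = structure(seqs, set_name = set_name(set), class = "SequenceSet"),
         truth = truth, occupied = occupied)
  })
}

#' Plant an anchor motif and an in-window secondary motif
#'
#' Anchors are planted at `anchor_rate` at a uniform position leaving
#' room for the secondary on either side; in each anchored sequence,
#' with probability `in_window_rate` a secondary site is planted with a
#' gap drawn uniformly from `0..window` on a random side of the anchor,
#' never overlapping it.
#'
#' @param set A `SequenceSet`.
#' @param anchor,secondary `ConsensusMotif` objects (or bracketed strings).
#' @param anchor_rate,in_window_rate Probabilities in `[0, 1]`.
#' @param window Maximum gap W in bp (default 100).
#' @param seed Integer seed.
#' @return List with `sequences`, `anchor_truth`, `secondary_truth` (the
#'   secondary truth carries the realized `gap` and `side`).
#' @export
plant_cooccurring <- function(set, anchor, secondary, anchor_rate = 1,
                              in_window_rate = 0.5, window = 100L, seed = NULL) {
  stopifnot(inherits(set, "SequenceSet"))
  if (is.character(anchor)) anchor <- parse_consensus(anchor)
  if (is.character(secondary)) secondary <- parse_consensus(secondary)
  La <- motif_length(anchor); Ls <- motif_length(secondary)
  margin <- as.integer(window) + Ls
  M_all <- nchar(set)
  if (any(M_all < La + 2L * margin)) {
    stop(sprintf("sequences must be at least %d bp to fit anchor plus a %d bp window on both sides",
                 La + 2L * margin, window))
  }
  a_words <- expand_consensus(anchor)
  s_words <- expand_consensus(secondary)
  .with_seed(seed, {
    seqs <- unclass(set)
    a_truth <- list(); s_truth <- list()
    anchored <- which(stats::runif(length(set)) < anchor_rate)
    for (g in anchored) {
      M <- M_all[g]
      i0a <- .sample1(seq.int(margin, M - La - margin))
      aword <- a_words[sample.int(length(a_words), 1L)]
      substr(seqs[g], i0a + 1L, i0a + La) <- aword
      a_truth[[length(a_truth) + 1L]] <- data.frame(
        gene_id = names(set)[g], motif_id = anchor$motif_id,
        start = i0a - M, end = i0a - M + La - 1L, strand = "+",
        site = aword, stringsAsFactors = FALSE)
      if (stats::runif(1) < in_window_rate) {
        gap <- sample.int(as.integer(window) + 1L, 1L) - 1L
        side <- if (stats::runif(1) < 0.5) "5prime" else "3prime"
        i0s <- if (side == "3prime") i0a + La + gap else i0a - gap - Ls
        sword <- s_words[sample.int(length(s_words), 1L)]
        substr(seqs[g], i0s + 1L, i0s + Ls) <- sword
        s_truth[[length(s_truth) + 1L]] <- data.frame(
          gene_id = names(set)[g], motif_id = secondary$motif_id,
          start = i0s - M, end = i0s - M + Ls - 1L, strand = "+",
          site = sword, gap = gap, side = side, stringsAsFactors = FALSE)
      }
    }
    bind <- function(lst, cols) if (length(lst)) do.call(rbind, lst) else
      stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    list(sequences = structure(seqs, set_name = set_name(set), class = "SequenceSet"),
         anchor_truth = bind(a_truth, c("gene_id", "motif_id", "start", "end", "strand", "site")),
         secondary_truth = bind(s_truth, c("gene_id", "motif_id", "start", "end", "strand", "site", "gap", "side")))
  })
}

#' Plant a motif at different presence rates in a target subset and its
#' background
#'
#' The rates parameterize the quantities the enrichment statistics
#' consume: `rate_target` is the expected fraction of TARGET genes
#' carrying the motif, and `rate_background` the expected fraction of the
#' WHOLE background set (target included, since the target is nested in
#' the background urn). The planting rate applied to non-target genes is
#' therefore derived as `(N * rate_background - n * rate_target) / (N - n)`
#' and must land in `[0, 1]`.
#'
#' @param set Background `SequenceSet` of N genes.
#' @param n_target Number of leading genes designated as the target set.
#' @param motif A `ConsensusMotif` (or bracketed string).
#' @param rate_target Expected motif-presence fraction among target genes.
#' @param rate_background Expected motif-presence fraction over the whole
#'   background set.
#' @param position_model,strand_prob,seed As in [plant_motif()].
#' @return List with `sequences`, `target_genes`, `truth`.
#' @export
plant_two_group <- function(set, n_target, motif, rate_target, rate_background,
                            position_model = position_uniform(), strand_prob = 0,
                            seed = NULL) {
  stopifnot(inherits(set, "SequenceSet"))
  N <- length(set)
  if (n_target < 1L || n_target > N) stop("n_target must lie in 1..N")
  n <- as.integer(n_target)
  rate_rest <- if (N == n) rate_target else (N * rate_background - n * rate_target) / (N - n)
  if (rate_rest < -1e-9 || rate_rest > 1 + 1e-9) {
    stop(sprintf("derived non-target planting rate %.3f is outside [0, 1]; adjust the rates", rate_rest))
  }
  rate_rest <- min(max(rate_rest, 0), 1)
  .with_seed(seed, {
    target <- set[seq_len(n)]
    rest <- if (N > n) set[seq.int(n + 1L, N)] else NULL
    pt <- plant_motif(target, motif, rate = rate_target,
                      position_model = position_model, strand_prob = strand_prob)
    if (!is.null(rest)) {
      pr <- plant_motif(rest, motif, rate = rate_rest,
                        position_model = position_model, strand_prob = strand_prob)
      seqs <- c(pt$sequences, pr$sequences)
      truth <- rbind(pt$truth, pr$truth)
    } else {
      seqs <- pt$sequences
      truth <- pt$truth
    }
    list(sequences = seqs, target_genes = names(target), truth = truth)
  })
}

#' Generate a flat annotation map with one enriched term
#'
#' `n_terms - 1` background terms each annotate a uniform random sample
#' of the genes; one designated term annotates `target_fraction` of the
#' target subset and `background_fraction` of the remaining genes, giving
#' a known positive for over-representation testing.
#'
#' @param genes Character vector: the gene universe.
#' @param n_terms Total number of terms (>= 1).
#' @param target_genes Genes forming the enriched subset.
#' @param target_fraction,background_fraction Coverage of the enriched
#'   term inside and outside the target subset.
#' @param term_size_fraction Fraction of the universe covered by each
#'   background term (default 0.1).
#' @param seed Integer seed.
#' @return List with `annotation` (term_id, term_name, gene_id) and
#'   `enriched_term` (its term_id, `NA` when n_terms' enriched coverage
#'   is not applicable).
#' @export
generate_annotation <- function(genes, n_terms, target_genes,
                                target_fraction = 0.8, background_fraction = 0.1,
                                term_size_fraction = 0.1, seed = NULL) {
  genes <- unique(as.character(genes))
  target_genes <- unique(as.character(target_genes))
  if (!all(target_genes %in% genes)) stop("target genes must belong to the universe")
  for (f in c(target_fraction, background_fraction, term_size_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (n_terms < 1L) stop("n_terms must be >= 1")
  .with_seed(seed, {
    rest <- setdiff(genes, target_genes)
    rows <- list()
    enr <- c(sample(target_genes, round(target_fraction * length(target_genes))),
             sample(rest, round(background_fraction * length(rest))))
    if (length(enr) == 0L) stop("enriched-term fractions select no genes")
    rows[[1L]] <- data.frame(term_id = "T0001", term_name = "enriched term",
                             gene_id = enr, stringsAsFactors = FALSE)
    size <- max(1L, round(term_size_fraction * length(genes)))
    for (t in seq_len(n_terms - 1L)) {
      rows[[t + 1L]] <- data.frame(
        term_id = sprintf("T%04d", t + 1L),
        term_name = sprintf("background term %d", t),
        gene_id = sample(genes, size), stringsAsFactors = FALSE)
    }
    list(annotation = do.call(rbind, rows), enriched_term = "T0001")
  })
}

#' Generate a differential-expression table with known truth labels
#'
#' A fraction of genes are true positives: their p-values come from
#' `alt_p` (a constant or a function of n drawing small values) and their
#' fold changes from a log2 effect drawn uniformly in
#' `alt_log2fc_range` with random sign. Null genes get p-values from
#' `null_p` (default Uniform(0,1)) and fold changes near 1
#' (log2 noise with sd `null_log2fc_sd`).
#'
#' @param n_genes Number of genes.
#' @param true_fraction Fraction of true positives in `[0, 1]`.
#' @param alt_p Constant p-value or `function(n)` for true positives
#'   (default 1e-4).
#' @param null_p Constant p-value or `function(n)` for nulls (default
#'   `stats::runif`).
#' @param alt_log2fc_range Range of |log2 fold change| for true positives.
#' @param null_log2fc_sd SD of log2 fold-change noise for nulls.
#' @param seed Integer seed.
#' @param prefix Gene-id prefix.
#' @return A `de_table_sim`: list with `table` (gene_id, fold_change,
#'   p_value) and `truth` (logical: true positive).
#' @export
generate_de_table <- function(n_genes, true_fraction, alt_p = 1e-4,
                              null_p = stats::runif,
                              alt_log2fc_range = c(1, 2),
                              null_log2fc_sd = 0.1,
                              seed = NULL, prefix = "g") {
  if (true_fraction < 0 || true_fraction > 1) stop("true_fraction must lie in [0, 1]")
  stopifnot(n_genes >= 1)
  draw <- function(model, n) {
    v <- if (is.function(model)) model(n) else rep(as.numeric(model), n)
    if (any(v < 0 | v > 1)) stop("p-value model produced values outside [0, 1]")
    v
  }
  .with_seed(seed, {
    n_true <- round(true_fraction * n_genes)
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n_genes - n_true))
    p <- numeric(n_genes)
    p[is_true] <- draw(alt_p, n_true)
    p[!is_true] <- draw(null_p, n_genes - n_true)
    lfc <- numeric(n_genes)
    lfc[is_true] <- sample(c(-1, 1), n_true, replace = TRUE) *
      stats::runif(n_true, alt_log2fc_range[1], alt_log2fc_range[2])
    lfc[!is_true] <- stats::rnorm(n_genes - n_true, 0, null_log2fc_sd)
    tab <- data.frame(gene_id = sprintf("%s%06d", prefix, seq_len(n_genes)),
                      fold_change = 2^lfc, p_value = p,
                      stringsAsFactors = FALSE)
    structure(list(table = tab, truth = is_true), class = "de_table_sim")
  })
}
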
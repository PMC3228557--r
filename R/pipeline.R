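# Recognized configuration keys, their defaults, and coercion.
.CONFIG_SPEC <- list(
  # input / output paths
  sequences = list(type = "path"), motif_library = list(type = "path"),
  consensus_motifs = list(type = "path"), target_list = list(type = "path"),
  annotation = list(type = "path"), de_table = list(type = "path"),
  de_table_b = list(type = "path"), outdir = list(type = "string", default = "."),
  # parameters
  anchor_motif = list(type = "string", default = "AAAGA[G/C]A[A/C/T][T/G]"),
  extent = list(type = "numeric", default = 10000, min = 1),
  anchor_cutoff = list(type = "numeric", default = 1, min = 0, max = 1),
  secondary_cutoff = list(type = "numeric", default = 0.9, min = 0, max = 1),
  window = list(type = "numeric", default = 100, min = 0),
  alpha = list(type = "numeric", default = 0.05, min = 0, max = 1),
  bin_width = list(type = "numeric", default = 1000, min = 1),
  cutoff_fraction = list(type = "numeric", default = 0.10, min = 0, max = 0.999),
  seed = list(type = "numeric", default = 1),
  # synthetic-study parameters
  n_background = list(type = "numeric", default = 500, min = 2),
  n_target = list(type = "numeric", default = 50, min = 1),
  length = list(type = "numeric", default = 2000, min = 50),
  gc = list(type = "numeric", default = 0.5, min = 0, max = 1),
  plant_rate_target = list(type = "numeric", default = 0.5, min = 0, max = 1),
  plant_rate_background = list(type = "numeric", default = 0.05, min = 0, max = 1),
  proximal_fraction = list(type = "numeric", default = 0.7, min = 0, max = 1),
  strand_prob = list(type = "numeric", default = 0.5, min = 0, max = 1),
  n_terms = list(type = "numeric", default = 20, min = 1),
  de_true_fraction = list(type = "numeric", default = 0.05, min = 0, max = 1)
)

.SUBCOMMANDS <- c("scan", "distribution", "cooccur", "enrich-motifs",
                  "enrich-annotation", "de-select", "common-set",
                  "simulate", "all")

.config_error <- function(msg) {
  stop(structure(class = c("promscan_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a flat key = value run configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Unknown keys are an error that lists the valid keys.
#'
#' @param path Path to the config file, or `NULL` for an all-defaults
#'   configuration.
#' @param overrides Named list of values overriding the file (recorded as
#'   such in the run manifest).
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) .config_error(paste0("config file not found: ", path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        .config_error(paste0("malformed config line (expected key = value): ", ln))
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      raw[[key]] <- val
    }
  }
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  unknown <- setdiff(names(raw), names(.CONFIG_SPEC))
  if (length(unknown) > 0L) {
    .config_error(sprintf("unknown config key(s): %s\nvalid keys: %s",
                          paste(unknown, collapse = ", "),
                          paste(names(.CONFIG_SPEC), collapse = ", ")))
  }
  cfg <- list()
  for (k in names(.CONFIG_SPEC)) {
    sp <- .CONFIG_SPEC[[k]]
    if (k %in% names(raw)) {
      v <- raw[[k]]
      if (sp$type == "numeric") {
        v <- suppressWarnings(as.numeric(v))
        if (is.na(v)) .config_error(paste0("config key '", k, "' must be numeric"))
        if (!is.null(sp$min) && v < sp$min ||
            !is.null(sp$max) && v > sp$max) {
          .config_error(sprintf("config key '%s' = %s is out of range", k, raw[[k]]))
        }
      } else {
        v <- as.character(v)
      }
      cfg[[k]] <- v
    } else if (!is.null(sp$default)) {
      cfg[[k]] <- sp$default
    }
  }
  structure(cfg, class = "run_config", overrides = names(overrides))
}

# Check that every input path a subcommand needs exists, before any output
# is produced.
.require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) .config_error(paste0("subcommand requires config key '", k, "'"))
    if (!file.exists(cfg[[k]])) {
      .config_error(paste0("input file for '", k, "' not found: ", cfg[[k]]))
    }
  }
}

.load_library <- function(cfg) {
  read_motif_library(transfac = cfg$motif_library, consensus_tsv = cfg$consensus_motifs)
}

#' Run one stage of the promoter-motif pipeline
#'
#' Subcommands: `scan` (anchor-motif scan of the sequence set),
#' `distribution` (scan + positional histogram), `cooccur` (co-occurrence
#' records and secondary-motif enrichment near the anchor),
#' `enrich-motifs` (gene-set motif enrichment), `enrich-annotation`
#' (term over-representation), `de-select` (differential list
#' preparation), `common-set` (two-experiment diminished-response
#' intersection), `simulate` (write a synthetic study with ground truth)
#' and `all` (simulate then scan, distribution, co-occurrence and motif
#' enrichment on the synthetic data). Every run writes its TSV outputs
#' plus `manifest.json` recording parameters, seed, input checksums and
#' output row counts; reruns with identical inputs and seed are
#' byte-identical. On error all files written by the failed run are
#' removed.
#'
#' @param subcommand One of the subcommands above.
#' @param config A `run_config` from [read_run_config()], a path to a
#'   config file, or a named list of settings.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(subcommand, config = read_run_config()) {
  if (!subcommand %in% .SUBCOMMANDS) {
    .config_error(sprintf("unknown subcommand '%s'; valid: %s",
                          subcommand, paste(.SUBCOMMANDS, collapse = ", ")))
  }
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    config <- read_run_config(NULL, overrides = config)
  }
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, file) {
    path <- file.path(outdir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  inputs <- character(0)
  counts <- list()
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  if (subcommand == "scan") {
    .require_inputs(config, "sequences")
    inputs <- config$sequences
    set <- truncate_to_extent(read_fasta(config$sequences), config$extent)
    sc <- scan_set(parse_consensus(config$anchor_motif, "anchor"), set,
                   cutoff = config$anchor_cutoff)
    emit(write_hits_tsv, sc, "hits.tsv")
    summ <- data.frame(n_genes = sc$n_genes, n_with_hit = sc$n_with_hit,
                       percent_with_hit = sc$percent_with_hit)
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE), summ, "scan_summary.tsv")
    counts$hits <- nrow(sc$hits)
  } else if (subcommand == "distribution") {
    .require_inputs(config, "sequences")
    inputs <- config$sequences
    set <- read_fasta(config$sequences)
    sc <- scan_set(parse_consensus(config$anchor_motif, "anchor"), set,
                   cutoff = config$anchor_cutoff)
    h <- positional_distribution(sc, bin_width = config$bin_width,
                                 extent = config$extent)
    emit(write_histogram_tsv, h, "histogram.tsv")
    counts$bins <- nrow(h)
  } else if (subcommand == "cooccur") {
    .require_inputs(config, c("sequences", "target_list"))
    if (is.null(config$motif_library) && is.null(config$consensus_motifs)) {
      .config_error("cooccur needs motif_library and/or consensus_motifs")
    }
    .require_inputs(config, intersect(c("motif_library", "consensus_motifs"), names(config)))
    inputs <- c(config$sequences, config$target_list,
                config$motif_library, config$consensus_motifs)
    set <- truncate_to_extent(read_fasta(config$sequences), config$extent)
    target <- read_gene_list(config$target_list)
    lib <- .load_library(config)
    anchor <- parse_consensus(config$anchor_motif, "anchor")
    a_sc <- scan_set(anchor, set, cutoff = config$anchor_cutoff)
    co_all <- lapply(lib, function(mo) {
      s_sc <- scan_set(mo, set, cutoff = config$secondary_cutoff)
      find_cooccurrences(a_sc$hits, s_sc$hits, window = config$window)
    })
    co <- do.call(rbind, co_all)
    rownames(co) <- NULL
    emit(write_cooccurrences_tsv, co, "cooccurrences.tsv")
    enr <- cooccurrence_enrichment(target, set, anchor, lib,
                                   anchor_cutoff = config$anchor_cutoff,
                                   secondary_cutoff = config$secondary_cutoff,
                                   window = config$window, alpha = config$alpha)
    emit(write_enrichment_tsv, enr, "cooccurrence_enrichment.tsv")
    counts$cooccurrences <- nrow(co); counts$motifs_tested <- nrow(enr)
  } else if (subcommand == "enrich-motifs") {
    .require_inputs(config, c("sequences", "target_list"))
    if (is.null(config$motif_library) && is.null(config$consensus_motifs)) {
      .config_error("enrich-motifs needs motif_library and/or consensus_motifs")
    }
    .require_inputs(config, intersect(c("motif_library", "consensus_motifs"), names(config)))
    inputs <- c(config$sequences, config$target_list,
                config$motif_library, config$consensus_motifs)
    set <- read_fasta(config$sequences)
    target <- read_gene_list(config$target_list)
    lib <- .load_library(config)
    enr <- motif_set_enrichment(target, set, lib, cutoff = config$secondary_cutoff,
                                extent = config$extent, alpha = config$alpha)
    emit(write_enrichment_tsv, enr, "motif_enrichment.tsv")
    counts$motifs_tested <- nrow(enr)
  } else if (subcommand == "enrich-annotation") {
    .require_inputs(config, c("sequences", "target_list", "annotation"))
    inputs <- c(config$sequences, config$target_list, config$annotation)
    set <- read_fasta(config$sequences)
    target <- read_gene_list(config$target_list)
    ann <- read_annotation(config$annotation)
    enr <- annotation_enrichment(target, ann, names(set), alpha = config$alpha)
    emit(write_enrichment_tsv, enr, "annotation_enrichment.tsv")
    counts$terms_tested <- nrow(enr)
  } else if (subcommand == "de-select") {
    .require_inputs(config, "de_table")
    inputs <- config$de_table
    sel <- select_differential(read_de_table(config$de_table),
                               alpha = config$alpha, correct = TRUE)
    emit(function(o, p) writeLines(o, p), sel$up, "de_selected_up.txt")
    emit(function(o, p) writeLines(o, p), sel$down, "de_selected_down.txt")
    counts$up <- length(sel$up); counts$down <- length(sel$down)
  } else if (subcommand == "common-set") {
    .require_inputs(config, c("de_table", "de_table_b"))
    inputs <- c(config$de_table, config$de_table_b)
    cs <- select_common_set(read_de_table(config$de_table),
                            read_de_table(config$de_table_b),
                            cutoff_fraction = config$cutoff_fraction,
                            alpha = config$alpha)
    emit(function(o, p) writeLines(o, p), cs$common_up, "common_up.txt")
    emit(function(o, p) writeLines(o, p), cs$common_down, "common_down.txt")
    counts$common_up <- length(cs$common_up)
    counts$common_down <- length(cs$common_down)
  } else if (subcommand %in% c("simulate", "all")) {
    sim <- .simulate_study(config)
    emit(write_fasta, sim$sequences, "sequences.fasta")
    emit(function(o, p) writeLines(o, p), sim$target_genes, "target_genes.txt")
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         sim$truth, "planted_sites.tsv")
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         sim$annotation, "annotation.tsv")
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         sim$de_table, "de_table.tsv")
    emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, pretty = TRUE),
         unclass(config), "config.json")
    counts$sequences <- length(sim$sequences)
    counts$planted_sites <- nrow(sim$truth)
    if (subcommand == "all") {
      anchor <- parse_consensus(config$anchor_motif, "anchor")
      sc <- scan_set(anchor, sim$sequences, cutoff = config$anchor_cutoff)
      emit(write_hits_tsv, sc, "hits.tsv")
      h <- positional_distribution(sc, bin_width = config$bin_width,
                                   extent = min(config$extent, config$length))
      emit(write_histogram_tsv, h, "histogram.tsv")
      sec_lib <- list(consensus_to_pwm(parse_consensus(sim$secondary_pattern, "planted_secondary")))
      co_enr <- cooccurrence_enrichment(sim$cooccur_target, sim$cooccur_sequences,
                                        anchor, sec_lib,
                                        anchor_cutoff = config$anchor_cutoff,
                                        secondary_cutoff = config$secondary_cutoff,
                                        window = config$window, alpha = config$alpha)
      emit(write_enrichment_tsv, co_enr, "cooccurrence_enrichment.tsv")
      enr <- motif_set_enrichment(sim$target_genes, sim$sequences,
                                  consensus_to_pwm(parse_consensus(sim$planted_pattern, "planted_motif")),
                                  cutoff = 1, alpha = config$alpha)
      emit(write_enrichment_tsv, enr, "motif_enrichment.tsv")
      counts$hits <- nrow(sc$hits)
    }
  }

  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("promscan")),
    parameters = unclass(config),
    overridden_keys = attr(config, "overrides"),
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    output_row_counts = counts)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, mpath)
  ok <- TRUE
  invisible(written)
}

# The default synthetic study behind `simulate` and `all`: a background
# promoter set with the anchor motif planted TSS-proximally, a planted
# 12-mer target motif at two presence rates (target vs background
# marginal), a co-occurrence design, an annotation map with one enriched
# term, and a differential table.
.simulate_study <- function(cfg) {
  seed <- as.integer(cfg$seed)
  planted_pattern <- "ACGTACGTTGCA"    # non-degenerate 12-mer: negligible chance hits
  secondary_pattern <- "GTACCAGTTAAC"
  set <- generate_promoters(cfg$n_background, cfg$length, gc = cfg$gc,
                            seed = seed, name = "background")
  anchor <- parse_consensus(cfg$anchor_motif, "anchor")
  pa <- plant_motif(set, anchor, rate = 0.8,
                    position_model = position_proximal(cfg$proximal_fraction, 2000L),
                    strand_prob = cfg$strand_prob, seed = seed + 1L)
  # two-group planting with the derived non-target rate clamped at 0: a
  # small simulated cohort may not support the requested marginal rate
  nt <- as.integer(cfg$n_target); nb <- as.integer(cfg$n_background)
  if (nt >= nb) .config_error("n_target must be smaller than n_background")
  rt <- cfg$plant_rate_target
  rr <- min(max((nb * cfg$plant_rate_background - nt * rt) / max(nb - nt, 1L), 0), 1)
  pm12 <- parse_consensus(planted_pattern, "planted_motif")
  p_t <- plant_motif(pa$sequences[seq_len(nt)], pm12, rate = rt, seed = seed + 2L)
  p_r <- plant_motif(pa$sequences[seq.int(nt + 1L, nb)], pm12, rate = rr,
                     seed = seed + 8L)
  pg <- list(sequences = c(p_t$sequences, p_r$sequences),
             target_genes = names(pa$sequences)[seq_len(nt)],
             truth = rbind(p_t$truth, p_r$truth))
  truth <- rbind(pa$truth, pg$truth)
  co_set <- generate_promoters(cfg$n_background, cfg$length, gc = cfg$gc,
                               seed = seed + 3L, name = "cooccur")
  n <- as.integer(cfg$n_target); N <- as.integer(cfg$n_background)
  r_rest <- (N * cfg$plant_rate_background - n * cfg$plant_rate_target) / (N - n)
  r_rest <- min(max(r_rest, 0), 1)
  sec <- parse_consensus(secondary_pattern, "planted_secondary")
  co_t <- plant_cooccurring(co_set[seq_len(n)], anchor, sec, anchor_rate = 1,
                            in_window_rate = cfg$plant_rate_target,
                            window = cfg$window, seed = seed + 4L)
  co_r <- plant_cooccurring(co_set[seq.int(n + 1L, N)], anchor, sec, anchor_rate = 1,
                            in_window_rate = r_rest,
                            window = cfg$window, seed = seed + 7L)
  co_sequences <- c(co_t$sequences, co_r$sequences)
  ann <- generate_annotation(names(set), cfg$n_terms, pg$target_genes,
                             seed = seed + 5L)
  de <- generate_de_table(cfg$n_background, cfg$de_true_fraction,
                          seed = seed + 6L)
  list(sequences = pg$sequences, target_genes = pg$target_genes, truth = truth,
       cooccur_sequences = co_sequences,
       cooccur_target = names(co_set)[seq_len(n)],
       annotation = ann$annotation, de_table = de$table,
       planted_pattern = planted_pattern, secondary_pattern = secondary_pattern)
}
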
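.BASES <- c("A", "C", "G", "T")

#' Parse a bracketed degenerate consensus motif
#'
#' The notation writes one position per plain base or per bracketed group of
#' alternatives, e.g. the 9 bp HIPPI binding site `"AAAGA[G/C]A[A/C/T][T/G]"`.
#'
#' @param text Bracketed consensus string over A, C, G, T, `[`, `]`, `/`.
#' @param motif_id Identifier attached to the motif (default: the text).
#' @return A `ConsensusMotif`: list with `motif_id`, `sets` (one character
#'   vector of allowed bases per position) and `source_text`.
#' @examples
#' m <- parse_consensus("AAAGA[G/C]A[A/C/T][T/G]", "HBS")
#' motif_length(m)        # 9
#' m$sets[[6]]            # "G" "C"
#' @export
parse_consensus <- function(text, motif_id = text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("consensus text must be a single non-empty string")
  }
  text <- toupper(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  sets <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% .BASES) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      grp <- character(0)
      expecting_base <- TRUE
      while (j <= n && chars[j] != "]") {
        cj <- chars[j]
        if (expecting_base) {
          if (!cj %in% .BASES) {
            stop(sprintf("consensus parse error at offset %d: expected a base, got '%s'", j, cj))
          }
          grp <- c(grp, cj)
          expecting_base <- FALSE
        } else {
          if (cj != "/") {
            stop(sprintf("consensus parse error at offset %d: expected '/', got '%s'", j, cj))
          }
          expecting_base <- TRUE
        }
        j <- j + 1L
      }
      if (j > n) stop(sprintf("consensus parse error at offset %d: unclosed '['", i))
      if (length(grp) == 0L) stop(sprintf("consensus parse error at offset %d: empty bracket group", i))
      if (expecting_base) stop(sprintf("consensus parse error at offset %d: trailing '/'", j))
      sets[[length(sets) + 1L]] <- unique(grp)
      i <- j + 1L
    } else {
      stop(sprintf("consensus parse error at offset %d: illegal character '%s'", i, ch))
    }
  }
  if (length(sets) == 0L) stop("consensus pattern has no positions")
  structure(list(motif_id = motif_id, sets = sets, source_text = text),
            class = "ConsensusMotif")
}

#' @export
print.ConsensusMotif <- function(x, ...) {
  cat(sprintf("ConsensusMotif '%s': %s (%d positions)\n",
              x$motif_id, consensus_text(x), length(x$sets)))
  invisible(x)
}

#' Canonical bracketed rendering of a consensus motif
#' @param motif A `ConsensusMotif`.
#' @return Character scalar in bracket notation.
#' @export
consensus_text <- function(motif) {
  stopifnot(inherits(motif, "ConsensusMotif"))
  paste(vapply(motif$sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = "/"), "]")
  }, ""), collapse = "")
}

#' Number of positions of a motif
#' @param motif A `ConsensusMotif` or `PWM`.
#' @return Integer motif length L.
#' @export
motif_length <- function(motif) {
  if (inherits(motif, "ConsensusMotif")) return(length(motif$sets))
  if (inherits(motif, "PWM")) return(ncol(motif))
  stop("not a motif object")
}

#' Enumerate all exact strings matching a consensus motif
#'
#' @param motif A `ConsensusMotif`.
#' @param max_expansion Refuse to enumerate more than this many strings.
#' @return Character vector of all Cartesian-product expansions; the HIPPI
#'   binding site consensus yields 12 strings (2 x 3 x 2 degenerate choices).
#' @export
expand_consensus <- function(motif, max_expansion = 65536L) {
  stopifnot(inherits(motif, "ConsensusMotif"))
  n_exp <- prod(lengths(motif$sets))
  if (n_exp > max_expansion) {
    stop(sprintf("consensus expands to %d strings, above the bound %d",
                 n_exp, max_expansion))
  }
  grid <- do.call(expand.grid, c(rev(motif$sets),
                                 list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  apply(grid[, rev(seq_along(motif$sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Construct a position weight matrix
#'
#' Columns are per-position base frequencies (rows A, C, G, T); counts are
#' normalized to frequencies per column. A matrix whose columns are all
#' uniform carries no score contrast (S_max = S_min) and is rejected.
#'
#' @param mat 4 x L numeric matrix of non-negative counts or frequencies;
#'   rows in A, C, G, T order (row names, if present, must match).
#' @param motif_id Motif identifier.
#' @param name Human-readable name (default `motif_id`).
#' @return A `PWM`: 4 x L frequency matrix with identity attributes.
#' @export
pwm <- function(mat, motif_id, name = motif_id) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("a PWM needs 4 rows (A, C, G, T)")
  if (!is.null(rownames(mat)) && !identical(rownames(mat), .BASES)) {
    mat <- mat[.BASES, , drop = FALSE]
  }
  if (ncol(mat) < 1L) stop("a PWM needs at least one column")
  if (any(!is.finite(mat)) || any(mat < 0)) stop("PWM entries must be finite and non-negative")
  csum <- colSums(mat)
  if (any(csum <= 0)) {
    stop("all-zero column in PWM '", motif_id, "' (column ",
         which(csum <= 0)[1L], ")")
  }
  mat <- sweep(mat, 2L, csum, "/")
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("column normalization failed")
  smax <- sum(apply(mat, 2L, max))
  smin <- sum(apply(mat, 2L, min))
  if (smax - smin <= 1e-12) {
    stop("PWM '", motif_id, "' is unscorable: every column is uniform (S_max = S_min)")
  }
  dimnames(mat) <- list(.BASES, NULL)
  structure(mat, motif_id = motif_id, name = name, class = c("PWM", "matrix"))
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s): %d positions\n", motif_id(x), attr(x, "name"), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Motif identifier of a PWM
#' @param x A `PWM`.
#' @export
motif_id <- function(x) attr(x, "motif_id")

#' Convert a consensus motif to an equivalent PWM
#'
#' Column i gives frequency `1/|set_i|` to each allowed base and 0 to the
#' rest, so a window scores exactly 1.0 under [score_window()] if and only
#' if it is one of the consensus expansions.
#'
#' @param motif A `ConsensusMotif`.
#' @return A `PWM` with the same `motif_id`.
#' @export
consensus_to_pwm <- function(motif) {
  stopifnot(inherits(motif, "ConsensusMotif"))
  mat <- vapply(motif$sets, function(s) {
    col <- numeric(4L)
    col[match(s, .BASES)] <- 1 / length(s)
    col
  }, numeric(4L))
  pwm(matrix(mat, nrow = 4L, dimnames = list(.BASES, NULL)),
      motif_id = motif$motif_id, name = consensus_text(motif))
}

# Per-column maxima/minima and the additive score range of a PWM.
.pwm_range <- function(p) {
  fmax <- apply(unclass(p), 2L, max)
  fmin <- apply(unclass(p), 2L, min)
  list(fmax = fmax, fmin = fmin, smax = sum(fmax), smin = sum(fmin))
}

#' Min-max-normalized similarity score of one window
#'
#' The additive score `S = sum_i f_i(base_i)` is rescaled to
#' `(S - S_min) / (S_max - S_min)`, where `S_max`/`S_min` sum the
#' per-column maxima/minima, so 1.0 means every column at its best base
#' (a perfect consensus match) and 0.0 every column at its worst. An `N`
#' contributes the column minimum, so N-rich sequence cannot generate hits.
#'
#' @param pwm A `PWM` of length L.
#' @param window String of exactly L characters over A, C, G, T, N.
#' @param .range Internal: precomputed score range, to avoid recomputation
#'   in tight loops.
#' @return Similarity score in `[0, 1]`.
#' @examples
#' hbs <- consensus_to_pwm(parse_consensus("AAAGA[G/C]A[A/C/T][T/G]", "HBS"))
#' score_window(hbs, "AAAGACATG")  # 1
#' @export
score_window <- function(pwm, window, .range = NULL) {
  stopifnot(inherits(pwm, "PWM"))
  window <- toupper(window)
  L <- ncol(pwm)
  if (nchar(window) != L) {
    stop(sprintf("window length %d does not match motif length %d", nchar(window), L))
  }
  idx <- match(strsplit(window, "", fixed = TRUE)[[1L]], .BASES)
  if (any(is.na(idx) & strsplit(window, "", fixed = TRUE)[[1L]] != "N")) {
    stop("window contains characters outside A/C/G/T/N")
  }
  r <- if (is.null(.range)) .pwm_range(pwm) else .range
  contrib <- ifelse(is.na(idx), r$fmin, unclass(pwm)[cbind(idx, seq_len(L))])
  (sum(contrib) - r$smin) / (r$smax - r$smin)
}

#' Parse a TRANSFAC-format matrix flat file
#'
#' Accepts the classic block dialect: an `AC` accession line, an optional
#' `ID` line, a `P0 A C G T` (or `PO`) column header, numbered count rows
#' with four numeric fields (an optional trailing consensus letter is
#' ignored), and a `//` terminator per block. Counts are normalized per
#' column to frequencies.
#'
#' @param path Path to the flat file.
#' @return List of [pwm()] objects in file order; `motif_id` from `AC`,
#'   `name` from `ID` (falling back to the accession).
#' @export
parse_transfac <- function(path) {
  if (!file.exists(path)) stop("TRANSFAC file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty TRANSFAC file: ", path)
  out <- list()
  ac <- id <- NULL
  rows <- list()
  in_block <- FALSE
  flush_block <- function() {
    if (is.null(ac)) stop("TRANSFAC block without AC accession before '//'")
    if (length(rows) == 0L) stop("TRANSFAC block '", ac, "' has no matrix rows")
    mat <- t(do.call(rbind, rows))
    pwm(mat, motif_id = ac, name = if (is.null(id)) ac else id)
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    tag <- sub("^(\\S+).*$", "\\1", ln)
    if (tag == "AC") {
      ac <- sub("^AC\\s+", "", ln)
      id <- NULL
      rows <- list()
      in_block <- TRUE
    } else if (tag == "ID") {
      id <- sub("^ID\\s+", "", ln)
    } else if (tag %in% c("P0", "PO")) {
      # column header; nothing to keep
    } else if (tag == "//") {
      out[[length(out) + 1L]] <- flush_block()
      ac <- id <- NULL
      rows <- list()
      in_block <- FALSE
    } else if (grepl("^[0-9]+\\s", ln) && in_block) {
      fields <- strsplit(ln, "\\s+")[[1L]][-1L]
      # drop an optional trailing consensus letter
      if (length(fields) == 5L && grepl("^[A-Za-z]$", fields[5L])) {
        fields <- fields[1:4]
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 4L || anyNA(vals)) {
        stop(sprintf("TRANSFAC block '%s', row '%s': expected 4 numeric fields",
                     if (is.null(ac)) "?" else ac, ln))
      }
      rows[[length(rows) + 1L]] <- vals
    }
    # other tags (XX, NA, BF, CC, ...) are ignored
  }
  if (in_block) stop("TRANSFAC block '", ac, "' is missing its '//' terminator")
  if (length(out) == 0L) stop("no TRANSFAC blocks found in ", path)
  out
}

#' Read a motif library from TRANSFAC and/or consensus TSV sources
#'
#' The consensus TSV has two columns, `motif_id` and the bracketed pattern
#' (header optional); consensus motifs are converted to PWMs with
#' [consensus_to_pwm()] so one scanning code path serves both kinds.
#'
#' @param transfac Optional path to a TRANSFAC flat file.
#' @param consensus_tsv Optional path to a motif_id/pattern TSV.
#' @return Named list of `PWM` objects (names are motif ids).
#' @export
read_motif_library <- function(transfac = NULL, consensus_tsv = NULL) {
  lib <- list()
  if (!is.null(transfac)) lib <- c(lib, parse_transfac(transfac))
  if (!is.null(consensus_tsv)) {
    df <- utils::read.delim(consensus_tsv, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("consensus TSV needs columns motif_id, pattern")
    if (identical(tolower(df[1, 1]), "motif_id")) df <- df[-1L, , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      lib[[length(lib) + 1L]] <-
        consensus_to_pwm(parse_consensus(df[i, 2L], motif_id = df[i, 1L]))
    }
  }
  if (length(lib) == 0L) stop("motif library is empty: supply transfac and/or consensus_tsv")
  ids <- vapply(lib, motif_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate motif_id in library: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(lib) <- ids
  lib
}

#' The HIPPI binding site consensus
#'
#' Convenience constructor for the 9 bp degenerate consensus
#' `AAAGA[G/C]A[A/C/T][T/G]` (canonical instance `AAAGACATG`), the default
#' anchor motif of the pipeline.
#'
#' @return A `ConsensusMotif` with id `"HBS"`.
#' @export
hbs_motif <- function() parse_consensus("AAAGA[G/C]A[A/C/T][T/G]", motif_id = "HBS")
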
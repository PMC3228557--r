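# Alphabet shared by every module. Lowercase input is upcased on load;
# anything outside {A,C,G,T,N} is rejected at the boundary.
.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a set of TSS-anchored upstream sequences
#'
#' A `SequenceSet` holds one upstream (promoter) sequence per gene, written
#' 5'->3' on the sense strand and ending at the base immediately 5' of the
#' transcription start site (TSS). The TSS itself is position 0 and is not
#' part of the sequence: a sequence of length M covers TSS-relative
#' positions -M..-1, so the character at 0-based string index `i` sits at
#' position `i - M`.
#'
#' @param sequences Named character vector; names are gene identifiers,
#'   values are sequences over A, C, G, T, N (lowercase is upcased).
#' @param name Label for the set, e.g. `"background"` or `"target"`.
#' @return A `SequenceSet`: a named character vector with a `set_name`
#'   attribute.
#' @examples
#' ss <- sequence_set(c(g1 = "ACGT", g2 = "acgtn"), name = "demo")
#' upstream_start(ss)  # TSS-relative position of each first base
#' @export
sequence_set <- function(sequences, name = "unnamed") {
  if (length(sequences) == 0L) {
    stop("a SequenceSet must contain at least one sequence")
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must carry a gene_id name")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in sequence set: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(sequences))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) < 1L)) {
    stop("zero-length sequence for gene_id: ",
         paste(ids[nchar(seqs) < 1L], collapse = ", "))
  }
  structure(seqs, names = ids, set_name = name, class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  rng <- range(nchar(x))
  cat(sprintf("SequenceSet '%s': %d sequences, lengths %d..%d bp\n",
              set_name(x), length(x), rng[1], rng[2]))
  invisible(x)
}

#' @rdname sequence_set
#' @param x A `SequenceSet`.
#' @export
set_name <- function(x) attr(x, "set_name")

#' @export
`[.SequenceSet` <- function(x, i, ...) {
  y <- NextMethod()
  if (anyNA(names(y))) stop("unknown gene_id in SequenceSet subset")
  structure(y, set_name = set_name(x), class = "SequenceSet")
}

#' @export
c.SequenceSet <- function(...) {
  parts <- list(...)
  out <- unlist(lapply(parts, unclass))
  sequence_set(out, name = set_name(parts[[1L]]))
}

#' TSS-relative position of the first base of each sequence
#'
#' @param set A `SequenceSet`.
#' @return Integer vector: `-M` for each sequence of length M (the last base
#'   is always at -1).
#' @export
upstream_start <- function(set) {
  stopifnot(inherits(set, "SequenceSet"))
  -nchar(set)
}

#' Read TSS-anchored upstream sequences from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token of each
#' header. Lowercase bases are upcased; characters outside A/C/G/T/N,
#' duplicated identifiers and empty files are errors.
#'
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @param name Label for the resulting set.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- as.character(dss)
  names(seqs) <- ids
  sequence_set(seqs, name = name)
}

#' Write a SequenceSet as FASTA
#'
#' @param set A `SequenceSet`.
#' @param path Output path; lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "SequenceSet"))
  dss <- Biostrings::DNAStringSet(unclass(set))
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Truncate every sequence to its TSS-proximal extent
#'
#' Keeps the 3'-most `min(M, extent)` bases of each sequence so that the
#' last base stays at TSS-relative position -1. Sequences shorter than
#' `extent` are kept at full length. Typical use: narrowing a 10 kb
#' upstream collection to the 1 kb or 2 kb closest to the TSS.
#'
#' @param set A `SequenceSet`.
#' @param extent Number of bases upstream of the TSS to retain (>= 1).
#' @return A `SequenceSet` with the same gene order and set name.
#' @export
truncate_to_extent <- function(set, extent) {
  stopifnot(inherits(set, "SequenceSet"))
  if (!is.numeric(extent) || length(extent) != 1L || is.na(extent) || extent < 1) {
    stop("extent must be a positive number of base pairs")
  }
  extent <- as.integer(extent)
  m <- nchar(set)
  keep <- pmin(m, extent)
  out <- substr(unclass(set), m - keep + 1L, m)
  names(out) <- names(set)
  structure(out, set_name = set_name(set), class = "SequenceSet")
}

#' Reverse complement of a sequence string
#'
#' N complements to N; applying the function twice returns the input.
#'
#' @param seq Character scalar (or vector) over A, C, G, T, N.
#' @return The reverse complement(s).
#' @examples
#' reverse_complement("AAAGACATG")  # "CATGTCTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L & nzchar(seq))) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d",
                 substr(seq[i], bad[i], bad[i]), bad[i]))
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Read a target gene list
#'
#' Plain text, one gene identifier per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
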
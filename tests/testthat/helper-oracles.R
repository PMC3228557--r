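# Independent oracles and shared fixtures. Each oracle deliberately avoids
# the code path it is used to check.

hbs <- hbs_motif()
hbs_pwm <- consensus_to_pwm(hbs)

random_seq <- function(len, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# Exact-string scanner oracle: fixed-string search of every consensus
# expansion on the sense strand and of every reverse-complemented expansion,
# reported as TSS-relative (start, strand) pairs.
oracle_scan <- function(consensus, s) {
  words <- expand_consensus(consensus)
  M <- nchar(s)
  out <- list()
  for (w in words) {
    for (pos in unlist(gregexpr(w, s, fixed = TRUE))) {
      if (pos > 0) out[[length(out) + 1L]] <- c(pos - 1L - M, 1L)
    }
    rc <- reverse_complement(w)
    for (pos in unlist(gregexpr(rc, s, fixed = TRUE))) {
      if (pos > 0) out[[length(out) + 1L]] <- c(pos - 1L - M, -1L)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Hit table -> comparable (start, strand) matrix.
hits_to_matrix <- function(hits) {
  if (nrow(hits) == 0L) return(matrix(integer(0), ncol = 2))
  m <- cbind(hits$start, ifelse(hits$strand == "+", 1L, -1L))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Exhaustive hypergeometric tail: enumerate every n-subset of an urn with
# K marked of N and count subsets holding >= k marked.
oracle_hyper <- function(k, K, n, N) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(subsets %in% marked, nrow = n))
  mean(hits >= k)
}

# Hand step-up BH, independent of p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(max(0L, m - 1L)))) q[i] <- min(q[i], q[i + 1L])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# A non-degenerate 12-mer used where chance-hit background must be
# negligible (expected chance rate ~1e-4 per kb of uniform sequence).
planted12 <- parse_consensus("ACGTACGTTGCA", motif_id = "M12")
secondary12 <- parse_consensus("GTACCAGTTAAC", motif_id = "S12")
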
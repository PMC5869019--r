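# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# unordered positive-weight pairs, by explicit double loop
oracle_edge_count <- function(w) {
  n <- nrow(w)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) if (w[i, j] > 0) cnt <- cnt + 1L
  }
  cnt
}

oracle_disconnected <- function(w) {
  n <- nrow(w)
  out <- character(0)
  for (i in seq_len(n)) {
    deg <- 0L
    for (j in seq_len(n)) if (j != i && w[i, j] > 0) deg <- deg + 1L
    if (deg == 0L) out <- c(out, rownames(w)[i])
  }
  out
}

# all strict -35/-10 pairs by position-by-position substring comparison
oracle_scan <- function(seq, spacer_min = 15, spacer_max = 17,
                        m35 = "GGAAC", m10 = "CGTT") {
  n <- nchar(seq)
  p35 <- integer(0)
  for (i in seq_len(max(n - nchar(m35) + 1, 0))) {
    if (substr(seq, i, i + nchar(m35) - 1) == m35) p35 <- c(p35, i)
  }
  p10 <- integer(0)
  for (i in seq_len(max(n - nchar(m10) + 1, 0))) {
    if (substr(seq, i, i + nchar(m10) - 1) == m10) p10 <- c(p10, i)
  }
  out <- NULL
  for (a in p35) {
    for (b in p10) {
      sp <- b - (a + nchar(m35))
      if (sp >= spacer_min && sp <= spacer_max) {
        out <- rbind(out, c(a, b, sp))
      }
    }
  }
  out
}

# per-base coverage oracle: a read hits a window iff they share >= 1 base
oracle_window_counts <- function(alignments, windows, samples) {
  counts <- matrix(0L, nrow(windows), length(samples),
                   dimnames = list(NULL, samples))
  for (k in seq_len(nrow(alignments))) {
    a <- alignments[k, ]
    read_bases <- seq(a$start, a$end - 1)
    for (w in seq_len(nrow(windows))) {
      if (windows$replicon[w] != a$replicon) next
      win_bases <- seq(windows$start[w], windows$end[w] - 1)
      if (length(intersect(read_bases, win_bases)) >= 1) {
        counts[w, a$sample] <- counts[w, a$sample] + 1L
      }
    }
  }
  counts
}

# random transition matrix for ranking tests: random sparse symmetric
# weights, coerced and normalized through the public constructors
random_transition <- function(n, density = 0.3, keep_diagonal = TRUE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- runif(sum(ut))
  vals[runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w <- w + t(w)
  diag(w) <- 1
  rho <- as_rho_matrix(w)
  normalize_transition(rho, keep_diagonal = keep_diagonal)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
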
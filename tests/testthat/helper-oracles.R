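# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# frame selection by explicit sorting: per-subject ranks via order(order(.)),
# tie-handling by averaging positions, CV by direct formula, top-k by the
# (cv, -mean_rank, index) ordering
brute_force_frame <- function(strengths, fraction) {
  S <- nrow(strengths); E <- ncol(strengths)
  ranks <- matrix(0, S, E)
  for (s in seq_len(S)) {
    v <- strengths[s, ]
    pos <- order(v)                      # ascending: weakest first
    r <- numeric(E)
    r[pos] <- seq_len(E)
    for (val in unique(v[duplicated(v)])) {
      ix <- which(v == val)
      r[ix] <- mean(r[ix])
    }
    ranks[s, ] <- r
  }
  mean_rank <- numeric(E); sd_rank <- numeric(E)
  for (e in seq_len(E)) {
    mean_rank[e] <- sum(ranks[, e]) / S
    sd_rank[e] <- sqrt(sum((ranks[, e] - mean_rank[e])^2) / (S - 1))
  }
  cv <- sd_rank / mean_rank
  n <- (1 + sqrt(1 + 8 * E)) / 2
  k <- floor(n^2 * fraction / 2 + 0.5)
  ord <- order(cv, -mean_rank, seq_len(E))
  sort(ord[seq_len(k)])
}

# Benjamini-Hochberg by definition: flags from max{k: p(k) <= k q / m},
# adjusted values by the step-up minimum
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_ok <- which(ps <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(k_ok)) flags[o[seq_len(max(k_ok))]] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  list(p_adjusted = adj, significant = flags)
}

# small control-like spec used across tests (non-AAL so no default patient
# alterations are attached)
small_control_spec <- function(n = 10, regions = 12, timepoints = 80,
                               seed = 1, ...) {
  cohort_spec(n_control = n, n_patient = 0, n_regions = regions,
              n_timepoints = timepoints, seed = seed, ...)
}
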
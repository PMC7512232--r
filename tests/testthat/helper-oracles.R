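# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and direct formulas only.

# Exhaustive Theiler-windowed correlation sum for a single embedding
# dimension: enumerate every admissible pair and compare squared distances.
oracle_corr_sum <- function(x, tau, m, w, radii) {
  N <- length(x)
  M <- N - (m - 1) * tau
  emb <- sapply(seq_len(m) - 1, function(k) x[(1 + k * tau):(M + k * tau)])
  emb <- matrix(emb, nrow = M)
  counts <- numeric(length(radii))
  total <- 0
  for (i in seq_len(M)) {
    js <- seq_len(M)
    js <- js[js >= i + 1 + w]
    for (j in js) {
      d2 <- sum((emb[i, ] - emb[j, ])^2)
      counts <- counts + as.numeric(d2 <= radii^2)
      total <- total + 1
    }
  }
  counts / ((M - w) * (M - w - 1) / 2)
}

# Direct 2-D histogram mutual information (bits) at one lag, fixed bins.
oracle_ami <- function(x, lag, n_bins) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cut_bin <- function(v) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  n <- length(x)
  a <- cut_bin(x[1:(n - lag)])
  b <- cut_bin(x[(1 + lag):n])
  joint <- matrix(0, n_bins, n_bins)
  for (k in seq_along(a)) joint[a[k], b[k]] <- joint[a[k], b[k]] + 1
  p <- joint / sum(joint)
  ph <- rowSums(p); pk <- colSums(p)
  s <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (ph[i] * pk[j]))
  }
  s
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Build a corr_sum object directly from a C matrix (for closed-form tests).
make_corr_sum <- function(radii, m_values, C, theiler_w = 0) {
  structure(list(radii = radii, m_values = m_values, C = C,
                 theiler_w = theiler_w,
                 n_vectors = stats::setNames(rep(1000L, length(m_values)),
                                             paste0("m", m_values)),
                 tau = 1L),
            class = "corr_sum")
}

noise_free_params <- function(latency = list(c(0, 0)), saccade_ms = 0) {
  oculomotor_params(latency_ranges_ms = latency,
                    saccade_duration_ms = saccade_ms,
                    fixation_drift_sd = 0,
                    tremor_amplitude_deg = 0,
                    measurement_noise_sd = 0)
}
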
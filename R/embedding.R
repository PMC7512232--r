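#' Average mutual information profile
#'
#' Computes the average mutual information (AMI, in bits) between a series
#' and its lagged copy for lags `0..max_lag`:
#' `I = sum_{h,k} P_hk log2( P_hk / (P_h P_k) )`, estimated from a 2-D
#' histogram. The number of bins follows the Freedman-Diaconis rule (bin
#' width `2 IQR n^(-1/3)`) applied to the series, capped at `sqrt(n)` bins
#' so the joint histogram stays populated, unless given explicitly.
#' The first marked local minimum of the profile is the conventional choice
#' of embedding time lag.
#'
#' @param series an [eyets] or numeric vector, not constant.
#' @param max_lag largest lag (samples) to evaluate.
#' @param n_bins number of histogram bins; `NULL` (default) uses
#'   Freedman-Diaconis.
#' @return Object of class `ami_profile`: list with `lags` (0..max_lag),
#'   `ami` (bits, all `>= 0` up to rounding), `n_bins`.
#' @export
ami_profile <- function(series, max_lag = 20, n_bins = NULL) {
  x <- series_values(series)
  n <- length(x)
  if (n <= max_lag + 2) stop("series too short for requested max_lag",
                             call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("degenerate input: constant series has zero IQR", call. = FALSE)
  }
  if (is.null(n_bins)) {
    bw <- 2 * stats::IQR(x) * n^(-1 / 3)
    n_bins <- if (bw > 0) max(2L, ceiling(diff(rng) / bw))
              else max(2L, ceiling(log2(n)) + 1L)  # Sturges fallback
    # a 2-D histogram cannot support more cells than samples; heavy-tailed
    # series (tiny IQR, large range) would otherwise explode the bin count
    n_bins <- min(n_bins, ceiling(sqrt(n)))
  }
  n_bins <- as.integer(n_bins)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)

  ami_one <- function(lag) {
    a <- bin[seq_len(n - lag)]
    b <- bin[seq_len(n - lag) + lag]
    joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
    pm <- matrix(joint / sum(joint), n_bins, n_bins, byrow = TRUE)
    ph <- rowSums(pm)
    pk <- colSums(pm)
    nz <- pm > 0
    sum(pm[nz] * log2(pm[nz] / (ph[row(pm)[nz]] * pk[col(pm)[nz]])))
  }
  ami <- vapply(0:max_lag, ami_one, numeric(1))
  structure(list(lags = 0:max_lag, ami = ami, n_bins = n_bins),
            class = "ami_profile")
}

#' @export
print.ami_profile <- function(x, ...) {
  cat(sprintf("<ami_profile> lags 0..%d, %d bins; I(0) = %.3f bits\n",
              max(x$lags), x$n_bins, x$ami[1]))
  invisible(x)
}

#' @export
plot.ami_profile <- function(x, ...) {
  graphics::plot(x$lags, x$ami, type = "b", xlab = "lag (samples)",
                 ylab = "AMI (bits)", ...)
}

#' Choose the embedding time lag from an AMI profile
#'
#' Returns the smallest lag that is a strict local minimum of the AMI
#' profile. If no local minimum exists, falls back to the smallest lag where
#' AMI drops to `I(0)/e`; failing that, returns the largest lag with a
#' warning. The rule used is recorded in the `"rule"` attribute
#' (`"local_min"`, `"one_over_e"` or `"max_lag"`).
#'
#' @param profile an [ami_profile].
#' @return Integer lag (samples).
#' @export
select_lag <- function(profile) {
  stopifnot(inherits(profile, "ami_profile"))
  a <- profile$ami
  lags <- profile$lags
  if (length(a) < 3) stop("profile must cover at least 3 lags", call. = FALSE)
  for (i in 2:(length(a) - 1)) {
    if (a[i] < a[i - 1] && a[i] < a[i + 1]) {
      return(structure(lags[i], rule = "local_min"))
    }
  }
  thr <- a[1] / exp(1)
  hit <- which(a <= thr)
  if (length(hit) > 0) {
    return(structure(lags[hit[1]], rule = "one_over_e"))
  }
  warning("no AMI minimum or 1/e crossing below max_lag; returning max_lag")
  structure(lags[length(lags)], rule = "max_lag")
}

#' False nearest neighbours profile
#'
#' For each candidate embedding dimension `m`, embeds the series at `(tau,
#' m)`, finds each vector's Euclidean nearest neighbour, and marks the
#' neighbour false when the extra-coordinate ratio
#' `|x[i + m tau] - x[NN + m tau]| / ||y_i - y_NN||` exceeds `threshold_R`.
#' The fraction of false neighbours collapses near zero once `m` unfolds the
#' attractor. Duplicate neighbours (distance at or below `dup_eps`, which
#' covers exact duplicates and the floating-point revisits of periodic
#' signals) are excluded from the ratio and counted, since the ratio of two
#' roundoff-scale distances is meaningless.
#'
#' @param series an [eyets] or numeric vector.
#' @param tau embedding time lag (samples).
#' @param m_range candidate dimensions (increasing integers).
#' @param threshold_R false-neighbour distance ratio threshold (default 10).
#' @param theiler_w temporal exclusion window for the neighbour search
#'   (default 0: only self-matches excluded).
#' @param dup_eps duplicate-distance floor; defaults to `1e-7` times the
#'   series range.
#' @return Object of class `fnn_profile`: `dims`, `fnn_fraction` in [0,1],
#'   `threshold_R`, `n_zero_excluded`.
#' @export
fnn_profile <- function(series, tau, m_range = 1:10, threshold_R = 10,
                        theiler_w = 0, dup_eps = NULL) {
  x <- series_values(series)
  m_range <- sort(as.integer(m_range))
  mmax <- max(m_range)
  if (length(x) < mmax * tau + 2) {
    stop(sprintf("series too short for m = %d at tau = %d (need > %d samples)",
                 mmax, tau, mmax * tau + 1), call. = FALSE)
  }
  if (is.null(dup_eps)) dup_eps <- 1e-7 * diff(range(x))
  res <- fnn_profile_cpp(x, as.integer(tau), m_range, threshold_R,
                         as.integer(theiler_w), dup_eps)
  structure(list(dims = m_range,
                 fnn_fraction = res$fnn_fraction,
                 threshold_R = threshold_R,
                 n_zero_excluded = res$n_zero_excluded),
            class = "fnn_profile")
}

#' @export
print.fnn_profile <- function(x, ...) {
  cat("<fnn_profile> R =", x$threshold_R, "\n")
  print(stats::setNames(round(x$fnn_fraction, 4), paste0("m", x$dims)))
  invisible(x)
}

#' @export
plot.fnn_profile <- function(x, ...) {
  graphics::plot(x$dims, x$fnn_fraction, type = "b", xlab = "embedding dim m",
                 ylab = "FNN fraction", ylim = c(0, max(x$fnn_fraction)), ...)
}

#' Choose the embedding dimension from an FNN profile
#'
#' Smallest dimension whose false-neighbour fraction drops to `tol` or
#' below; if none qualifies, returns the largest candidate with a warning
#' (`"rule"` attribute `"threshold"` or `"max_m"`).
#'
#' @param profile an [fnn_profile].
#' @param tol acceptable false-neighbour fraction (default 0.01).
#' @return Integer embedding dimension.
#' @export
select_embedding_dim <- function(profile, tol = 0.01) {
  stopifnot(inherits(profile, "fnn_profile"))
  ok <- which(profile$fnn_fraction <= tol)
  if (length(ok) > 0) {
    return(structure(profile$dims[ok[1]], rule = "threshold"))
  }
  warning("no dimension reached the FNN tolerance; returning max of range")
  structure(profile$dims[length(profile$dims)], rule = "max_m")
}

#' Delay-coordinate embedding
#'
#' Builds the matrix of delay vectors
#' `y(i) = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, `i = 1..M` with
#' `M = N - (m-1) tau`, reconstructing the system's phase space from one
#' scalar observable.
#'
#' @param series an [eyets] or numeric vector of length `N`.
#' @param tau time lag in samples (>= 1).
#' @param m embedding dimension (>= 1).
#' @return An `M x m` matrix of class `delay_embedding` with attributes
#'   `tau`, `m`, `source_length`, and `series` (the original samples).
#' @examples
#' delay_embed(1:5, tau = 2, m = 2)  # rows (1,3), (2,4), (3,5)
#' @export
delay_embed <- function(series, tau, m) {
  x <- series_values(series)
  n <- length(x)
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1 || m < 1) stop("'tau' and 'm' must be >= 1", call. = FALSE)
  M <- n - (m - 1) * tau
  if (M < 1) {
    stop(sprintf("series too short: need N >= %d for (tau = %d, m = %d), got %d",
                 (m - 1) * tau + 1, tau, m, n), call. = FALSE)
  }
  emb <- vapply(seq_len(m) - 1L, function(k) x[(1 + k * tau):(M + k * tau)],
                numeric(M))
  emb <- matrix(emb, nrow = M, ncol = m)
  structure(emb, tau = tau, m = m, source_length = n, series = x,
            class = c("delay_embedding", "matrix", "array"))
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding> M = %d vectors, m = %d, tau = %d (N = %d)\n",
              nrow(x), attr(x, "m"), attr(x, "tau"),
              attr(x, "source_length")))
  invisible(x)
}
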
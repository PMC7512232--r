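#' Radius grid for correlation-sum analysis
#'
#' Log-spaced grid of `n_radii` radii between `rmin = sd(x)/10` and
#' `rmax = 10 sd(x)`, the conventional two-decade bracket around the series'
#' scale.
#'
#' @param series an [eyets] or numeric vector with positive standard
#'   deviation, or a single positive number interpreted as the standard
#'   deviation itself.
#' @param n_radii number of radii (default 100).
#' @return Object of class `radius_grid`: `radii` (increasing), `rmin`,
#'   `rmax`, `n_radii`.
#' @examples
#' g <- radius_grid(1)  # unit sd: rmin 0.1, rmax 10
#' c(g$rmin, g$rmax)
#' @export
radius_grid <- function(series, n_radii = 100) {
  s <- if (is.numeric(series) && length(series) == 1) series
       else stats::sd(series_values(series))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate input: constant series (zero standard deviation)",
         call. = FALSE)
  }
  n_radii <- as.integer(n_radii)
  if (n_radii < 2) stop("'n_radii' must be >= 2", call. = FALSE)
  rmin <- s / 10
  rmax <- 10 * s
  radii <- exp(seq(log(rmin), log(rmax), length.out = n_radii))
  radii[1] <- rmin; radii[n_radii] <- rmax  # guard fp endpoints
  structure(list(radii = radii, rmin = rmin, rmax = rmax, n_radii = n_radii),
            class = "radius_grid")
}

#' @export
print.radius_grid <- function(x, ...) {
  cat(sprintf("<radius_grid> %d log-spaced radii in [%.4g, %.4g]\n",
              x$n_radii, x$rmin, x$rmax))
  invisible(x)
}

# internal: accept a radius_grid or a numeric vector of radii
as_radii <- function(radii) {
  r <- if (inherits(radii, "radius_grid")) radii$radii else as.numeric(radii)
  if (any(r <= 0) || is.unsorted(r, strictly = TRUE)) {
    stop("radii must be positive and strictly increasing", call. = FALSE)
  }
  r
}

#' Theiler-windowed correlation sum
#'
#' Grassberger-Procaccia correlation sum over a radius grid. For each
#' embedding dimension `m`, vector pairs `(i, j)` with `j >= i + 1 + w`
#' (Theiler window `w` excludes temporally close, hence dynamically
#' correlated, pairs) are counted when their Euclidean distance is `<= r`,
#' normalised by the number of admissible pairs
#' `(M - w)(M - w - 1)/2`, `M = N - (m-1) tau`. With `w = 0` this is the
#' plain correlation sum.
#'
#' Called either on a [delay_embedding] (one `m`) or on a series with `tau`
#' and a vector `ms` of dimensions, in which case all dimensions share one
#' pass over the pairs.
#'
#' @param x a [delay_embedding], or an [eyets]/numeric series (then supply
#'   `tau` and `ms`).
#' @param radii a [radius_grid] or increasing positive vector of radii.
#' @param theiler_w Theiler window `w` in samples (default 100).
#' @param tau,ms time lag and embedding dimensions, when `x` is a series.
#' @param min_pairs smallest admissible pair count accepted before an
#'   insufficient-pairs error (default 1; raise to e.g. 10 to guard real
#'   analyses against meaningless sums).
#' @return Object of class `corr_sum`: `radii`, `m_values`, `C` (matrix
#'   `length(ms) x length(radii)`, values in [0,1], non-decreasing in `r`),
#'   `theiler_w`, `n_vectors` per `m`, `tau`.
#' @examples
#' cs <- correlation_sum(delay_embed(c(0, 1, 2, 3), 1, 1),
#'                       radii = c(0.5, 1.5, 3.5), theiler_w = 0)
#' cs$C  # 0, 0.5, 1
#' @export
correlation_sum <- function(x, radii, theiler_w = 100, tau = NULL, ms = NULL,
                            min_pairs = 1) {
  if (inherits(x, "delay_embedding")) {
    series <- attr(x, "series")
    tau <- attr(x, "tau")
    ms <- attr(x, "m")
  } else {
    series <- series_values(x)
    if (is.null(tau) || is.null(ms)) {
      stop("supply 'tau' and 'ms' when calling on a plain series",
           call. = FALSE)
    }
  }
  r <- as_radii(radii)
  ms <- sort(unique(as.integer(ms)))
  tau <- as.integer(tau)
  w <- as.integer(theiler_w)
  if (w < 0) stop("'theiler_w' must be >= 0", call. = FALSE)
  n <- length(series)
  M <- n - (ms - 1L) * tau
  n_admissible <- (M - w) * (M - w - 1) / 2
  if (any(n_admissible < min_pairs)) {
    bad <- ms[which.min(n_admissible)]
    stop(sprintf(
      "insufficient admissible pairs at m = %d (M = %d vectors, w = %d)",
      bad, M[which(ms == bad)], w), call. = FALSE)
  }
  C <- corr_sum_multi_cpp(series, tau, ms, w, r)
  dimnames(C) <- list(paste0("m", ms), NULL)
  structure(list(radii = r, m_values = ms, C = C, theiler_w = w,
                 n_vectors = stats::setNames(M, paste0("m", ms)), tau = tau),
            class = "corr_sum")
}

#' @export
print.corr_sum <- function(x, ...) {
  cat(sprintf("<corr_sum> m = {%s}, %d radii in [%.3g, %.3g], w = %d\n",
              paste(x$m_values, collapse = ","), length(x$radii),
              min(x$radii), max(x$radii), x$theiler_w))
  invisible(x)
}

#' @export
plot.corr_sum <- function(x, ...) {
  graphics::matplot(log10(x$radii), t(log10(x$C)), type = "l", lty = 1,
                    xlab = "log10 r", ylab = "log10 C(m, r)", ...)
}

#' Local scaling exponents of the correlation sum
#'
#' Centred finite differences of `log C` versus `log r` per embedding
#' dimension (one-sided at the grid ends); the plateau of these local slopes
#' identifies the linear scaling region whose slope is D2. Entries where
#' `C = 0` (or where a difference involves one) are `NA`.
#'
#' @param result a [corr_sum].
#' @return Matrix of local slopes, same shape as `result$C`, with attribute
#'   `undefined` (logical matrix flagging `NA` cells).
#' @export
scaling_exponents <- function(result) {
  stopifnot(inherits(result, "corr_sum"))
  lr <- log(result$radii)
  lC <- log(result$C)
  lC[!is.finite(lC)] <- NA
  nr <- length(lr)
  slopes <- matrix(NA_real_, nrow(result$C), nr,
                   dimnames = dimnames(result$C))
  for (mi in seq_len(nrow(lC))) {
    y <- lC[mi, ]
    if (nr >= 2) {
      slopes[mi, 1] <- (y[2] - y[1]) / (lr[2] - lr[1])
      slopes[mi, nr] <- (y[nr] - y[nr - 1]) / (lr[nr] - lr[nr - 1])
    }
    if (nr >= 3) {
      idx <- 2:(nr - 1)
      slopes[mi, idx] <- (y[idx + 1] - y[idx - 1]) / (lr[idx + 1] - lr[idx - 1])
    }
  }
  attr(slopes, "undefined") <- is.na(slopes)
  slopes
}

# internal: pick a scaling region automatically from the local slopes.
# Slides a window of `width` grid points over the radii and picks the one
# minimising the dispersion of local slopes across radii and dimensions
# (m >= min_m), i.e. the flattest joint plateau. Returns c(r_low, r_high).
auto_scaling_region <- function(result, width = 10, min_m = 3) {
  slopes <- scaling_exponents(result)
  use_m <- result$m_values >= min_m
  if (!any(use_m)) use_m <- rep(TRUE, length(result$m_values))
  s <- slopes[use_m, , drop = FALSE]
  nr <- length(result$radii)
  width <- min(width, nr)
  best <- Inf; best_i <- 1
  for (i in seq_len(nr - width + 1)) {
    blk <- s[, i:(i + width - 1), drop = FALSE]
    if (any(!is.finite(blk))) next
    if (mean(blk) <= 0) next          # saturated / empty region
    score <- stats::sd(as.numeric(blk)) / max(mean(blk), .Machine$double.eps)
    if (is.finite(score) && score < best) { best <- score; best_i <- i }
  }
  c(result$radii[best_i], result$radii[best_i + width - 1])
}

# internal: least-squares slope and R^2 of log C vs log r inside a region
region_fit <- function(lr, lC, in_region) {
  ok <- in_region & is.finite(lC)
  if (sum(ok) < 3) return(c(NA_real_, NA_real_, sum(ok)))
  fit <- stats::lm.fit(cbind(1, lr[ok]), lC[ok])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lC[ok] - mean(lC[ok]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  c(fit$coefficients[2], r2, sum(ok))
}

# internal: longest run of consecutive dimensions whose successive values
# differ by less than tol; returns indices, or integer(0) if none
plateau_run <- function(values, tol = 0.2) {
  ok <- which(abs(diff(values)) < tol & is.finite(values[-length(values)]) &
                is.finite(values[-1]))
  if (length(ok) == 0) return(integer(0))
  # group consecutive indices
  grp <- cumsum(c(1, diff(ok) != 1))
  runs <- split(ok, grp)
  len <- lengths(runs)
  best <- runs[[max(which(len == max(len)))]]  # ties -> largest m
  c(best, best[length(best)] + 1L)
}

#' Correlation dimension from the scaling region
#'
#' For each embedding dimension (>= `min_m`), fits the least-squares slope
#' of `log C` versus `log r` inside the scaling region; the reported D2 is
#' the median of the slopes over the m-plateau (the longest run of
#' dimensions whose successive slopes differ by less than 0.2). A plateau of
#' slopes across `m` is the convergence signature of a deterministic
#' (low-dimensional) series; stochastic series show slopes growing with `m`
#' and get `plateau_found = FALSE`.
#'
#' If `region` is `NULL`, or does not contain at least 3 usable radii, a
#' scaling region is detected automatically from the flattest joint slope
#' plateau (`region_fallback` flag set).
#'
#' @param result a [corr_sum].
#' @param region numeric `c(r_low, r_high)`, or `NULL` for automatic
#'   detection. Conventional per-condition defaults for the eye-movement
#'   pipeline are `c(0.00055, 0.0018)` (BNR) and `c(0.001, 0.003)` (ANR).
#' @param min_m smallest embedding dimension used in the aggregate
#'   (default 3).
#' @param plateau_tol maximum difference between successive per-m slopes
#'   inside the plateau (default 0.2).
#' @return Object of class `invariant_estimate` (kind `"D2"`): `value`,
#'   `scaling_region`, `per_m` data frame (m, slope, r2, n_radii),
#'   `plateau_found`, `plateau_m`, `fit_quality`, `region_fallback`.
#' @export
estimate_d2 <- function(result, region = NULL, min_m = 3, plateau_tol = 0.2) {
  stopifnot(inherits(result, "corr_sum"))
  lr <- log(result$radii)
  lC <- log(result$C)
  lC[!is.finite(lC)] <- NA

  usable <- function(reg) {
    inr <- result$radii >= reg[1] & result$radii <= reg[2]
    any(apply(lC[, inr, drop = FALSE], 1, function(z) sum(is.finite(z)) >= 3))
  }
  fallback <- FALSE
  if (is.null(region) || !usable(region)) {
    fallback <- !is.null(region)
    region <- auto_scaling_region(result, min_m = min_m)
  }
  in_region <- result$radii >= region[1] & result$radii <= region[2]

  fits <- t(vapply(seq_along(result$m_values),
                   function(mi) region_fit(lr, lC[mi, ], in_region),
                   numeric(3)))
  per_m <- data.frame(m = result$m_values, slope = fits[, 1], r2 = fits[, 2],
                      n_radii = fits[, 3])
  cand <- per_m[per_m$m >= min_m & is.finite(per_m$slope), ]
  if (nrow(cand) == 0) cand <- per_m[is.finite(per_m$slope), ]
  if (nrow(cand) == 0) {
    return(structure(list(kind = "D2", value = NA_real_,
                          scaling_region = region, per_m = per_m,
                          plateau_found = FALSE, plateau_m = integer(0),
                          fit_quality = NA_real_, region_fallback = fallback),
                     class = "invariant_estimate"))
  }
  run <- plateau_run(cand$slope, tol = plateau_tol)
  plateau_found <- length(run) >= 2
  use <- if (plateau_found) run else seq_len(nrow(cand))
  structure(list(kind = "D2",
                 value = stats::median(cand$slope[use]),
                 scaling_region = region,
                 per_m = per_m,
                 plateau_found = plateau_found,
                 plateau_m = cand$m[use],
                 fit_quality = stats::median(cand$r2[use], na.rm = TRUE),
                 region_fallback = fallback),
            class = "invariant_estimate")
}

#' @export
print.invariant_estimate <- function(x, ...) {
  reg <- paste(signif(x$scaling_region, 3), collapse = ", ")
  cat(sprintf("<invariant_estimate> %s = %.4g  (region [%s]%s)\n",
              x$kind, x$value, reg,
              if (isTRUE(x$plateau_found)) ""
              else if (!is.null(x$plateau_found)) ", no m-plateau" else ""))
  invisible(x)
}

#' Data-length bounds for the correlation dimension
#'
#' A series of `n` points supports reliable correlation-dimension estimates
#' only up to `D2 <= 2 log10 n`; inverting, estimating a dimension `d2`
#' requires at least `10^(d2/2)` points. For the 2999-sample fixation series
#' the bound is 6.95, i.e. dimensions up to about seven are estimable.
#'
#' @param n series length (>= 2).
#' @return `sample_size_bound`: the bound `2 log10 n`.
#' @examples
#' sample_size_bound(1000)  # 6
#' required_n(6)            # 1000
#' @export
sample_size_bound <- function(n) {
  if (any(n < 2)) stop("'n' must be >= 2", call. = FALSE)
  2 * log10(n)
}

#' @rdname sample_size_bound
#' @param d2 correlation dimension (>= 0).
#' @return `required_n`: the minimum integer series length `ceil(10^(d2/2))`.
#' @export
required_n <- function(d2) {
  if (any(d2 < 0)) stop("'d2' must be >= 0", call. = FALSE)
  as.integer(ceiling(10^(d2 / 2)))
}

# internal: radius region for the entropy estimate. K2 is defined in the
# joint limit r -> 0, m -> infinity; the m side is handled by the plateau
# aggregation, the r side here: the smallest few radii at which every
# consecutive-m pair still has support (and the sums are unsaturated).
auto_k2_region <- function(result, pairs, both_pos) {
  ok <- which(apply(both_pos, 2, all) & result$C[1, ] < 0.5)
  if (length(ok) < 2) ok <- which(apply(both_pos, 2, all))
  if (length(ok) < 2) ok <- which(apply(both_pos, 2, any))
  width <- min(length(ok), max(3L, ceiling(length(result$radii) / 20)))
  c(result$radii[ok[1]], result$radii[ok[width]])
}

#' Correlation entropy K2
#'
#' Estimates the correlation (K2) entropy from the decay of the correlation
#' sum with embedding dimension: `K2(m, r) = ln( C(m, r) / C(m+1, r) )`,
#' averaged over the radii of the scaling region and aggregated as the
#' median over the m-plateau. K2 is ~0 for periodic signals, positive and
#' finite for chaotic ones, and grows with `m` without plateau for random
#' signals. Units: nats per embedding step (one step = `tau` samples).
#'
#' @param result a [corr_sum] computed for at least two consecutive
#'   embedding dimensions.
#' @param region numeric `c(r_low, r_high)` or `NULL` for automatic
#'   selection: the smallest few radii at which every consecutive pair of
#'   dimensions still has support, honouring the `r -> 0` limit in the
#'   definition (the `m -> infinity` limit is handled by the plateau
#'   aggregation).
#' @param plateau_tol plateau tolerance on successive `K2(m)` differences
#'   (default 0.2 nats).
#' @return Object of class `invariant_estimate` (kind `"K2"`): `value`,
#'   `per_m` data frame (m, k2, n_radii), `plateau_found`, `plateau_m`,
#'   `scaling_region`.
#' @export
k2_entropy <- function(result, region = NULL, plateau_tol = 0.2) {
  stopifnot(inherits(result, "corr_sum"))
  ms <- result$m_values
  pairs <- which(diff(ms) == 1L)
  if (length(pairs) == 0) {
    stop("need correlation sums at consecutive embedding dimensions",
         call. = FALSE)
  }
  both_pos <- result$C[pairs, , drop = FALSE] > 0 &
    result$C[pairs + 1L, , drop = FALSE] > 0
  if (!any(both_pos)) {
    stop("insufficient neighbours: C(m+1, r) vanishes on the whole grid",
         call. = FALSE)
  }
  if (is.null(region)) {
    region <- auto_k2_region(result, pairs, both_pos)
  }
  in_region <- result$radii >= region[1] & result$radii <= region[2]

  k2_m <- vapply(pairs, function(p) {
    ok <- in_region & both_pos[match(p, pairs), ]
    if (sum(ok) < 1) return(NA_real_)
    mean(log(result$C[p, ok] / result$C[p + 1L, ok]))
  }, numeric(1))
  n_ok <- vapply(pairs, function(p) sum(in_region & both_pos[match(p, pairs), ]),
                 numeric(1))
  per_m <- data.frame(m = ms[pairs], k2 = k2_m, n_radii = n_ok)
  cand <- per_m[is.finite(per_m$k2), ]
  if (nrow(cand) == 0) {
    stop("insufficient neighbours inside the requested region", call. = FALSE)
  }
  run <- plateau_run(cand$k2, tol = plateau_tol)
  plateau_found <- length(run) >= 2
  use <- if (plateau_found) run else seq_len(nrow(cand))
  structure(list(kind = "K2",
                 value = stats::median(cand$k2[use]),
                 scaling_region = region,
                 per_m = per_m,
                 plateau_found = plateau_found,
                 plateau_m = cand$m[use],
                 fit_quality = NA_real_,
                 region_fallback = FALSE),
            class = "invariant_estimate")
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For every embedded vector, finds its nearest neighbour under Theiler
#' exclusion (`|i - j| > w`), tracks the mean log distance of the pairs over
#' forward time steps, and fits the slope of the initial linear rise of this
#' divergence curve; the slope divided by `dt` is the largest Lyapunov
#' exponent. Positive values indicate exponential divergence of nearby
#' trajectories (chaos); ~0 indicates periodic or stable dynamics.
#' Zero-distance neighbour pairs are excluded, not divided by.
#'
#' @param embedding a [delay_embedding].
#' @param dt time per step, in whatever units the exponent is wanted
#'   (default 1: per sample/iterate).
#' @param theiler_w Theiler exclusion window (default 100).
#' @param n_steps how many forward steps of divergence to track (default 30).
#' @param fit_range integer step range for the slope fit, or `NULL` to fit
#'   from step 0 up to where the curve reaches 80% of its total rise.
#' @param dup_eps duplicate-distance floor for neighbour seeding (default
#'   `1e-7` times the series range): exact duplicates and floating-point
#'   revisits are excluded, not divided by.
#' @return Object of class `invariant_estimate` (kind `"LLE"`): `value`
#'   (per `dt`), `divergence` (mean log-divergence curve), `scaling_region`
#'   (fitted step range), `fit_quality` (R^2), `n_pairs`.
#' @export
lle_rosenstein <- function(embedding, dt = 1, theiler_w = 100, n_steps = 30,
                           fit_range = NULL, dup_eps = NULL) {
  stopifnot(inherits(embedding, "delay_embedding"))
  x <- attr(embedding, "series")
  tau <- attr(embedding, "tau")
  m <- attr(embedding, "m")
  M <- nrow(embedding)
  w <- as.integer(theiler_w)
  if (M <= w + 10) {
    stop(sprintf("insufficient vectors (M = %d) for Theiler window w = %d",
                 M, w), call. = FALSE)
  }
  if (is.null(dup_eps)) dup_eps <- 1e-7 * diff(range(x))
  res <- lle_divergence_cpp(x, tau, m, w, as.integer(n_steps), dup_eps)
  if (res$n_pairs < 5) {
    stop("insufficient neighbour pairs for divergence tracking",
         call. = FALSE)
  }
  curve <- res$mean_log_divergence
  steps <- seq_along(curve) - 1L
  if (is.null(fit_range)) {
    fin <- which(is.finite(curve))
    lo <- min(curve[fin]); hi <- max(curve[fin])
    thresh <- lo + 0.8 * (hi - lo)
    stop_at <- which(curve >= thresh)[1]
    if (is.na(stop_at) || stop_at < 4) stop_at <- min(length(curve), 4)
    fit_range <- 0:(stop_at - 1)
  }
  sel <- steps %in% fit_range & is.finite(curve)
  fit <- stats::lm.fit(cbind(1, steps[sel]), curve[sel])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((curve[sel] - mean(curve[sel]))^2)
  structure(list(kind = "LLE",
                 value = unname(fit$coefficients[2]) / dt,
                 scaling_region = range(steps[sel]),
                 divergence = curve,
                 per_m = NULL,
                 plateau_found = NA,
                 fit_quality = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_pairs = res$n_pairs,
                 n_zero_excluded = res$n_zero_excluded),
            class = "invariant_estimate")
}
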
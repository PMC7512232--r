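#' FFT phase-randomised surrogate
#'
#' Generates a surrogate series embodying the linear-stochastic null
#' hypothesis: the DFT amplitudes of the original are kept exactly, the
#' phases are replaced by uniform random phases with Hermitian symmetry (DC
#' bin and, for even length, the Nyquist bin keep their values), and the
#' inverse transform is returned. The surrogate therefore has the same
#' amplitude spectrum, mean and autocorrelation as the original but no
#' deterministic structure.
#'
#' @param series an [eyets] or numeric vector, length >= 8.
#' @param seed integer RNG seed.
#' @return An [eyets] of the same length, rate, units and condition.
#' @export
fft_surrogate <- function(series, seed = 1) {
  x <- series_values(series)
  n <- length(x)
  if (n < 8) stop("series too short for surrogate generation (need >= 8)",
                  call. = FALSE)
  spec <- stats::fft(x)
  half <- floor((n - 1) / 2)           # bins 2..half+1 are free phases
  phases <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  newspec <- spec
  if (half > 0) {
    idx <- 2:(half + 1)
    newspec[idx] <- Mod(spec[idx]) * exp(1i * phases)
    newspec[n + 2 - idx] <- Conj(newspec[idx])  # Hermitian mirror
  }
  # DC (and Nyquist when n is even) stay untouched: mean preserved
  y <- Re(stats::fft(newspec, inverse = TRUE)) / n
  eyets(y, rate = series_rate(series),
        units = if (inherits(series, "eyets")) series$units else "a.u.",
        condition = series_condition(series))
}

#' Surrogate ensemble
#'
#' A set of phase-randomised surrogates of one series (the conventional
#' ensemble size is 5), with per-member phase draws derived
#' deterministically from one seed.
#'
#' @param series an [eyets] or numeric vector.
#' @param n_surrogates ensemble size (default 5).
#' @param seed integer RNG seed.
#' @param original_id label for bookkeeping.
#' @return Object of class `surrogate_ensemble`: `original`, `surrogates`
#'   (list of [eyets]), `seed`, `original_id`.
#' @export
surrogate_ensemble <- function(series, n_surrogates = 5, seed = 1,
                               original_id = "series") {
  member_seeds <- with_seed(seed,
                            sample.int(.Machine$integer.max - 1, n_surrogates))
  surr <- lapply(member_seeds, function(s) fft_surrogate(series, seed = s))
  structure(list(original = series, surrogates = surr, seed = seed,
                 member_seeds = member_seeds, original_id = original_id),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates of '%s' (n = %d, seed %d)\n",
              length(x$surrogates), x$original_id,
              length(series_values(x$original)), x$seed))
  invisible(x)
}

#' Surrogate test against the linear-stochastic null
#'
#' Runs the correlation-dimension analysis on the original series and on
#' each surrogate of the ensemble. The null hypothesis "the series comes
#' from a linear stochastic process" is rejected when the original shows a
#' convergent m-plateau of scaling-region slopes (`plateau_found`) while at
#' least `k` of the surrogates do not. Surrogates whose analysis fails are
#' excluded and `k` is re-based proportionally.
#'
#' @param series an [eyets] or numeric vector.
#' @param ensemble a [surrogate_ensemble] of the series, or `NULL` to
#'   generate one.
#' @param tau embedding lag; `NULL` selects it from the AMI profile.
#' @param ms embedding dimensions analysed (default 2:5).
#' @param theiler_w Theiler window (default 100).
#' @param n_radii radius grid size (default 100).
#' @param region scaling region passed to [estimate_d2()] (`NULL`: auto).
#' @param k minimum number of non-converging surrogates required to reject
#'   (default 4 of 5).
#' @param n_surrogates,seed ensemble parameters when `ensemble` is `NULL`.
#' @return Object of class `surrogate_test`: `rejected`, `original`
#'   (its [estimate_d2()] result), `surrogate_estimates`, `k_required`,
#'   `n_excluded`, `tau`.
#' @export
surrogate_d2_test <- function(series, ensemble = NULL, tau = NULL, ms = 2:5,
                              theiler_w = 100, n_radii = 100, region = NULL,
                              k = 4, n_surrogates = 5, seed = 1) {
  if (is.null(ensemble)) {
    ensemble <- surrogate_ensemble(series, n_surrogates = n_surrogates,
                                   seed = seed)
  }
  if (is.null(tau)) {
    tau <- as.integer(suppressWarnings(select_lag(ami_profile(
      series, max_lag = min(20, length(series_values(series)) %/% 4)))))
  }
  analyse <- function(s) {
    cs <- correlation_sum(s, radii = radius_grid(s, n_radii = n_radii),
                          theiler_w = theiler_w, tau = tau, ms = ms)
    estimate_d2(cs, region = region, min_m = min(ms))
  }
  orig <- analyse(series)
  surr <- lapply(ensemble$surrogates, function(s) {
    tryCatch(analyse(s), error = function(e) e)
  })
  failed <- vapply(surr, inherits, logical(1), what = "error")
  ok <- surr[!failed]
  n_total <- length(surr)
  k_eff <- if (any(failed)) max(1L, ceiling(k * length(ok) / n_total)) else k
  surr_no_plateau <- vapply(ok, function(e) !isTRUE(e$plateau_found),
                            logical(1))
  rejected <- isTRUE(orig$plateau_found) && sum(surr_no_plateau) >= k_eff
  structure(list(rejected = rejected,
                 original = orig,
                 surrogate_estimates = ok,
                 surrogate_no_plateau = surr_no_plateau,
                 k_required = k_eff,
                 n_excluded = sum(failed),
                 tau = tau),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf(
    "<surrogate_test> null (linear stochastic) %s\n  original plateau: %s; surrogates without plateau: %d/%d (k = %d)\n",
    if (x$rejected) "REJECTED" else "not rejected",
    x$original$plateau_found, sum(x$surrogate_no_plateau),
    length(x$surrogate_no_plateau), x$k_required))
  invisible(x)
}
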
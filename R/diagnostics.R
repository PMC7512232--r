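#' Space-time separation plot
#'
#' For each temporal separation `dt`, computes percentile contours of the
#' Euclidean distances between embedded vector pairs exactly `dt` samples
#' apart. The separation after which the contours saturate is a safe Theiler
#' window: pairs closer in time than that are close in space merely because
#' they are temporal neighbours. For chaotic series the contours rise and
#' then oscillate around a constant level.
#'
#' @param embedding a [delay_embedding] with `M > max_dt` vectors.
#' @param max_dt largest temporal separation (samples) examined.
#' @param percentiles probability levels of the contours (default deciles).
#' @return Object of class `space_time_separation`: `dt_values`,
#'   `percentile_contours` (matrix percentile x dt, non-decreasing across
#'   percentiles at fixed dt), `percentiles`.
#' @export
space_time_separation <- function(embedding, max_dt = 500,
                                  percentiles = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(embedding, "delay_embedding"))
  M <- nrow(embedding)
  if (max_dt >= M) {
    stop(sprintf("max_dt (%d) must be smaller than the number of vectors (%d)",
                 max_dt, M), call. = FALSE)
  }
  emb <- unclass(embedding)
  contours <- vapply(seq_len(max_dt), function(dt) {
    d <- sqrt(rowSums((emb[seq_len(M - dt), , drop = FALSE] -
                         emb[(1 + dt):M, , drop = FALSE])^2))
    stats::quantile(d, probs = percentiles, names = FALSE)
  }, numeric(length(percentiles)))
  contours <- matrix(contours, nrow = length(percentiles),
                     dimnames = list(paste0("p", percentiles * 100), NULL))
  structure(list(dt_values = seq_len(max_dt),
                 percentile_contours = contours,
                 percentiles = percentiles),
            class = "space_time_separation")
}

#' @export
print.space_time_separation <- function(x, ...) {
  cat(sprintf("<space_time_separation> dt 1..%d, %d percentile contours\n",
              max(x$dt_values), length(x$percentiles)))
  invisible(x)
}

#' @export
plot.space_time_separation <- function(x, ...) {
  graphics::matplot(x$dt_values, t(x$percentile_contours), type = "l",
                    lty = 1, xlab = "temporal separation dt (samples)",
                    ylab = "distance", ...)
}

#' Suggest a Theiler window from a space-time separation plot
#'
#' Finds the smallest temporal separation after which the median contour
#' stays within `tol` (relative) of its long-separation level; if the
#' contour never saturates within the examined range, falls back to the
#' `3 tau` rule with a flag. Both values are reported.
#'
#' @param stsep a [space_time_separation].
#' @param tol relative tolerance around the saturation level (default 0.1).
#' @param tau embedding lag, used for the `3 tau` fallback/report.
#' @return List with `theiler_w` (samples), `rule` (`"saturation"` or
#'   `"3tau"`), `rule_3tau`, `saturated`.
#' @export
suggest_theiler <- function(stsep, tol = 0.1, tau = 1) {
  stopifnot(inherits(stsep, "space_time_separation"))
  med_i <- which.min(abs(stsep$percentiles - 0.5))
  contour <- stsep$percentile_contours[med_i, ]
  n <- length(contour)
  tail_idx <- max(1, ceiling(0.75 * n)):n
  level <- stats::median(contour[tail_idx])
  within <- abs(contour - level) <= tol * level
  # smallest dt from which the contour stays within the band for good
  ok_from <- rev(cumprod(rev(within))) == 1
  if (any(ok_from)) {
    list(theiler_w = stsep$dt_values[which(ok_from)[1]],
         rule = "saturation", rule_3tau = 3L * as.integer(tau),
         saturated = TRUE)
  } else {
    list(theiler_w = 3L * as.integer(tau), rule = "3tau",
         rule_3tau = 3L * as.integer(tau), saturated = FALSE)
  }
}

#' Recurrence matrix (unthresholded recurrence plot)
#'
#' All pairwise distances between the elements of a series window (absolute
#' differences for scalars, Euclidean distances between rows for a
#' [delay_embedding]), normalised by the maximum distance. Rendered as an
#' image with 0 mapped to black (identical states) and 1 to white (maximally
#' distant states), recurring states show up as dark off-diagonal structure;
#' periodic signals give diagonal banding at the period.
#'
#' @param x an [eyets], numeric vector, or [delay_embedding].
#' @return Object of class `recurrence_matrix`: `distances` (symmetric,
#'   zero diagonal, in [0,1]), `normalisation` (the max distance divided
#'   by).
#' @export
recurrence_matrix <- function(x) {
  if (inherits(x, "delay_embedding")) {
    d <- as.matrix(stats::dist(unclass(x)))
  } else {
    v <- series_values(x)
    if (length(v) < 2) stop("need at least 2 elements", call. = FALSE)
    d <- abs(outer(v, v, "-"))
  }
  mx <- max(d)
  if (mx > 0) d <- d / mx
  dimnames(d) <- NULL
  structure(list(distances = d, normalisation = mx),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, max distance %.4g\n",
              nrow(x$distances), ncol(x$distances), x$normalisation))
  invisible(x)
}

#' @export
plot.recurrence_matrix <- function(x, ...) {
  n <- nrow(x$distances)
  graphics::image(seq_len(n), seq_len(n), x$distances,
                  col = grDevices::grey(seq(0, 1, length.out = 256)),
                  xlab = "i", ylab = "j", useRaster = TRUE, ...)
}
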
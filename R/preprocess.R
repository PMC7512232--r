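#' Two-point differentiation of a position series
#'
#' Forward difference over adjacent samples, `v[i] = (x[i+1] - x[i]) / dt`
#' with `dt` in ms, turning a position trace (deg) into a velocity series
#' (deg/ms) one sample shorter. A 3000-sample fixation therefore yields a
#' 2999-sample velocity series.
#'
#' @param position an [eyets] (or numeric vector, assumed 1000 Hz).
#' @return An [eyets] velocity series of length `length(position) - 1`, in
#'   `deg/ms`, condition `"BNR"` (before noise reduction).
#' @examples
#' v <- differentiate(eyets(c(0, 1, 3, 6), rate = 1000))
#' series_values(v)  # 1, 2, 3 deg/ms
#' @export
differentiate <- function(position) {
  x <- series_values(position)
  if (length(x) < 2) stop("series too short to differentiate (length < 2)",
                          call. = FALSE)
  rate <- series_rate(position)
  dt_ms <- 1000 / rate
  v <- diff(x) / dt_ms
  eyets(v, rate = rate, units = "deg/ms", condition = "BNR")
}

#' Ideal low-pass filter via the DFT
#'
#' Transforms the series with the FFT, zeroes every bin whose frequency is
#' strictly greater than `cutoff_hz` in absolute value (the bin at exactly
#' the cutoff is kept), and inverts the transform. This is the "ideal"
#' (brick-wall) low-pass used for noise reduction at 50 Hz; it preserves the
#' mean exactly and is a projection, hence idempotent.
#'
#' @param series an [eyets] or numeric vector.
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @return Filtered series of the same length; condition becomes `"ANR"`.
#' @export
lowpass_ideal <- function(series, cutoff_hz = 50) {
  x <- series_values(series)
  rate <- series_rate(series)
  if (cutoff_hz >= rate / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, rate / 2), call. = FALSE)
  }
  n <- length(x)
  spec <- stats::fft(x)
  # frequency of bin k (0-based): k*rate/n, folded to (-rate/2, rate/2]
  k <- 0:(n - 1)
  freq <- k * rate / n
  freq <- ifelse(freq > rate / 2, freq - rate, freq)
  spec[abs(freq) > cutoff_hz] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  out <- eyets(y, rate = rate,
               units = if (inherits(series, "eyets")) series$units else "a.u.",
               condition = "ANR")
  out
}

#' Window specification and sub-series extraction
#'
#' Windows are 1-based and inclusive on both ends, written `<start...end>`.
#' The default analysis windows for a 2999-sample velocity series are
#' `<1...700>`, `<700...1500>` and `<1500...2999>` (lengths 700, 801 and
#' 1500; adjacent windows share one boundary sample).
#'
#' @param start,end 1-based inclusive sample indices, `start < end`.
#' @return `window_spec` returns a `window_spec` object; `default_windows`
#'   a list of the three standard windows.
#' @export
window_spec <- function(start, end) {
  if (!(start >= 1 && start < end)) {
    stop("window requires 1 <= start < end", call. = FALSE)
  }
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
default_windows <- function() {
  list(window_spec(1, 700), window_spec(700, 1500), window_spec(1500, 2999))
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> <%d...%d> (%d samples)\n",
              x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

#' Cut a series into analysis windows
#'
#' @param series an [eyets] or numeric vector.
#' @param windows list of [window_spec]; defaults to [default_windows()].
#' @return List of [eyets] sub-series (copies), one per window, inheriting
#'   rate, units and condition.
#' @examples
#' segs <- segment(eyets(rnorm(2999)))
#' vapply(segs, length, 1L)  # 700 801 1500
#' @export
segment <- function(series, windows = default_windows()) {
  x <- series_values(series)
  if (inherits(windows, "window_spec")) windows <- list(windows)
  lapply(windows, function(w) {
    stopifnot(inherits(w, "window_spec"))
    if (w$end > length(x)) {
      stop(sprintf("window <%d...%d> out of range for series of length %d",
                   w$start, w$end, length(x)), call. = FALSE)
    }
    eyets(x[w$start:w$end], rate = series_rate(series),
          units = if (inherits(series, "eyets")) series$units else "a.u.",
          condition = series_condition(series))
  })
}

#' Split a session recording into stimulus-locked fixation segments
#'
#' Cuts the position trace at the scheduled stimulus onsets, giving one
#' segment per stimulus location (29 segments of 3000 samples under the
#' default protocol). Each segment covers the full display interval of its
#' stimulus, i.e. latency + saccade + fixation.
#'
#' @param recording a `session_recording` from [generate_session()] or
#'   [read_session_csv()].
#' @return List of [eyets] position segments.
#' @export
split_fixations <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  pos <- recording$position
  n_fix <- nrow(recording$schedule$locations)
  n_per <- round(recording$schedule$display_duration_ms * pos$rate / 1000)
  if (length(pos) != n_fix * n_per) {
    stop(sprintf(
      "recording length %d does not match schedule (%d fixations x %d samples)",
      length(pos), n_fix, n_per), call. = FALSE)
  }
  lapply(seq_len(n_fix), function(f) {
    eyets(pos$values[(f - 1) * n_per + seq_len(n_per)],
          rate = pos$rate, units = pos$units)
  })
}
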
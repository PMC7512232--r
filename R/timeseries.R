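#' Uniformly sampled scalar time series
#'
#' Light container for the signals the package analyses: a numeric vector of
#' samples together with its sampling rate, units, and noise-reduction
#' condition. `"BNR"`/`"ANR"` mark a velocity series before/after noise
#' reduction by the ideal low-pass filter; `"raw"` marks anything else
#' (typically a position trace).
#'
#' @param values numeric vector of samples, length >= 2, all finite.
#' @param rate sampling rate in Hz.
#' @param units unit label, e.g. `"deg"` or `"deg/ms"`.
#' @param condition one of `"raw"`, `"BNR"`, `"ANR"`.
#' @return An object of class `eyets`.
#' @examples
#' s <- eyets(sin(2 * pi * 10 * (0:999) / 1000), rate = 1000, units = "deg")
#' length(s)
#' @export
eyets <- function(values, rate = 1000, units = "deg", condition = "raw") {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("time series must contain at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time series contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("'rate' must be a positive scalar (Hz)", call. = FALSE)
  }
  condition <- match.arg(condition, c("raw", "BNR", "ANR"))
  structure(list(values = values, rate = rate, units = units,
                 condition = condition),
            class = "eyets")
}

#' @export
print.eyets <- function(x, ...) {
  cat(sprintf("<eyets> %d samples @ %g Hz [%s, %s]\n",
              length(x$values), x$rate, x$units, x$condition))
  cat(sprintf("  range [%.4g, %.4g], sd %.4g\n",
              min(x$values), max(x$values), stats::sd(x$values)))
  invisible(x)
}

#' @export
length.eyets <- function(x) length(x$values)

#' Extract the sample vector from a series-like object
#'
#' Accepts an [eyets] object or a plain numeric vector, so every estimator in
#' the package can be called on either.
#'
#' @param x an `eyets` or numeric vector.
#' @return Numeric vector of samples.
#' @export
series_values <- function(x) {
  if (inherits(x, "eyets")) x$values else as.numeric(x)
}

# internal: rate with a default for bare vectors
series_rate <- function(x, default = 1000) {
  if (inherits(x, "eyets")) x$rate else default
}

series_condition <- function(x) {
  if (inherits(x, "eyets")) x$condition else "raw"
}

#' Read and write time series as CSV
#'
#' The on-disk format is two columns, `index` and `value`, preceded by `#`
#' comment header lines carrying the sampling rate, units and condition, so a
#' series round-trips losslessly through plain text.
#'
#' @param x an [eyets] object.
#' @param path file path.
#' @return `write_eyets_csv` returns `path` invisibly; `read_eyets_csv`
#'   returns an [eyets].
#' @export
write_eyets_csv <- function(x, path) {
  stopifnot(inherits(x, "eyets"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.10g", x$rate),
               sprintf("# units: %s", x$units),
               sprintf("# condition: %s", x$condition),
               "index,value"), con)
  utils::write.table(
    data.frame(index = seq_along(x$values), value = x$values),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_eyets_csv
#' @export
read_eyets_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  eyets(df$value,
        rate = as.numeric(get_field("rate_hz", "1000")),
        units = get_field("units", "deg"),
        condition = get_field("condition", "raw"))
}
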
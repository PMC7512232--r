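#' Pipeline run configuration
#'
#' Bundle of every tunable the end-to-end analysis uses. Defaults follow the
#' standard analysis protocol: 50 Hz ideal low-pass cutoff, series lengths
#' 1000/1500/2999 (leading prefixes of the velocity series), the three
#' fixation windows `<1...700>`, `<700...1500>`, `<1500...2999>`, 100
#' log-spaced radii, Theiler window 100, embedding dimensions 3..15, 5 FFT
#' surrogates, alpha 0.05, and the per-condition scaling regions
#' (BNR `[0.00055, 0.0018]`, ANR `[0.001, 0.003]`, with automatic fallback
#' when a region misses the computed correlation-sum support).
#'
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param lengths analysed prefix lengths (samples).
#' @param windows list of [window_spec] for the entropy analysis.
#' @param n_radii radius grid size.
#' @param theiler_w Theiler window (samples).
#' @param m_range embedding dimensions for the D2 analysis.
#' @param n_surrogates FFT surrogates per tested series (0 disables the
#'   surrogate stage).
#' @param surrogate_fixations_per_session how many fixations per session get
#'   the surrogate test (the stage is expensive; a representative subsample
#'   suffices to screen a cohort).
#' @param alpha significance level.
#' @param seed master RNG seed; per-session and per-surrogate seeds derive
#'   from it.
#' @param n_sessions sessions simulated when the input is `"simulate"`
#'   (the emulated protocol records 48).
#' @param max_lag largest lag scanned by the AMI profile.
#' @param scaling_regions named list `list(BNR = c(lo, hi), ANR = c(lo, hi))`
#'   or `NULL` for fully automatic region detection.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(cutoff_hz = 50,
                       lengths = c(1000, 1500, 2999),
                       windows = default_windows(),
                       n_radii = 100,
                       theiler_w = 100,
                       m_range = 3:15,
                       n_surrogates = 5,
                       surrogate_fixations_per_session = 3,
                       alpha = 0.05,
                       seed = 1,
                       n_sessions = 48,
                       max_lag = 20,
                       scaling_regions = list(BNR = c(0.00055, 0.0018),
                                              ANR = c(0.001, 0.003))) {
  cfg <- list(cutoff_hz = cutoff_hz, lengths = as.integer(lengths),
              windows = windows, n_radii = as.integer(n_radii),
              theiler_w = as.integer(theiler_w),
              m_range = as.integer(m_range),
              n_surrogates = as.integer(n_surrogates),
              surrogate_fixations_per_session =
                as.integer(surrogate_fixations_per_session),
              alpha = alpha, seed = as.integer(seed),
              n_sessions = as.integer(n_sessions),
              max_lag = as.integer(max_lag),
              scaling_regions = scaling_regions)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$cutoff_hz > 0, "cutoff_hz must be positive")
  chk(all(cfg$lengths >= 100), "lengths must be >= 100 samples")
  chk(all(vapply(cfg$windows, inherits, logical(1), "window_spec")),
      "windows must be window_spec objects")
  chk(cfg$n_radii >= 2, "n_radii must be >= 2")
  chk(cfg$theiler_w >= 0, "theiler_w must be >= 0")
  chk(length(cfg$m_range) >= 2 && all(diff(cfg$m_range) == 1),
      "m_range must be >= 2 consecutive integers")
  chk(cfg$n_surrogates >= 0, "n_surrogates must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$n_sessions >= 1, "n_sessions must be >= 1")
  if (length(problems) > 0) {
    stop("invalid run_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> cutoff %g Hz, lengths {%s}, m %d..%d, w %d, %d radii, %d surrogates, alpha %g, seed %d\n",
    x$cutoff_hz, paste(x$lengths, collapse = ","), min(x$m_range),
    max(x$m_range), x$theiler_w, x$n_radii, x$n_surrogates, x$alpha,
    x$seed))
  invisible(x)
}

#' Save / load a run configuration as JSON
#'
#' `load_run_config(save_run_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg a [run_config].
#' @param path JSON file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   returns a [run_config].
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$windows <- lapply(cfg$windows, function(w) c(w$start, w$end))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  wins <- raw$windows
  if (is.matrix(wins)) {
    wins <- lapply(seq_len(nrow(wins)), function(i) wins[i, ])
  }
  raw$windows <- lapply(wins, function(w) window_spec(w[1], w[2]))
  if (!is.null(raw$scaling_regions)) {
    raw$scaling_regions <- lapply(raw$scaling_regions, as.numeric)
  }
  do.call(run_config, raw)
}

# internal: analyse one velocity series at one length -> D2 row fields
analyse_d2_one <- function(v, L, cond, cfg, tau) {
  x <- series_values(v)[seq_len(L)]
  cs <- correlation_sum(x, radii = radius_grid(stats::sd(x),
                                               n_radii = cfg$n_radii),
                        theiler_w = cfg$theiler_w, tau = tau,
                        ms = cfg$m_range)
  region <- if (is.null(cfg$scaling_regions)) NULL
            else cfg$scaling_regions[[cond]]
  est <- estimate_d2(cs, region = region, min_m = min(cfg$m_range))
  list(D2 = est$value, r2 = est$fit_quality,
       plateau = est$plateau_found,
       region_low = est$scaling_region[1],
       region_high = est$scaling_region[2],
       region_fallback = est$region_fallback)
}

# internal: analyse one velocity series window -> K2 row fields
analyse_k2_one <- function(v, win, cfg, tau) {
  x <- series_values(v)[win$start:win$end]
  ms <- c(cfg$m_range, max(cfg$m_range) + 1L)
  cs <- correlation_sum(x, radii = radius_grid(stats::sd(x),
                                               n_radii = cfg$n_radii),
                        theiler_w = min(cfg$theiler_w,
                                        (length(x) - 20) %/% 4),
                        tau = tau, ms = ms)
  est <- k2_entropy(cs)
  list(K2 = est$value, plateau = est$plateau_found)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> differentiate -> filter -> embed ->
#' estimate (D2 per length, K2 per window) -> surrogate-test -> report. Per
#' fixation and condition (BNR/ANR) the velocity series is analysed at each
#' configured prefix length for D2 and in each window for K2. Failures on
#' individual series are logged and skipped; the cohort always completes.
#' The run is deterministic given `(config, input)`.
#'
#' @param config a [run_config].
#' @param input `"simulate"` (generate `config$n_sessions` synthetic
#'   sessions) or a directory of session CSVs written by
#'   [write_session_csv()].
#' @param out_dir optional directory; when given, the manifest and report
#'   tables are written there as CSV/JSON.
#' @param progress print per-session progress.
#' @return Object of class `pipeline_result`: `d2` and `k2` manifests
#'   (data frames), `surrogates` (data frame of per-series test decisions),
#'   `tables` (a [build_summary_tables()] bundle), `skipped` (data frame of
#'   skip reasons), `config`.
#' @export
run_pipeline <- function(config = run_config(), input = "simulate",
                         out_dir = NULL, progress = FALSE) {
  validate_run_config(config)
  sessions <- if (identical(input, "simulate")) {
    lapply(seq_len(config$n_sessions), function(i) {
      generate_session(stimulus_schedule(), oculomotor_params(),
                       seed = config$seed * 1000L + i,
                       subject_id = sprintf("S%02d", i),
                       session_id = as.character(i))
    })
  } else {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    files <- files[!grepl("\\.json$", files)]
    if (length(files) == 0) stop("no session CSVs found in ", input,
                                 call. = FALSE)
    lapply(files, read_session_csv)
  }

  d2_rows <- list(); k2_rows <- list(); surr_rows <- list()
  skipped <- list()
  log_skip <- function(sess, fix, cond, stage, msg) {
    skipped[[length(skipped) + 1]] <<- data.frame(
      session_id = sess, fixation_id = fix, condition = cond,
      stage = stage, reason = conditionMessage(msg))
  }

  for (rec in sessions) {
    sid <- rec$session_id
    if (progress) message("session ", sid)
    fixations <- tryCatch(split_fixations(rec), error = function(e) e)
    if (inherits(fixations, "error")) {
      log_skip(sid, NA, "raw", "split_fixations", fixations)
      next
    }
    for (f in seq_along(fixations)) {
      vel_bnr <- tryCatch(differentiate(fixations[[f]]),
                          error = function(e) e)
      if (inherits(vel_bnr, "error")) {
        log_skip(sid, f, "BNR", "differentiate", vel_bnr)
        next
      }
      vel_anr <- lowpass_ideal(vel_bnr, cutoff_hz = config$cutoff_hz)
      for (cond in c("BNR", "ANR")) {
        v <- if (cond == "BNR") vel_bnr else vel_anr
        tau <- tryCatch(
          as.integer(suppressWarnings(select_lag(
            ami_profile(v, max_lag = config$max_lag)))),
          error = function(e) e)
        if (inherits(tau, "error")) {
          log_skip(sid, f, cond, "select_lag", tau)
          next
        }
        for (L in config$lengths) {
          res <- tryCatch(analyse_d2_one(v, L, cond, config, tau),
                          error = function(e) e)
          if (inherits(res, "error")) {
            log_skip(sid, f, cond, sprintf("D2@%d", L), res)
            next
          }
          d2_rows[[length(d2_rows) + 1]] <- data.frame(
            session_id = sid, fixation_id = f, condition = cond,
            length = L, tau = tau, theiler_w = config$theiler_w,
            D2 = res$D2, r2 = res$r2, plateau = res$plateau,
            region_low = res$region_low, region_high = res$region_high,
            region_fallback = res$region_fallback)
        }
        for (win in config$windows) {
          wlab <- sprintf("<%d...%d>", win$start, win$end)
          res <- tryCatch(analyse_k2_one(v, win, config, tau),
                          error = function(e) e)
          if (inherits(res, "error")) {
            log_skip(sid, f, cond, sprintf("K2@%s", wlab), res)
            next
          }
          k2_rows[[length(k2_rows) + 1]] <- data.frame(
            session_id = sid, fixation_id = f, condition = cond,
            window = wlab, tau = tau, K2 = res$K2, plateau = res$plateau)
        }
        if (config$n_surrogates > 0 &&
              f <= config$surrogate_fixations_per_session) {
          st <- tryCatch(
            surrogate_d2_test(
              v, tau = tau, ms = config$m_range,
              theiler_w = config$theiler_w, n_radii = config$n_radii,
              region = if (is.null(config$scaling_regions)) NULL
                       else config$scaling_regions[[cond]],
              n_surrogates = config$n_surrogates,
              seed = config$seed * 1000L + f),
            error = function(e) e)
          if (inherits(st, "error")) {
            log_skip(sid, f, cond, "surrogate_test", st)
          } else {
            surr_rows[[length(surr_rows) + 1]] <- data.frame(
              session_id = sid, fixation_id = f, condition = cond,
              null_rejected = st$rejected,
              original_plateau = st$original$plateau_found,
              surrogates_no_plateau = sum(st$surrogate_no_plateau),
              k_required = st$k_required)
          }
        }
      }
    }
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  d2 <- bind(d2_rows); k2 <- bind(k2_rows)
  if (is.null(d2) || is.null(k2)) {
    stop("no series could be analysed; see skip log", call. = FALSE)
  }
  tables <- build_summary_tables(d2, k2, alpha = config$alpha)
  result <- structure(list(d2 = d2, k2 = k2,
                           surrogates = bind(surr_rows),
                           tables = tables,
                           skipped = bind(skipped),
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d D2 rows, %d K2 rows, %d surrogate tests, %d skips\n",
    nrow(x$d2), nrow(x$k2),
    if (is.null(x$surrogates)) 0L else nrow(x$surrogates),
    if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  print(x$tables)
  invisible(x)
}

#' Write a pipeline result to disk
#'
#' Emits `d2_manifest.csv`, `k2_manifest.csv`, `surrogate_tests.csv`,
#' `skipped.csv`, the four report tables, and `manifest.json` (config plus
#' row counts) into `dir`.
#'
#' @param result a [pipeline_result][run_pipeline].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$d2, file.path(dir, "d2_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(result$k2, file.path(dir, "k2_manifest.csv"),
                   row.names = FALSE)
  if (!is.null(result$surrogates)) {
    utils::write.csv(result$surrogates,
                     file.path(dir, "surrogate_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$skipped)) {
    utils::write.csv(result$skipped, file.path(dir, "skipped.csv"),
                     row.names = FALSE)
  }
  write_report_bundle(result$tables, dir)
  cfg <- unclass(result$config)
  cfg$windows <- lapply(result$config$windows,
                        function(w) c(w$start, w$end))
  jsonlite::write_json(
    list(config = cfg,
         n_d2_rows = nrow(result$d2),
         n_k2_rows = nrow(result$k2),
         n_skipped = if (is.null(result$skipped)) 0L
                     else nrow(result$skipped)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: generates `n_sessions` synthetic jumping-point
#' sessions and writes one CSV (+ JSON sidecar) per session.
#'
#' @param n_sessions number of sessions.
#' @param seed master seed; session `i` uses `seed * 1000 + i`.
#' @param dir output directory.
#' @param params an [oculomotor_params].
#' @return Character vector of the CSV paths, invisibly.
#' @export
simulate_cohort <- function(n_sessions = 48, seed = 1, dir = ".",
                            params = oculomotor_params()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(n_sessions), function(i) {
    rec <- generate_session(stimulus_schedule(), params,
                            seed = seed * 1000L + i,
                            subject_id = sprintf("S%02d", i),
                            session_id = as.character(i))
    write_session_csv(rec, file.path(dir, sprintf("session_%02d.csv", i)))
  }, character(1))
  invisible(paths)
}
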
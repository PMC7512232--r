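#' Shapiro-Wilk normality gate
#'
#' Thin wrapper around [stats::shapiro.test()], used to justify the
#' non-parametric (Wilcoxon) comparisons: when most per-session estimate
#' distributions fail normality, ranks are compared instead of means. The
#' result is reported, not branched on.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return The test's p-value; `NA` with a warning for degenerate
#'   (constant) input.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop(sprintf("Shapiro-Wilk supports 3 <= n <= 5000, got n = %d", n),
         call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    warning("degenerate (constant) input: normality undefined")
    return(NA_real_)
  }
  stats::shapiro.test(values)$p.value
}

# Exact null distribution of the signed-rank statistic W+ for given absolute
# ranks (average ranks allowed: everything is doubled to stay integer).
# Returns P(W2 = w) for w = 0..sum(ranks2) where W2 = 2*W+.
signed_rank_null <- function(ranks2) {
  f <- numeric(sum(ranks2) + 1)
  f[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), f[seq_len(length(f) - r)])
    f <- (f + shifted) / 2
  }
  f
}

#' Wilcoxon signed-rank test (exact for small samples, ties supported)
#'
#' Paired two-sided Wilcoxon signed-rank test. Zero differences are dropped;
#' tied absolute differences get average ranks. For `n <= 25` retained
#' differences the null distribution of the statistic is computed exactly by
#' convolution over sign assignments (exact even with ties); above that, the
#' normal approximation with continuity and tie correction is used. If all
#' differences are zero the comparison is degenerate and `p = 1`.
#'
#' @param a,b paired numeric vectors, or `a` alone interpreted as the
#'   differences when `b` is `NULL`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (in terms of the location of `a - b`).
#' @param exact_max largest n for which the exact distribution is used.
#' @return Object of class `wilcoxon_result`: `p.value`, `statistic` (W+,
#'   sum of positive-difference ranks), `n` (after zero removal), `exact`,
#'   `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p.value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(b)) as.numeric(a) else {
    if (length(a) != length(b)) stop("'a' and 'b' must be paired",
                                     call. = FALSE)
    as.numeric(a) - as.numeric(b)
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(p.value = 1, statistic = NA_real_, n = 0L,
                          exact = NA, degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    f <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):length(f)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5  # continuity correction
    z_ge <- (W - mu - cc) / sqrt(sigma2)
    z_le <- (W - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                           stats::pnorm(z_ge,
                                                        lower.tail = FALSE))),
                greater = stats::pnorm(z_ge, lower.tail = FALSE),
                less = stats::pnorm(z_le))
    exact <- FALSE
  }
  structure(list(p.value = p, statistic = W, n = as.integer(n),
                 exact = exact, degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<wilcoxon_result> degenerate (all differences zero), p = 1\n")
  } else {
    cat(sprintf("<wilcoxon_result> W+ = %g, n = %d, p = %.4g (%s)\n",
                x$statistic, x$n, x$p.value,
                if (x$exact) "exact" else "normal approx."))
  }
  invisible(x)
}

#' Per-session significance of a paired comparison
#'
#' For every session, pairs the estimates of its fixations across the two
#' levels of a grouping column (e.g. condition BNR vs ANR at a fixed length,
#' or one analysis window vs another), runs a paired two-sided Wilcoxon
#' signed-rank test per session, and summarises the cohort as the percentage
#' of sessions with `p < alpha` plus a histogram of the session p-values
#' (bin width 0.05).
#'
#' @param table data frame with at least columns `session_id`,
#'   `fixation_id`, the grouping column, and the value column.
#' @param value_col name of the numeric column compared (e.g. `"D2"`,
#'   `"K2"`).
#' @param group_col name of the column holding the two compared levels.
#' @param level_a,level_b the two levels paired within each session.
#' @param alpha significance level (default 0.05).
#' @param min_pairs minimum complete pairs per session (default 5; sessions
#'   with fewer are excluded and listed).
#' @return Object of class `comparison_result`: `label`, `per_session`
#'   (data frame session_id, n_pairs, p, significant, shapiro_p),
#'   `percent_significant`, `p_histogram` (counts per 0.05 bin),
#'   `excluded_sessions`, `alpha`.
#' @export
session_significance <- function(table, value_col, group_col,
                                 level_a, level_b, alpha = 0.05,
                                 min_pairs = 5) {
  stopifnot(all(c("session_id", "fixation_id", group_col, value_col) %in%
                  names(table)))
  sessions <- unique(table$session_id)
  rows <- list()
  excluded <- character(0)
  for (s in sessions) {
    sub <- table[table$session_id == s, ]
    a <- sub[sub[[group_col]] == level_a, c("fixation_id", value_col)]
    b <- sub[sub[[group_col]] == level_b, c("fixation_id", value_col)]
    mrg <- merge(a, b, by = "fixation_id", suffixes = c("_a", "_b"))
    mrg <- mrg[stats::complete.cases(mrg), ]
    if (nrow(mrg) < min_pairs) {
      excluded <- c(excluded, as.character(s))
      next
    }
    va <- mrg[[paste0(value_col, "_a")]]
    vb <- mrg[[paste0(value_col, "_b")]]
    wt <- wilcoxon_signed_rank(va, vb)
    sh <- tryCatch(suppressWarnings(shapiro_wilk(va - vb)),
                   error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      session_id = s, n_pairs = nrow(mrg), p = wt$p.value,
      significant = wt$p.value < alpha, shapiro_p = sh)
  }
  if (length(rows) == 0) {
    stop("no session had enough complete pairs for the comparison",
         call. = FALSE)
  }
  per_session <- do.call(rbind, rows)
  breaks <- seq(0, 1, by = 0.05)
  hist_counts <- as.integer(table(cut(per_session$p, breaks,
                                      include.lowest = TRUE)))
  structure(list(label = sprintf("%s: %s vs %s", value_col,
                                 level_a, level_b),
                 per_session = per_session,
                 percent_significant = 100 * mean(per_session$significant),
                 p_histogram = data.frame(bin_low = breaks[-length(breaks)],
                                          bin_high = breaks[-1],
                                          count = hist_counts),
                 excluded_sessions = excluded,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %.1f%% of %d sessions significant (alpha = %g)\n",
              x$label, x$percent_significant, nrow(x$per_session), x$alpha))
  invisible(x)
}

# internal: "mean (stdev)" cell over a numeric vector, NA-aware
mean_sd_cell <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_character_)
  sprintf("%.4f(%.4f)", mean(v), stats::sd(v))
}

#' Cohort summary tables
#'
#' Builds the report tables of a full cohort analysis:
#' \describe{
#'   \item{d2_means}{mean (stdev) of D2 per condition (BNR/ANR) x series
#'     length, with the BNR-vs-ANR percent-significant row appended.}
#'   \item{d2_length_significance}{percent of sessions with significant D2
#'     differences between each pair of lengths, per condition.}
#'   \item{k2_means}{mean (stdev) of K2 per condition x analysis window,
#'     with the BNR-vs-ANR percent-significant row.}
#'   \item{k2_window_significance}{percent of sessions with significant K2
#'     differences between each pair of windows, per condition.}
#' }
#' Cells without data are `NA` and counted in `missing_cells`. D2 values at
#' a given length that exceed the data-length bound `2 log10 n` raise the
#' `bound_violations` flag count.
#'
#' @param d2_table data frame with columns `session_id`, `fixation_id`,
#'   `condition`, `length`, `D2`.
#' @param k2_table data frame with columns `session_id`, `fixation_id`,
#'   `condition`, `window`, `K2`.
#' @param alpha significance level for the embedded comparisons.
#' @return Object of class `report_bundle`: the four tables (data frames),
#'   `comparisons` (the underlying [session_significance()] results),
#'   `missing_cells`, `bound_violations`.
#' @export
build_summary_tables <- function(d2_table, k2_table, alpha = 0.05) {
  lengths_used <- sort(unique(d2_table$length))
  windows_used <- unique(k2_table$window)
  conditions <- c("BNR", "ANR")
  comparisons <- list()
  missing_cells <- 0L

  # condition x length means + BNR vs ANR significance per length
  d2_means <- data.frame(ts_type = c("BNR mean (stdev)", "ANR mean (stdev)",
                                     sprintf("BNR vs ANR (p < %g)", alpha)))
  for (L in lengths_used) {
    col <- character(3)
    for (ci in 1:2) {
      v <- d2_table$D2[d2_table$condition == conditions[ci] &
                         d2_table$length == L]
      cell <- mean_sd_cell(v)
      if (is.na(cell)) missing_cells <- missing_cells + 1L
      col[ci] <- cell
    }
    cmp <- tryCatch(
      session_significance(d2_table[d2_table$length == L, ], "D2",
                           "condition", "BNR", "ANR", alpha = alpha),
      error = function(e) NULL)
    col[3] <- if (is.null(cmp)) NA_character_
              else sprintf("%.0f%%", cmp$percent_significant)
    if (!is.null(cmp)) {
      comparisons[[sprintf("D2_BNRvsANR_len%d", L)]] <- cmp
    }
    d2_means[[as.character(L)]] <- col
  }

  # length-vs-length significance per condition
  len_pairs <- utils::combn(lengths_used, 2, simplify = FALSE)
  d2_len_sig <- data.frame(ts_type = sprintf("%s (p < %g)", conditions,
                                             alpha))
  for (pr in len_pairs) {
    col <- character(2)
    for (ci in 1:2) {
      sub <- d2_table[d2_table$condition == conditions[ci], ]
      sub$length_lvl <- as.character(sub$length)
      cmp <- tryCatch(
        session_significance(sub, "D2", "length_lvl",
                             as.character(pr[1]), as.character(pr[2]),
                             alpha = alpha),
        error = function(e) NULL)
      col[ci] <- if (is.null(cmp)) NA_character_
                 else sprintf("%.0f%%", cmp$percent_significant)
      if (!is.null(cmp)) {
        comparisons[[sprintf("D2_%s_len%dvs%d", conditions[ci],
                             pr[1], pr[2])]] <- cmp
      }
    }
    d2_len_sig[[sprintf("%d vs %d", pr[1], pr[2])]] <- col
  }

  # condition x window means + BNR vs ANR significance per window
  k2_means <- data.frame(ts_type = c("BNR mean (stdev)", "ANR mean (stdev)",
                                     sprintf("BNR vs ANR (p < %g)", alpha)))
  for (wlab in windows_used) {
    col <- character(3)
    for (ci in 1:2) {
      v <- k2_table$K2[k2_table$condition == conditions[ci] &
                         k2_table$window == wlab]
      cell <- mean_sd_cell(v)
      if (is.na(cell)) missing_cells <- missing_cells + 1L
      col[ci] <- cell
    }
    cmp <- tryCatch(
      session_significance(k2_table[k2_table$window == wlab, ], "K2",
                           "condition", "BNR", "ANR", alpha = alpha),
      error = function(e) NULL)
    col[3] <- if (is.null(cmp)) NA_character_
              else sprintf("%.0f%%", cmp$percent_significant)
    if (!is.null(cmp)) {
      comparisons[[sprintf("K2_BNRvsANR_%s", wlab)]] <- cmp
    }
    k2_means[[wlab]] <- col
  }

  # window-vs-window significance per condition
  win_pairs <- utils::combn(windows_used, 2, simplify = FALSE)
  k2_win_sig <- data.frame(ts_type = sprintf("%s (p < %g)", conditions,
                                             alpha))
  for (pr in win_pairs) {
    col <- character(2)
    for (ci in 1:2) {
      sub <- k2_table[k2_table$condition == conditions[ci], ]
      cmp <- tryCatch(
        session_significance(sub, "K2", "window", pr[1], pr[2],
                             alpha = alpha),
        error = function(e) NULL)
      col[ci] <- if (is.null(cmp)) NA_character_
                 else sprintf("%.0f%%", cmp$percent_significant)
      if (!is.null(cmp)) {
        comparisons[[sprintf("K2_%s_%svs%s", conditions[ci],
                             pr[1], pr[2])]] <- cmp
      }
    }
    k2_win_sig[[sprintf("%s vs %s", pr[1], pr[2])]] <- col
  }

  bound_viol <- sum(vapply(lengths_used, function(L) {
    sum(d2_table$D2[d2_table$length == L] > sample_size_bound(L),
        na.rm = TRUE)
  }, numeric(1)))

  structure(list(d2_means = d2_means,
                 d2_length_significance = d2_len_sig,
                 k2_means = k2_means,
                 k2_window_significance = k2_win_sig,
                 comparisons = comparisons,
                 missing_cells = missing_cells,
                 bound_violations = as.integer(bound_viol)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== D2: mean (stdev) per condition x length ==\n")
  print(x$d2_means, row.names = FALSE)
  cat("\n== D2: significance across lengths ==\n")
  print(x$d2_length_significance, row.names = FALSE)
  cat("\n== K2: mean (stdev) per condition x window ==\n")
  print(x$k2_means, row.names = FALSE)
  cat("\n== K2: significance across windows ==\n")
  print(x$k2_window_significance, row.names = FALSE)
  if (x$bound_violations > 0) {
    cat(sprintf("\nWARNING: %d D2 values exceed the 2 log10 N bound\n",
                x$bound_violations))
  }
  invisible(x)
}

#' Write a report bundle as CSV files
#'
#' @param bundle a [build_summary_tables()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("d2_means", "d2_length_significance", "k2_means",
            "k2_window_significance")
  for (tb in tabs) {
    utils::write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  pvals <- lapply(bundle$comparisons, function(cmp) {
    list(label = cmp$label,
         percent_significant = cmp$percent_significant,
         p_values = cmp$per_session$p)
  })
  jsonlite::write_json(pvals, file.path(dir, "p_values.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
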
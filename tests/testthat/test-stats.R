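test_that("Shapiro-Wilk gate reports normality sensibly", {
  withr::with_seed(1, z <- rnorm(50))
  expect_gt(shapiro_wilk(z), 0.05)

  withr::with_seed(2, {
    rejections <- vapply(1:100, function(i) {
      shapiro_wilk(runif(50)) < 0.05
    }, logical(1))
  })
  # uniform data fails normality in most runs (power ~0.8 at n = 50)
  expect_gte(mean(rejections), 0.7)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_warning(p <- shapiro_wilk(rep(1, 20)), "degenerate")
  expect_true(is.na(p))
})

test_that("signed-rank test matches its worked example and handles degeneracy", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(res$p.value, 0.0625)
  expect_true(res$exact)
  expect_equal(res$statistic, 15)

  same <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(same$degenerate)
  expect_equal(same$p.value, 1)

  a <- c(1.2, -0.5, 2.2, 0.3, -1.9, 0.8, 1.1)
  expect_equal(wilcoxon_signed_rank(a)$p.value,
               wilcoxon_signed_rank(-a)$p.value, tolerance = 1e-12)
})

test_that("exact p-values equal the full sign-assignment enumeration (ties included)", {
  withr::with_seed(7, {
    for (case in 1:25) {
      n <- sample(4:12, 1)
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE) +
        sample(c(0, 0.5), n, replace = TRUE)  # duplicates -> tied ranks
      expect_equal(wilcoxon_signed_rank(d)$p.value, oracle_wilcoxon_exact(d),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact and approximate branches agree with the reference implementation", {
  withr::with_seed(5, {
    # tie-free exact case vs stats::wilcox.test(exact = TRUE)
    for (case in 1:10) {
      d <- rnorm(12)
      expect_equal(wilcoxon_signed_rank(d)$p.value,
                   suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value),
                   tolerance = 1e-12)
    }
    # large-n normal approximation with continuity correction
    for (case in 1:10) {
      d <- rnorm(40, mean = 0.2)
      expect_equal(wilcoxon_signed_rank(d)$p.value,
                   suppressWarnings(
                     stats::wilcox.test(d, exact = FALSE,
                                        correct = TRUE)$p.value),
                   tolerance = 1e-10)
    }
  })
})

make_cohort_table <- function(n_sessions, n_fix = 29, shift = 0, sd = 1,
                              seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_sessions), function(s) {
      base <- rnorm(n_fix, sd = sd)
      data.frame(session_id = rep(sprintf("S%03d", s), 2 * n_fix),
                 fixation_id = rep(seq_len(n_fix), 2),
                 condition = rep(c("BNR", "ANR"), each = n_fix),
                 D2 = c(base + rnorm(n_fix, sd = sd),
                        base + rnorm(n_fix, sd = sd) + shift))
    }))
  })
}

test_that("session significance is calibrated under the null and powered under a shift", {
  null_tab <- make_cohort_table(500, seed = 31)
  res <- session_significance(null_tab, "D2", "condition", "BNR", "ANR")
  # binomial 99% band around alpha = 5% with 500 sessions: ~[2.5%, 7.5%]
  band <- 100 * (0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / 500))
  expect_gte(res$percent_significant, band[1])
  expect_lte(res$percent_significant, band[2])
  expect_equal(sum(res$p_histogram$count), 500)

  shifted <- make_cohort_table(40, shift = 3, seed = 32)
  res_s <- session_significance(shifted, "D2", "condition", "BNR", "ANR")
  expect_gt(res_s$percent_significant, 95)

  single <- make_cohort_table(1, seed = 33)
  res_1 <- session_significance(single, "D2", "condition", "BNR", "ANR")
  expect_true(res_1$percent_significant %in% c(0, 100))
})

test_that("session significance is invariant to row order and excludes unpairable sessions", {
  tab <- make_cohort_table(20, seed = 41)
  res_a <- session_significance(tab, "D2", "condition", "BNR", "ANR")
  withr::with_seed(42, tab_sh <- tab[sample(nrow(tab)), ])
  res_b <- session_significance(tab_sh, "D2", "condition", "BNR", "ANR")
  expect_equal(res_a$percent_significant, res_b$percent_significant)
  expect_equal(sort(res_a$per_session$p), sort(res_b$per_session$p))

  crippled <- tab[!(tab$session_id == "S001" & tab$condition == "ANR" &
                      tab$fixation_id > 2), ]
  res_c <- session_significance(crippled, "D2", "condition", "BNR", "ANR")
  expect_identical(res_c$excluded_sessions, "S001")
  expect_equal(nrow(res_c$per_session), 19)
})

test_that("summary tables mirror the condition x length / window report layout", {
  d2 <- expand.grid(session_id = sprintf("S%02d", 1:2), fixation_id = 1:29,
                    condition = c("BNR", "ANR"),
                    length = c(1000L, 1500L, 2999L),
                    stringsAsFactors = FALSE)
  withr::with_seed(51, d2$D2 <- runif(nrow(d2), 0.2, 0.6))
  k2 <- expand.grid(session_id = sprintf("S%02d", 1:2), fixation_id = 1:29,
                    condition = c("BNR", "ANR"),
                    window = c("<1...700>", "<700...1500>", "<1500...2999>"),
                    stringsAsFactors = FALSE)
  withr::with_seed(52, k2$K2 <- runif(nrow(k2), 0.01, 0.2))

  bundle <- build_summary_tables(d2, k2)
  expect_named(bundle$d2_means, c("ts_type", "1000", "1500", "2999"))
  expect_equal(nrow(bundle$d2_means), 3)  # BNR, ANR, significance row
  expect_named(bundle$d2_length_significance,
               c("ts_type", "1000 vs 1500", "1000 vs 2999", "1500 vs 2999"))
  expect_named(bundle$k2_means,
               c("ts_type", "<1...700>", "<700...1500>", "<1500...2999>"))
  expect_equal(nrow(bundle$k2_window_significance), 2)
  expect_equal(bundle$bound_violations, 0L)
  expect_equal(bundle$missing_cells, 0L)

  # all-equal inputs give zero stdev cells
  d2$D2 <- 0.5
  k2$K2 <- 0.1
  b2 <- build_summary_tables(d2, k2)
  expect_true(all(grepl("\\(0\\.0000\\)", b2$d2_means[1:2, -1])))

  # a D2 above the 2 log10 N bound at length 1000 raises the flag
  d2$D2[d2$length == 1000][1] <- 6.5
  b3 <- build_summary_tables(d2, k2)
  expect_gte(b3$bound_violations, 1L)

  dir <- withr::local_tempdir()
  write_report_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir,
    c("d2_means.csv", "d2_length_significance.csv", "k2_means.csv",
      "k2_window_significance.csv", "p_values.json")))))
})
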
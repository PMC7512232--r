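test_that("AMI matches hand-computable cases and the histogram oracle", {
  # alternating 0/1 with balanced pairs: lag 1 is perfectly informative
  alt <- rep_len(c(0, 1), 101)
  prof <- ami_profile(alt, max_lag = 2, n_bins = 2)
  expect_equal(prof$ami[prof$lags == 1], 1, tolerance = 1e-12)
  # lag 0 equals the binned marginal entropy (self-information):
  # 51 zeros and 50 ones in 101 samples
  h_marginal <- -(51 / 101) * log2(51 / 101) - (50 / 101) * log2(50 / 101)
  expect_equal(prof$ami[prof$lags == 0], h_marginal, tolerance = 1e-12)

  x <- series_values(generate_reference("henon", 800, seed = 1))
  prof2 <- ami_profile(x, max_lag = 5, n_bins = 12)
  for (lag in 0:5) {
    expect_equal(prof2$ami[prof2$lags == lag], oracle_ami(x, lag, 12),
                 tolerance = 1e-10)
  }

  expect_error(ami_profile(rep(1, 100), max_lag = 5), "constant")
})

test_that("AMI is symmetric in its two coordinates and small for independent data", {
  x <- series_values(generate_reference("ar1", 2000, list(phi = 0.9),
                                        seed = 2))
  fwd <- ami_profile(x, max_lag = 6)
  bwd <- ami_profile(rev(x), max_lag = 6)
  expect_equal(fwd$ami, bwd$ami, tolerance = 1e-12)

  wn <- series_values(generate_reference("white_noise", 5000, seed = 9))
  expect_lt(ami_profile(wn, max_lag = 10, n_bins = 8)$ami[11], 0.02)

  withr::with_seed(3, {
    sh <- sample(x)
  })
  expect_lt(ami_profile(sh, max_lag = 5, n_bins = 10)$ami[6], 0.05)
})

test_that("lag selection uses first local minimum, then the 1/e fallback", {
  mk <- function(ami) structure(list(lags = seq_along(ami) - 1L, ami = ami,
                                     n_bins = 10L), class = "ami_profile")
  expect_equal(as.integer(select_lag(mk(c(2.0, 1.0, 1.5, 1.2)))), 1L)
  expect_identical(attr(select_lag(mk(c(2.0, 1.0, 1.5, 1.2))), "rule"),
                   "local_min")

  mono <- 2 * exp(-(0:10) / 6.3)  # crosses 2/e between lag 6 and 7
  expect_equal(as.integer(select_lag(mk(mono))), 7L)
  expect_identical(attr(select_lag(mk(mono)), "rule"), "one_over_e")

  expect_warning(res <- select_lag(mk(c(3, 2.9, 2.8, 2.7))), "max_lag")
  expect_equal(as.integer(res), 3L)
})

test_that("FNN collapses for deterministic signals and stays high for noise", {
  sine <- series_values(generate_reference("sine", 1500,
                                           list(freq_hz = 10), seed = 1))
  f <- fnn_profile(sine, tau = 25, m_range = 1:5)
  expect_lt(f$fnn_fraction[f$dims == 2], 0.01)
  # non-increasing in m for the noise-free deterministic fixture
  expect_true(all(diff(f$fnn_fraction) <= 1e-12))

  h <- series_values(generate_reference("henon", 2000, seed = 1))
  fh <- fnn_profile(h, tau = 1, m_range = 1:6)
  expect_true(all(diff(fh$fnn_fraction) <= 1e-12))
  expect_true(select_embedding_dim(fh) %in% c(2L, 3L))

  wn <- series_values(generate_reference("white_noise", 1500, seed = 4))
  fw <- fnn_profile(wn, tau = 1, m_range = 1:4)
  expect_gt(fw$fnn_fraction[fw$dims == 1], 0.2)
  expect_gt(fw$fnn_fraction[fw$dims == 2], 0.2)

  # points on a line in delay space: the ratio never exceeds the threshold
  line <- seq(0, 1, length.out = 200)
  fl <- fnn_profile(line, tau = 1, m_range = 1)
  expect_equal(fl$fnn_fraction, 0)
})

test_that("embedding dimension selection applies the tolerance rule", {
  mk <- function(fr) structure(list(dims = seq_along(fr), fnn_fraction = fr,
                                    threshold_R = 10,
                                    n_zero_excluded = rep(0, length(fr))),
                               class = "fnn_profile")
  expect_equal(as.integer(select_embedding_dim(mk(c(0.4, 0.05, 0.004)),
                                               tol = 0.01)), 3L)
  expect_warning(res <- select_embedding_dim(mk(c(0.4, 0.3, 0.2))), "max")
  expect_equal(as.integer(res), 3L)
})

test_that("delay embedding produces the Takens vector matrix", {
  e <- delay_embed(1:5, tau = 2, m = 2)
  expect_equal(unclass(e)[, 1], c(1, 2, 3))
  expect_equal(unclass(e)[, 2], c(3, 4, 5))
  expect_equal(nrow(e), 3)

  x <- rnorm(2999)
  e2 <- delay_embed(x, tau = 9, m = 3)
  expect_equal(nrow(e2), 2999 - 2 * 9)

  e1 <- delay_embed(x, tau = 5, m = 1)
  expect_equal(as.numeric(unclass(e1)), x)

  expect_error(delay_embed(1:10, tau = 5, m = 3), "too short")
})
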
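test_that("the radius grid spans stdev/10 to 10*stdev", {
  g <- radius_grid(1)
  expect_equal(c(g$rmin, g$rmax), c(0.1, 10))
  g2 <- radius_grid(0.02)
  expect_equal(c(g2$rmin, g2$rmax), c(0.002, 0.2))
  g3 <- radius_grid(1, n_radii = 2)
  expect_equal(g3$radii, c(0.1, 10))
  expect_length(radius_grid(rnorm(100), n_radii = 100)$radii, 100)
  expect_error(radius_grid(rep(2, 50)), "constant")
})

test_that("correlation sums match exhaustive pair enumeration on worked examples", {
  e <- delay_embed(c(0, 1, 2, 3), tau = 1, m = 1)
  cs <- correlation_sum(e, radii = c(1.5), theiler_w = 0)
  expect_equal(as.numeric(cs$C), 0.5)  # 3 of 6 pairs within r

  cs_w <- correlation_sum(e, radii = c(1.5), theiler_w = 1)
  expect_equal(as.numeric(cs_w$C), 0)  # admissible pairs all farther

  x <- rnorm(50)
  e2 <- delay_embed(x, tau = 2, m = 3)
  diam <- max(stats::dist(unclass(e2)))
  cs_d <- correlation_sum(e2, radii = c(diam * 1.01), theiler_w = 0)
  expect_equal(as.numeric(cs_d$C), 1)

  expect_error(correlation_sum(delay_embed(1:8, 1, 1), radii = 1,
                               theiler_w = 7),
               "insufficient admissible pairs")
})

test_that("the fast kernel equals the brute-force oracle on random instances", {
  withr::with_seed(42, {
    for (case in 1:40) {
      N <- sample(30:150, 1)
      tau <- sample(1:3, 1)
      m_max <- sample(2:4, 1)
      w <- sample(0:5, 1)
      x <- rnorm(N)
      radii <- sort(abs(rnorm(12, sd = 2)))
      ms <- 1:m_max
      cs <- correlation_sum(x, radii = radii, theiler_w = w, tau = tau,
                            ms = ms)
      for (m in ms) {
        expect_identical(unname(cs$C[paste0("m", m), ]),
                         oracle_corr_sum(x, tau, m, w, radii))
      }
    }
  })
})

test_that("correlation sums are monotone in radius and dimension", {
  h <- generate_reference("henon", 1500, seed = 6)
  cs <- correlation_sum(h, radii = radius_grid(h), theiler_w = 10,
                        tau = 1, ms = 2:5)
  for (mi in seq_len(nrow(cs$C))) {
    expect_true(all(diff(cs$C[mi, ]) >= 0))
  }
  # same vector count: C at m+1 on x never exceeds C at m on the shortened x
  x <- series_values(h)
  tau <- 1
  r <- radius_grid(h)$radii
  c_hi <- correlation_sum(x, radii = r, theiler_w = 10, tau = tau, ms = 3)
  c_lo <- correlation_sum(x[1:(length(x) - tau)], radii = r, theiler_w = 10,
                          tau = tau, ms = 2)
  expect_true(all(c_hi$C <= c_lo$C + 1e-15))
})

test_that("widening the Theiler window removes temporally correlated close pairs", {
  a <- generate_reference("ar1", 2000, list(phi = 0.98), seed = 4)
  g <- radius_grid(a)
  c0 <- correlation_sum(a, radii = g, theiler_w = 0, tau = 1, ms = 2)
  c50 <- correlation_sum(a, radii = g, theiler_w = 50, tau = 1, ms = 2)
  idx <- which(c0$C[1, ] > 0)[1:40]  # small radii, where the bias lives
  expect_true(all(c50$C[1, idx] <= c0$C[1, idx] + 1e-12))
})

test_that("local scaling exponents recover exact power laws", {
  r <- exp(seq(log(0.01), log(1), length.out = 50))
  C2 <- matrix(r^2, nrow = 1)
  cs <- make_corr_sum(r, 2L, C2)
  sl <- scaling_exponents(cs)
  expect_equal(as.numeric(sl), rep(2, 50), tolerance = 1e-9)

  cs_flat <- make_corr_sum(r, 2L, matrix(0.5, 1, 50))
  expect_equal(as.numeric(scaling_exponents(cs_flat)), rep(0, 50),
               tolerance = 1e-12)

  withzero <- make_corr_sum(r, 2L, matrix(c(rep(0, 10), r[11:50]^1.5), 1))
  sz <- scaling_exponents(withzero)
  expect_true(all(is.na(sz[1, 1:10])))
})

test_that("D2 estimation recovers exact and analytic slopes", {
  r <- exp(seq(log(0.01), log(1), length.out = 60))
  C <- t(sapply(3:6, function(m) 0.9 * r^0.9 / max(r^0.9)))
  cs <- make_corr_sum(r, 3:6, C)
  est <- estimate_d2(cs, region = c(0.02, 0.5))
  expect_equal(est$value, 0.9, tolerance = 1e-9)
  expect_equal(est$fit_quality, 1, tolerance = 1e-9)
  expect_true(est$plateau_found)

  # uniform iid noise at m = 1 fills the line: slope ~ 1, analytic C known
  withr::with_seed(8, u <- runif(4000))
  g <- radius_grid(stats::sd(u))
  cs_u <- correlation_sum(u, radii = g, theiler_w = 0, tau = 1, ms = 1)
  est_u <- estimate_d2(cs_u, region = c(0.05, 0.2), min_m = 1)
  expect_equal(est_u$value, 1, tolerance = 0.1)
  analytic <- 2 * g$radii - g$radii^2  # P(|u - v| <= r) for U[0,1]
  mid <- g$radii < 0.9
  expect_equal(as.numeric(cs_u$C[1, mid]), analytic[mid], tolerance = 0.02)
})

test_that("chaotic and stochastic signals separate through the m-plateau", {
  h <- generate_reference("henon", 5000, seed = 1)
  cs <- correlation_sum(h, radii = radius_grid(h), theiler_w = 10,
                        tau = 1, ms = 2:5)
  est <- estimate_d2(cs, min_m = 2)
  expect_true(est$plateau_found)
  expect_gt(est$value, 1.10)
  expect_lt(est$value, 1.35)

  wn <- generate_reference("white_noise", 3000, seed = 3)
  cw <- correlation_sum(wn, radii = radius_grid(wn), theiler_w = 10,
                        tau = 1, ms = 2:5)
  ew <- estimate_d2(cw, min_m = 2)
  expect_false(ew$plateau_found)
  # slopes track the embedding dimension (space filling)
  expect_true(all(diff(ew$per_m$slope) > 0.5))
  expect_gt(ew$per_m$slope[4], 4)
})

test_that("data-length bounds reproduce the published limits", {
  expect_equal(sample_size_bound(1000), 6)
  expect_equal(sample_size_bound(2999), 6.9539, tolerance = 1e-4)
  expect_lt(sample_size_bound(2999), 7)
  expect_equal(sample_size_bound(1500), 6.3522, tolerance = 1e-4)
  expect_equal(required_n(6), 1000L)
  expect_equal(required_n(0), 1L)
  expect_error(sample_size_bound(1), ">= 2")
  expect_error(required_n(-1), ">= 0")
})

test_that("K2 entropy has its closed-form, periodic and stochastic signatures", {
  # C(m, r) = q^m exactly -> K2 = ln(1/q) for every m
  r <- exp(seq(log(0.01), log(1), length.out = 30))
  q <- 0.7
  C <- t(sapply(2:6, function(m) rep(q^m, 30)))
  est <- k2_entropy(make_corr_sum(r, 2:6, C), region = c(0.01, 1))
  expect_equal(est$value, log(1 / q), tolerance = 1e-12)
  expect_equal(est$per_m$k2, rep(log(1 / q), 4), tolerance = 1e-12)

  s <- generate_reference("sine", 3000, list(freq_hz = 10), seed = 1)
  cs <- correlation_sum(s, radii = radius_grid(s), theiler_w = 100,
                        tau = 25, ms = 2:6)
  expect_lt(k2_entropy(cs)$value, 0.01)

  wn <- generate_reference("white_noise", 3000, seed = 2)
  cw <- correlation_sum(wn, radii = radius_grid(wn), theiler_w = 10,
                        tau = 1, ms = 2:6)
  kw <- k2_entropy(cw)
  expect_gt(kw$value, 0.5)
  # divergence: entropy keeps growing with m at small radii
  expect_gt(kw$per_m$k2[3] - kw$per_m$k2[1], 0)

  empty <- make_corr_sum(r, 2:3, matrix(0, 2, 30))
  expect_error(k2_entropy(empty), "insufficient neighbours")
  expect_error(k2_entropy(make_corr_sum(r, c(2L, 4L), C[c(1, 3), ])),
               "consecutive")
})

test_that("the Rosenstein exponent is positive for chaos and null for a periodic orbit", {
  s <- generate_reference("sine", 2000, list(freq_hz = 10), seed = 1)
  lle_s <- lle_rosenstein(delay_embed(s, 25, 2), dt = 1, theiler_w = 100,
                          n_steps = 20)
  expect_lte(abs(lle_s$value), 0.01)

  h <- generate_reference("henon", 5000, seed = 1)
  lle_h <- lle_rosenstein(delay_embed(h, 1, 2), dt = 1, theiler_w = 10,
                          n_steps = 20)
  expect_gt(lle_h$value, 0.3)
  expect_lt(lle_h$value, 0.55)

  # duplicated trajectories: zero initial separations are excluded, not divided
  y <- series_values(generate_reference("henon", 300, seed = 5))
  dup <- c(y, y)
  lle_d <- lle_rosenstein(delay_embed(dup, 1, 2), dt = 1, theiler_w = 5,
                          n_steps = 5)
  expect_gt(lle_d$n_zero_excluded, 0)
  expect_true(is.finite(lle_d$value))

  expect_error(lle_rosenstein(delay_embed(rnorm(30), 1, 2), theiler_w = 25),
               "insufficient")
})
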
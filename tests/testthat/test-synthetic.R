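test_that("noise-free instantaneous sessions reduce to a step function through the targets", {
  sched <- stimulus_schedule(display_duration_ms = 200)
  rec <- generate_session(sched, noise_free_params(), seed = 1)
  pos <- series_values(rec$position)
  expect_length(pos, 29 * 200)
  # expected abscissae: horizontal screen coordinate -> degrees
  expected <- atan(((sched$locations[, 1] - 0.5) * 370) / 450) * 180 / pi
  segs <- matrix(pos, nrow = 200)
  expect_true(all(apply(segs, 2, function(s) length(unique(s)) == 1)))
  expect_equal(unname(segs[1, ]), unname(expected), tolerance = 1e-12)
})

test_that("session generation is a pure function of (schedule, params, seed)", {
  sched <- stimulus_schedule(display_duration_ms = 500)
  a <- generate_session(sched, oculomotor_params(), seed = 42)
  b <- generate_session(sched, oculomotor_params(), seed = 42)
  c <- generate_session(sched, oculomotor_params(), seed = 43)
  expect_identical(a$position$values, b$position$values)
  expect_false(identical(a$position$values, c$position$values))
})

test_that("measurement noise puts energy above 50 Hz; the noise-free trace has none", {
  sched <- stimulus_schedule(locations = matrix(c(0.3, 0.5), 1, 2),
                             display_duration_ms = 2000)
  energy_above <- function(x, cutoff = 50, rate = 1000) {
    x <- x - mean(x)
    spec <- Mod(stats::fft(x))^2
    n <- length(x)
    freq <- (0:(n - 1)) * rate / n
    freq <- ifelse(freq > rate / 2, freq - rate, freq)
    sum(spec[abs(freq) > cutoff]) / sum(spec)
  }
  noisy <- generate_session(sched, oculomotor_params(), seed = 5)
  hold <- series_values(noisy$position)[500:2000]  # fixation part
  expect_gt(energy_above(hold), 0.01)
  clean <- generate_session(sched, noise_free_params(), seed = 5)
  hold_c <- series_values(clean$position)[500:2000]
  expect_equal(stats::sd(hold_c), 0)
})

test_that("low-pass filtering removes in-band tremor almost entirely", {
  # single fixation, tremor only (band 60-100 Hz, above the 50 Hz cutoff)
  sched <- stimulus_schedule(locations = matrix(c(0.5, 0.5), 1, 2),
                             display_duration_ms = 3000)
  p <- oculomotor_params(latency_ranges_ms = list(c(0, 0)),
                         saccade_duration_ms = 0,
                         fixation_drift_sd = 0,
                         tremor_amplitude_deg = 0.05,
                         measurement_noise_sd = 0)
  rec <- generate_session(sched, p, seed = 9)
  x <- rec$position
  filtered <- lowpass_ideal(x, cutoff_hz = 50)
  var_before <- stats::var(series_values(x))
  var_after <- stats::var(series_values(filtered))
  expect_gt(var_before, 0)
  expect_lt(var_after / var_before, 0.01)
})

test_that("reference signals have their canonical properties", {
  s <- generate_reference("sine", 1000, list(freq_hz = 10), seed = 1)
  t_s <- (0:999) / 1000
  expect_equal(series_values(s), sin(2 * pi * 10 * t_s), tolerance = 1e-12)
  expect_equal(max(abs(series_values(s))), 1)

  h <- generate_reference("henon", 3000, seed = 1)
  expect_true(all(abs(series_values(h)) <= 1.5))
  expect_true(all(is.finite(series_values(h))))

  wn <- generate_reference("white_noise", 1e4, list(sd = 1), seed = 7)
  expect_gt(stats::sd(series_values(wn)), 0.95)
  expect_lt(stats::sd(series_values(wn)), 1.05)

  lz <- generate_reference("lorenz", 500, seed = 2)
  expect_true(all(is.finite(series_values(lz))))
  expect_identical(series_values(lz),
                   series_values(generate_reference("lorenz", 500, seed = 2)))

  a1 <- generate_reference("ar1", 2000, list(phi = 0.8), seed = 3)
  expect_true(all(is.finite(series_values(a1))))
  expect_gt(stats::cor(series_values(a1)[-1], series_values(a1)[-2000]), 0.6)
})

test_that("a diverging map parameterisation raises an overflow error naming the kind", {
  expect_error(generate_reference("henon", 1000, list(a = 2.5), seed = 1),
               "henon")
})

test_that("parameter validation rejects invalid schedules and amplitudes", {
  expect_error(stimulus_schedule(display_duration_ms = 0), "positive")
  expect_error(stimulus_schedule(locations = matrix(c(-0.1, 0.5), 1, 2)),
               "universal scale")
  expect_error(oculomotor_params(measurement_noise_sd = -1), ">= 0")
  expect_error(
    generate_session(stimulus_schedule(display_duration_ms = 100),
                     oculomotor_params(), seed = 1),
    "latency")
  expect_error(generate_reference("sine", 1), ">= 2")
})

test_that("a session splits into stimulus-locked fixations and round-trips through CSV", {
  rec <- generate_session(stimulus_schedule(), oculomotor_params(), seed = 2)
  fixes <- split_fixations(rec)
  expect_length(fixes, 29)
  expect_true(all(vapply(fixes, length, 1L) == 3000))

  dir <- withr::local_tempdir()
  path <- write_session_csv(rec, file.path(dir, "s1.csv"))
  back <- read_session_csv(path)
  expect_equal(back$position$values, rec$position$values, tolerance = 1e-12)
  expect_identical(back$session_id, rec$session_id)
  expect_length(split_fixations(back), 29)
})
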
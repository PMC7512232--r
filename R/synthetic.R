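#' @useDynLib oculochaos, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Jumping-point stimulus schedule
#'
#' Describes the stimulus of a "jumping point" eye-tracking experiment: a dot
#' displayed at a sequence of screen locations in the universal scale
#' ([0,1] x [0,1], origin at the top-left corner), each shown for a fixed
#' duration. The default emulates a 29-location protocol with 3000 ms per
#' location.
#'
#' @param locations two-column matrix of (x, y) screen coordinates in [0,1];
#'   by default 29 locations laid out deterministically over the screen.
#' @param display_duration_ms how long each location is displayed (ms).
#' @return Object of class `stimulus_schedule` with fields `locations`,
#'   `onset_times_ms` (strictly increasing) and `display_duration_ms`.
#' @export
stimulus_schedule <- function(locations = default_stimulus_locations(),
                              display_duration_ms = 3000) {
  locations <- as.matrix(locations)
  if (ncol(locations) != 2 || nrow(locations) < 1) {
    stop("'locations' must be an n x 2 matrix", call. = FALSE)
  }
  if (any(locations < 0) || any(locations > 1)) {
    stop("stimulus locations must lie in the universal scale [0,1]x[0,1]",
         call. = FALSE)
  }
  if (!is.numeric(display_duration_ms) || display_duration_ms <= 0) {
    stop("'display_duration_ms' must be positive", call. = FALSE)
  }
  onsets <- (seq_len(nrow(locations)) - 1) * display_duration_ms
  structure(list(locations = locations,
                 onset_times_ms = onsets,
                 display_duration_ms = display_duration_ms),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d locations, %g ms each (total %g ms)\n",
              nrow(x$locations), x$display_duration_ms,
              nrow(x$locations) * x$display_duration_ms))
  invisible(x)
}

#' @rdname stimulus_schedule
#' @param n number of locations.
#' @export
default_stimulus_locations <- function(n = 29) {
  # deterministic low-discrepancy layout over the screen (golden-ratio walk),
  # kept away from the edges
  i <- seq_len(n)
  phi <- (sqrt(5) - 1) / 2
  x <- 0.1 + 0.8 * ((i * phi) %% 1)
  y <- 0.1 + 0.8 * ((i * phi * phi + 0.5) %% 1)
  cbind(x = x, y = y)
}

#' Oculomotor simulation parameters
#'
#' Parameters of the synthetic eye-movement generator. A saccade to each new
#' target starts after a saccadic latency drawn uniformly from one of the
#' three empirically reported latency bands (90-120, 135-170 or 200-220 ms,
#' band chosen uniformly), follows a minimum-jerk position profile of fixed
#' duration, and is followed by fixational micro-movement: a slow random-walk
#' drift, band-limited tremor, and white (flat-spectrum) measurement noise.
#'
#' @param latency_ranges_ms list of numeric length-2 vectors, the latency
#'   bands (ms) sampled per saccade.
#' @param saccade_duration_ms saccade duration (ms); 0 gives an instantaneous
#'   jump.
#' @param fixation_drift_sd per-sample standard deviation (deg) of the
#'   random-walk drift increment.
#' @param tremor_amplitude_deg amplitude (deg) of the tremor sinusoid.
#' @param tremor_band_hz length-2 vector, frequency band (Hz) the tremor
#'   frequency is drawn from; the default lies strictly above the 50 Hz
#'   noise-reduction cutoff so filtering removes it.
#' @param measurement_noise_sd standard deviation (deg) of additive white
#'   Gaussian measurement noise (flat spectrum up to Nyquist).
#' @param screen_width_mm,screen_height_mm,eye_distance_mm screen geometry
#'   used to convert universal-scale coordinates to degrees of visual angle.
#' @return Object of class `oculomotor_params`.
#' @export
oculomotor_params <- function(latency_ranges_ms = list(c(90, 120),
                                                       c(135, 170),
                                                       c(200, 220)),
                              saccade_duration_ms = 40,
                              fixation_drift_sd = 5e-4,
                              tremor_amplitude_deg = 0.01,
                              tremor_band_hz = c(60, 100),
                              measurement_noise_sd = 0.01,
                              screen_width_mm = 370,
                              screen_height_mm = 295,
                              eye_distance_mm = 450) {
  amps <- c(fixation_drift_sd, tremor_amplitude_deg, measurement_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (saccade_duration_ms < 0) {
    stop("'saccade_duration_ms' must be >= 0", call. = FALSE)
  }
  for (r in latency_ranges_ms) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) {
      stop("each latency range must be a nondecreasing pair of ms >= 0",
           call. = FALSE)
    }
  }
  structure(list(latency_ranges_ms = latency_ranges_ms,
                 saccade_duration_ms = saccade_duration_ms,
                 fixation_drift_sd = fixation_drift_sd,
                 tremor_amplitude_deg = tremor_amplitude_deg,
                 tremor_band_hz = tremor_band_hz,
                 measurement_noise_sd = measurement_noise_sd,
                 screen_width_mm = screen_width_mm,
                 screen_height_mm = screen_height_mm,
                 eye_distance_mm = eye_distance_mm),
            class = "oculomotor_params")
}

# Universal-scale x in [0,1] -> horizontal degrees of visual angle, with 0 deg
# at screen centre. The default 370 mm screen at 450 mm subtends ~44 deg
# edge-to-edge (approximately the reported ~40 deg field).
screen_x_to_deg <- function(x, params) {
  atan(((x - 0.5) * params$screen_width_mm) / params$eye_distance_mm) *
    180 / pi
}

#' Simulate one jumping-point session recording
#'
#' Generates the horizontal eye-position trace of one experimental session:
#' for each scheduled stimulus location the simulated gaze holds its previous
#' position during a sampled saccadic latency, executes a minimum-jerk saccade
#' to the new target, then fixates with random-walk drift plus band-limited
#' tremor; white measurement noise is added to the whole trace. Output is
#' fully determined by `(schedule, params, seed)`.
#'
#' @param schedule a [stimulus_schedule].
#' @param params an [oculomotor_params].
#' @param seed integer RNG seed.
#' @param subject_id,session_id labels stored in the recording.
#' @param rate sampling rate in Hz (the emulated tracker records at 1000 Hz).
#' @return Object of class `session_recording` with fields `position`
#'   (an [eyets] in degrees), `schedule`, `subject_id`, `session_id`.
#' @examples
#' rec <- generate_session(stimulus_schedule(), oculomotor_params(), seed = 1)
#' length(rec$position)  # 29 * 3000
#' @export
generate_session <- function(schedule, params = oculomotor_params(),
                             seed = 1, subject_id = "S1", session_id = "1",
                             rate = 1000) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(params, "oculomotor_params"))
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  dt_ms <- 1000 / rate
  n_per_fix <- round(schedule$display_duration_ms / dt_ms)
  if (n_per_fix < 1) stop("display duration shorter than one sample",
                          call. = FALSE)
  for (r in params$latency_ranges_ms) {
    if (r[2] >= schedule$display_duration_ms) {
      stop("latency range must lie within [0, display_duration)",
           call. = FALSE)
    }
  }
  targets_deg <- screen_x_to_deg(schedule$locations[, 1], params)
  n_fix <- length(targets_deg)

  pos <- with_seed(seed, {
    out <- numeric(n_fix * n_per_fix)
    current <- targets_deg[1]
    for (f in seq_len(n_fix)) {
      target <- targets_deg[f]
      latency <- {
        band <- params$latency_ranges_ms[[sample.int(
          length(params$latency_ranges_ms), 1)]]
        stats::runif(1, band[1], band[2])
      }
      if (f == 1) latency <- 0  # first target: assume gaze already settling
      n_lat <- min(round(latency / dt_ms), n_per_fix)
      n_sac <- min(round(params$saccade_duration_ms / dt_ms),
                   n_per_fix - n_lat)
      n_hold <- n_per_fix - n_lat - n_sac

      seg <- numeric(n_per_fix)
      if (n_lat > 0) seg[seq_len(n_lat)] <- current
      if (n_sac > 0) {
        u <- seq_len(n_sac) / n_sac
        jerk <- 10 * u^3 - 15 * u^4 + 6 * u^5  # minimum-jerk profile
        seg[n_lat + seq_len(n_sac)] <- current + (target - current) * jerk
      }
      if (n_hold > 0) {
        hold <- rep(target, n_hold)
        if (params$fixation_drift_sd > 0) {
          hold <- hold + cumsum(stats::rnorm(n_hold, 0,
                                             params$fixation_drift_sd))
        }
        if (params$tremor_amplitude_deg > 0) {
          f_tr <- stats::runif(1, params$tremor_band_hz[1],
                               params$tremor_band_hz[2])
          ph <- stats::runif(1, 0, 2 * pi)
          t_s <- (seq_len(n_hold) - 1) / rate
          hold <- hold + params$tremor_amplitude_deg *
            sin(2 * pi * f_tr * t_s + ph)
        }
        seg[n_lat + n_sac + seq_len(n_hold)] <- hold
        current <- hold[n_hold]
      } else {
        current <- seg[n_per_fix]
      }
      out[(f - 1) * n_per_fix + seq_len(n_per_fix)] <- seg
    }
    if (params$measurement_noise_sd > 0) {
      out <- out + stats::rnorm(length(out), 0, params$measurement_noise_sd)
    }
    out
  })

  structure(list(position = eyets(pos, rate = rate, units = "deg"),
                 schedule = schedule,
                 subject_id = subject_id,
                 session_id = session_id),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s session %s: %d samples (%d fixations)\n",
              x$subject_id, x$session_id, length(x$position),
              nrow(x$schedule$locations)))
  invisible(x)
}

#' Write / read a session recording as CSV plus JSON sidecar
#'
#' One CSV per session with columns `time_ms`, `x_position_deg`; the stimulus
#' schedule and labels go to a `.json` sidecar next to the CSV.
#'
#' @param rec a `session_recording`.
#' @param path CSV file path (sidecar is `path` with `.json` appended).
#' @return `write_session_csv` returns `path` invisibly; `read_session_csv`
#'   returns a `session_recording`.
#' @export
write_session_csv <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  n <- length(rec$position)
  dt_ms <- 1000 / rec$position$rate
  utils::write.csv(data.frame(time_ms = (seq_len(n) - 1) * dt_ms,
                              x_position_deg = rec$position$values),
                   path, row.names = FALSE)
  side <- list(subject_id = rec$subject_id,
               session_id = rec$session_id,
               rate_hz = rec$position$rate,
               display_duration_ms = rec$schedule$display_duration_ms,
               locations = rec$schedule$locations)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- stimulus_schedule(as.matrix(side$locations),
                             display_duration_ms = side$display_duration_ms)
  structure(list(position = eyets(df$x_position_deg, rate = side$rate_hz,
                                  units = "deg"),
                 schedule = sched,
                 subject_id = side$subject_id,
                 session_id = as.character(side$session_id)),
            class = "session_recording")
}

#' Canonical reference signals for estimator validation
#'
#' Generates time series with known dynamical character: the Henon map
#' (chaotic, D2 about 1.2), the Lorenz system (chaotic flow), a sine
#' (periodic, zero entropy), Gaussian white noise (space-filling), and a
#' Gaussian AR(1) process (linear stochastic, the surrogate null).
#'
#' @param kind one of `"henon"`, `"lorenz"`, `"sine"`, `"white_noise"`,
#'   `"ar1"`.
#' @param n series length (>= 2).
#' @param params named list of kind-specific parameters. Henon: `a` (1.4),
#'   `b` (0.3), `transient` (1000). Lorenz: `sigma` (10), `rho` (28), `beta`
#'   (8/3), `dt` (0.01), `transient` (10 time units). Sine: `freq_hz` (10),
#'   `amplitude` (1), `rate` (1000). White noise: `sd` (1). AR(1): `phi`
#'   (0.8), `sd` (1).
#' @param seed integer RNG seed (controls initial conditions / innovations).
#' @return An [eyets] of length `n` (rate 1000 Hz for `sine`, 1 otherwise),
#'   NaN-free.
#' @examples
#' h <- generate_reference("henon", 3000, seed = 1)
#' range(series_values(h))
#' @export
generate_reference <- function(kind = c("henon", "lorenz", "sine",
                                        "white_noise", "ar1"),
                               n, params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 2) stop("'n' must be >= 2", call. = FALSE)
  n <- as.integer(n)
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  vals <- switch(kind,
    henon = with_seed(seed, {
      a <- p("a", 1.4); b <- p("b", 0.3)
      transient <- p("transient", 1000)
      x <- stats::runif(1, -0.1, 0.1); y <- stats::runif(1, -0.1, 0.1)
      out <- numeric(n)
      total <- transient + n
      for (i in seq_len(total)) {
        xn <- 1 - a * x * x + y
        y <- b * x
        x <- xn
        if (!is.finite(x) || abs(x) > 1e6) {
          stop("henon trajectory diverged (numeric overflow)", call. = FALSE)
        }
        if (i > transient) out[i - transient] <- x
      }
      out
    }),
    lorenz = with_seed(seed, {
      sigma <- p("sigma", 10); rho <- p("rho", 28); beta <- p("beta", 8 / 3)
      dt <- p("dt", 0.01); transient <- p("transient", 10)
      deriv <- function(s) c(sigma * (s[2] - s[1]),
                             s[1] * (rho - s[3]) - s[2],
                             s[1] * s[2] - beta * s[3])
      rk4_step <- function(s) {
        k1 <- deriv(s)
        k2 <- deriv(s + dt / 2 * k1)
        k3 <- deriv(s + dt / 2 * k2)
        k4 <- deriv(s + dt * k3)
        s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      s <- c(1, 1, 1) + stats::runif(3, -0.5, 0.5)
      n_trans <- ceiling(transient / dt)
      for (i in seq_len(n_trans)) s <- rk4_step(s)
      out <- numeric(n)
      for (i in seq_len(n)) {
        s <- rk4_step(s)
        if (!all(is.finite(s)) || max(abs(s)) > 1e6) {
          stop("lorenz trajectory diverged (numeric overflow)", call. = FALSE)
        }
        out[i] <- s[1]
      }
      out
    }),
    sine = {
      freq <- p("freq_hz", 10); amp <- p("amplitude", 1)
      rate <- p("rate", 1000)
      t_s <- (seq_len(n) - 1) / rate
      amp * sin(2 * pi * freq * t_s + p("phase", 0))
    },
    white_noise = with_seed(seed, stats::rnorm(n, 0, p("sd", 1))),
    ar1 = with_seed(seed, {
      phi <- p("phi", 0.8); sd_e <- p("sd", 1)
      e <- stats::rnorm(n + 100, 0, sd_e)
      x <- stats::filter(e, phi, method = "recursive")
      as.numeric(x)[101:(100 + n)]  # drop burn-in
    })
  )
  rate <- if (kind == "sine") p("rate", 1000) else 1
  eyets(vals, rate = rate, units = "a.u.")
}
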
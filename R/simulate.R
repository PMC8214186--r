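#' Constant heart-rate profile
#'
#' @param bpm Heart rate in beats per minute.
#' @return A function of time `t` (seconds) returning bpm, with attribute
#'   `phase_integral(t)` giving beats accumulated by time `t` (analytic).
#' @export
hr_profile_constant <- function(bpm) {
  f <- function(t) rep(bpm, length(t))
  attr(f, "beats") <- function(t) bpm * t / 60
  attr(f, "max_bpm") <- bpm
  f
}

#' Mono-exponential post-exercise recovery heart-rate profile
#'
#' `hr(t) = asymptote + (start - asymptote) * exp(-t / tau)`: the heart rate
#' decays from its end-of-exercise value toward a resting asymptote. The
#' accumulated beat count has the closed form
#' `(asymptote * t + (start - asymptote) * tau * (1 - exp(-t/tau))) / 60`,
#' used for phase-continuous oscillator synthesis and as analytic ground
#' truth.
#'
#' @param start Heart rate at `t = 0`, bpm.
#' @param asymptote Resting asymptote, bpm.
#' @param tau Exponential time constant, seconds.
#' @return A profile function as in [hr_profile_constant()].
#' @export
hr_profile_recovery <- function(start = 160, asymptote = 70, tau = 60) {
  f <- function(t) asymptote + (start - asymptote) * exp(-t / tau)
  attr(f, "beats") <- function(t)
    (asymptote * t + (start - asymptote) * tau * (1 - exp(-t / tau))) / 60
  attr(f, "max_bpm") <- max(start, asymptote)
  f
}

#' Simulate a fingertip camera-PPG capture with known ground truth
#'
#' Generates a quasi-periodic channel-mean series the way a flash-lit
#' fingertip capture produces one: a phase-continuous oscillator whose
#' instantaneous frequency follows the heart-rate profile, a configurable
#' harmonic-rich pulse shape, per-channel gains (a crude surrogate for skin
#' tone and device differences), low-frequency baseline drift, additive
#' Gaussian noise, and an intensity offset into a 0-255-like range. The
#' default pulse carries a 0.4-amplitude second harmonic because harmonic
#' rejection is the hard case for autocorrelation period selection. The true
#' mean heart rate over each analysis window is returned alongside.
#'
#' @param duration Capture length, seconds.
#' @param rate Frame rate, Hz.
#' @param hr_profile A profile function ([hr_profile_constant()] /
#'   [hr_profile_recovery()]).
#' @param harmonics Numeric vector of harmonic amplitudes; element `k` is
#'   the amplitude of the k-th harmonic (default `c(1, 0.4)`).
#' @param channel_gains Named numeric, amplitude per channel (default
#'   `c(red = 1, green = 1, blue = 0.2)`).
#' @param noise_sd Additive Gaussian noise sd per channel (signal units).
#' @param drift_amp,drift_freq Baseline drift amplitude and frequency (Hz).
#' @param offset Mean intensity level added to every channel.
#' @param window_seconds Window length used for the ground-truth table.
#' @param seed Integer seed; identical seeds give identical captures.
#' @return A list: `series` ([channel_series()]), `truth` (data.frame with
#'   `window`, `window_start`, `window_end`, `hr_true` = mean profile bpm
#'   over the window), `hr_profile`.
#' @examples
#' sim <- simulate_ppg(duration = 20, hr_profile = hr_profile_constant(80),
#'                     noise_sd = 0.1, seed = 7)
#' sim$truth
#' @export
simulate_ppg <- function(duration = 60, rate = 60,
                         hr_profile = hr_profile_constant(75),
                         harmonics = c(1, 0.4),
                         channel_gains = c(red = 1, green = 1, blue = 0.2),
                         noise_sd = 0, drift_amp = 0, drift_freq = 0.1,
                         offset = 128, window_seconds = 10, seed = 1) {
  if (duration <= 0 || rate <= 0) hs_config_error("duration and rate must be > 0")
  max_f <- attr(hr_profile, "max_bpm") / 60 * length(harmonics)
  if (rate < 2 * max_f)
    hs_config_error(sprintf(
      "rate %.4g Hz violates Nyquist for the highest harmonic (%.4g Hz)",
      rate, max_f))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  t <- t[t < duration]
  phase <- 2 * pi * attr(hr_profile, "beats")(t)
  pulse <- rep(0, length(t))
  for (k in seq_along(harmonics))
    pulse <- pulse + harmonics[k] * sin(k * phase)
  drift <- if (drift_amp > 0) drift_amp * sin(2 * pi * drift_freq * t) else 0
  mk <- function(gain) offset + gain * pulse + drift +
    if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  series <- channel_series(t, mk(channel_gains[["red"]]),
                           mk(channel_gains[["green"]]),
                           mk(channel_gains[["blue"]]), nominal_rate = rate)
  n_win <- floor(duration / window_seconds)
  beats <- attr(hr_profile, "beats")
  truth <- data.frame(
    window = seq_len(n_win),
    window_start = (seq_len(n_win) - 1) * window_seconds,
    window_end = seq_len(n_win) * window_seconds)
  truth$hr_true <- (beats(truth$window_end) - beats(truth$window_start)) /
    window_seconds * 60
  list(series = series, truth = truth, hr_profile = hr_profile)
}

# save/restore the global RNG state so simulators are pure functions of
# their seed without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a 1 Hz displacement track of known length
#'
#' Generates a noiseless waypoint path (straight line, circle, or piecewise
#' linear through waypoints) traversed at constant speed and sampled at the
#' track rate, adds iid Gaussian position jitter, and differences the
#' positions into the requested platform dialect. The true path length is
#' returned analytically.
#'
#' @param shape `"line"`, `"circle"`, or a 2-column matrix of waypoints
#'   (meters) traversed in order.
#' @param speed Meters per second.
#' @param duration Seconds.
#' @param jitter_sd Per-position Gaussian jitter sd, meters.
#' @param dialect `"meters"` or `"degrees"`.
#' @param anchor `(lat, lon)` anchor, required for the degrees dialect.
#' @param radius Circle radius in meters (circle shape only).
#' @param rate Samples per second (1 Hz in the protocol).
#' @param seed Integer seed.
#' @return A list: `track` ([displacement_track()]), `true_length` (meters),
#'   `positions_true` (noiseless planar positions).
#' @examples
#' sim <- simulate_track("line", speed = 2, duration = 600, seed = 3)
#' sim$true_length
#' @export
simulate_track <- function(shape = "line", speed = 2, duration = 720,
                           jitter_sd = 0, dialect = c("meters", "degrees"),
                           anchor = c(32.8801, -117.2340), radius = 100,
                           rate = 1, seed = 1) {
  dialect <- match.arg(dialect)
  if (speed < 0 || jitter_sd < 0) hs_config_error("speed and jitter_sd must be >= 0")
  if (dialect == "degrees" && is.null(anchor))
    hs_config_error("degrees dialect requires an anchor")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- seq(0, duration, by = 1 / rate)
  s <- speed * tt
  if (is.matrix(shape)) {
    seg <- diff(shape)
    seg_len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(seg_len))
    s <- pmin(s, cum[length(cum)])
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    frac <- (s - cum[idx]) / seg_len[idx]
    pos <- shape[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  } else if (shape == "line") {
    pos <- cbind(s, 0)
  } else if (shape == "circle") {
    th <- s / radius
    pos <- cbind(radius * cos(th), radius * sin(th))
  } else hs_config_error("shape must be 'line', 'circle' or a waypoint matrix")
  true_length <- if (is.matrix(shape)) max(s) else speed * duration
  noisy <- pos + if (jitter_sd > 0)
    matrix(stats::rnorm(length(pos), 0, jitter_sd), ncol = 2) else 0
  if (dialect == "meters") {
    track <- displacement_track(diff(noisy[, 1]), diff(noisy[, 2]),
                                dialect = "meters", rate = rate,
                                max_step = Inf)
  } else {
    lat0 <- anchor[1] * pi / 180
    lat <- anchor[1] + noisy[, 2] / EARTH_RADIUS_M * 180 / pi
    lon <- anchor[2] + noisy[, 1] / (EARTH_RADIUS_M * cos(lat0)) * 180 / pi
    track <- displacement_track(diff(lat), diff(lon), dialect = "degrees",
                                anchor = anchor, rate = rate, max_step = Inf)
  }
  list(track = track, true_length = true_length, positions_true = pos)
}

#' Simulate a test-retest cohort with known variance components
#'
#' Each measurement is `subject effect + repeat bias + noise`, with subject
#' effects Gaussian `(0, subject_sd)` and noise Gaussian `(0, error_sd)`.
#' The implied single-measure ICC, `subject_sd^2 / (subject_sd^2 +
#' error_sd^2)`, is returned as ground truth for recovery tests.
#'
#' @param n Subjects (>= 2).
#' @param repeats Repeats per subject (>= 2).
#' @param subject_sd Between-subject sd.
#' @param error_sd Within-subject (error) sd.
#' @param bias Optional per-repeat additive bias, length 1 or `repeats`
#'   (e.g. a device offset between two measurement methods).
#' @param mean_level Grand mean added to every value.
#' @param seed Integer seed.
#' @return A numeric `n x repeats` matrix with attribute `true_icc`.
#' @export
simulate_agreement_cohort <- function(n = 100, repeats = 2, subject_sd = 3,
                                      error_sd = 1, bias = 0,
                                      mean_level = 40, seed = 1) {
  if (n < 2 || repeats < 2) hs_config_error("need n >= 2 and repeats >= 2")
  bias <- rep(bias, length.out = repeats)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subj <- stats::rnorm(n, 0, subject_sd)
  m <- outer(subj, bias, `+`) + mean_level +
    matrix(stats::rnorm(n * repeats, 0, error_sd), n, repeats)
  attr(m, "true_icc") <- subject_sd^2 / (subject_sd^2 + error_sd^2)
  m
}
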
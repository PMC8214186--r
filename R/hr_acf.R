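#' Heart-rate estimation configuration
#'
#' Collects every tunable parameter of the camera-PPG heart-rate pipeline in
#' one validated object.
#'
#' @param hr_min,hr_max Supported heart-rate range in bpm (default 45-210).
#' @param band Band-pass edges in Hz for [ppg_preprocess()].
#' @param window_seconds Analysis window length in seconds.
#' @param cutoff Confidence cutoff in `[0, 1]`; windows below it are flagged
#'   invalid (default 0.5).
#' @param peak_threshold Spurious-peak threshold: minimum normalized ACF
#'   magnitude (relative to lag 0) for a local maximum to count as a
#'   candidate period (default 0.25).
#' @param use_blue If `TRUE`, the blue channel is also estimated (reported
#'   only; never fused).
#' @return A list of class `hr_config`.
#' @export
hr_config <- function(hr_min = 45, hr_max = 210, band = c(0.6, 4.0),
                      window_seconds = 10, cutoff = 0.5,
                      peak_threshold = 0.25, use_blue = FALSE) {
  if (!(hr_min > 0 && hr_max > hr_min))
    hs_config_error("need 0 < hr_min < hr_max")
  if (cutoff < 0 || cutoff > 1)
    hs_config_error("cutoff must lie in [0, 1]")
  if (peak_threshold < 0 || peak_threshold >= 1)
    hs_config_error("peak_threshold must lie in [0, 1)")
  if (window_seconds <= 0) hs_config_error("window_seconds must be > 0")
  structure(list(hr_min = hr_min, hr_max = hr_max, band = band,
                 window_seconds = window_seconds, cutoff = cutoff,
                 peak_threshold = peak_threshold, use_blue = use_blue),
            class = "hr_config")
}

# Lag search bounds for a period in [hr_min, hr_max] bpm at `rate` Hz.
# Rounded outward (floor on the short-period side, ceiling on the long-period
# side) so a signal exactly at a range edge still has its ACF peak inside the
# searched lags; sub-sample refinement then lands on the true period.
hr_lag_bounds <- function(rate, hr_min, hr_max) {
  c(lo = max(2L, as.integer(floor(rate * 60 / hr_max))),
    hi = as.integer(ceiling(rate * 60 / hr_min)))
}

#' Autocorrelation period estimate for one window of one channel
#'
#' Computes the normalized (biased, lag-0 = 1) autocorrelation of a single
#' channel over one analysis window and searches for the fundamental period:
#' local ACF maxima whose lag corresponds to a heart rate in
#' `[hr_min, hr_max]` and whose normalized magnitude is at least
#' `peak_threshold` (a magnitude threshold relative to the lag-0 peak, which
#' filters spurious peaks). The surviving peak of maximum magnitude is the
#' fundamental; its lag is refined to sub-sample precision by parabolic
#' interpolation through the ACF values at the neighboring lags.
#'
#' @param x Numeric vector: one preprocessed (filtered, mean-centered),
#'   uniformly sampled channel window.
#' @param rate Sampling rate in Hz.
#' @param hr_min,hr_max Heart-rate search range in bpm.
#' @param peak_threshold Minimum normalized ACF magnitude for a candidate.
#' @return An object of class `ppg_acf`: list with `lags` (0..max searched),
#'   `acf` (normalized values), `candidates` (data.frame lag/magnitude),
#'   `fundamental_lag` (integer lag of the selected peak, `NA` if none),
#'   `refined_lag` (sub-sample lag), and `rate`.
#' @export
ppg_acf <- function(x, rate, hr_min = 45, hr_max = 210,
                    peak_threshold = 0.25) {
  lb <- hr_lag_bounds(rate, hr_min, hr_max)
  n <- length(x)
  if (n <= lb["hi"] + 1L)
    hs_insufficient_data("window too short for the requested heart-rate range")
  if (stats::var(x) == 0) {
    # flat window: ACF undefined; report no candidates rather than erroring
    return(structure(list(
      lags = 0:(lb[["hi"]] + 1L), acf = c(1, rep(NA_real_, lb[["hi"]] + 1L)),
      candidates = data.frame(lag = integer(), magnitude = numeric()),
      fundamental_lag = NA_integer_, refined_lag = NA_real_, rate = rate),
      class = "ppg_acf"))
  }
  a <- as.numeric(stats::acf(x, lag.max = lb[["hi"]] + 1L, plot = FALSE,
                             demean = TRUE)$acf)  # a[l + 1] = ACF at lag l
  is_peak <- function(l) a[l + 1] > a[l] && a[l + 1] >= a[l + 2]
  cand_lags <- Filter(function(l) is_peak(l) && a[l + 1] >= peak_threshold,
                      lb[["lo"]]:lb[["hi"]])
  cand <- data.frame(lag = as.integer(cand_lags),
                     magnitude = a[as.integer(cand_lags) + 1])
  if (nrow(cand) == 0) {
    fund <- NA_integer_; refined <- NA_real_
  } else {
    fund <- cand$lag[which.max(cand$magnitude)]
    ym1 <- a[fund]; y0 <- a[fund + 1]; yp1 <- a[fund + 2]
    den <- ym1 - 2 * y0 + yp1
    delta <- if (is.finite(den) && den < 0) 0.5 * (ym1 - yp1) / den else 0
    refined <- fund + max(-0.5, min(0.5, delta))
  }
  structure(list(lags = 0:(lb[["hi"]] + 1L), acf = a, candidates = cand,
                 fundamental_lag = fund, refined_lag = refined, rate = rate),
            class = "ppg_acf")
}

#' @export
print.ppg_acf <- function(x, ...) {
  cat(sprintf("<ppg_acf> %d candidate peak(s); fundamental lag %s\n",
              nrow(x$candidates),
              if (is.na(x$fundamental_lag)) "absent"
              else sprintf("%d (refined %.3f)", x$fundamental_lag,
                           x$refined_lag)))
  invisible(x)
}

#' Confidence score of a window's period estimate
#'
#' The default quality score: the normalized ACF magnitude at the fundamental
#' lag (the ACF maximum is at lag 0 and equals 1 after normalization), clipped
#' to `[0, 1]`; 0 when no fundamental was found. A strongly periodic window
#' scores near 1; noise scores near 0. Windows below the configured cutoff
#' (default 0.5) are discarded as quality control.
#'
#' @param acf_result A [ppg_acf()] result.
#' @return A score in `[0, 1]`.
#' @seealso [peak_ratio_score()] for the alternative peak-to-next-peak ratio.
#' @export
confidence_score <- function(acf_result) {
  if (is.na(acf_result$fundamental_lag)) return(0)
  max(0, min(1, acf_result$acf[acf_result$fundamental_lag + 1]))
}

#' Peak-to-next-peak ratio score (secondary)
#'
#' An alternative periodicity score: the ratio of the fundamental peak's ACF
#' magnitude to the next-largest candidate peak's magnitude. Unlike
#' [confidence_score()] it is unbounded above (`Inf` when the fundamental is
#' the only candidate) and is provided for comparison only; the bounded
#' normalized-ACF score is the default used for quality control.
#'
#' @param acf_result A [ppg_acf()] result.
#' @return Ratio `>= 1`, `Inf` with a single candidate, 0 with none.
#' @export
peak_ratio_score <- function(acf_result) {
  if (is.na(acf_result$fundamental_lag)) return(0)
  mags <- sort(acf_result$candidates$magnitude, decreasing = TRUE)
  if (length(mags) < 2) return(Inf)
  mags[1] / mags[2]
}

# per-channel HR + confidence for one preprocessed window
channel_estimate <- function(x, rate, config) {
  ar <- ppg_acf(x, rate, config$hr_min, config$hr_max, config$peak_threshold)
  conf <- confidence_score(ar)
  hr <- if (is.na(ar$refined_lag)) NA_real_ else
    max(config$hr_min, min(config$hr_max, rate * 60 / ar$refined_lag))
  list(hr = hr, conf = conf)
}

#' Estimate heart rate for a single analysis window
#'
#' Runs the autocorrelation period estimator on the red and green channels of
#' one preprocessed window and fuses them by choosing the estimate from the
#' channel with the maximum confidence score. Ties prefer green (hemoglobin
#' absorbs more strongly at green wavelengths, so green typically carries the
#' stronger pulsatile signal). The blue channel is never fused. The window is
#' valid when the fused confidence reaches the configured cutoff.
#'
#' @param window A single preprocessed analysis window ([channel_series()]).
#' @param config An [hr_config()].
#' @return A one-row data.frame with columns `window_start`, `window_end`,
#'   `hr_red`, `conf_red`, `hr_green`, `conf_green`, `hr_fused`,
#'   `conf_fused`, `source_channel` ("red", "green" or "none") and `valid`.
#' @export
estimate_window_hr <- function(window, config = hr_config()) {
  fs <- window$nominal_rate
  red <- channel_estimate(window$red, fs, config)
  green <- channel_estimate(window$green, fs, config)
  if (is.na(green$hr) && is.na(red$hr)) {
    src <- "none"; fused_hr <- NA_real_; fused_conf <- 0
  } else if (is.na(red$hr) || (!is.na(green$hr) && green$conf >= red$conf)) {
    src <- "green"; fused_hr <- green$hr; fused_conf <- green$conf
  } else {
    src <- "red"; fused_hr <- red$hr; fused_conf <- red$conf
  }
  data.frame(window_start = window$t[1],
             window_end = window$t[length(window$t)] + 1 / fs,
             hr_red = red$hr, conf_red = red$conf,
             hr_green = green$hr, conf_green = green$conf,
             hr_fused = fused_hr, conf_fused = fused_conf,
             source_channel = src,
             valid = fused_conf >= config$cutoff)
}

#' Heart-rate timecourse from a fingertip camera capture
#'
#' The main entry point of the camera-PPG estimator. The capture is resampled
#' to a uniform grid, band-pass filtered and mean-centered, split into
#' consecutive 10-second analysis windows, and each window's heart rate is
#' estimated by autocorrelation with red/green channel fusion
#' ([estimate_window_hr()]). Windows whose fused confidence falls below the
#' cutoff are retained in the output but flagged invalid; the retained
#' fraction (valid / total) is the quality-control summary.
#'
#' @param series A [channel_series()] capture.
#' @param config An [hr_config()].
#' @return An object of class `hr_timecourse`: list with `windows` (one row
#'   per analysis window, see [estimate_window_hr()]), `retention` (valid
#'   fraction), and `config`.
#' @examples
#' sim <- simulate_ppg(duration = 30, hr_profile = hr_profile_constant(72),
#'                     seed = 1)
#' tc <- hr_timecourse(sim$series)
#' summary(tc)
#' @export
hr_timecourse <- function(series, config = hr_config()) {
  u <- resample_uniform(series)
  p <- ppg_preprocess(u, band = config$band)
  wins <- split_windows(p, config$window_seconds)
  rows <- do.call(rbind, lapply(wins, estimate_window_hr, config = config))
  structure(list(windows = rows,
                 retention = mean(rows$valid),
                 config = config),
            class = "hr_timecourse")
}

#' @export
print.hr_timecourse <- function(x, ...) {
  cat(sprintf(
    "<hr_timecourse> %d windows of %.4g s; %d valid (retention %.3f) at cutoff %.2f\n",
    nrow(x$windows), x$config$window_seconds, sum(x$windows$valid),
    x$retention, x$config$cutoff))
  if (any(x$windows$valid))
    cat(sprintf("  valid fused HR: median %.1f bpm (range %.1f-%.1f)\n",
                stats::median(x$windows$hr_fused[x$windows$valid]),
                min(x$windows$hr_fused[x$windows$valid]),
                max(x$windows$hr_fused[x$windows$valid])))
  invisible(x)
}

#' @export
summary.hr_timecourse <- function(object, ...) {
  print(object)
  print(object$windows, digits = 4)
  invisible(object)
}

#' @export
as.data.frame.hr_timecourse <- function(x, ...) x$windows

#' @export
plot.hr_timecourse <- function(x, ...) {
  w <- x$windows
  mid <- (w$window_start + w$window_end) / 2
  graphics::plot(mid, w$hr_fused, pch = ifelse(w$valid, 19, 1),
                 xlab = "time (s)", ylab = "heart rate (bpm)",
                 main = "Fused window heart rate", ...)
  graphics::legend("topright", pch = c(19, 1),
                   legend = c("valid", sprintf("conf < %.2f", x$config$cutoff)))
  invisible(x)
}

#' Resting heart rate from a short capture
#'
#' Aggregates a short resting capture (20 s in the deployed protocol, i.e.
#' two analysis windows) into a single resting heart rate: the mean fused
#' heart rate over valid windows.
#'
#' @param tc An [hr_timecourse()] result.
#' @return Resting heart rate in bpm.
#' @export
resting_hr <- function(tc) {
  v <- tc$windows[tc$windows$valid, ]
  if (nrow(v) == 0)
    hs_insufficient_data("no valid windows; cannot estimate resting heart rate")
  mean(v$hr_fused)
}
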
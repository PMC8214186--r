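#' Construct a camera channel-mean time series
#'
#' A `channel_series` holds the per-frame mean pixel intensity of each color
#' channel from a flash-illuminated fingertip video capture, together with
#' frame timestamps. Raw video is never stored (for privacy); these per-frame
#' channel means are the only signal the heart-rate estimator sees.
#'
#' @param t Numeric vector of frame timestamps in seconds since capture
#'   start, strictly increasing.
#' @param red,green,blue Numeric vectors of mean pixel intensity per frame
#'   (arbitrary units, typically 0-255), same length as `t`.
#' @param nominal_rate Nominal frame rate in Hz (target 60).
#' @return An object of class `channel_series`: a list with elements `t`,
#'   `red`, `green`, `blue` and `nominal_rate`.
#' @examples
#' t <- seq(0, 10, by = 1 / 60)
#' s <- channel_series(t, red = sin(2 * pi * 1.2 * t) + 128,
#'                     green = sin(2 * pi * 1.2 * t) + 120,
#'                     blue = rep(100, length(t)), nominal_rate = 60)
#' s
#' @export
channel_series <- function(t, red, green, blue, nominal_rate = 60) {
  t <- as.numeric(t)
  red <- as.numeric(red); green <- as.numeric(green); blue <- as.numeric(blue)
  n <- length(t)
  if (length(red) != n || length(green) != n || length(blue) != n)
    hs_invalid_input("red/green/blue must have the same length as t")
  if (n >= 2 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)
    hs_invalid_input(sprintf(
      "timestamps must be strictly increasing; violations at index %s",
      paste(utils::head(bad + 1L, 5L), collapse = ", ")))
  }
  if (!is.finite(nominal_rate) || nominal_rate <= 0)
    hs_invalid_input("nominal_rate must be > 0")
  if (anyNA(t) || anyNA(red) || anyNA(green) || anyNA(blue))
    hs_invalid_input("channel series must not contain missing values")
  structure(list(t = t, red = red, green = green, blue = blue,
                 nominal_rate = as.numeric(nominal_rate)),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf(
    "<channel_series> %d frames, %.2f s, nominal %.6g Hz\n",
    length(x$t), series_duration(x), x$nominal_rate))
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$t)

#' @export
as.data.frame.channel_series <- function(x, ...) {
  data.frame(t = x$t, red = x$red, green = x$green, blue = x$blue)
}

#' Capture duration in seconds
#' @param series A [channel_series()].
#' @return Duration from first to last timestamp, seconds.
#' @export
series_duration <- function(series) {
  if (length(series$t) < 2) return(0)
  series$t[length(series$t)] - series$t[1]
}

#' Resample a channel series onto a uniform grid
#'
#' Camera frame timestamps jitter; downstream zero-phase filtering and
#' autocorrelation assume uniform sampling. Each channel is linearly
#' interpolated onto a uniform grid from the first to the last timestamp.
#'
#' @param series A [channel_series()].
#' @param target_rate Output sampling rate in Hz; defaults to the series'
#'   nominal rate.
#' @return A uniformly sampled `channel_series` at `target_rate`.
#' @export
resample_uniform <- function(series, target_rate = series$nominal_rate) {
  if (length(series$t) < 2)
    hs_invalid_input("need at least 2 samples to resample")
  if (!is.finite(target_rate) || target_rate <= 0)
    hs_config_error("target_rate must be > 0")
  grid <- seq(series$t[1], series$t[length(series$t)], by = 1 / target_rate)
  interp <- function(v) stats::approx(series$t, v, xout = grid)$y
  channel_series(grid, interp(series$red), interp(series$green),
                 interp(series$blue), nominal_rate = target_rate)
}

#' Band-pass filter and mean-center each channel
#'
#' Applies a zero-phase Butterworth band-pass (4th-order transfer function,
#' forward-backward filtering) to each channel and removes the mean, so that
#' baseline intensity and slow drift do not dominate the autocorrelation.
#' The default band 0.6-4.0 Hz covers the supported 45-210 bpm heart-rate
#' range (0.75-3.5 Hz) with margin.
#'
#' @param series A uniformly sampled [channel_series()] (see
#'   [resample_uniform()]).
#' @param band Length-2 numeric, pass band `(low, high)` in Hz; must satisfy
#'   `0 < low < high < nominal_rate / 2`.
#' @return A `channel_series` with each channel filtered and mean-centered.
#' @export
ppg_preprocess <- function(series, band = c(0.6, 4.0)) {
  fs <- series$nominal_rate
  if (length(band) != 2 || !all(is.finite(band)) ||
      band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    hs_config_error("band must satisfy 0 < low < high < nominal_rate/2")
  # butter(n = 2, type = "pass") yields a 4th-order band-pass
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  f <- function(v) {
    y <- signal::filtfilt(bf, v - mean(v))
    y - mean(y)
  }
  channel_series(series$t, f(series$red), f(series$green), f(series$blue),
                 nominal_rate = fs)
}

#' Split a series into consecutive analysis windows
#'
#' Splits a capture into consecutive non-overlapping windows of exactly
#' `window_seconds` (default 10 s, the autocorrelation analysis window). A
#' trailing partial window is discarded.
#'
#' @param series A uniformly sampled [channel_series()].
#' @param window_seconds Window length in seconds.
#' @return A list of `channel_series`, one per full window.
#' @export
split_windows <- function(series, window_seconds = 10) {
  fs <- series$nominal_rate
  n_per <- round(window_seconds * fs)
  n <- length(series$t)
  n_win <- n %/% n_per
  if (n_win < 1)
    hs_insufficient_data(sprintf(
      "capture (%.2f s) shorter than one %.4g-s analysis window",
      series_duration(series), window_seconds))
  lapply(seq_len(n_win), function(k) {
    i <- ((k - 1L) * n_per + 1L):(k * n_per)
    channel_series(series$t[i], series$red[i], series$green[i],
                   series$blue[i], nominal_rate = fs)
  })
}
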
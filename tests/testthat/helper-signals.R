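# shared fixtures: all synthetic, generated in code

# single-channel sinusoid window (unfiltered), amplitude 1 around `offset`
sine_window <- function(bpm, duration = 10, fs = 60, offset = 0, phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  t <- t[t < duration]
  sin(2 * pi * bpm / 60 * t + phase) + offset
}

# independent period oracle: periodogram argmax restricted to [f_lo, f_hi],
# direct FFT so it shares no code with the ACF path; zero-padding refines
# the frequency grid below the one-bin comparison tolerance
periodogram_peak_hz <- function(x, fs, f_lo, f_hi, pad = 8) {
  n <- length(x) * pad
  p <- abs(stats::fft(c(x - mean(x), rep(0, n - length(x)))))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= f_lo & f <= f_hi
  f[sel][which.max(p[sel])]
}

# one preprocessed (band-passed, mean-centered) noisy sinusoid window
noisy_filtered_window <- function(bpm, noise_sd, fs = 60, seed = 1) {
  set.seed(seed)
  raw <- sine_window(bpm, fs = fs, offset = 128) +
    stats::rnorm(10 * fs, 0, noise_sd)
  t <- seq(0, 10, by = 1 / fs)
  t <- t[t < 10]
  s <- channel_series(t, raw, raw, raw, nominal_rate = fs)
  ppg_preprocess(s)$green
}

# three-channel capture with a clean pulse in chosen channels only
capture_with_signal <- function(bpm, duration = 10, fs = 60,
                                gains = c(red = 1, green = 1, blue = 0.2),
                                noise_sd = 0, seed = 1) {
  simulate_ppg(duration = duration, rate = fs,
               hr_profile = hr_profile_constant(bpm),
               channel_gains = gains, noise_sd = noise_sd,
               seed = seed)$series
}
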
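test_that("fusion picks the channel carrying the signal", {
  # clean 1.25 Hz (75 bpm) pulse in green only, noise in red
  sim <- simulate_ppg(duration = 10, hr_profile = hr_profile_constant(75),
                      channel_gains = c(red = 0, green = 1, blue = 0),
                      noise_sd = 0.3, seed = 5)
  tc <- hr_timecourse(sim$series)
  w <- tc$windows
  expect_equal(w$source_channel, "green")
  expect_equal(w$hr_fused, 75, tolerance = 1)
  expect_true(w$valid)
})

test_that("identical channels tie-break deterministically to green", {
  s <- capture_with_signal(80, duration = 10,
                           gains = c(red = 1, green = 1, blue = 1))
  w <- hr_timecourse(s)$windows
  expect_equal(w$conf_red, w$conf_green, tolerance = 1e-9)
  expect_equal(w$source_channel, "green")
  expect_equal(w$hr_fused, w$hr_green)
})

test_that("range-edge heart rates are recovered within 1 bpm", {
  for (bpm in c(45, 210)) {
    sim <- simulate_ppg(duration = 10, hr_profile = hr_profile_constant(bpm),
                        seed = 1)
    w <- hr_timecourse(sim$series)$windows
    expect_equal(w$hr_fused, bpm, tolerance = 1)
    expect_true(w$valid)
  }
})

test_that("clean signals across the full physiological range recover within 1 bpm", {
  # frequency sweep at every integer bpm in 45..210
  errs <- vapply(45:210, function(bpm) {
    sim <- simulate_ppg(duration = 10, rate = 60,
                        hr_profile = hr_profile_constant(bpm), seed = 1)
    w <- hr_timecourse(sim$series)$windows
    expect_true(w$valid)
    abs(w$hr_fused - bpm)
  }, numeric(1))
  expect_lte(max(errs), 1)
})

test_that("ACF frequency agrees with a periodogram oracle on noisy windows", {
  # documented SNR level for oracle equivalence: ~6 dB (sd 0.35 on a
  # unit-amplitude pulse), windows band-pass filtered as in the pipeline
  fs <- 60
  agree <- vapply(seq_len(60), function(i) {
    bpm <- 50 + (i * 17) %% 150
    x <- noisy_filtered_window(bpm, noise_sd = 0.35, fs = fs, seed = i)
    a <- ppg_acf(x, fs)
    if (is.na(a$refined_lag)) return(FALSE)
    f_acf <- fs / a$refined_lag
    f_pgram <- periodogram_peak_hz(x, fs, 45 / 60, 210 / 60)
    abs(f_acf - f_pgram) <= fs / 600 + 1e-9  # within one frequency bin
  }, logical(1))
  expect_true(all(agree))
})

test_that("fused estimate is one of the channel estimates with max confidence", {
  for (seed in 1:10) {
    sim <- simulate_ppg(duration = 20,
                        hr_profile = hr_profile_constant(60 + 10 * seed),
                        channel_gains = c(red = 0.5, green = 1, blue = 0.1),
                        noise_sd = 0.8, seed = seed)
    w <- hr_timecourse(sim$series)$windows
    for (i in seq_len(nrow(w))) {
      expect_equal(w$conf_fused[i], max(w$conf_red[i], w$conf_green[i]))
      if (w$source_channel[i] != "none")
        expect_true(w$hr_fused[i] %in% c(w$hr_red[i], w$hr_green[i]))
      expect_true(w$conf_fused[i] >= 0 && w$conf_fused[i] <= 1)
      if (w$source_channel[i] != "none")
        expect_true(w$hr_fused[i] >= 45 && w$hr_fused[i] <= 210)
    }
  }
})

test_that("a constant capture yields flagged invalid windows, not errors", {
  t <- seq(0, 60, by = 1 / 60); t <- t[t < 60]
  s <- channel_series(t, rep(100, length(t)), rep(100, length(t)),
                      rep(100, length(t)), 60)
  tc <- hr_timecourse(s)
  expect_equal(nrow(tc$windows), 6)
  expect_false(any(tc$windows$valid))
  expect_equal(tc$retention, 0)
  expect_equal(tc$windows$source_channel, rep("none", 6))
  expect_error(resting_hr(tc), class = "hs_insufficient_data")
})

test_that("noise-corrupted windows lower the retention fraction", {
  hit <- vapply(1:20, function(seed) {
    sim <- simulate_ppg(duration = 60, hr_profile = hr_profile_constant(90),
                        seed = seed)
    s <- sim$series
    set.seed(seed + 500)
    idx <- 1:(2 * 600)  # first two windows become pure noise
    for (ch in c("red", "green", "blue"))
      s[[ch]][idx] <- 128 + stats::rnorm(length(idx), 0, 1)
    tc <- hr_timecourse(s)
    isTRUE(all.equal(tc$retention, 4 / 6))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("retention is monotone non-increasing in the cutoff", {
  sim <- simulate_ppg(duration = 60, hr_profile = hr_profile_constant(100),
                      noise_sd = 2, seed = 9)
  tc <- hr_timecourse(sim$series)
  rc <- retention_curve(tc$windows$conf_fused)
  expect_true(all(diff(rc$retained) <= 1e-12))
  expect_equal(rc$retained[rc$cutoff == 0], 1)
})

test_that("a 20-s resting capture aggregates to a single resting rate", {
  sim <- simulate_ppg(duration = 20, hr_profile = hr_profile_constant(62),
                      noise_sd = 0.2, seed = 13)
  tc <- hr_timecourse(sim$series)
  expect_equal(nrow(tc$windows), 2)
  expect_equal(resting_hr(tc), 62, tolerance = 1)
})
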
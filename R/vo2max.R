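#' Default 3-minute step test (Tecumseh/Milligan) coefficients
#'
#' VO2max prediction for the 3-minute step test from the heart beats counted
#' between 30 and 60 seconds after stepping ends (HB3060), age and sex:
#' `vo2max = intercept + b_hb3060 * HB3060 + b_age * age + b_sex * sex`
#' with sex coded 0 = male, 1 = female. The defaults are Milligan's
#' Tecumseh-family equation
#' `83.477 - 0.586 * HB3060 - 0.404 * age - 7.030 * sex`.
#' All coefficient sets carry a `source` string so substituted equations
#' remain traceable.
#'
#' @param intercept,b_hb3060,b_age,b_sex Equation coefficients.
#' @param source Non-empty provenance string for the coefficient set.
#' @return A list of class `step_coefficients`.
#' @export
step_coefficients <- function(intercept = 83.477, b_hb3060 = -0.586,
                              b_age = -0.404, b_sex = -7.030,
                              source = "Milligan (2013) Tecumseh-family step-test equation") {
  if (!nzchar(source)) hs_config_error("coefficient set requires a source")
  structure(list(intercept = intercept, b_hb3060 = b_hb3060, b_age = b_age,
                 b_sex = b_sex, source = source),
            class = "step_coefficients")
}

#' Default 12-minute run test (Cooper) coefficients
#'
#' VO2max prediction from distance covered in 12 minutes:
#' `vo2max = (d12 - offset) / divisor` with `d12` in meters. Defaults are
#' Cooper's (1968) equation `(d12 - 504.9) / 44.73`.
#'
#' @param offset,divisor Equation constants (meters; meters per unit VO2max).
#' @param source Non-empty provenance string.
#' @return A list of class `run_coefficients`.
#' @export
run_coefficients <- function(offset = 504.9, divisor = 44.73,
                             source = "Cooper (1968) 12-minute run equation") {
  if (!nzchar(source)) hs_config_error("coefficient set requires a source")
  if (divisor == 0) hs_config_error("divisor must be nonzero")
  structure(list(offset = offset, divisor = divisor, source = source),
            class = "run_coefficients")
}

#' Recovery beat count (HB3060) from windowed heart-rate estimates
#'
#' The step-test protocol counts the heart beats between 30 and 60 seconds
#' after stepping ends. From a windowed heart-rate timecourse this is the
#' overlap-weighted mean of the valid fused window heart rates over
#' `[test_end + 30, test_end + 60]` (the 10-s analysis windows do not align
#' with that interval), converted to beats over the half minute.
#'
#' @param estimates An [hr_timecourse()] or its `windows` data.frame (times
#'   in seconds on the capture clock).
#' @param test_end Time the stepping ended, seconds on the capture clock.
#' @return HB3060, beats in the 30-60 s post-test interval.
#' @export
hb3060_from_windows <- function(estimates, test_end = 0) {
  w <- if (inherits(estimates, "hr_timecourse")) estimates$windows else estimates
  lo <- test_end + 30
  hi <- test_end + 60
  ov <- pmin(w$window_end, hi) - pmax(w$window_start, lo)
  keep <- w$valid & ov > 1e-9
  if (!any(keep))
    hs_insufficient_data(
      "no valid heart-rate window overlaps the 30-60 s recovery interval")
  mean_hr <- sum(w$hr_fused[keep] * ov[keep]) / sum(ov[keep])
  mean_hr * 0.5
}

#' VO2max from the 3-minute step test
#'
#' Affine prediction of VO2max (mL·kg^-1·min^-1) from step-test recovery
#' heart beats, age and sex, using a configurable coefficient set
#' ([step_coefficients()]). HB3060 outside the physiologically plausible
#' 22.5-105 beats (45-210 bpm over half a minute) triggers a warning, as
#' does a non-positive prediction.
#'
#' @param hb3060 Beats counted 30-60 s after the step test.
#' @param age Age in years.
#' @param sex 0 if male, 1 if female.
#' @param coeffs A [step_coefficients()] set.
#' @return Estimated VO2max in mL·kg^-1·min^-1.
#' @examples
#' vo2max_step(hb3060 = 52, age = 34, sex = 0)
#' @export
vo2max_step <- function(hb3060, age, sex, coeffs = step_coefficients()) {
  if (!all(sex %in% c(0, 1)))
    hs_invalid_input("sex must be coded 0 (male) or 1 (female)")
  if (any(hb3060 <= 0)) hs_invalid_input("hb3060 must be positive")
  if (any(hb3060 < 22.5 | hb3060 > 105))
    warning("hb3060 outside the plausible 22.5-105 beat range (45-210 bpm)")
  v <- coeffs$intercept + coeffs$b_hb3060 * hb3060 + coeffs$b_age * age +
    coeffs$b_sex * sex
  if (any(v <= 0))
    warning("non-positive VO2max prediction; inputs outside the equation's range")
  v
}

#' VO2max from the 12-minute run test
#'
#' Affine prediction of VO2max (mL·kg^-1·min^-1) from the distance covered
#' in 12 minutes, using a configurable coefficient set
#' ([run_coefficients()]); strictly increasing in distance. Distances outside
#' 500-6000 m trigger a plausibility warning (a meters/kilometers mix-up
#' changes the result by an order of magnitude).
#'
#' @param d12 Distance covered in 12 minutes, meters.
#' @param coeffs A [run_coefficients()] set.
#' @return Estimated VO2max in mL·kg^-1·min^-1.
#' @examples
#' vo2max_run(2400)
#' @export
vo2max_run <- function(d12, coeffs = run_coefficients()) {
  if (any(d12 <= 0)) hs_invalid_input("d12 must be positive (meters)")
  if (any(d12 < 500 | d12 > 6000))
    warning("d12 outside the plausible 500-6000 m range; check units (meters)")
  (d12 - coeffs$offset) / coeffs$divisor
}

#' Run the full step-test pipeline on a capture
#'
#' Composes the camera heart-rate estimator, recovery beat counting and the
#' step-test VO2max equation: capture -> [hr_timecourse()] ->
#' [hb3060_from_windows()] -> [vo2max_step()].
#'
#' @param series A [channel_series()] capture covering at least
#'   `[test_end + 30, test_end + 60]`.
#' @param test_end Time the stepping ended, seconds on the capture clock.
#' @param age Age in years.
#' @param sex 0 if male, 1 if female.
#' @param config An [hr_config()].
#' @param coeffs A [step_coefficients()] set.
#' @return An object of class `step_test`: list with `vo2max`, `hb3060`,
#'   `timecourse`, `retention`, `age`, `sex`, `coeffs`.
#' @export
run_step_test <- function(series, test_end = 0, age, sex,
                          config = hr_config(),
                          coeffs = step_coefficients()) {
  tc <- hr_timecourse(series, config)
  hb <- hb3060_from_windows(tc, test_end)
  v <- vo2max_step(hb, age, sex, coeffs)
  structure(list(vo2max = v, hb3060 = hb, timecourse = tc,
                 retention = tc$retention, age = age, sex = sex,
                 coeffs = coeffs),
            class = "step_test")
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf("<step_test> HB3060 = %.1f beats; VO2max = %.1f mL/kg/min\n",
              x$hb3060, x$vo2max))
  cat(sprintf("  window retention %.3f; equation: %s\n",
              x$retention, x$coeffs$source))
  invisible(x)
}
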
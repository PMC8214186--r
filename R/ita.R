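#' Individual typology angle (ITA) from CIELAB L* and b*
#'
#' Skin pigmentation from spectrocolorimetry, as the angle
#' `arctan((L* - 50) / b*) * 180 / 3.14159` in degrees. Lighter skin has
#' higher L* (lightness) and hence a larger angle; the constant 180/3.14159
#' is kept verbatim by default so results match the deployed arithmetic
#' digit-for-digit (`exact_pi = TRUE` switches to true pi). For `b* <= 0`
#' (possible under instrument noise) the two-argument arctangent is used so
#' the sign of `L* - 50` resolves toward the +/-90 degree limits, with a
#' warning.
#'
#' @param L_star CIELAB lightness L*.
#' @param b_star CIELAB yellow-blue axis b*.
#' @param exact_pi Use true pi instead of the literal 3.14159.
#' @return Angle in degrees (vectorized).
#' @examples
#' compute_ita(65, 15)  # 45 degrees
#' @export
compute_ita <- function(L_star, b_star, exact_pi = FALSE) {
  pi_const <- if (exact_pi) pi else 3.14159
  if (any(b_star == 0 & L_star == 50))
    hs_invalid_input("ITA undefined at L* = 50, b* = 0")
  if (any(b_star <= 0))
    warning("b* <= 0: using the two-argument arctangent (angle near +/-90)")
  atan2(L_star - 50, b_star) * 180 / pi_const
}

#' Default ITA category boundaries (degrees)
#'
#' The six-category chain very light > 55 > light > 41 > intermediate >
#' 28 > tan > 10 > brown > -30 > dark. Boundary values belong to the darker
#' category (e.g. exactly 55 degrees classifies as light).
#' @return Named numeric vector of upper-exclusive cutoffs.
#' @export
ita_cutoffs <- function() c(`very light` = 55, light = 41, intermediate = 28,
                            tan = 10, brown = -30)

#' Classify an ITA value into the six skin-color groups
#'
#' @param ita Angle(s) in degrees.
#' @param cutoffs Boundary table as produced by [ita_cutoffs()]: named,
#'   strictly decreasing; `ita > cutoffs[k]` selects category `k`.
#' @return An ordered factor with levels dark < brown < tan < intermediate <
#'   light < very light.
#' @examples
#' classify_ita(c(60, 0, -31))
#' @export
classify_ita <- function(ita, cutoffs = ita_cutoffs()) {
  if (any(!is.finite(ita))) hs_invalid_input("ita must be finite")
  if (is.unsorted(rev(cutoffs), strictly = TRUE))
    hs_config_error("cutoffs must be strictly decreasing")
  levels_dark_to_light <- c("dark", rev(names(cutoffs)))
  # ita > cutoff => the lighter class; boundary goes to the darker class
  idx <- vapply(ita, function(a) sum(a > cutoffs), numeric(1))
  factor(levels_dark_to_light[idx + 1],
         levels = levels_dark_to_light, ordered = TRUE)
}

#' ITA measurement with classification
#'
#' @param L_star,b_star CIELAB inputs (vectorized).
#' @param exact_pi See [compute_ita()].
#' @return A data.frame with `L_star`, `b_star`, `ita_degrees`, `category`.
#' @export
ita_measurement <- function(L_star, b_star, exact_pi = FALSE) {
  ita <- compute_ita(L_star, b_star, exact_pi)
  data.frame(L_star = L_star, b_star = b_star, ita_degrees = ita,
             category = classify_ita(ita))
}
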
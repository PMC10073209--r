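#' Mean Joule power dissipated in the winding
#'
#' Lumped DC estimate: wire length is the sum of loop circumferences of
#' the filamentary winding, resistance follows from the copper
#' resistivity and the rectangular W x height cross-section, and the
#' RMS current is `I sqrt(duty)` for a pulse train of duty cycle `duty`.
#' Skin and proximity effects are deliberately ignored.
#'
#' @param spec a [coil_spec()].
#' @param duty pulse duty cycle in (0, 1].
#' @param current_A drive current override, A; defaults to the spec's.
#' @return list with `power_W`, `resistance_Ohm`, `wire_length_m`,
#'   `I_rms_A`.
#' @export
joule_power <- function(spec, duty = 1, current_A = spec$current_A) {
  validate_coil_spec(spec)
  if (!(duty > 0 && duty <= 1)) stop("duty must be in (0, 1]")
  w <- build_winding(spec)
  len_m <- sum(2 * pi * mm_to_m(w$loops$radius_mm))
  xsec_m2 <- mm_to_m(spec$wire_width_mm) * mm_to_m(spec$wire_height_mm)
  if (xsec_m2 <= 0) stop("zero wire cross-section")
  R <- RHO_CU * len_m / xsec_m2
  I_rms <- current_A * sqrt(duty)
  list(power_W = I_rms^2 * R, resistance_Ohm = R,
       wire_length_m = len_m, I_rms_A = I_rms)
}

#' Steady-state coil temperature under convective cooling
#'
#' Single-node balance `T = T_ambient + P / (h A)`. The convective
#' coefficient and dissipation area defaults are plausible for a small
#' air-cooled coil casing but uncalibrated; the model is meant for
#' orderings and scaling laws (temperature rise proportional to I^2),
#' not for absolute FEM temperatures.
#'
#' @param power_W mean dissipated power, W.
#' @param convective_coefficient_W_m2K convective film coefficient h,
#'   W/(m^2 K) (> 0).
#' @param area_m2 effective dissipation area, m^2 (> 0).
#' @param ambient_C ambient temperature, degrees C (default 25).
#' @return steady temperature in degrees C.
#' @export
steady_temperature <- function(power_W,
                               convective_coefficient_W_m2K = 25,
                               area_m2 = 6e-3,
                               ambient_C = 25) {
  if (!(convective_coefficient_W_m2K > 0)) stop("h must be > 0")
  if (!(area_m2 > 0)) stop("area must be > 0")
  ambient_C + power_W / (convective_coefficient_W_m2K * area_m2)
}

#' Lumped thermal report for a coil
#'
#' @inheritParams joule_power
#' @inheritParams steady_temperature
#' @return list combining the [joule_power()] fields with
#'   `steady_temperature_C`, `ambient_C`, `convective_coefficient_W_m2K`,
#'   `area_m2`.
#' @export
thermal_report <- function(spec, duty = 1, current_A = spec$current_A,
                           convective_coefficient_W_m2K = 25,
                           area_m2 = 6e-3, ambient_C = 25) {
  jp <- joule_power(spec, duty, current_A)
  Tst <- steady_temperature(jp$power_W, convective_coefficient_W_m2K,
                            area_m2, ambient_C)
  c(jp, list(steady_temperature_C = Tst, ambient_C = ambient_C,
             convective_coefficient_W_m2K = convective_coefficient_W_m2K,
             area_m2 = area_m2, duty = duty))
}
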
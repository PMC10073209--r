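#' Construct a coil specification
#'
#' A `coil_spec` collects the geometric and drive parameters of one flat
#' spiral winding: the quantities needed both for the closed-form design
#' formulas and for the loop-stack field solver. Defaults are the
#' parameters of the miniaturized murine coil (7-turn flat spiral,
#' 20 mm bore, 3 mm x 2 mm rectangular wire, 1000 A peak drive).
#'
#' @param topology `"circular"` (single spiral) or `"figure8"` (two
#'   adjacent spirals of opposite polarity).
#' @param inner_diameter_mm inner (bore) diameter D_i, mm.
#' @param outer_diameter_mm outer diameter D_o, mm. Checked for
#'   consistency with spiral growth `D_i + 2 N (W + S)` to within one
#'   turn pitch.
#' @param turns number of turns N per spiral (per lobe for figure-8).
#' @param wire_width_mm radial width W of the wire cross-section, mm.
#' @param wire_height_mm axial height of the wire cross-section, mm.
#' @param turn_gap_mm spacing S between adjacent turns, mm.
#' @param current_A peak drive current, A.
#' @param voltage_V drive voltage, V (carried for reporting; not used by
#'   the magnetostatic solver).
#' @param frequency_Hz pulse repetition frequency, Hz (carried for
#'   reporting; the induced-field stage uses an effective angular
#'   frequency instead, see [calibrate_drive()]).
#' @param label free-text name used in reports.
#' @param validate if `FALSE`, skip invariant checks (used for
#'   deliberately degenerate specs in limiting-case analysis).
#'
#' @return an object of class `coil_spec`.
#' @seealso [coil_area()], [wheeler_inductance()], [peak_field_estimate()],
#'   [build_winding()]
#' @export
coil_spec <- function(topology = c("circular", "figure8"),
                      inner_diameter_mm = 20,
                      outer_diameter_mm = 65,
                      turns = 7,
                      wire_width_mm = 3,
                      wire_height_mm = 2,
                      turn_gap_mm = 0.2,
                      current_A = 1000,
                      voltage_V = 500,
                      frequency_Hz = 20,
                      label = "murine circular coil",
                      validate = TRUE) {
  topology <- match.arg(topology)
  spec <- structure(list(
    topology = topology,
    inner_diameter_mm = as.numeric(inner_diameter_mm),
    outer_diameter_mm = as.numeric(outer_diameter_mm),
    turns = as.integer(round(turns)),
    wire_width_mm = as.numeric(wire_width_mm),
    wire_height_mm = as.numeric(wire_height_mm),
    turn_gap_mm = as.numeric(turn_gap_mm),
    current_A = as.numeric(current_A),
    voltage_V = as.numeric(voltage_V),
    frequency_Hz = as.numeric(frequency_Hz),
    label = as.character(label)
  ), class = "coil_spec")
  if (validate) validate_coil_spec(spec)
  spec
}

#' Validate a coil specification
#'
#' Checks the geometric invariants: positive bore, at least one turn,
#' positive wire cross-section, non-negative gap and current, and outer
#' diameter consistent with spiral growth,
#' `|D_o - (D_i + 2 N (W + S))| <= W + S`.
#'
#' @param spec a [coil_spec()].
#' @return `spec`, invisibly; stops with the violated invariant otherwise.
#' @export
validate_coil_spec <- function(spec) {
  stopifnot(inherits(spec, "coil_spec"))
  fail <- function(msg) stop("invalid coil_spec: ", msg, call. = FALSE)
  with(spec, {
    if (!(inner_diameter_mm > 0)) fail("inner_diameter_mm must be > 0")
    if (!(turns >= 1)) fail("turns must be >= 1")
    if (!(wire_width_mm > 0)) fail("wire_width_mm must be > 0")
    if (!(wire_height_mm > 0)) fail("wire_height_mm must be > 0")
    if (!(turn_gap_mm >= 0)) fail("turn_gap_mm must be >= 0")
    if (!(current_A >= 0)) fail("current_A must be >= 0")
    pitch <- wire_width_mm + turn_gap_mm
    grown <- inner_diameter_mm + 2 * turns * pitch
    if (abs(outer_diameter_mm - grown) > pitch)
      fail(sprintf(
        "outer_diameter_mm (%.3g) inconsistent with spiral growth (%.3g)",
        outer_diameter_mm, grown))
  })
  invisible(spec)
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf("<coil_spec> %s [%s]\n", x$label, x$topology))
  cat(sprintf("  Di %.4g mm, Do %.4g mm, N %d, wire %.3g x %.3g mm, gap %.3g mm\n",
              x$inner_diameter_mm, x$outer_diameter_mm, x$turns,
              x$wire_width_mm, x$wire_height_mm, x$turn_gap_mm))
  cat(sprintf("  drive %.4g A, %.4g V, %.4g Hz\n",
              x$current_A, x$voltage_V, x$frequency_Hz))
  invisible(x)
}

#' Flat-spiral cross-section radius parameter
#'
#' The radius-like parameter `A = (D_i + N (W + S)) / 2` of the
#' Wheeler flat-spiral inductance formula: the mean of the inner radius
#' and the outer radius reached after N turns of pitch W + S. Returned
#' in the same unit as the spec lengths (mm).
#'
#' @param spec a [coil_spec()]; degenerate specs (built with
#'   `validate = FALSE`) are accepted, in which case the formula
#'   collapses towards the inner radius as N -> 0.
#' @return A in mm.
#' @export
coil_area <- function(spec) {
  stopifnot(inherits(spec, "coil_spec"))
  # negative gaps are tolerated here (degenerate analysis) and surface
  # as a non-physical-geometry error in wheeler_inductance instead
  if (spec$inner_diameter_mm <= 0 || spec$wire_width_mm < 0 ||
      spec$turns < 0)
    stop("invalid coil_spec: non-physical lengths for coil_area")
  (spec$inner_diameter_mm +
     spec$turns * (spec$wire_width_mm + spec$turn_gap_mm)) / 2
}

#' Wheeler inductance of a flat spiral coil
#'
#' Evaluates the empirical Harold Wheeler low-frequency flat-spiral
#' formula `L = N^2 A^2 / (30 A - 11 D_i)`, which yields microhenries
#' when lengths are expressed in inches. Spec lengths (mm) are converted
#' to inches internally; the unit convention is the reason the printed
#' design value for the default murine coil is ~2 uH rather than an
#' order-of-magnitude different number.
#'
#' @param spec a [coil_spec()].
#' @return inductance in microhenry.
#' @export
wheeler_inductance <- function(spec) {
  stopifnot(inherits(spec, "coil_spec"))
  if (spec$turns == 0) return(0)
  A_in <- mm_to_in(coil_area(spec))
  Di_in <- mm_to_in(spec$inner_diameter_mm)
  den <- 30 * A_in - 11 * Di_in
  if (den <= 0) stop("non-physical geometry: 30 A - 11 Di <= 0")
  spec$turns^2 * A_in^2 / den
}

#' Closed-form coil-centre flux density estimate
#'
#' The loop-stack centre estimate `B = mu0 N I / (2 R)`. The radius
#' convention defaults to the inner radius `R = D_i / 2`, which is the
#' convention that reproduces the design-stage value for the murine
#' coil (0.44 T); the outer and mean radius conventions are provided
#' for sensitivity analysis.
#'
#' @param spec a [coil_spec()].
#' @param radius_convention one of `"inner_radius"`, `"outer_radius"`,
#'   `"mean_radius"`.
#' @return flux density in tesla.
#' @export
peak_field_estimate <- function(spec,
                                radius_convention = c("inner_radius",
                                                      "outer_radius",
                                                      "mean_radius")) {
  stopifnot(inherits(spec, "coil_spec"))
  radius_convention <- match.arg(radius_convention)
  R_mm <- switch(radius_convention,
    inner_radius = spec$inner_diameter_mm / 2,
    outer_radius = spec$outer_diameter_mm / 2,
    mean_radius  = (spec$inner_diameter_mm + spec$outer_diameter_mm) / 4)
  if (R_mm <= 0) stop("radius must be > 0")
  MU0 * spec$turns * spec$current_A / (2 * mm_to_m(R_mm))
}

#' Closed-form design report for a coil
#'
#' Bundles the three design estimates into a `design_estimates` object:
#' the cross-section parameter A (mm), the Wheeler inductance (uH) and
#' the coil-centre flux density (T) under the chosen radius convention.
#'
#' @inheritParams peak_field_estimate
#' @return object of class `design_estimates` with fields `area_mm`,
#'   `inductance_uH`, `peak_field_T`, `radius_convention`.
#' @export
design_report <- function(spec, radius_convention = "inner_radius") {
  est <- list(
    area_mm = coil_area(spec),
    inductance_uH = wheeler_inductance(spec),
    peak_field_T = peak_field_estimate(spec, radius_convention),
    radius_convention = radius_convention
  )
  stopifnot(est$inductance_uH >= 0, est$peak_field_T >= 0,
            est$area_mm >= spec$inner_diameter_mm / 2)
  structure(est, class = "design_estimates", spec = spec)
}

#' @export
print.design_estimates <- function(x, ...) {
  cat("<design_estimates>\n")
  cat(sprintf("  A = %.4g mm, L = %.4g uH, B = %.4g T (%s)\n",
              x$area_mm, x$inductance_uH, x$peak_field_T,
              x$radius_convention))
  invisible(x)
}

#' Read a coil specification from a JSON config file
#'
#' The config is a flat JSON object with keys `topology`,
#' `inner_diameter_mm`, `outer_diameter_mm`, `turns`, `wire_width_mm`,
#' `wire_height_mm`, `turn_gap_mm`, `current_A`, `voltage_V`,
#' `frequency_Hz` and optionally `label`.
#'
#' @param path path to the JSON file.
#' @return a validated [coil_spec()].
#' @export
read_coil_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  required <- c("topology", "inner_diameter_mm", "outer_diameter_mm",
                "turns", "wire_width_mm", "wire_height_mm", "turn_gap_mm",
                "current_A", "voltage_V", "frequency_Hz")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("coil config missing keys: ", paste(missing, collapse = ", "))
  coil_spec(topology = cfg$topology,
            inner_diameter_mm = cfg$inner_diameter_mm,
            outer_diameter_mm = cfg$outer_diameter_mm,
            turns = cfg$turns,
            wire_width_mm = cfg$wire_width_mm,
            wire_height_mm = cfg$wire_height_mm,
            turn_gap_mm = cfg$turn_gap_mm,
            current_A = cfg$current_A,
            voltage_V = cfg$voltage_V,
            frequency_Hz = cfg$frequency_Hz,
            label = if (is.null(cfg$label)) basename(path) else cfg$label)
}

#' Write a design report as JSON
#'
#' @param report a [design_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_estimates"))
  jsonlite::write_json(
    list(area_mm = report$area_mm,
         inductance_uH = report$inductance_uH,
         peak_field_T = report$peak_field_T,
         radius_convention = report$radius_convention),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
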
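#' Discretize a coil spec into a filamentary winding model
#'
#' Each turn of the flat spiral becomes one filamentary circular loop at
#' its centerline radius `Di/2 + W/2 + k (W + S)`, k = 0..N-1, in the
#' plane z = 0 with normal +z (the subject side). The rectangular
#' W x height wire cross-section is retained only through the
#' geometric-mean-distance equivalent wire radius `0.2235 (W + h)`,
#' used by the inductance formulas and the near-field clamp.
#'
#' For the figure-8 topology, two identical lobes of opposite current
#' sign are placed side by side on the x axis, tangent and
#' non-overlapping: the centre-to-centre separation equals the lobe's
#' physical outer diameter `2 (a_max + W/2)`.
#'
#' @param spec a [coil_spec()].
#' @return an object of class `winding_model`: a list with a data frame
#'   `loops` (`cx_mm`, `cy_mm`, `cz_mm`, `radius_mm`, `current_A` signed;
#'   all normals +z), `equivalent_wire_radius_mm`, and the source `spec`.
#' @export
build_winding <- function(spec) {
  # a negative drive current is a polarity reversal, not a geometry error
  geom <- spec
  geom$current_A <- abs(spec$current_A)
  validate_coil_spec(geom)
  k <- seq_len(spec$turns) - 1
  a <- spec$inner_diameter_mm / 2 + spec$wire_width_mm / 2 +
    k * (spec$wire_width_mm + spec$turn_gap_mm)
  rw <- 0.2235 * (spec$wire_width_mm + spec$wire_height_mm)
  if (spec$topology == "circular") {
    loops <- data.frame(cx_mm = 0, cy_mm = 0, cz_mm = 0,
                        radius_mm = a, current_A = spec$current_A)
  } else if (spec$topology == "figure8") {
    lobe_outer_r <- max(a) + spec$wire_width_mm / 2
    sep <- 2 * lobe_outer_r   # tangent lobes
    loops <- rbind(
      data.frame(cx_mm = -sep / 2, cy_mm = 0, cz_mm = 0,
                 radius_mm = a, current_A = spec$current_A),
      data.frame(cx_mm = +sep / 2, cy_mm = 0, cz_mm = 0,
                 radius_mm = a, current_A = -spec$current_A))
  } else {
    stop("unsupported topology: ", spec$topology)
  }
  structure(list(loops = loops,
                 equivalent_wire_radius_mm = rw,
                 spec = spec),
            class = "winding_model")
}

#' @export
print.winding_model <- function(x, ...) {
  cat(sprintf("<winding_model> %d loops (%s), r_wire %.3g mm\n",
              nrow(x$loops), x$spec$topology, x$equivalent_wire_radius_mm))
  cat(sprintf("  radii %s mm\n",
              paste(format(sort(unique(x$loops$radius_mm))), collapse = ", ")))
  invisible(x)
}
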
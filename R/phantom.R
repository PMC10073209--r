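#' Tissue layer of the murine head phantom
#'
#' @param name tissue name.
#' @param thickness_um layer thickness, micrometres (> 0).
#' @param permittivity relative permittivity (>= 1). Carried in the data
#'   model for completeness; it does not enter the default quasi-static
#'   computation.
#' @param conductivity_S_per_m electrical conductivity, S/m (>= 0).
#' @return object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness_um, permittivity,
                         conductivity_S_per_m) {
  if (!(is.finite(thickness_um) && thickness_um > 0))
    stop("tissue_layer: thickness_um must be > 0")
  if (!(is.finite(permittivity) && permittivity >= 1))
    stop("tissue_layer: permittivity must be >= 1")
  if (!(is.finite(conductivity_S_per_m) && conductivity_S_per_m >= 0))
    stop("tissue_layer: conductivity_S_per_m must be >= 0")
  structure(list(name = as.character(name),
                 thickness_um = thickness_um,
                 permittivity = permittivity,
                 conductivity_S_per_m = conductivity_S_per_m),
            class = "tissue_layer")
}

#' Layered murine head phantom
#'
#' An ordered outer-to-inner stack of [tissue_layer()]s plus the
#' coil-to-scalp standoff. The default stack is the five quantified
#' murine tissues (scalp, skull, dura mater, arachnoid, brain); the
#' depth from the scalp surface to the brain surface is then the sum of
#' the four non-brain thicknesses, 1.875 mm.
#'
#' @param layers list of [tissue_layer()]s, ordered outer to inner.
#' @param standoff_mm coil-to-scalp gap, mm (>= 0).
#' @return object of class `head_phantom`.
#' @export
head_phantom <- function(layers, standoff_mm = 0) {
  if (!length(layers)) stop("head_phantom: empty layer list")
  if (!all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop("head_phantom: all layers must be tissue_layer objects")
  if (standoff_mm < 0) stop("head_phantom: standoff_mm must be >= 0")
  structure(list(layers = layers, standoff_mm = standoff_mm),
            class = "head_phantom")
}

#' Default five-layer murine head phantom
#'
#' Scalp (500 um, eps 3056, 0.0009 S/m), skull (1000, 1246, 0.0203),
#' dura mater (300, 2360, 0.5010), arachnoid (75, 3013, 0.0650), brain
#' (890, 6683, 0.1056).
#'
#' @param standoff_mm coil-to-scalp gap, mm.
#' @return a [head_phantom()].
#' @export
default_head_phantom <- function(standoff_mm = 0) {
  head_phantom(list(
    tissue_layer("scalp",      500, 3056, 0.0009),
    tissue_layer("skull",     1000, 1246, 0.0203),
    tissue_layer("dura",       300, 2360, 0.5010),
    tissue_layer("arachnoid",   75, 3013, 0.0650),
    tissue_layer("brain",      890, 6683, 0.1056)
  ), standoff_mm = standoff_mm)
}

#' @export
print.head_phantom <- function(x, ...) {
  cat(sprintf("<head_phantom> %d layers, standoff %.3g mm\n",
              length(x$layers), x$standoff_mm))
  for (l in x$layers)
    cat(sprintf("  %-10s %6g um  eps_r %5g  sigma %.4g S/m\n",
                l$name, l$thickness_um, l$permittivity,
                l$conductivity_S_per_m))
  invisible(x)
}

#' Depth of the brain surface below the scalp surface
#'
#' Sum of the thicknesses of all layers above the innermost (brain)
#' layer, in mm (1.875 mm for the default stack).
#'
#' @param phantom a [head_phantom()].
#' @return depth in mm.
#' @export
brain_surface_depth <- function(phantom) {
  stopifnot(inherits(phantom, "head_phantom"))
  n <- length(phantom$layers)
  if (n == 1) return(0)
  sum(vapply(phantom$layers[-n], `[[`, numeric(1), "thickness_um")) / 1000
}

#' Total phantom thickness in mm
#' @param phantom a [head_phantom()].
#' @return thickness in mm.
#' @export
phantom_thickness <- function(phantom) {
  sum(vapply(phantom$layers, `[[`, numeric(1), "thickness_um")) / 1000
}

#' Read a phantom from a JSON config file
#'
#' The config holds an array `layers` of objects with keys `tissue`,
#' `thickness_um`, `permittivity`, `conductivity_S_per_m` (ordered outer
#' to inner) and optionally `standoff_mm`.
#'
#' @param path path to the JSON file.
#' @return a [head_phantom()].
#' @export
read_phantom_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(cfg$layers)) stop("phantom config missing 'layers'")
  ld <- cfg$layers
  layers <- lapply(seq_len(nrow(ld)), function(i)
    tissue_layer(ld$tissue[i], ld$thickness_um[i], ld$permittivity[i],
                 ld$conductivity_S_per_m[i]))
  head_phantom(layers,
               standoff_mm = if (is.null(cfg$standoff_mm)) 0 else cfg$standoff_mm)
}

#' Write a phantom to a JSON config file
#' @param phantom a [head_phantom()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(phantom, path) {
  stopifnot(inherits(phantom, "head_phantom"))
  layers <- data.frame(
    tissue = vapply(phantom$layers, `[[`, character(1), "name"),
    thickness_um = vapply(phantom$layers, `[[`, numeric(1), "thickness_um"),
    permittivity = vapply(phantom$layers, `[[`, numeric(1), "permittivity"),
    conductivity_S_per_m = vapply(phantom$layers, `[[`, numeric(1),
                                  "conductivity_S_per_m"))
  jsonlite::write_json(list(layers = layers,
                            standoff_mm = phantom$standoff_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Azimuthal vector potential A_phi (T m) of the winding's loop stack at
# cylindrical (rho_m, z_m), loops coaxial about the winding axis.
# Closed form in complete elliptic integrals. Circular topology only.
aphi_stack <- function(winding, rho_m, z_m) {
  lp <- winding$loops
  A <- numeric(length(rho_m))
  pos <- rho_m > 0
  if (!any(pos)) return(A)
  for (i in seq_len(nrow(lp))) {
    a_m <- mm_to_m(lp$radius_mm[i])
    I <- lp$current_A[i]
    rho <- rho_m[pos]; z <- z_m[pos] - mm_to_m(lp$cz_mm[i])
    Q <- (a_m + rho)^2 + z^2
    m <- pmin(4 * a_m * rho / Q, 1 - 1e-15)
    ke <- ellipke(m)
    A[pos] <- A[pos] + MU0 / (4 * pi) * 4 * I * a_m / sqrt(Q) *
      (((2 - m) * ke$K - 2 * ke$E) / m)
  }
  A
}

# Maximum of |A_phi| over the in-plane radius at axial position z_m.
# The stack potential is unimodal in rho; coarse grid plus golden-section
# refinement via optimize().
aphi_max <- function(winding, z_m) {
  rmax <- mm_to_m(max(winding$loops$radius_mm) * 2)
  grid <- seq(1e-5, rmax, length.out = 80)
  vals <- abs(aphi_stack(winding, grid, rep(z_m, length(grid))))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  op <- stats::optimize(function(r)
    -abs(aphi_stack(winding, r, z_m)), c(lo, hi), tol = 1e-10)
  list(value = -op$objective, rho_m = op$minimum)
}

#' Quasi-static induced electric field profile in the phantom
#'
#' Under the TMS quasi-static approximation the tissue does not perturb
#' the coil field, and for an axisymmetric (circular) winding the
#' induced field is purely azimuthal with no charge-accumulation term:
#' `E_phi(rho, z) = omega * A_phi(rho, z)`, where `A_phi` is the
#' magnetic vector potential of the loop stack and `omega` the effective
#' angular frequency of the pulse. At each depth the magnitude is
#' reported on the ring of maximal |A_phi|. Tangential continuity across
#' layer boundaries is automatic: conductivity and permittivity are
#' carried in the phantom but do not enter this primary-field estimate.
#'
#' @param winding circular-topology [build_winding()] result; the coil
#'   plane sits `standoff_mm` above the scalp surface.
#' @param phantom a [head_phantom()].
#' @param omega_rad_s effective angular frequency, rad/s (see
#'   [calibrate_drive()]).
#' @param depths_mm depths below the scalp surface at which to evaluate,
#'   mm; defaults to a uniform grid through the full stack.
#' @return object of class `efield_profile`: data frame with columns
#'   `depth_mm`, `E_V_per_m`, `ring_radius_mm`, with attributes
#'   `omega_rad_s` and `standoff_mm`.
#' @export
induced_efield <- function(winding, phantom, omega_rad_s,
                           depths_mm = NULL) {
  stopifnot(inherits(winding, "winding_model"),
            inherits(phantom, "head_phantom"))
  if (winding$spec$topology != "circular")
    stop("not supported: induced_efield requires an axisymmetric ",
         "(circular) winding; use field maps for figure-8 coils")
  if (omega_rad_s < 0) stop("omega_rad_s must be >= 0")
  if (is.null(depths_mm))
    depths_mm <- seq(0, phantom_thickness(phantom), length.out = 112)
  res <- lapply(depths_mm, function(d) {
    am <- aphi_max(winding, mm_to_m(phantom$standoff_mm + d))
    c(E = omega_rad_s * am$value, r = am$rho_m * 1e3)
  })
  res <- do.call(rbind, res)
  structure(data.frame(depth_mm = depths_mm,
                       E_V_per_m = res[, "E"],
                       ring_radius_mm = res[, "r"]),
            class = c("efield_profile", "data.frame"),
            omega_rad_s = omega_rad_s,
            standoff_mm = phantom$standoff_mm)
}

#' Calibrate the effective drive frequency to a target E-field
#'
#' The effective spectral content of the stimulator pulse is not a
#' design input (the repetition rate, e.g. 20 Hz, is orders of magnitude
#' too slow to produce cortical fields of order 100 V/m); instead the
#' effective angular frequency is recovered from a target field value:
#' `omega = E_target / max_rho |A_phi|` at the requested depth. Feeding
#' the result back into [induced_efield()] reproduces the target
#' exactly, by construction.
#'
#' @param winding circular-topology [build_winding()] result.
#' @param phantom a [head_phantom()].
#' @param target_e_V_per_m target field magnitude, V/m (> 0).
#' @param depth_mm depth below the scalp surface, mm; defaults to the
#'   brain surface.
#' @return effective angular frequency in rad/s.
#' @export
calibrate_drive <- function(winding, phantom, target_e_V_per_m,
                            depth_mm = brain_surface_depth(phantom)) {
  stopifnot(inherits(winding, "winding_model"),
            inherits(phantom, "head_phantom"))
  if (!(target_e_V_per_m > 0)) stop("target_e_V_per_m must be > 0")
  am <- aphi_max(winding, mm_to_m(phantom$standoff_mm + depth_mm))
  if (am$value <= 0)
    stop("|A_phi| vanishes at the requested depth; cannot calibrate")
  target_e_V_per_m / am$value
}
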
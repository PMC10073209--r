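# Field of a single filamentary circular loop, loop frame: centre at the
# origin, loop in the z = 0 plane, radius a_m (metres), current I (A).
# Inputs rho_m, z_m are equal-length vectors; returns list(Brho, Bz) in
# tesla. Exact off-axis solution in complete elliptic integrals.
loop_field_elliptic <- function(a_m, I, rho_m, z_m) {
  Q <- (a_m + rho_m)^2 + z_m^2
  m <- 4 * a_m * rho_m / Q
  m <- pmin(pmax(m, 0), 1 - 1e-15)  # guard on-wire singular limit
  ke <- ellipke(m)
  den <- (a_m - rho_m)^2 + z_m^2
  pref <- MU0 * I / (2 * pi * sqrt(Q))
  Bz <- pref * (ke$K + (a_m^2 - rho_m^2 - z_m^2) / den * ke$E)
  Brho <- ifelse(rho_m > 0,
    pref * z_m / rho_m * (-ke$K + (a_m^2 + rho_m^2 + z_m^2) / den * ke$E),
    0)
  list(Brho = Brho, Bz = Bz)
}

# Same loop, segment-discretized Biot-Savart (nseg straight segments).
# Kept as an independent route for verification of the elliptic solution.
loop_field_segments <- function(a_m, I, rho_m, z_m, nseg = 1024) {
  phi <- (seq_len(nseg) - 0.5) * 2 * pi / nseg
  dphi <- 2 * pi / nseg
  sx <- a_m * cos(phi); sy <- a_m * sin(phi)       # segment midpoints
  dlx <- -a_m * sin(phi) * dphi; dly <- a_m * cos(phi) * dphi
  n <- length(rho_m)
  Brho <- numeric(n); Bz <- numeric(n)
  for (i in seq_len(n)) {
    rx <- rho_m[i] - sx; ry <- -sy; rz <- z_m[i]
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    # dl x r
    cx <- dly * rz
    cy <- -dlx * rz
    cz <- dlx * ry - dly * rx
    f <- MU0 * I / (4 * pi)
    Brho[i] <- f * sum(cx / r3)    # field x-component at point (rho,0,z)
    Bz[i] <- f * sum(cz / r3)
  }
  list(Brho = Brho, Bz = Bz)
}

# Clamp points closer to the loop centerline than the equivalent wire
# radius onto the wire surface (radially in the (rho, z) half-plane).
# Returns adjusted (rho, z) and the number of clamped points.
clamp_to_wire <- function(a_m, rho_m, z_m, rw_m) {
  d <- sqrt((rho_m - a_m)^2 + z_m^2)
  near <- d < rw_m
  n_clamped <- sum(near)
  if (n_clamped) {
    on_axis <- near & d == 0
    sc <- ifelse(d > 0, rw_m / d, 1)
    rho_m[near] <- a_m + (rho_m[near] - a_m) * sc[near]
    z_m[near] <- z_m[near] * sc[near]
    z_m[on_axis] <- rw_m
  }
  list(rho = rho_m, z = z_m, n_clamped = n_clamped)
}

#' Magnetic flux density of a winding at arbitrary points
#'
#' Vector sum of the exact (complete-elliptic-integral) fields of all
#' filamentary loops of the winding: the quasi-static tissue currents are
#' assumed too weak to perturb this source field. Points closer to a
#' loop centerline than the equivalent wire radius are clamped to the
#' wire surface (the filament field diverges on the centerline while the
#' real field stays finite inside the conductor); the number of clamped
#' points is reported in the `n_clamped` attribute.
#'
#' @param winding a [build_winding()] result.
#' @param points_mm numeric matrix with columns x, y, z in mm (one row
#'   per evaluation point).
#' @param method `"elliptic"` (default, exact) or `"segments"`
#'   (straight-segment Biot-Savart, for cross-checking).
#' @param nseg number of segments per loop for `method = "segments"`.
#' @return an n x 3 matrix of B vectors in tesla, with attribute
#'   `n_clamped`.
#' @export
bfield_at_points <- function(winding, points_mm,
                             method = c("elliptic", "segments"),
                             nseg = 1024) {
  stopifnot(inherits(winding, "winding_model"))
  method <- match.arg(method)
  pts <- as.matrix(points_mm)
  if (ncol(pts) != 3) stop("points_mm must have 3 columns (x, y, z in mm)")
  P <- mm_to_m(pts)
  rw_m <- mm_to_m(winding$equivalent_wire_radius_mm)
  B <- matrix(0, nrow(P), 3)
  total_clamped <- 0L
  lp <- winding$loops
  for (i in seq_len(nrow(lp))) {
    a_m <- mm_to_m(lp$radius_mm[i])
    cx <- mm_to_m(lp$cx_mm[i]); cy <- mm_to_m(lp$cy_mm[i])
    cz <- mm_to_m(lp$cz_mm[i])
    dx <- P[, 1] - cx; dy <- P[, 2] - cy; dz <- P[, 3] - cz
    rho <- sqrt(dx^2 + dy^2)
    cl <- clamp_to_wire(a_m, rho, dz, rw_m)
    total_clamped <- total_clamped + cl$n_clamped
    f <- if (method == "elliptic")
      loop_field_elliptic(a_m, lp$current_A[i], cl$rho, cl$z)
    else
      loop_field_segments(a_m, lp$current_A[i], cl$rho, cl$z, nseg)
    ux <- ifelse(rho > 0, dx / rho, 0)
    uy <- ifelse(rho > 0, dy / rho, 0)
    B[, 1] <- B[, 1] + f$Brho * ux
    B[, 2] <- B[, 2] + f$Brho * uy
    B[, 3] <- B[, 3] + f$Bz
  }
  attr(B, "n_clamped") <- total_clamped
  B
}

#' Field-magnitude map on a plane parallel to the coil
#'
#' Samples |B| (vector magnitude) on a square grid on the plane
#' z = `distance_mm` (coil plane z = 0, subject side +z), centred on the
#' coil axis.
#'
#' @param winding a [build_winding()] result.
#' @param distance_mm coil-to-plane distance, mm (>= 0).
#' @param extent_mm full side length of the square observation window, mm.
#' @param spacing_mm grid spacing, mm.
#' @param keep_components if `TRUE`, retain the Bx, By, Bz grids.
#' @return object of class `field_map`: list with `x_mm`, `y_mm` (axis
#'   coordinates), `values` (|B| matrix, tesla, rows indexed by x),
#'   `distance_mm`, `spacing_mm`, optionally `components`.
#' @export
field_map_on_plane <- function(winding, distance_mm, extent_mm = 130,
                               spacing_mm = 1, keep_components = FALSE) {
  stopifnot(inherits(winding, "winding_model"))
  if (distance_mm < 0) stop("distance_mm must be >= 0")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  half <- extent_mm / 2
  x <- seq(-half, half, by = spacing_mm)
  if (length(x) < 2) stop("empty grid: extent smaller than spacing")
  g <- expand.grid(x = x, y = x)
  pts <- cbind(g$x, g$y, distance_mm)
  B <- bfield_at_points(winding, pts)
  mag <- matrix(sqrt(rowSums(B^2)), nrow = length(x))
  out <- list(x_mm = x, y_mm = x, values = mag,
              distance_mm = distance_mm, spacing_mm = spacing_mm,
              n_clamped = attr(B, "n_clamped"))
  if (keep_components)
    out$components <- lapply(1:3, function(j)
      matrix(B[, j], nrow = length(x)))
  structure(out, class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d grid, spacing %.3g mm, plane at %.3g mm\n",
              length(x$x_mm), length(x$y_mm), x$spacing_mm, x$distance_mm))
  cat(sprintf("  |B| range %.4g .. %.4g T\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Peak field versus coil-target distance
#'
#' For each distance, samples a plane map and records the maximum |B|
#' over the observation window. Physics guarantees a strictly decreasing
#' sequence for single-lobe windings with ascending distances.
#'
#' @param winding a [build_winding()] result.
#' @param distances_mm ascending distances, mm.
#' @param extent_mm,spacing_mm observation window passed to
#'   [field_map_on_plane()].
#' @return object of class `distance_sweep`: data frame with columns
#'   `distance_mm`, `peak_B_T`.
#' @export
distance_sweep <- function(winding, distances_mm = c(0, 2, 5, 8, 10),
                           extent_mm = 130, spacing_mm = 1) {
  stopifnot(inherits(winding, "winding_model"))
  if (is.unsorted(distances_mm, strictly = TRUE))
    stop("distances_mm must be sorted strictly ascending")
  peak <- vapply(distances_mm, function(d) {
    max(field_map_on_plane(winding, d, extent_mm, spacing_mm)$values)
  }, numeric(1))
  structure(data.frame(distance_mm = distances_mm, peak_B_T = peak),
            class = c("distance_sweep", "data.frame"))
}
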
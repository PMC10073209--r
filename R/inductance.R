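#' Self-inductance of a single circular loop
#'
#' Closed form `mu0 a (ln(8 a / r_w) - 2)` for a thin circular loop of
#' radius `a` and wire radius `r_w` (uniform current, external plus
#' internal inductance neglected beyond the -2 constant).
#'
#' @param radius_mm loop centerline radius, mm.
#' @param wire_radius_mm equivalent wire radius, mm.
#' @return inductance in microhenry.
#' @export
loop_self_inductance <- function(radius_mm, wire_radius_mm) {
  a <- mm_to_m(radius_mm); rw <- mm_to_m(wire_radius_mm)
  stopifnot(a > 0, rw > 0, rw < a)
  MU0 * a * (log(8 * a / rw) - 2) * 1e6
}

#' Mutual inductance of two coaxial circular loops
#'
#' Neumann-formula closed form in complete elliptic integrals for two
#' coaxial loops of radii a, b with axial separation z:
#' `M = mu0 sqrt(a b) ((2/k - k) K(m) - (2/k) E(m))`, `m = k^2 =
#' 4 a b / ((a + b)^2 + z^2)`.
#'
#' @param a_mm,b_mm loop radii, mm.
#' @param z_mm axial separation of the loop planes, mm (0 for coplanar
#'   concentric loops).
#' @return mutual inductance in microhenry.
#' @export
loop_mutual_inductance <- function(a_mm, b_mm, z_mm = 0) {
  a <- mm_to_m(a_mm); b <- mm_to_m(b_mm); z <- mm_to_m(z_mm)
  stopifnot(a > 0, b > 0)
  m <- 4 * a * b / ((a + b)^2 + z^2)
  if (m >= 1) stop("coincident loops: mutual inductance diverges")
  k <- sqrt(m)
  ke <- ellipke(m)
  MU0 * sqrt(a * b) * ((2 / k - k) * ke$K - (2 / k) * ke$E) * 1e6
}

#' Neumann partial-inductance of a flat spiral winding
#'
#' Independent (non-Wheeler) self-inductance of the filamentary loop
#' stack: the sum of per-loop self terms and all pairwise coaxial
#' coplanar Neumann mutual terms. Serves as the desk-scale counterpart
#' of an FEM inductance extraction for the same coil.
#'
#' @param winding a [build_winding()] result with circular topology.
#' @return inductance in microhenry.
#' @export
neumann_self_inductance <- function(winding) {
  stopifnot(inherits(winding, "winding_model"))
  if (winding$spec$topology != "circular")
    stop("neumann_self_inductance supports circular topology only")
  a <- winding$loops$radius_mm
  rw <- winding$equivalent_wire_radius_mm
  if (any(diff(sort(a)) < 2 * rw))
    stop("overlapping loops: centerline spacing below wire diameter")
  L <- sum(vapply(a, loop_self_inductance, numeric(1),
                  wire_radius_mm = rw))
  n <- length(a)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        L <- L + 2 * loop_mutual_inductance(a[i], a[j])
      }
    }
  }
  L
}
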
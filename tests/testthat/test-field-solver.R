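test_that("AGM elliptic integrals agree with reference values", {
  # frozen from scipy.special.ellipk / ellipe (parameter m = k^2)
  m <- c(0, 0.1, 0.5, 0.9, 0.99)
  K_ref <- c(1.570796326794897, 1.612441348720219, 1.854074677301372,
             2.578092113348173, 3.695637362989875)
  E_ref <- c(1.570796326794897, 1.530757636897763, 1.350643881047676,
             1.104774732704073, 1.015993545025224)
  ke <- rtmscoil:::ellipke(m)
  expect_equal(ke$K, K_ref, tolerance = 1e-14)
  expect_equal(ke$E, E_ref, tolerance = 1e-14)
  expect_error(rtmscoil:::ellipke(1), "m must lie")
})

test_that("build_winding lays out the loop stack", {
  w <- build_winding(murine_spec())
  expect_equal(w$loops$radius_mm,
               c(11.5, 14.7, 17.9, 21.1, 24.3, 27.5, 30.7))
  expect_equal(w$loops$current_A, rep(1000, 7))
  expect_equal(w$equivalent_wire_radius_mm, 0.2235 * 5)

  # figure-8: 14 loops, two lobes of opposite sign, ampere-turns N*I/lobe
  f8 <- build_winding(murine_spec(topology = "figure8"))
  expect_equal(nrow(f8$loops), 14)
  expect_setequal(unique(f8$loops$current_A), c(1000, -1000))
  expect_equal(sum(f8$loops$current_A > 0), 7)
  # lobes tangent: separation equals the physical outer diameter
  expect_equal(sort(unique(f8$loops$cx_mm)), c(-32.2, 32.2))

  # reversing I negates every loop current
  rev <- build_winding(murine_spec(current_A = -1000, validate = FALSE))
  expect_equal(rev$loops$current_A, -w$loops$current_A)
})

test_that("single-loop field matches closed forms on and off axis", {
  w <- single_loop(a_mm = 10, current_A = 1000)
  # centre: mu0 I / (2 a)
  B0 <- bfield_at_points(w, rbind(c(0, 0, 0)))
  expect_equal(B0[1, 3], MU0 * 1000 / 0.02, tolerance = 1e-12)
  expect_equal(B0[1, 1:2], c(0, 0))

  # on axis at z = a: 2^(-3/2) of the centre value
  Bz <- bfield_at_points(w, rbind(c(0, 0, 10)))
  expect_equal(Bz[1, 3], B0[1, 3] * 2^(-1.5), tolerance = 1e-12)

  # off-axis reference point frozen from scipy (rho = 5, z = 7 mm)
  Boff <- bfield_at_points(w, rbind(c(5, 0, 7)))
  expect_equal(Boff[1, 1], 0.0127711483, tolerance = 1e-8)
  expect_equal(Boff[1, 3], 0.0308333011, tolerance = 1e-8)

  # zero current: zero vector everywhere
  w0 <- single_loop(a_mm = 10, current_A = 0)
  expect_equal(bfield_at_points(w0, rbind(c(3, 4, 5))),
               matrix(0, 1, 3), ignore_attr = TRUE)
})

test_that("elliptic and segment-discretized routes agree", {
  w <- build_winding(murine_spec())
  pts <- rbind(c(0, 0, 5), c(10, 5, 5), c(-20, 13, 8), c(35, 0, 3))
  Be <- bfield_at_points(w, pts, method = "elliptic")
  Bs <- bfield_at_points(w, pts, method = "segments", nseg = 1024)
  expect_equal(Bs, Be, tolerance = 1e-4)
})

test_that("superposition: figure-8 equals the sum of its lobes", {
  f8 <- build_winding(murine_spec(topology = "figure8"))
  lobe1 <- f8; lobe1$loops <- f8$loops[1:7, ]
  lobe2 <- f8; lobe2$loops <- f8$loops[8:14, ]
  pts <- rbind(c(0, 0, 5), c(20, -7, 5), c(-32.2, 0, 2))
  expect_equal(bfield_at_points(f8, pts),
               bfield_at_points(lobe1, pts) + bfield_at_points(lobe2, pts),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("near-conductor points are clamped and counted", {
  w <- single_loop(a_mm = 10, current_A = 1000)
  rw <- w$equivalent_wire_radius_mm
  on_wire <- bfield_at_points(w, rbind(c(10, 0, 0)))
  expect_equal(attr(on_wire, "n_clamped"), 1L)
  expect_true(all(is.finite(on_wire)))
  # clamped value matches evaluation on the wire surface
  surf <- bfield_at_points(w, rbind(c(10, 0, rw)))
  expect_equal(sqrt(sum(on_wire^2)), sqrt(sum(surf^2)), tolerance = 1e-9)
})

test_that("field maps are axisymmetric for the circular coil", {
  w <- build_winding(murine_spec())
  map <- field_map_on_plane(w, 5, extent_mm = 60, spacing_mm = 5)
  expect_s3_class(map, "field_map")
  expect_true(all(map$values >= 0))
  # mirror symmetry in x and y
  expect_equal(map$values, map$values[rev(seq_along(map$x_mm)), ],
               tolerance = 1e-9)
  expect_equal(map$values, map$values[, rev(seq_along(map$y_mm))],
               tolerance = 1e-9)
  expect_error(field_map_on_plane(w, -1), "distance_mm")
  expect_error(field_map_on_plane(w, 5, extent_mm = 0.1, spacing_mm = 1),
               "empty grid")
})

test_that("distance sweep decreases strictly and decays as a dipole", {
  w <- build_winding(murine_spec())
  sw <- distance_sweep(w, c(0, 2, 5, 8, 10), extent_mm = 80,
                       spacing_mm = 2)
  expect_true(all(diff(sw$peak_B_T) < 0))
  expect_error(distance_sweep(w, c(5, 2)), "ascending")

  # far field: log-log slope -3 between 200 and 400 mm
  far <- distance_sweep(w, c(200, 400), extent_mm = 40, spacing_mm = 4)
  slope <- diff(log(far$peak_B_T)) / diff(log(far$distance_mm))
  expect_equal(slope, -3, tolerance = 0.035)

  # zero-current winding sweeps to all zeros
  w0 <- build_winding(murine_spec(current_A = 0))
  sw0 <- distance_sweep(w0, c(2, 5), extent_mm = 40, spacing_mm = 4)
  expect_equal(sw0$peak_B_T, c(0, 0))
})
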
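test_that("default phantom is the five-layer murine stack", {
  ph <- default_head_phantom()
  expect_length(ph$layers, 5)
  expect_equal(vapply(ph$layers, `[[`, character(1), "name"),
               c("scalp", "skull", "dura", "arachnoid", "brain"))
  expect_equal(vapply(ph$layers, `[[`, numeric(1), "thickness_um"),
               c(500, 1000, 300, 75, 890))
  expect_equal(vapply(ph$layers, `[[`, numeric(1), "conductivity_S_per_m"),
               c(0.0009, 0.0203, 0.5010, 0.0650, 0.1056))
  expect_equal(vapply(ph$layers, `[[`, numeric(1), "permittivity"),
               c(3056, 1246, 2360, 3013, 6683))
  expect_equal(brain_surface_depth(ph), 1.875)
  expect_equal(phantom_thickness(ph), 2.765)
})

test_that("phantom validation rejects bad input", {
  expect_error(head_phantom(list()), "empty")
  expect_error(tissue_layer("x", -1, 100, 0.1), "thickness")
  expect_error(tissue_layer("x", 10, 0.5, 0.1), "permittivity")
  expect_error(tissue_layer("x", 10, 100, -0.1), "conductivity")
})

test_that("phantom config round trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  ph <- default_head_phantom(standoff_mm = 2)
  write_phantom_config(ph, path)
  back <- read_phantom_config(path)
  expect_equal(back, ph)
})

test_that("bundled phantom config matches the in-code default", {
  path <- system.file("extdata", "murine_phantom.json",
                      package = "rtmscoil")
  expect_equal(read_phantom_config(path), default_head_phantom())
})

test_that("induced E-field is linear in omega and current, zero at DC", {
  w <- build_winding(murine_spec())
  ph <- default_head_phantom()
  d <- c(0, 1, 1.875)
  p0 <- induced_efield(w, ph, 0, depths_mm = d)
  expect_equal(p0$E_V_per_m, c(0, 0, 0))
  p1 <- induced_efield(w, ph, 3e4, depths_mm = d)
  p2 <- induced_efield(w, ph, 6e4, depths_mm = d)
  expect_equal(p2$E_V_per_m, 2 * p1$E_V_per_m, tolerance = 1e-9)
  # linear in drive current
  wI <- build_winding(murine_spec(current_A = 500))
  pI <- induced_efield(wI, ph, 3e4, depths_mm = d)
  expect_equal(pI$E_V_per_m, p1$E_V_per_m / 2, tolerance = 1e-9)
})

test_that("profile is continuous across layer boundaries", {
  w <- build_winding(murine_spec())
  ph <- default_head_phantom()
  eps <- 1e-9
  bounds <- c(0.5, 1.5, 1.8, 1.875)     # cumulative non-brain depths, mm
  d <- sort(c(bounds - eps, bounds + eps))
  prof <- induced_efield(w, ph, 6e4, depths_mm = d)
  below <- prof$E_V_per_m[seq(1, length(d), by = 2)]
  above <- prof$E_V_per_m[seq(2, length(d), by = 2)]
  expect_equal(above, below, tolerance = 1e-6)
})

test_that("B and E are independent of tissue conductivity (quasi-static)", {
  w <- build_winding(murine_spec())
  ph <- default_head_phantom()
  ph0 <- head_phantom(lapply(ph$layers, function(l)
    tissue_layer(l$name, l$thickness_um, l$permittivity, 0)),
    standoff_mm = ph$standoff_mm)
  pts <- rbind(c(0, 0, 1), c(5, 0, 2))
  expect_identical(bfield_at_points(w, pts), bfield_at_points(w, pts))
  p1 <- induced_efield(w, ph, 5e4, depths_mm = c(0.2, 1.875))
  p2 <- induced_efield(w, ph0, 5e4, depths_mm = c(0.2, 1.875))
  expect_identical(p1$E_V_per_m, p2$E_V_per_m)
})

test_that("drive calibration inverts the forward model", {
  w <- build_winding(murine_spec())
  ph <- default_head_phantom()
  omega <- calibrate_drive(w, ph, 136.1452)
  prof <- induced_efield(w, ph, omega,
                         depths_mm = brain_surface_depth(ph))
  expect_equal(prof$E_V_per_m, 136.1452, tolerance = 1e-9)
  # linearity of the inverse
  expect_equal(calibrate_drive(w, ph, 2 * 136.1452), 2 * omega,
               tolerance = 1e-9)
  # effective frequency lands in the kHz band expected for TMS pulses
  f_kHz <- omega / (2 * pi * 1000)
  expect_gt(f_kHz, 1)
  expect_lt(f_kHz, 20)
  expect_error(calibrate_drive(w, ph, -1), "target")
})

test_that("figure-8 windings are routed to the map-based variant", {
  f8 <- build_winding(murine_spec(topology = "figure8"))
  expect_error(induced_efield(f8, default_head_phantom(), 1e4),
               "not supported")
})
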
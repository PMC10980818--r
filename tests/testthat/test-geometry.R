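test_that("closed-form slab depth matches the brute-force bead measurement", {
  # depth law Delta-z = W cos(phi), measured as the z-range of beads whose
  # frame signal exceeds 50% of their full-open signal
  cases <- list(list(phi = 45, W = 3.536), list(phi = 30, W = 4),
                list(phi = 60, W = 6))
  for (cs in cases) {
    depth <- cs$W * cos(cs$phi * pi / 180)
    sc <- ladder_scene(seq(0, ceiling(depth) + 2, by = 0.1), dz = 0.05,
                       phi = cs$phi)
    center_row <- (depth / 2 + 1) / cos(cs$phi * pi / 180)
    m <- ladder_slab_measure(sc, width = cs$W, center = center_row)
    sb <- slab_bounds(shutter_config(cs$W, center_row), sc$optics, sc$sweep,
                      shear_waveform(rate = td_rate(cs$phi)))
    # the ladder quantizes each slab edge by at most one bead spacing (0.1)
    expect_lt(abs(m$z_range - sb$z_depth), 0.2 + 1e-9)
    expect_lt(abs(m$z_center - sb$z_center), 0.1 + 1e-9)
  }
})

test_that("slab_bounds handles degenerate and limit shutters", {
  opt <- optics_config(tilt_phi = 45, z_max = 50)
  sw <- sweep_config(0, 100)
  sh <- shear_waveform(rate = 1)
  expect_equal(slab_bounds(shutter_config(width = 0, center = 20), opt, sw,
                           sh)$z_depth, 0)
  # cos(phi) -> 1 as the tilt vanishes
  opt_flat <- optics_config(tilt_phi = 0.01, z_max = 50)
  expect_equal(slab_bounds(shutter_config(width = 10, center = 20), opt_flat,
                           sw, sh)$z_depth, 10, tolerance = 1e-6)
  # delay moves the slab up by v_u * tau * cos(phi)
  sb0 <- slab_bounds(shutter_config(10, 10, delay = 0), opt, sw, sh)
  sb1 <- slab_bounds(shutter_config(10, 10, delay = 0.1), opt, sw, sh)
  vu <- row_speed(sh, sw)
  expect_equal(sb1$z_center - sb0$z_center, vu * 0.1 * cos(pi / 4))
  # clamping warns when a finite slab pokes outside [0, z_max]
  expect_warning(slab_bounds(shutter_config(10, 0), opt, sw, sh), "clamp")
})

test_that("slab_bounds rejects non-synchronized shutters and nonlinear shears", {
  opt <- optics_config(45, z_max = 50)
  sw <- sweep_config(0, 100)
  expect_error(slab_bounds(shutter_config(10, 0, synchronized = FALSE), opt,
                           sw, shear_waveform(rate = 1)), "synchronized")
  shq <- shear_waveform(rate = 1, q = data.frame(s = c(0, 100), q = c(0, 5)))
  expect_error(slab_bounds(shutter_config(10, 0), opt, sw, shq),
               "predicted_surface")
})

test_that("viewing angle follows tan(psi) = tan(phi) - 1/(r cos(phi))", {
  for (phi in c(30, 45, 60)) {
    opt <- optics_config(phi, z_max = 50)
    expect_equal(viewing_angle(shear_waveform(rate = td_rate(phi)),
                               opt)$psi, 0, tolerance = 1e-10)
  }
  opt45 <- optics_config(45, z_max = 50)
  expect_equal(viewing_angle(shear_waveform(rate = 0.70711), opt45)$psi, -45,
               tolerance = 1e-4)
  expect_equal(viewing_angle(shear_waveform(rate = 2 * sqrt(2)), opt45)$psi,
               atan(0.5) * 180 / pi, tolerance = 1e-10)
  # inverse round-trips and rejects unreachable angles
  for (psi in c(-60, -45, 0, 20, 44)) {
    r <- shear_rate_for_view(psi, opt45)
    expect_gt(r, 0)
    expect_equal(viewing_angle(shear_waveform(rate = r), opt45)$psi, psi,
                 tolerance = 1e-9)
  }
  expect_error(shear_rate_for_view(45, opt45), "unreachable")
  expect_error(shear_rate_for_view(50, opt45), "unreachable")
})

test_that("bead parallax measures the viewing angle set by the shear rate", {
  # the centroid shift of a bead at height z between a top-down and an
  # oblique acquisition equals z * tan(psi)
  bp <- make_bead_phantom(c(61, 11, 81), c(0.5, 0.5, 0.5),
                          beads = data.frame(x = 12, y = 2.5, z = 20,
                                             amplitude = 100, sigma = 1))
  opt <- optics_config(45, 0, 0.5, 30)
  sw <- sweep_config(-35, 45, duration = 0.01)
  frames <- lapply(c(td_rate(45), 0.70711, 2 * sqrt(2)), function(r) {
    simulate_projection(bp$volume,
                        acq_config(opt, sw, shear_waveform(rate = r),
                                   shutter_config(Inf),
                                   frame_origin = -25, n_rows = 140))
  })
  c0 <- frame_row_centroid_um(frames[[1]])
  for (i in 2:3) {
    r <- c(0.70711, 2 * sqrt(2))[i - 1]
    psi <- viewing_angle(shear_waveform(rate = r), opt)$psi
    shift <- frame_row_centroid_um(frames[[i]]) - c0
    expect_equal(shift, -20 * tan(psi * pi / 180), tolerance = 0.025)
  }
})

test_that("residual independence: slab membership does not depend on the shear rate", {
  # slab edges (1.375, 4.125 um) fall midway between ladder beads so that
  # membership is unambiguous under every viewing angle
  sc <- ladder_scene(seq(0, 8, by = 0.25), dz = 0.1, sigma = 0.3)
  members <- lapply(c(0.7, 1.0, td_rate(45), 2.828), function(r) {
    ladder_slab_measure(sc, width = 2.75 / cos(pi / 4),
                        center = 2.75 / cos(pi / 4), rate = r)$included
  })
  for (i in 2:4) expect_identical(members[[i]], members[[1]])
  expect_true(any(members[[1]]) && !all(members[[1]]))
})

test_that("design_shear_waveform reduces to a constant for a flat surface", {
  opt <- optics_config(45, z_max = 100)
  sw <- sweep_config(-50, 150, duration = 0.01)
  sh <- shear_waveform(rate = td_rate(45))
  shutter <- shutter_config(width = 5, center = 10, delay = 0.001)
  flat <- surface_spec(seq(0, 100, by = 1), rep(30, 101))
  wf <- design_shear_waveform(flat, opt, shutter, sw, sh)
  C <- shutter$center + row_speed(sh, sw) * shutter$delay
  expect_equal(unique(round(wf$q$q, 9)), round(C - 30 / cos(pi / 4), 9))
})

test_that("curved-surface waveform design round-trips through predicted_surface", {
  surf <- arc_surface()
  opt <- optics_config(45, z_max = 128)
  sw <- sweep_config(-60, 220, duration = 0.01)
  shutter <- shutter_config(width = 5, center = 0)
  wf <- design_shear_waveform(surf, opt, shutter, sw,
                              shear_waveform(rate = td_rate(45)))
  xq <- seq(45, 211, by = 1)
  rec <- predicted_surface(wf, opt, shutter, sw, xq)
  truth <- approx(surf$x, surf$z, xout = xq)$y
  expect_lt(max(abs(rec$z - truth)), 0.5)
  expect_equal(rec$half_width, 5 * cos(pi / 4) / 2)
})

test_that("waveform design rejects non-invertible and out-of-range surfaces", {
  opt <- optics_config(45, z_max = 128)
  sw <- sweep_config(-60, 220, duration = 0.01)
  shutter <- shutter_config(width = 5)
  # slope 1.2 at some x with tan(45) = 1 -> product > 1
  x <- seq(0, 100, by = 1)
  steep <- surface_spec(x, 20 + pmin(1.2 * x, 60))
  err <- expect_error(design_shear_waveform(steep, opt, shutter, sw,
                                            shear_waveform(rate = 1.5)),
                      "invertibility")
  expect_match(conditionMessage(err), "x in \\[")
  shallow <- arc_surface()
  expect_error(design_shear_waveform(shallow, opt, shutter,
                                     sweep_config(0, 100),
                                     shear_waveform(rate = 1.5)),
               "scan range")
  tall <- surface_spec(x, 110 + 0.3 * x)
  expect_error(design_shear_waveform(tall, opt, shutter, sw,
                                     shear_waveform(rate = 1.5)),
               "z_max")
})

test_that("predicted_surface agrees with slab_bounds for a linear shear", {
  opt <- optics_config(45, z_max = 100)
  sw <- sweep_config(-50, 150, duration = 0.01)
  sh <- shear_waveform(rate = td_rate(45))
  shutter <- shutter_config(width = 6, center = 40, delay = 2e-4)
  sb <- slab_bounds(shutter, opt, sw, sh)
  surf <- predicted_surface(sh, opt, shutter, sw, x_grid = seq(0, 100, 5))
  expect_equal(surf$z, rep(sb$z_center, length(surf$z)), tolerance = 1e-8)
  expect_equal(2 * surf$half_width, sb$z_depth)
})

test_that("waveform inversion is exact on a linear shear ramp", {
  # q(s) = a s gives the analytic solution
  # z = (C - a x) / (1/cos(phi) - a tan(phi)) whenever |a tan(phi)| < 1
  opt <- optics_config(45, z_max = 200)
  sw <- sweep_config(-200, 200, duration = 0.01)
  shutter <- shutter_config(width = 4, center = 80)
  for (a in c(-0.8, -0.3, 0.3, 0.8)) {
    sh <- shear_waveform(rate = 1.5,
                         q = data.frame(s = c(-200, 200),
                                        q = a * c(-200, 200)))
    x <- seq(20, 60, by = 5)
    got <- predicted_surface(sh, opt, shutter, sw, x)
    cphi <- cos(pi / 4)
    want <- (80 - a * x) / (1 / cphi - a * tan(pi / 4))
    expect_equal(got$z, want, tolerance = 1e-4)
  }
})

test_that("local viewing angle reflects the effective shear rate r + dq/ds", {
  opt <- optics_config(45, z_max = 100)
  a <- 0.25
  sh <- shear_waveform(rate = 1.5,
                       q = data.frame(s = c(-100, 100), q = a * c(-100, 100)))
  got <- local_view_angle(sh, opt, s = c(-50, 0, 50))
  phi <- pi / 4
  want <- atan(tan(phi) - 1 / ((1.5 + a) * cos(phi))) * 180 / pi
  expect_equal(got, rep(want, 3), tolerance = 1e-6)
})
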
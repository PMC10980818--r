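test_that("bead phantom conserves intensity and reproduces its ground truth", {
  set.seed(42)
  beads <- data.frame(x = runif(11, 8, 40), y = runif(11, 8, 40),
                      z = runif(11, 8, 40), amplitude = 100, sigma = 1)
  ph <- make_bead_phantom(c(48, 48, 48), beads = beads)
  # independent dense evaluation of the expected total intensity
  zg <- 0:47
  expected <- sum(vapply(seq_len(11), function(i) {
    100 * sum(exp(-(zg - beads$z[i])^2 / 2)) *
      sum(exp(-(zg - beads$y[i])^2 / 2)) *
      sum(exp(-(zg - beads$x[i])^2 / 2))
  }, numeric(1)))
  expect_equal(sum(ph$volume$data), expected, tolerance = 1e-3)
  expect_identical(ph$beads[, c("x", "y", "z")], beads[, c("x", "y", "z")])
})

test_that("bead phantom edge cases: empty, deterministic, bounds-checked", {
  empty <- make_bead_phantom(c(8, 8, 8), n_beads = 0)
  expect_true(all(empty$volume$data == 0))
  a <- make_bead_phantom(c(16, 16, 16), n_beads = 5, seed = 3)
  b <- make_bead_phantom(c(16, 16, 16), n_beads = 5, seed = 3)
  expect_identical(a$volume$data, b$volume$data)
  c2 <- make_bead_phantom(c(16, 16, 16), n_beads = 5, seed = 4)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_error(
    make_bead_phantom(c(16, 16, 16),
                      beads = data.frame(x = c(5, 99), y = 5, z = 5)),
    "rows 2")
  expect_error(
    make_bead_phantom(c(16, 16, 16), voxel_size = c(2, 2, 2),
                      beads = data.frame(x = 5, y = 5, z = 5, sigma = 0.5)),
    "half a voxel")
})

test_that("vessel phantom is seeded, bounded and fills slabs uniformly", {
  v1 <- make_vessel_phantom(c(32, 24, 32), n_vessels = 2, seed = 9)
  v2 <- make_vessel_phantom(c(32, 24, 32), n_vessels = 2, seed = 9)
  expect_identical(v1$data, v2$data)
  expect_true(all(v1$data >= 0))
  expect_gt(sum(v1$data), 0)
  # tubes span z: fraction of tube voxels inside a z-slab approximately
  # equals slab depth over z-extent
  v <- make_vessel_phantom(c(64, 32, 64), n_vessels = 50, seed = 11)
  zg <- vol_coords(v, "z")
  tube <- v$data > 0
  frac <- sum(tube[zg >= 16 & zg < 48, , ]) / sum(tube)
  expect_equal(frac, 0.5, tolerance = 0.2)
})

test_that("shell phantom builds the stated arc and flags blob membership", {
  sp <- make_shell_phantom(c(100, 24, 256), x_center = 128, radius = 150,
                           z_bottom = 60, x_halfspan = 88, thickness = 2,
                           n_blobs = 0)
  # bare shell: voxel set equals {|z - z*(x)| < thickness/2}
  xg <- vol_coords(sp$volume, "x")
  zg <- vol_coords(sp$volume, "z")
  inside_x <- abs(xg - 128) <= 88
  want <- array(0, dim = dim(sp$volume$data))
  for (j in which(inside_x)) {
    zs <- 60 + 150 - sqrt(150^2 - (xg[j] - 128)^2)
    want[abs(zg - zs) < 1, , j] <- 5
  }
  expect_identical(sp$volume$data, want)
  expect_equal(sp$surface$z, 60 + 150 - sqrt(150^2 - (xg[inside_x] - 128)^2))
  # decorated shell: on-surface blobs sit within 1 um of z*(x)
  sp2 <- make_shell_phantom(c(100, 24, 256), x_center = 128, radius = 150,
                            z_bottom = 60, x_halfspan = 88, n_blobs = 8,
                            n_distractors = 4, seed = 5)
  zs_at <- approx(sp2$surface$x, sp2$surface$z, xout = sp2$blobs$x)$y
  expect_true(all(abs(zs_at - sp2$blobs$z)[sp2$blobs$on_surface] < 1))
  expect_true(all(abs(zs_at - sp2$blobs$z)[!sp2$blobs$on_surface] > 10))
  expect_error(make_shell_phantom(c(20, 8, 256), x_center = 128,
                                  radius = 150, z_bottom = 10,
                                  x_halfspan = 88), "exits the volume")
})

test_that("calcium phantom transients follow the double-exponential kernel", {
  cal <- make_calcium_phantom(shape = c(40, 16, 32), layer_z = c(10, 30),
                              n_cells = 2, duration = 1.5,
                              frame_interval = 0.01, seed = 2)
  # dense numeric evaluation of the kernel peak (independent oracle)
  tt <- seq(0, 1.5, by = 1e-4)
  kmax <- max((1 - exp(-tt / 0.05)) * exp(-tt / 0.5))
  cells <- cal$truth$cells
  for (i in c(1, 3)) {
    # voxel at the cell center carries F(t) = F0 (1 + A sum k(t - t0))
    ci <- round(c(cells$z[i], cells$y[i], cells$x[i])) + 1
    trace <- vapply(cal$movie$items, function(v) v$data[ci[1], ci[2], ci[3]],
                    numeric(1))
    f0 <- min(trace)
    expect_equal(max(trace) / f0 - 1, cells$amplitude[i] * kmax,
                 tolerance = 0.02)
  }
  # zero transients: a static movie
  cal0 <- make_calcium_phantom(shape = c(40, 16, 32), layer_z = c(10, 30),
                               n_cells = 2, n_transients = 0, duration = 0.2,
                               frame_interval = 0.02, seed = 2)
  for (v in cal0$movie$items)
    expect_identical(v$data, cal0$movie$items[[1]]$data)
  # seeded noise reproducible
  n1 <- make_calcium_phantom(shape = c(24, 12, 24), layer_z = c(6, 18),
                             n_cells = 1, duration = 0.1,
                             frame_interval = 0.02,
                             noise_photon_scale = 1, seed = 8)
  n2 <- make_calcium_phantom(shape = c(24, 12, 24), layer_z = c(6, 18),
                             n_cells = 1, duration = 0.1,
                             frame_interval = 0.02,
                             noise_photon_scale = 1, seed = 8)
  expect_identical(n1$movie$items[[3]]$data, n2$movie$items[[3]]$data)
})

test_that("haze model conserves energy and only adds the pedestal", {
  set.seed(6)
  beads <- data.frame(x = runif(6, 13, 19), y = runif(6, 13, 19),
                      z = runif(6, 4, 28), amplitude = 100, sigma = 1.5)
  ph <- make_bead_phantom(c(32, 32, 32), beads = beads)
  # identity with all parameters zero
  same <- add_haze(ph$volume, 0, 0, 0)
  expect_identical(same$data, ph$volume$data)
  # normalized blur: per-plane sums conserved (content away from edges)
  blurred <- add_haze(ph$volume, sigma0 = 1, k = 0.05, pedestal_frac = 0)
  for (iz in seq(4, 28, by = 6)) {
    s0 <- sum(ph$volume$data[iz, , ])
    if (s0 > 1e-6)
      expect_equal(sum(blurred$data[iz, , ]), s0, tolerance = 1e-3)
  }
  # pedestal adds exactly pedestal_frac * plane mean everywhere
  hz <- add_haze(ph$volume, 0, 0, pedestal_frac = 0.5)
  expect_equal(sum(hz$data), 1.5 * sum(ph$volume$data), tolerance = 1e-12)
})

test_that("projection SBR degrades as the haze pedestal grows", {
  beads <- data.frame(x = seq(8, 40, by = 8), y = seq(8, 40, by = 8),
                      z = 16, amplitude = 200, sigma = 1)
  ph <- make_bead_phantom(c(32, 48, 48), beads = beads)
  fg <- matrix(FALSE, 48, 48)
  for (i in seq_len(nrow(beads)))
    fg[round(beads$x[i]) + 1 + (-1:1), round(beads$y[i]) + 1 + (-1:1)] <- TRUE
  bg <- !fg
  sbrs <- vapply(c(0, 0.2, 0.5), function(p) {
    hz <- add_haze(ph$volume, sigma0 = 0.5, k = 0.02, pedestal_frac = p)
    fr <- slab_project(hz, slab_spec(16, 64))
    sbr(fr, fg, bg)
  }, numeric(1))
  expect_true(all(diff(sbrs) < 0))
})
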
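make_small_scene <- function() {
  set.seed(21)
  beads <- data.frame(x = runif(8, 6, 42), y = runif(8, 6, 26),
                      z = runif(8, 6, 42), amplitude = 100, sigma = 1)
  ph <- make_bead_phantom(c(48, 32, 48), beads = beads)
  list(vol = ph$volume, beads = beads,
       optics = optics_config(45, 0, 1, 47),
       sweep = sweep_config(-52, 52, duration = 0.01))
}

test_that("an empty volume projects to an all-zero frame", {
  sc <- make_small_scene()
  zero <- volume(array(0, dim = c(16, 8, 16)))
  fr <- simulate_projection(zero, acq_config(sc$optics, sc$sweep,
                                             shear_waveform(rate = 1.4),
                                             shutter_config(Inf)))
  expect_true(all(fr$data == 0))
})

test_that("the projection is linear in the volume with noise off", {
  sc <- make_small_scene()
  v1 <- make_bead_phantom(c(48, 32, 48),
                          beads = data.frame(x = 12, y = 10, z = 20,
                                             amplitude = 50, sigma = 1))
  v2 <- make_bead_phantom(c(48, 32, 48),
                          beads = data.frame(x = 30, y = 20, z = 35,
                                             amplitude = 80, sigma = 1))
  acq <- acq_config(sc$optics, sc$sweep, shear_waveform(rate = 2),
                    shutter_config(20, 30), frame_origin = -50,
                    n_rows = 150)
  fsum <- simulate_projection(volume(v1$volume$data + v2$volume$data), acq)
  f1 <- simulate_projection(v1$volume, acq)
  f2 <- simulate_projection(v2$volume, acq)
  expect_lt(max(abs(fsum$data - (f1$data + f2$data))),
            1e-6 * max(fsum$data))
})

test_that("a full-open top-down acquisition conserves total intensity", {
  sc <- make_small_scene()
  fr <- simulate_projection(sc$vol,
                            acq_config(sc$optics, sc$sweep,
                                       shear_waveform(rate = td_rate(45)),
                                       shutter_config(Inf)))
  expect_equal(sum(fr$data), sum(sc$vol$data), tolerance = 0.01)
})

test_that("halving the sweep step changes the frame by less than 1%", {
  sc <- make_small_scene()
  mk <- function(n_steps) {
    sw <- sweep_config(sc$sweep$s_start, sc$sweep$s_end, n_steps = n_steps,
                       duration = 0.01)
    simulate_projection(sc$vol,
                        acq_config(sc$optics, sw,
                                   shear_waveform(rate = td_rate(45)),
                                   shutter_config(20, 25),
                                   frame_origin = 0, n_rows = 60))
  }
  coarse <- mk(105L)
  fine <- mk(209L)
  expect_lt(sqrt(mean((coarse$data - fine$data)^2)) / max(fine$data), 0.01)
})

test_that("a single bead lands where the shear-warp oracle puts it", {
  bp <- make_bead_phantom(c(48, 16, 48),
                          beads = data.frame(x = 25, y = 8, z = 20,
                                             amplitude = 100, sigma = 1))
  opt <- optics_config(45, 0, 1, 47)
  sw <- sweep_config(-52, 52, duration = 0.01)
  got <- sim_and_oracle(bp$volume, opt, sw, rate = td_rate(45),
                        width = Inf, center = 0)
  cmp <- compare_frames(got$fr, got$orc,
                        spots = bead_spots(got$fr, bp$beads, got$psi))
  expect_lt(cmp$nrmse, 0.05)
  expect_lt(max(abs(cmp$centroid_offsets)), 0.5)
  # top-down: the bead centroid sits at its x position
  expect_equal(frame_row_centroid_um(got$fr), 25, tolerance = 0.02)
})

test_that("the shutter warns and returns zeros when it never overlaps the image", {
  sc <- make_small_scene()
  expect_warning(
    fr <- simulate_projection(sc$vol,
                              acq_config(sc$optics, sc$sweep,
                                         shear_waveform(rate = td_rate(45)),
                                         shutter_config(2, 500))),
    "empty selection")
  expect_true(all(fr$data == 0))
})

test_that("simulate_stack reproduces the volume and the projection identity", {
  sc <- make_small_scene()
  acq <- acq_config(sc$optics, sc$sweep, shear_waveform(rate = td_rate(45)),
                    shutter_config(Inf))
  stack <- simulate_stack(sc$vol, acq, dz_step = 1)
  expect_identical(dim(stack$data)[1], 48L)  # floor(z_max/dz) + 1
  # summing the stack planes equals the full top-down projection
  proj <- apply(stack$data, c(3, 2), sum)
  fr <- simulate_projection(sc$vol, acq)
  expect_equal(sum(proj), sum(fr$data), tolerance = 0.01)
  zero <- simulate_stack(volume(array(0, c(8, 4, 4))), acq, dz_step = 2)
  expect_true(all(zero$data == 0))
})

test_that("frame sequences interleave shutter delays deterministically", {
  cal <- make_calcium_phantom(shape = c(40, 16, 32), layer_z = c(10, 30),
                              n_cells = 2, duration = 0.1,
                              frame_interval = 0.02, n_transients = 0,
                              seed = 3)
  opt <- optics_config(45, 0, 1, 39)
  sw <- sweep_config(-45, 40, duration = 0.005)
  sh <- shear_waveform(rate = td_rate(45))
  vu <- row_speed(sh, sw)
  acq <- acq_config(opt, sw, sh,
                    shutter_config(10 / cos(pi / 4), 10 / cos(pi / 4)))
  delays <- c(0, 20 / (vu * cos(pi / 4)))
  frames <- simulate_projection_sequence(cal$movie, acq, delays = delays)
  expect_length(frames, length(cal$movie$items))
  idx <- vapply(frames, function(f) f$meta$config_index, integer(1))
  expect_identical(idx, rep(c(1L, 2L), length.out = length(frames)))
  # static movie: all frames of one slab identical
  expect_identical(frames[[1]]$data, frames[[3]]$data)
  expect_identical(frames[[2]]$data, frames[[4]]$data)
  expect_false(identical(frames[[1]]$data, frames[[2]]$data))
  expect_error(simulate_projection_sequence(cal$movie, acq,
                                            acq_list = list(acq)),
               "configs")
})

test_that("the camera noise model is seeded and statistically calibrated", {
  fr <- frame(matrix(1e4, 20, 20))
  nm <- noise_model(photon_scale = 100, read_sigma = 0, offset = 0, seed = 5)
  n1 <- apply_noise(fr, nm)
  n2 <- apply_noise(fr, nm)
  expect_identical(n1$data, n2$data)
  # Poisson concentration: relative error < 1% at 1e4 counts
  expect_lt(max(abs(n1$data - 1e4) / 1e4), 0.01)
  # mean over repeated draws matches input + offset within 3 SE
  fr2 <- frame(matrix(c(10, 100), 10, 10))
  nm2 <- noise_model(photon_scale = 1, read_sigma = 2, offset = 7)
  set.seed(99)
  draws <- replicate(500, apply_noise(fr2, nm2)$data[1, 1])
  se <- sqrt(10 + 4) / sqrt(500)
  expect_lt(abs(mean(draws) - 17), 3 * se)
})
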
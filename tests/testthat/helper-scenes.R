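# Shared fixture builders: every fixture is generated in code, seeded.

td_rate <- function(phi_deg) 1 / sin(phi_deg * pi / 180)

# Bead z-ladder scene: beads at prescribed z, distinct x, cycled y lanes,
# plus the optics/sweep needed to image them.
ladder_scene <- function(z, dz = 0.05, dxy = 0.5, sigma = 0.3, x_step = 1,
                         y_step = 2, n_lanes = 10, z_top = max(z) + 1,
                         phi = 45, duration = 0.01) {
  beads <- bead_ladder(z, x_start = 5, x_step = x_step, y_start = 2,
                       y_step = y_step, n_y_lanes = n_lanes, sigma = sigma)
  nx <- ceiling((max(beads$x) + 5) / dxy) + 1L
  ny <- ceiling((max(beads$y) + 2) / dxy) + 1L
  nz <- ceiling(z_top / dz) + 1L
  ph <- make_bead_phantom(c(nz, ny, nx), c(dz, dxy, dxy), beads = beads)
  optics <- optics_config(tilt_phi = phi, sheet_sigma = 0,
                          pixel_pitch = dxy, z_max = (nz - 1L) * dz)
  sweep <- sweep_config(-2 * (nz - 1L) * dz - 5, (nx - 1L) * dxy + 5,
                        duration = duration)
  list(vol = ph$volume, beads = beads, optics = optics, sweep = sweep)
}

# Simulate a slab acquisition plus a full-open reference and measure the
# included-bead z statistics (the brute-force geometry oracle).
ladder_slab_measure <- function(scene, width, center, delay = 0,
                                rate = NULL) {
  if (is.null(rate)) rate <- td_rate(scene$optics$tilt_phi)
  sh <- shear_waveform(rate = rate)
  fr <- simulate_projection(scene$vol,
                            acq_config(scene$optics, scene$sweep, sh,
                                       shutter_config(width, center, delay)))
  rf <- simulate_projection(scene$vol,
                            acq_config(scene$optics, scene$sweep, sh,
                                       shutter_config(Inf)))
  psi <- viewing_angle(sh, scene$optics)$psi
  measure_slab(fr, rf, scene$beads, psi = psi)
}

# Run the optical simulator and the digital shear-warp renderer on the same
# volume and parameter set, on a shared frame grid.
sim_and_oracle <- function(vol, optics, sweep, rate, width, center,
                           delay = 0) {
  sh <- shear_waveform(rate = rate)
  sc <- shutter_config(width, center, delay)
  fr <- simulate_projection(vol, acq_config(optics, sweep, sh, sc))
  slab <- suppressWarnings(slab_bounds(sc, optics, sweep, sh))
  psi <- viewing_angle(sh, optics)$psi
  orc <- slab_project(vol, slab, view_spec(psi),
                      row_origin = fr$origin[1], n_rows = nrow(fr$data),
                      pixel_pitch = fr$pixel_size[1])
  list(fr = fr, orc = orc, psi = psi, slab = slab)
}

# Frame-pixel positions of beads for centroid tracking.
bead_spots <- function(fr, beads, psi = 0) {
  data.frame(
    row = (beads$x - beads$z * tan(psi * pi / 180) - fr$origin[1]) /
      fr$pixel_size[1] + 1,
    col = (beads$y - fr$origin[2]) / fr$pixel_size[2] + 1)
}

# Compliant circular-arc surface (satisfies the invertibility bound at 45
# degrees: max slope 88 / sqrt(150^2 - 88^2) = 0.72).
arc_surface <- function(x = seq(40, 216, by = 1), x_center = 128,
                        radius = 150, z_bottom = 60, half_width = 2.5) {
  surface_spec(x, z_bottom + radius - sqrt(radius^2 - (x - x_center)^2),
               half_width = half_width)
}
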
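resolve_n_steps <- function(acq) {
  acq$sweep$n_steps %||%
    max(2L, ceiling((acq$sweep$s_end - acq$sweep$s_start) /
                      acq$optics$pixel_pitch) + 1L)
}

# Default frame row grid: covers the projected x-range of the volume for the
# viewing angle(s) realized by the waveform (local angles when q is
# nonlinear), with a small margin.
default_row_grid <- function(vol, acq) {
  phi <- deg2rad(acq$optics$tilt_phi)
  r <- acq$shear$rate
  zr <- range(vol_coords(vol, "z"))
  xr <- range(vol_coords(vol, "x"))
  qr <- if (is.null(acq$shear$q)) c(0, 0) else range(acq$shear$q$q)
  # x0 = x - z*tan(phi) + (z/cos(phi) + q)/r over corner combinations
  cand <- c(outer(xr, zr, function(x, z) x - z * tan(phi) + z / (r * cos(phi))))
  cand <- c(cand + qr[1] / r, cand + qr[2] / r)
  pitch <- acq$optics$pixel_pitch
  origin <- floor(min(cand) / pitch) * pitch - 2 * pitch
  n_rows <- ceiling((max(cand) - origin) / pitch) + 3L
  list(origin = origin, n_rows = as.integer(n_rows))
}

#' Simulate a single props projection frame
#'
#' Forward model of one camera exposure: the tilted sheet is stepped across
#' the scan range; every illuminated sample is mapped to its camera row,
#' masked by the synchronized rolling-shutter window, and accumulated into the
#' frame. The frame's row coordinate is the camera row divided by the shear
#' rate, i.e. sample-space micrometers, so frames acquired at different shear
#' rates share one lateral grid (the scale component of the shear-warp
#' "warp"); a structure at height z appears at `x - z * tan(psi)`.
#'
#' With noise off the frame is linear in the input volume; out-of-volume
#' samples read as 0.
#'
#' @param vol A [volume()].
#' @param acq An [acq_config()].
#' @return A [frame()] with the acquisition parameters in `meta`.
#' @export
simulate_projection <- function(vol, acq) {
  stopifnot(inherits(vol, "props_volume"), inherits(acq, "acq_config"))
  if (!acq$shutter$synchronized)
    stop("only synchronized rolling shutters are modeled")
  n <- resolve_n_steps(acq)
  s_grid <- seq(acq$sweep$s_start, acq$sweep$s_end, length.out = n)
  q_grid <- eval_q(acq$shear, s_grid)
  vu <- row_speed(acq$shear, acq$sweep)
  grid <- if (is.null(acq$frame_origin) || is.null(acq$n_rows)) {
    default_row_grid(vol, acq)
  } else {
    list(origin = acq$frame_origin, n_rows = as.integer(acq$n_rows))
  }
  halfwidth <- if (is.infinite(acq$shutter$width)) -1 else acq$shutter$width / 2
  # warn if the shutter window cannot overlap any illuminated row
  if (halfwidth >= 0) {
    zr <- range(vol_coords(vol, "z"))
    cphi <- cos(deg2rad(acq$optics$tilt_phi))
    resid <- zr / cphi + range(q_grid)[c(1, 2)] + acq$shear$offset -
      acq$shutter$center - vu * acq$shutter$delay
    if (min(resid) > halfwidth || max(resid) < -halfwidth)
      warning("empty selection: the shutter window never overlaps the image rows")
  }
  mat <- cpp_project_sweep(vol$data, dim(vol$data), vol$voxel_size,
                           vol$origin, s_grid, q_grid,
                           acq$shear$rate, acq$shear$offset,
                           deg2rad(acq$optics$tilt_phi),
                           acq$optics$sheet_sigma,
                           acq$shutter$center, halfwidth,
                           vu * acq$shutter$delay,
                           acq$optics$pixel_pitch, grid$origin, grid$n_rows)
  fr <- frame(mat,
              pixel_size = c(acq$optics$pixel_pitch, vol$voxel_size[2]),
              origin = c(grid$origin, vol$origin[2]),
              meta = list(acq = acq))
  if (!is.null(acq$noise)) fr <- apply_noise(fr, acq$noise)
  fr
}

#' Simulate a sequence of props frames from a 3D+t movie
#'
#' One projection per movie time point. Either a single configuration is
#' used throughout, a list of per-frame configurations is given (must match
#' the movie length), or `delays` supplies shutter delays cycled across
#' frames -- the paper-style interleaved acquisition of two slabs with no
#' mechanical motion.
#'
#' @param movie A [time_lapse()] of volumes.
#' @param acq An [acq_config()] used for every frame (modulo `delays`).
#' @param delays Optional vector of shutter delays (seconds) cycled over
#'   frames; frame t uses `delays[((t - 1) %% length(delays)) + 1]`.
#' @param acq_list Optional explicit list of per-frame configurations.
#' @return A list of [frame()]s; each frame's `meta$config_index` records
#'   which configuration produced it.
#' @export
simulate_projection_sequence <- function(movie, acq, delays = NULL,
                                         acq_list = NULL) {
  stopifnot(inherits(movie, "time_lapse"))
  nt <- length(movie$items)
  if (!is.null(acq_list)) {
    if (length(acq_list) != nt)
      stop(sprintf("`acq_list` has %d configs but the movie has %d frames",
                   length(acq_list), nt))
    cfgs <- acq_list
    cfg_idx <- seq_len(nt)
  } else if (!is.null(delays)) {
    cfgs <- lapply(delays, function(d) {
      a <- acq
      a$shutter$delay <- d
      a
    })
    cfg_idx <- ((seq_len(nt) - 1L) %% length(delays)) + 1L
  } else {
    cfgs <- list(acq)
    cfg_idx <- rep(1L, nt)
  }
  # shared frame grid so interleaved series stay registered
  grid <- default_row_grid(movie$items[[1]], acq)
  lapply(seq_len(nt), function(t) {
    a <- cfgs[[cfg_idx[t]]]
    if (is.null(a$frame_origin)) {
      a$frame_origin <- grid$origin
      a$n_rows <- grid$n_rows
    }
    fr <- simulate_projection(movie$items[[t]], a)
    fr$meta$config_index <- cfg_idx[t]
    fr$meta$time <- (t - 1) * movie$frame_interval
    fr
  })
}

#' Simulate a conventional z-stack
#'
#' Plane-by-plane acquisition for comparison with projection imaging: plane k
#' is the sheet-weighted image at fixed height `z = k * dz_step` (no shear,
#' no shutter). With an ideal thin sheet each plane is the interpolated
#' volume section.
#'
#' @param vol A [volume()].
#' @param acq An [acq_config()] (supplies `sheet_sigma` and `z_max`).
#' @param dz_step Plane spacing, micrometers (> 0). The stack has
#'   `floor(z_max / dz_step) + 1` planes.
#' @return A [volume()] whose z-axis is the stack axis.
#' @export
simulate_stack <- function(vol, acq, dz_step) {
  stopifnot(inherits(vol, "props_volume"), inherits(acq, "acq_config"))
  if (dz_step <= 0) stop("`dz_step` must be > 0")
  z_max <- acq$optics$z_max
  zs <- seq(0, z_max, by = dz_step)
  zg <- vol_coords(vol, "z")
  d <- dim(vol$data)
  sig <- acq$optics$sheet_sigma / cos(deg2rad(acq$optics$tilt_phi))
  out <- array(0, dim = c(length(zs), d[2], d[3]))
  for (k in seq_along(zs)) {
    if (sig > 0) {
      w <- dnorm(zg, mean = zs[k], sd = sig)
      if (sum(w) == 0) next
      w <- w / sum(w)
      plane <- matrix(0, d[2], d[3])
      for (iz in which(w > 1e-12)) plane <- plane + w[iz] * vol$data[iz, , ]
      out[k, , ] <- plane
    } else {
      fz <- (zs[k] - vol$origin[1]) / vol$voxel_size[1] + 1
      if (fz < 1 || fz > d[1]) next
      iz0 <- floor(fz); a <- fz - iz0
      iz1 <- min(iz0 + 1, d[1])
      out[k, , ] <- (1 - a) * vol$data[iz0, , ] + a * vol$data[iz1, , ]
    }
  }
  volume(out, voxel_size = c(dz_step, vol$voxel_size[2], vol$voxel_size[3]),
         origin = c(0, vol$origin[2], vol$origin[3]))
}

#' Apply a camera noise model to a frame
#'
#' `Poisson(photon_scale * value) / photon_scale + N(0, read_sigma) + offset`,
#' seeded and reproducible. The calling RNG state is preserved when the model
#' carries its own seed.
#'
#' @param fr A [frame()].
#' @param model A [noise_model()].
#' @return A noisy [frame()].
#' @export
apply_noise <- function(fr, model) {
  stopifnot(inherits(fr, "props_frame"), inherits(model, "noise_model"))
  if (!is.null(model$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(model$seed)
  }
  m <- fr$data
  shot <- rpois(length(m), lambda = model$photon_scale * as.vector(m)) /
    model$photon_scale
  noisy <- shot + rnorm(length(m), 0, model$read_sigma) + model$offset
  out <- fr
  out$data <- matrix(noisy, nrow(m), ncol(m))
  out
}
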
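#' Add isotropic Gaussian blobs to an array
#'
#' Each row of `table` (columns `x`, `y`, `z`, `amplitude`, `sigma`) is
#' rendered as an isotropic Gaussian of the stated peak amplitude, truncated
#' at 4 sigma. Separable outer-product evaluation keeps this fast for
#' thousands of blobs.
#'
#' @param data 3D array (z, y, x) to accumulate into.
#' @param voxel_size,origin Volume geometry as in [volume()].
#' @param table Data frame of blob records.
#' @return The array with blobs added.
#' @keywords internal
splat_gaussians <- function(data, voxel_size, origin, table) {
  d <- dim(data)
  for (i in seq_len(nrow(table))) {
    pos <- c(table$z[i], table$y[i], table$x[i])
    sig <- table$sigma[i]
    amp <- table$amplitude[i]
    idx <- vector("list", 3L)
    w <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      ctr <- (pos[ax] - origin[ax]) / voxel_size[ax] + 1
      half <- 4 * sig / voxel_size[ax]
      lo <- max(1L, floor(ctr - half))
      hi <- min(d[ax], ceiling(ctr + half))
      if (lo > hi) { ok <- FALSE; break }
      idx[[ax]] <- lo:hi
      u <- (idx[[ax]] - ctr) * voxel_size[ax]
      w[[ax]] <- exp(-u^2 / (2 * sig^2))
    }
    if (!ok) next
    patch <- amp * (w[[1]] %o% w[[2]] %o% w[[3]])
    data[idx[[1]], idx[[2]], idx[[3]]] <-
      data[idx[[1]], idx[[2]], idx[[3]]] + patch
  }
  data
}

check_in_bounds <- function(table, voxel_size, origin, shape, what = "bead") {
  hi <- origin + (shape - 1) * voxel_size
  bad <- which(table$z < origin[1] | table$z > hi[1] |
               table$y < origin[2] | table$y > hi[2] |
               table$x < origin[3] | table$x > hi[3])
  if (length(bad))
    stop(sprintf("%s(s) outside the volume bounds: rows %s", what,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Bead phantom
#'
#' Renders point-like fluorescent beads as isotropic Gaussians, either at
#' caller-supplied positions (a bead table with columns `x`, `y`, `z` and
#' optionally `amplitude`, `sigma`) or at seeded uniform-random positions.
#' The realized table is returned alongside the volume so that downstream
#' parameter-recovery statistics never need to re-inspect the voxels.
#'
#' @param shape Integer length 3, `(nz, ny, nx)` voxels.
#' @param voxel_size `(dz, dy, dx)` micrometers.
#' @param beads Optional bead table; positions must lie inside the volume.
#' @param n_beads Number of random beads when `beads` is `NULL`.
#' @param seed Integer seed for random placement.
#' @param amplitude,sigma Defaults for table rows lacking these columns;
#'   `sigma` must be at least half the largest voxel size.
#' @param origin Volume origin, micrometers.
#' @return `list(volume = , beads = )`.
#' @export
make_bead_phantom <- function(shape, voxel_size = c(1, 1, 1), beads = NULL,
                              n_beads = 0, seed = 1, amplitude = 100,
                              sigma = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (is.null(beads)) {
    if (n_beads > 0) {
      set.seed(seed)
      hi <- origin + (shape - 1) * voxel_size
      margin <- pmin(4 * sigma, (hi - origin) / 4)
      beads <- data.frame(
        x = runif(n_beads, origin[3] + margin[3], hi[3] - margin[3]),
        y = runif(n_beads, origin[2] + margin[2], hi[2] - margin[2]),
        z = runif(n_beads, origin[1] + margin[1], hi[1] - margin[1]))
    } else {
      beads <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
    }
  } else {
    beads <- as.data.frame(beads)
  }
  if (is.null(beads$amplitude)) beads$amplitude <- rep(amplitude, nrow(beads))
  if (is.null(beads$sigma)) beads$sigma <- rep(sigma, nrow(beads))
  if (nrow(beads)) {
    if (any(beads$sigma < max(voxel_size) / 2))
      stop("bead sigma must be >= half a voxel")
    if (any(beads$amplitude <= 0)) stop("bead amplitude must be > 0")
    check_in_bounds(beads, voxel_size, origin, shape)
  }
  data <- array(0, dim = shape)
  data <- splat_gaussians(data, voxel_size, origin, beads)
  list(volume = volume(data, voxel_size, origin), beads = beads)
}

#' Bead z-ladder layout
#'
#' Builds a bead table whose beads take prescribed z values at strictly
#' distinct x positions, cycling over a few y lanes so that neighboring beads
#' never overlap in the projected frame.
#'
#' @param z Bead heights, micrometers.
#' @param x_start,x_step x position of the first bead and spacing between
#'   consecutive beads, micrometers.
#' @param y_start,y_step,n_y_lanes y lane layout, micrometers / count.
#' @param amplitude,sigma Bead photometry.
#' @return A bead table (data frame).
#' @export
bead_ladder <- function(z, x_start = 5, x_step = 1, y_start = 2, y_step = 2,
                        n_y_lanes = 10, amplitude = 100, sigma = 0.5) {
  i <- seq_along(z) - 1L
  data.frame(x = x_start + i * x_step,
             y = y_start + (i %% n_y_lanes) * y_step,
             z = z, amplitude = amplitude, sigma = sigma)
}

#' Vessel phantom
#'
#' Random smooth curvilinear tubes spanning the volume's z-range, emulating
#' vasculature: control points are cubic-spline interpolated into dense
#' center-lines and rasterized as solid tubes of radius 2-4 micrometers.
#'
#' @param shape,voxel_size,origin Volume geometry.
#' @param n_vessels Number of tubes (>= 1).
#' @param seed Integer seed.
#' @param radius_range Tube radius range, micrometers.
#' @param amplitude Tube intensity.
#' @param n_ctrl Control points per tube.
#' @return A [volume()].
#' @export
make_vessel_phantom <- function(shape, voxel_size = c(1, 1, 1), n_vessels = 1,
                                seed = 1, radius_range = c(2, 4),
                                amplitude = 100, n_ctrl = 6,
                                origin = c(0, 0, 0)) {
  if (n_vessels < 1) stop("`n_vessels` must be >= 1")
  shape <- as.integer(shape)
  set.seed(seed)
  data <- array(0, dim = shape)
  hi <- origin + (shape - 1) * voxel_size
  zs_step <- min(voxel_size) / 2
  for (v in seq_len(n_vessels)) {
    r <- runif(1, radius_range[1], radius_range[2])
    zc <- seq(origin[1], hi[1], length.out = n_ctrl)
    xc <- runif(n_ctrl, origin[3] + r, hi[3] - r)
    yc <- runif(n_ctrl, origin[2] + r, hi[2] - r)
    zd <- seq(origin[1], hi[1], by = zs_step)
    xd <- spline(zc, xc, xout = zd)$y
    yd <- spline(zc, yc, xout = zd)$y
    xd <- pmin(pmax(xd, origin[3]), hi[3])
    yd <- pmin(pmax(yd, origin[2]), hi[2])
    nr <- ceiling(r / voxel_size)
    for (p in seq_along(zd)) {
      ci <- (c(zd[p], yd[p], xd[p]) - origin) / voxel_size + 1
      lo <- pmax(1L, floor(ci - nr))
      up <- pmin(shape, ceiling(ci + nr))
      iz <- lo[1]:up[1]; iy <- lo[2]:up[2]; ix <- lo[3]:up[3]
      dz2 <- ((iz - ci[1]) * voxel_size[1])^2
      dy2 <- ((iy - ci[2]) * voxel_size[2])^2
      dx2 <- ((ix - ci[3]) * voxel_size[3])^2
      d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
      inside <- d2 <= r^2
      sub <- data[iz, iy, ix, drop = FALSE]
      sub[inside] <- amplitude
      data[iz, iy, ix] <- sub
    }
  }
  volume(data, voxel_size, origin)
}

#' Curved-shell phantom
#'
#' A cylindrically curved fluorescent shell (an embryo-surface analog):
#' `z*(x) = z_bottom + radius - sqrt(radius^2 - (x - x_center)^2)`, invariant
#' along y, decorated with Gaussian blobs on the surface plus optional
#' off-surface distractor blobs. The exact surface and a blob table (with an
#' `on_surface` flag, defined as `|z - z*(x)| < 1` micrometer) are returned.
#'
#' @param shape,voxel_size,origin Volume geometry.
#' @param x_center,radius,z_bottom Arc parameters, micrometers.
#' @param x_halfspan Half extent of the shell along x, micrometers; keep
#'   `x_halfspan / sqrt(radius^2 - x_halfspan^2) * tan(phi) < 1` for the tilt
#'   the phantom will be imaged with.
#' @param thickness Shell thickness, micrometers.
#' @param shell_amplitude Shell intensity.
#' @param n_blobs,n_distractors Numbers of on-surface / off-surface blobs.
#' @param blob_amplitude,blob_sigma Blob photometry.
#' @param distractor_offset Axial distance of distractors from the surface,
#'   micrometers.
#' @param half_width Stored in the returned [surface_spec()].
#' @param seed Integer seed.
#' @return `list(volume = , surface = , blobs = )`.
#' @export
make_shell_phantom <- function(shape, voxel_size = c(1, 1, 1),
                               x_center = 128, radius = 150, z_bottom = 60,
                               x_halfspan = 88, thickness = 2,
                               shell_amplitude = 5, n_blobs = 0,
                               n_distractors = 0, blob_amplitude = 100,
                               blob_sigma = 1, distractor_offset = 15,
                               half_width = 2.5, seed = 1,
                               origin = c(0, 0, 0)) {
  if (x_halfspan >= radius) stop("`x_halfspan` must be smaller than `radius`")
  shape <- as.integer(shape)
  set.seed(seed)
  xg <- origin[3] + (seq_len(shape[3]) - 1) * voxel_size[3]
  keep <- which(abs(xg - x_center) <= x_halfspan)
  if (!length(keep)) stop("shell does not intersect the volume along x")
  zstar_of <- function(x) z_bottom + radius - sqrt(radius^2 - (x - x_center)^2)
  zstar <- zstar_of(xg[keep])
  zg <- origin[1] + (seq_len(shape[1]) - 1) * voxel_size[1]
  if (min(zstar) - thickness / 2 < min(zg) ||
      max(zstar) + thickness / 2 > max(zg))
    stop("arc exits the volume along z")
  data <- array(0, dim = shape)
  for (j in seq_along(keep)) {
    zmask <- abs(zg - zstar[j]) < thickness / 2
    if (any(zmask)) data[zmask, , keep[j]] <- shell_amplitude
  }
  blobs <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0),
                      on_surface = logical(0))
  span <- 0.9 * x_halfspan
  hi <- origin + (shape - 1) * voxel_size
  if (n_blobs > 0) {
    bx <- runif(n_blobs, x_center - span, x_center + span)
    blobs <- rbind(blobs, data.frame(
      x = bx, y = runif(n_blobs, origin[2] + 4 * blob_sigma,
                        hi[2] - 4 * blob_sigma),
      z = zstar_of(bx), amplitude = blob_amplitude, sigma = blob_sigma,
      on_surface = TRUE))
  }
  if (n_distractors > 0) {
    dx <- runif(n_distractors, x_center - span, x_center + span)
    dzs <- zstar_of(dx) + distractor_offset *
      ifelse(zstar_of(dx) + distractor_offset < hi[1] - 4 * blob_sigma, 1, -1)
    blobs <- rbind(blobs, data.frame(
      x = dx, y = runif(n_distractors, origin[2] + 4 * blob_sigma,
                        hi[2] - 4 * blob_sigma),
      z = dzs, amplitude = blob_amplitude, sigma = blob_sigma,
      on_surface = FALSE))
  }
  if (nrow(blobs)) {
    check_in_bounds(blobs, voxel_size, origin, shape, what = "blob")
    data <- splat_gaussians(data, voxel_size, origin, blobs)
  }
  list(volume = volume(data, voxel_size, origin),
       surface = surface_spec(xg[keep], zstar, half_width = half_width),
       blobs = blobs)
}

#' Calcium transient kernel
#'
#' Double-exponential impulse response resembling GCaMP kinetics:
#' `k(t) = (1 - exp(-t / tau_r)) * exp(-t / tau_d)` for `t >= 0`, else 0.
#'
#' @param t Time since transient onset, seconds.
#' @param tau_r,tau_d Rise and decay time constants, seconds.
#' @return Kernel values (unit amplitude scale).
#' @export
calcium_kernel <- function(t, tau_r = 0.05, tau_d = 0.5) {
  ifelse(t < 0, 0, (1 - exp(-t / tau_r)) * exp(-t / tau_d))
}

#' Two-layer calcium phantom
#'
#' Soma-like cells (3D Gaussian blobs) in two axially separated layers, each
#' with a baseline fluorescence `F0` and seeded calcium transients
#' `F(t) = F0 * (1 + sum_k A * kernel(t - t_k))`. Cell geometry, kinetics and
#' onset times are returned as ground truth.
#'
#' @param shape,voxel_size,origin Volume geometry.
#' @param layer_z Heights of the two layers, micrometers; must be separated
#'   by more than one cell diameter.
#' @param n_cells Cells per layer.
#' @param cell_sigma Cell Gaussian radius, micrometers.
#' @param f0 Baseline peak intensity.
#' @param amplitude Transient dF/F amplitude `A`.
#' @param tau_r,tau_d Kernel time constants, seconds.
#' @param n_transients Transients per cell.
#' @param duration Movie length, seconds.
#' @param frame_interval Seconds per frame.
#' @param noise_photon_scale If non-`NULL`, per-frame Poisson noise at this
#'   photon scale (seeded).
#' @param seed Integer seed.
#' @return `list(movie = time_lapse of volumes, truth = list(cells, onsets))`.
#' @export
make_calcium_phantom <- function(shape = c(64, 24, 48),
                                 voxel_size = c(1, 1, 1),
                                 layer_z = c(15, 55), n_cells = 4,
                                 cell_sigma = 2, f0 = 100, amplitude = 0.5,
                                 tau_r = 0.05, tau_d = 0.5, n_transients = 1,
                                 duration = 3, frame_interval = 0.02,
                                 noise_photon_scale = NULL, seed = 1,
                                 origin = c(0, 0, 0)) {
  if (length(layer_z) != 2L) stop("`layer_z` must give two layer heights")
  if (abs(diff(layer_z)) <= 4 * cell_sigma)
    stop("layers must be separated by more than one cell diameter")
  shape <- as.integer(shape)
  set.seed(seed)
  hi <- origin + (shape - 1) * voxel_size
  mx <- min(4 * cell_sigma, (hi[3] - origin[3]) / 4)
  my <- min(4 * cell_sigma, (hi[2] - origin[2]) / 4)
  # layer-2 cells sit on the midpoints of the layer-1 x grid (staggered), so
  # the two layers stay laterally distinguishable in projections
  base <- seq(origin[3] + mx, hi[3] - mx, length.out = n_cells + 1L)
  jit <- cell_sigma / 2
  cells <- do.call(rbind, lapply(1:2, function(l) {
    xs <- if (l == 1L) base[seq_len(n_cells)] else
      (base[seq_len(n_cells)] + base[seq_len(n_cells) + 1L]) / 2
    xs <- xs + runif(n_cells, -jit, jit)
    data.frame(cell = paste0("L", l, "_", seq_len(n_cells)), layer = l,
               x = xs, y = runif(n_cells, origin[2] + my, hi[2] - my),
               z = layer_z[l], radius = cell_sigma, f0 = f0,
               amplitude = amplitude, tau_r = tau_r, tau_d = tau_d)
  }))
  if (nrow(cells) > 1) {
    dd <- as.matrix(stats::dist(cells[, c("x", "y")]))
    diag(dd) <- Inf
    if (min(dd) < 1.5 * cell_sigma)
      warning("cells overlap by more than ~20% of their volume")
  }
  onsets <- lapply(seq_len(nrow(cells)), function(i) {
    if (n_transients == 0) return(numeric(0))
    sort(runif(n_transients, 0.1 * duration, 0.7 * duration))
  })
  names(onsets) <- cells$cell
  times <- seq(0, duration, by = frame_interval)
  # per-cell unit patch, scaled per frame by F_c(t)
  patches <- lapply(seq_len(nrow(cells)), function(i) {
    tb <- cells[i, ]
    tmp <- array(0, dim = shape)
    tmp <- splat_gaussians(tmp, voxel_size, origin,
                           data.frame(x = tb$x, y = tb$y, z = tb$z,
                                      amplitude = 1, sigma = tb$radius))
    idx <- which(tmp > 0)
    list(idx = idx, val = tmp[idx])
  })
  items <- vector("list", length(times))
  for (ti in seq_along(times)) {
    arr <- array(0, dim = shape)
    for (i in seq_len(nrow(cells))) {
      dff <- sum(cells$amplitude[i] *
                   calcium_kernel(times[ti] - onsets[[i]],
                                  cells$tau_r[i], cells$tau_d[i]))
      f <- cells$f0[i] * (1 + dff)
      p <- patches[[i]]
      arr[p$idx] <- arr[p$idx] + f * p$val
    }
    if (!is.null(noise_photon_scale)) {
      arr[] <- rpois(length(arr), noise_photon_scale * arr) /
        noise_photon_scale
    }
    items[[ti]] <- volume(arr, voxel_size, origin)
  }
  list(movie = time_lapse(items, frame_interval),
       truth = list(cells = cells, onsets = onsets, times = times))
}

conv1d_norm <- function(m, sigma_px, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (sigma_px <= 0) return(m)
  L <- max(1L, ceiling(3 * sigma_px))
  w <- dnorm(-L:L, sd = sigma_px)
  w <- w / sum(w)
  out <- matrix(0, nrow(m), ncol(m))
  if (along == "rows") {
    n <- nrow(m)
    for (j in -L:L) {
      src <- max(1, 1 + j):min(n, n + j)
      dst <- src - j
      out[dst, ] <- out[dst, ] + w[j + L + 1] * m[src, ]
    }
  } else {
    n <- ncol(m)
    for (j in -L:L) {
      src <- max(1, 1 + j):min(n, n + j)
      dst <- src - j
      out[, dst] <- out[, dst] + w[j + L + 1] * m[, src]
    }
  }
  out
}

#' Depth-dependent scattering haze
#'
#' A deliberately simple scattering surrogate: each z-plane is blurred with a
#' normalized Gaussian of width `sigma(z) = sigma0 + k * z` (so blur grows
#' with depth) and a spatially uniform pedestal of `pedestal_frac` times the
#' plane mean is added. The blur kernel is normalized, so away from the
#' lateral boundaries the per-plane sum is conserved and the total intensity
#' increases by exactly the pedestal contribution.
#'
#' @param vol A [volume()].
#' @param sigma0 Blur at z = 0, micrometers (>= 0).
#' @param k Blur growth per micrometer of depth (>= 0).
#' @param pedestal_frac Pedestal as a fraction of the plane mean (>= 0).
#' @return A hazed [volume()].
#' @export
add_haze <- function(vol, sigma0 = 0, k = 0, pedestal_frac = 0) {
  stopifnot(inherits(vol, "props_volume"))
  if (sigma0 < 0 || k < 0 || pedestal_frac < 0)
    stop("`sigma0`, `k` and `pedestal_frac` must be >= 0")
  data <- vol$data
  zg <- vol_coords(vol, "z")
  for (iz in seq_along(zg)) {
    s <- sigma0 + k * zg[iz]
    plane <- data[iz, , ]
    if (s > 0) {
      plane <- conv1d_norm(plane, s / vol$voxel_size[2], "rows")
      plane <- conv1d_norm(plane, s / vol$voxel_size[3], "cols")
    }
    data[iz, , ] <- plane + pedestal_frac * mean(plane)
  }
  volume(data, vol$voxel_size, vol$origin)
}
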
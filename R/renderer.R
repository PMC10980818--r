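# linear interpolation of each row of `plane` (ny x nx, volume x-grid) at
# fractional x indices `fx` (0-based); out-of-range -> 0
sample_plane_x <- function(plane, fx) {
  nx <- ncol(plane)
  ok <- fx >= 0 & fx <= nx - 1
  fxc <- pmin(pmax(fx, 0), nx - 1)
  i0 <- floor(fxc)
  a <- fxc - i0
  i1 <- pmin(i0 + 1, nx - 1)
  out <- plane[, i0 + 1, drop = FALSE] * rep(1 - a, each = nrow(plane)) +
    plane[, i1 + 1, drop = FALSE] * rep(a, each = nrow(plane))
  out[, !ok] <- 0
  out
}

#' Digital shear-warp slab projection
#'
#' The post-hoc rendering analog of a props acquisition, and the package's
#' independent oracle for the optical simulator: z-planes are masked by slab
#' membership (hard: plane center inside the closed interval
#' `z_center +/- z_depth / 2`; gaussian: weight
#' `exp(-(z - z_center)^2 / (2 sigma^2))` with `sigma = z_depth / 2.355`),
#' each plane is sampled at `x0 + z * tan(psi)` (linear interpolation), and
#' the result is reduced along z. The final 2D warp of the shear-warp
#' factorization is a global affine and is not applied.
#'
#' @param vol A [volume()].
#' @param slab A [slab_spec()].
#' @param view A [view_spec()] (default top-down).
#' @param reducer `"sum"` (linear in the volume), `"max"` or `"mean"`.
#' @param row_origin,n_rows,pixel_pitch Output row grid; defaults to the
#'   volume's x grid.
#' @return A [frame()] (rows = projection coordinate, columns = y).
#' @export
slab_project <- function(vol, slab, view = view_spec(0),
                         reducer = c("sum", "max", "mean"),
                         row_origin = NULL, n_rows = NULL,
                         pixel_pitch = NULL) {
  stopifnot(inherits(vol, "props_volume"), inherits(slab, "slab_spec"),
            inherits(view, "view_spec"))
  reducer <- match.arg(reducer)
  d <- dim(vol$data)
  pixel_pitch <- pixel_pitch %||% vol$voxel_size[3]
  row_origin <- row_origin %||% vol$origin[3]
  n_rows <- as.integer(n_rows %||% d[3])
  zg <- vol_coords(vol, "z")
  if (slab$weighting == "hard") {
    inside <- abs(zg - slab$z_center) <= slab$z_depth / 2
    wz <- as.numeric(inside)
  } else {
    sigma <- slab$z_depth / 2.355
    wz <- if (sigma > 0) exp(-(zg - slab$z_center)^2 / (2 * sigma^2)) else
      as.numeric(zg == slab$z_center)
  }
  sel <- which(wz > 1e-12)
  tpsi <- tan(deg2rad(view$psi))
  rows_um <- row_origin + (seq_len(n_rows) - 1) * pixel_pitch
  acc <- matrix(0, n_rows, d[2])
  cnt <- 0
  if (!length(sel)) {
    warning("empty slab: no z-plane lies inside the selection")
  }
  for (iz in sel) {
    fx <- (rows_um + zg[iz] * tpsi - vol$origin[3]) / vol$voxel_size[3]
    shifted <- t(sample_plane_x(vol$data[iz, , , drop = TRUE], fx))
    w <- wz[iz]
    if (reducer == "max") {
      acc <- pmax(acc, w * shifted)
    } else {
      acc <- acc + w * shifted
      cnt <- cnt + 1
    }
  }
  if (reducer == "mean" && cnt > 0) acc <- acc / cnt
  frame(acc, pixel_size = c(pixel_pitch, vol$voxel_size[2]),
        origin = c(row_origin, vol$origin[2]),
        meta = list(slab = slab, view = view, reducer = reducer))
}

#' Curved-surface projection
#'
#' For each (x, y), reduces the intensity over the band
#' `z*(x) +/- half_width` (plane centers inside the closed band;
#' `half_width = 0` takes a single z-interpolated sample at `z*(x)`). The
#' output x coordinate is the untransformed x: the curved layer is mapped to
#' a planar image.
#'
#' @param vol A [volume()].
#' @param surface A [surface_spec()] (its `half_width` is used). If the
#'   surface does not cover the volume's full x-range the output is
#'   restricted to the covered range, with a warning.
#' @param reducer `"sum"`, `"max"` or `"mean"`.
#' @return A [frame()] (rows = x over the covered range, columns = y).
#' @export
curved_project <- function(vol, surface, reducer = c("sum", "max", "mean")) {
  stopifnot(inherits(vol, "props_volume"), inherits(surface, "surface_spec"))
  reducer <- match.arg(reducer)
  d <- dim(vol$data)
  xg <- vol_coords(vol, "x")
  zg <- vol_coords(vol, "z")
  covered <- which(xg >= min(surface$x) & xg <= max(surface$x))
  if (!length(covered)) stop("surface does not cover any volume x position")
  if (length(covered) < d[3])
    warning("surface covers only part of the volume x-range; output restricted")
  zstar <- approx(surface$x, surface$z, xout = xg[covered])$y
  hw <- surface$half_width
  if (any(zstar - hw < min(zg) - vol$voxel_size[1] / 2) ||
      any(zstar + hw > max(zg) + vol$voxel_size[1] / 2))
    stop("surface band lies outside the volume z-range")
  out <- matrix(0, length(covered), d[2])
  for (j in seq_along(covered)) {
    ix <- covered[j]
    if (hw == 0) {
      fz <- (zstar[j] - vol$origin[1]) / vol$voxel_size[1] + 1
      iz0 <- max(1, min(floor(fz), d[1] - 1))
      a <- fz - iz0
      out[j, ] <- (1 - a) * vol$data[iz0, , ix] + a * vol$data[iz0 + 1, , ix]
    } else {
      sel <- which(abs(zg - zstar[j]) <= hw)
      if (!length(sel)) next
      col <- vol$data[sel, , ix, drop = FALSE]
      out[j, ] <- switch(reducer,
                         sum = colSums(matrix(col, length(sel), d[2])),
                         mean = colMeans(matrix(col, length(sel), d[2])),
                         max = apply(matrix(col, length(sel), d[2]), 2, max))
    }
  }
  frame(out, pixel_size = c(vol$voxel_size[3], vol$voxel_size[2]),
        origin = c(xg[covered[1]], vol$origin[2]),
        meta = list(surface = surface, reducer = reducer))
}

#' Shift a frame along its row axis
#'
#' Linear-interpolation translation of the projection coordinate, e.g. to
#' digitally unshear an oblique projection back to the top-down geometry.
#'
#' @param fr A [frame()].
#' @param shift_um Row-axis shift, micrometers; content moves by
#'   `-shift_um` (the frame is resampled at `row + shift_um`).
#' @return The shifted [frame()].
#' @export
shift_frame <- function(fr, shift_um) {
  stopifnot(inherits(fr, "props_frame"))
  fpix <- shift_um / fr$pixel_size[1]
  n <- nrow(fr$data)
  fx <- (seq_len(n) - 1) + fpix
  out <- fr
  out$data <- t(sample_plane_x(t(fr$data), fx))
  out
}

frame_centroid <- function(m, rows = seq_len(nrow(m))) {
  sub <- m[rows, , drop = FALSE]
  tot <- sum(sub)
  if (tot == 0) return(c(NA_real_, NA_real_))
  c(sum(rowSums(sub) * rows) / tot,
    sum(colSums(sub) * seq_len(ncol(sub))) / tot)
}

#' Compare two frames
#'
#' Oracle-equivalence harness: normalized RMSE
#' (`RMSE / (max(a) - min(a))`), Pearson correlation, and per-spot centroid
#' offsets for labeled spots.
#'
#' @param a,b [frame()]s of identical shape and pixel size.
#' @param spots Optional data frame with columns `row`, `col` (1-based pixel
#'   positions of spots to track).
#' @param window Half-width (pixels) of the centroid window around each spot.
#' @return A list with `nrmse`, `correlation` and (when `spots` is given) a
#'   data frame `centroid_offsets` of row/col offsets in pixels.
#' @export
compare_frames <- function(a, b, spots = NULL, window = 4L) {
  stopifnot(inherits(a, "props_frame"), inherits(b, "props_frame"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("frame shapes differ")
  if (max(abs(a$pixel_size - b$pixel_size)) > 1e-9)
    stop("frame pixel sizes differ")
  rng <- max(a$data) - min(a$data)
  rmse <- sqrt(mean((a$data - b$data)^2))
  nrmse <- if (rng > 0) rmse / rng else if (rmse == 0) 0 else Inf
  corr <- if (sd(a$data) > 0 && sd(b$data) > 0)
    stats::cor(as.vector(a$data), as.vector(b$data)) else NA_real_
  out <- list(nrmse = nrmse, correlation = corr)
  if (!is.null(spots) && nrow(spots)) {
    offs <- t(vapply(seq_len(nrow(spots)), function(i) {
      r0 <- max(1, round(spots$row[i]) - window)
      r1 <- min(nrow(a$data), round(spots$row[i]) + window)
      c0 <- max(1, round(spots$col[i]) - window)
      c1 <- min(ncol(a$data), round(spots$col[i]) + window)
      ca <- frame_centroid(a$data[r0:r1, c0:c1, drop = FALSE])
      cb <- frame_centroid(b$data[r0:r1, c0:c1, drop = FALSE])
      cb - ca
    }, numeric(2)))
    out$centroid_offsets <- data.frame(d_row = offs[, 1], d_col = offs[, 2])
  }
  out
}
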
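#' Intensity volume
#'
#' A 3D nonnegative intensity grid with physical voxel sizes. Arrays are
#' indexed `(z, y, x)`; the continuous coordinate of voxel `(i, j, k)`
#' (1-based indices) is `origin + (i - 1, j - 1, k - 1) * voxel_size`
#' micrometers (voxel-center convention).
#'
#' @param data 3D numeric array, all values finite and >= 0.
#' @param voxel_size Numeric length 3, `(dz, dy, dx)` micrometers, all > 0.
#' @param origin Numeric length 3, `(z0, y0, x0)` micrometers.
#' @return An object of class `props_volume`.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume values must be finite")
  if (any(data < 0)) stop("volume values must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (dz, dy, dx)")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "props_volume")
}

#' @export
print.props_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<props_volume> %d x %d x %d voxels (z,y,x) at (%g, %g, %g) um; total %.4g\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    sum(x$data)))
  invisible(x)
}

#' Physical axis coordinates of a volume
#'
#' @param vol A [volume()].
#' @param axis One of `"z"`, `"y"`, `"x"`.
#' @return Voxel-center coordinates along the axis, micrometers.
#' @export
vol_coords <- function(vol, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  i <- match(axis, c("z", "y", "x"))
  vol$origin[i] + (seq_len(dim(vol$data)[i]) - 1) * vol$voxel_size[i]
}

vol_extent <- function(vol) {
  vol$origin + (dim(vol$data) - 1) * vol$voxel_size
}

#' Projection frame
#'
#' A single 2D projection image. Rows index the projection coordinate (the
#' sheared camera-row coordinate mapped to sample-space x, micrometers) and
#' columns index y. Row `i` (1-based) sits at `origin[1] + (i - 1) *
#' pixel_size[1]` micrometers, and likewise for columns.
#'
#' @param data 2D numeric matrix, finite.
#' @param pixel_size Numeric length 2: (row pitch, column pitch), micrometers.
#' @param origin Numeric length 2: coordinates of pixel (1, 1), micrometers.
#' @param meta List of provenance metadata (e.g. the acquisition or render
#'   parameters that produced the frame).
#' @return An object of class `props_frame`.
#' @export
frame <- function(data, pixel_size = c(1, 1), origin = c(0, 0),
                  meta = list()) {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (anyNA(data) || any(!is.finite(data))) stop("frame values must be finite")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (any(pixel_size <= 0)) stop("`pixel_size` must be > 0")
  structure(list(data = data, pixel_size = pixel_size,
                 origin = as.numeric(origin), meta = meta),
            class = "props_frame")
}

#' @export
print.props_frame <- function(x, ...) {
  cat(sprintf("<props_frame> %d x %d px at (%g, %g) um; total %.4g\n",
              nrow(x$data), ncol(x$data), x$pixel_size[1], x$pixel_size[2],
              sum(x$data)))
  invisible(x)
}

#' Time-lapse container
#'
#' A sequence of volumes (or frames) of constant shape and voxel size with a
#' fixed frame interval.
#'
#' @param items List of [volume()]s (a 3D+t movie or a z-stack) or
#'   [frame()]s.
#' @param frame_interval Seconds between consecutive items (> 0).
#' @return An object of class `time_lapse`.
#' @export
time_lapse <- function(items, frame_interval = 1) {
  if (!length(items)) stop("`items` must be non-empty")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  d1 <- dim(items[[1]]$data)
  for (i in seq_along(items)) {
    if (!identical(dim(items[[i]]$data), d1))
      stop(sprintf("item %d has a different shape", i))
  }
  structure(list(items = items, frame_interval = frame_interval),
            class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d items, interval %g s\n", length(x$items),
              x$frame_interval))
  invisible(x)
}

#' @rdname time_lapse
#' @param tl A `time_lapse`.
#' @return `frame_times()`: acquisition times of the items, seconds.
#' @export
frame_times <- function(tl) {
  (seq_along(tl$items) - 1) * tl$frame_interval
}
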
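#' Optical configuration
#'
#' Fixed optical parameters of the props geometry. The coordinate convention
#' is: x = scan axis along the coverslip, y = sheet-invariant axis (camera
#' columns), z = height above the coverslip; all lengths in micrometers,
#' angles in degrees; volume arrays are indexed (z, y, x) with voxel-center,
#' 0-based continuous coordinates. Optical magnification is fixed at 1, so the
#' camera row coordinate is expressed directly in sample-space micrometers.
#'
#' @param tilt_phi Tilt of the light-sheet plane's in-plane direction from the
#'   z-axis, degrees; the sheet spans y and the unit vector
#'   (sin phi, 0, cos phi). Must lie strictly between 0 and 90.
#' @param sheet_sigma Light-sheet 1/e half-thickness (Gaussian profile across
#'   the sheet), micrometers. 0 means an ideal thin sheet.
#' @param pixel_pitch Camera pixel size mapped to sample space, micrometers.
#' @param z_max Usable height above the coverslip, micrometers.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(tilt_phi = 45, sheet_sigma = 0, pixel_pitch = 1,
                          z_max = 100) {
  stopifnot(is.numeric(tilt_phi), length(tilt_phi) == 1L, is.finite(tilt_phi))
  if (tilt_phi <= 0 || tilt_phi >= 90)
    stop("`tilt_phi` must lie strictly between 0 and 90 degrees")
  if (!is.numeric(sheet_sigma) || sheet_sigma < 0)
    stop("`sheet_sigma` must be >= 0")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("`pixel_pitch` must be > 0")
  if (!is.numeric(z_max) || z_max <= 0)
    stop("`z_max` must be > 0")
  structure(list(tilt_phi = tilt_phi, sheet_sigma = sheet_sigma,
                 pixel_pitch = pixel_pitch, z_max = z_max),
            class = "optics_config")
}

#' Focal-sweep configuration
#'
#' The focal sweep moves the sheet from `s_start` to `s_end` (scan positions
#' along x, micrometers) linearly in time over `duration` seconds, so the scan
#' speed is `v_s = (s_end - s_start) / duration`.
#'
#' @param s_start,s_end Scan range, micrometers; `s_end > s_start`.
#' @param n_steps Integer sweep sampling for the simulator; `NULL` (default)
#'   resolves at simulation time to one step per camera-row pixel of travel.
#' @param duration Sweep duration, seconds.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(s_start, s_end, n_steps = NULL, duration = 1) {
  if (s_end <= s_start) stop("`s_end` must be greater than `s_start`")
  if (!is.null(n_steps)) {
    n_steps <- as.integer(n_steps)
    if (n_steps < 2L) stop("`n_steps` must be >= 2")
  }
  if (duration <= 0) stop("`duration` must be > 0")
  structure(list(s_start = s_start, s_end = s_end, n_steps = n_steps,
                 duration = duration),
            class = "sweep_config")
}

#' @rdname sweep_config
#' @param sweep A `sweep_config`.
#' @return `scan_speed()`: the scan speed in micrometers per second.
#' @export
scan_speed <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_config"))
  (sweep$s_end - sweep$s_start) / sweep$duration
}

#' Shear waveform
#'
#' Total image shift on the camera as a function of scan position:
#' `g(s) = rate * s + q(s) + offset`, in sample-space micrometers. The linear
#' rate sets the viewing angle; the nonlinear component `q(s)` lets the
#' selected layer vary axially during the sweep (curved-surface projection).
#'
#' @param rate Dimensionless shear rate (camera-row micrometers per scan
#'   micrometer); must be > 0.
#' @param offset Constant image shift, micrometers.
#' @param q Optional nonlinear component: a data frame with columns `s` and
#'   `q` (micrometers), `s` strictly increasing. `NULL` means `q(s) == 0`.
#' @return An object of class `shear_waveform`.
#' @export
shear_waveform <- function(rate = 1, offset = 0, q = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  if (!is.null(q)) {
    q <- as.data.frame(q)
    if (!all(c("s", "q") %in% names(q)))
      stop("`q` must have columns `s` and `q`")
    if (any(!is.finite(q$s)) || any(!is.finite(q$q)))
      stop("`q` samples must be finite")
    if (any(diff(q$s) <= 0)) stop("`q$s` must be strictly increasing")
  }
  structure(list(rate = rate, offset = offset, q = q),
            class = "shear_waveform")
}

has_nonlinear_q <- function(shear) {
  !is.null(shear$q) && any(shear$q$q != 0)
}

#' Evaluate the nonlinear shear component
#'
#' @param shear A [shear_waveform()].
#' @param s Scan positions, micrometers.
#' @return `q(s)` in micrometers (constant extrapolation outside the sampled
#'   grid; 0 everywhere when no nonlinear component is set).
#' @export
eval_q <- function(shear, s) {
  if (is.null(shear$q)) return(rep(0, length(s)))
  approx(shear$q$s, shear$q$q, xout = s, rule = 2)$y
}

#' @rdname shear_waveform
#' @param shear A `shear_waveform`.
#' @param sweep A [sweep_config()].
#' @return `row_speed()`: the shutter/image row speed `v_u = rate * v_s`,
#'   micrometers per second.
#' @export
row_speed <- function(shear, sweep) {
  stopifnot(inherits(shear, "shear_waveform"))
  shear$rate * scan_speed(sweep)
}

#' Rolling-shutter configuration
#'
#' The active rolling-shutter window, expressed in sample-space row units
#' (micrometers; magnification 1). When synchronized to the shear, the shutter
#' center row follows `u_sh(s) = rate * s + center + v_u * delay` where
#' `v_u = rate * v_s` is the row speed. Positive `delay` therefore moves the
#' selected slab up (+z).
#'
#' @param width Rolling-shutter window extent, micrometers (>= 0). `Inf`
#'   means a fully open (global) shutter.
#' @param center Shutter row offset at `s = s_start`, micrometers.
#' @param delay Time delay between the shutter sweep and the focal sweep,
#'   seconds.
#' @param synchronized Logical; the shutter row slope equals the shear rate.
#'   Only synchronized acquisitions are modeled.
#' @return An object of class `shutter_config`.
#' @seealso [shutter_um_to_rows()] and [shutter_rows_to_um()] to convert the
#'   width between camera rows and micrometers.
#' @export
shutter_config <- function(width = Inf, center = 0, delay = 0,
                           synchronized = TRUE) {
  if (!is.numeric(width) || is.na(width) || width < 0)
    stop("`width` must be >= 0")
  structure(list(width = width, center = center, delay = delay,
                 synchronized = isTRUE(synchronized)),
            class = "shutter_config")
}

#' Convert shutter width between camera rows and micrometers
#'
#' @param rows,um Width in camera rows / in sample-space micrometers.
#' @param optics An [optics_config()] (supplies the pixel pitch).
#' @return The converted width.
#' @export
shutter_rows_to_um <- function(rows, optics) rows * optics$pixel_pitch

#' @rdname shutter_rows_to_um
#' @export
shutter_um_to_rows <- function(um, optics) um / optics$pixel_pitch

#' Camera noise model
#'
#' Shot noise plus Gaussian read noise:
#' `Poisson(photon_scale * value) / photon_scale + N(0, read_sigma) + offset`.
#'
#' @param photon_scale Counts per intensity unit (> 0).
#' @param read_sigma Read-noise standard deviation, counts (>= 0).
#' @param offset Constant camera offset, counts.
#' @param seed Optional integer seed for reproducible noise.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 1, read_sigma = 0, offset = 0,
                        seed = NULL) {
  if (photon_scale <= 0) stop("`photon_scale` must be > 0")
  if (read_sigma < 0) stop("`read_sigma` must be >= 0")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset, seed = seed),
            class = "noise_model")
}

#' Full acquisition configuration
#'
#' Bundles optics, sweep, shear and shutter (plus an optional noise model and
#' an optional explicit frame grid) into one object consumed by
#' [simulate_projection()].
#'
#' @param optics An [optics_config()].
#' @param sweep A [sweep_config()].
#' @param shear A [shear_waveform()].
#' @param shutter A [shutter_config()].
#' @param noise A [noise_model()] or `NULL`.
#' @param frame_origin,n_rows Optional frame row grid: the sample-space
#'   coordinate of row 0 (micrometers) and the number of rows. When `NULL`
#'   the grid is derived from the volume extent and the viewing angle.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(optics, sweep, shear, shutter, noise = NULL,
                       frame_origin = NULL, n_rows = NULL) {
  stopifnot(inherits(optics, "optics_config"),
            inherits(sweep, "sweep_config"),
            inherits(shear, "shear_waveform"),
            inherits(shutter, "shutter_config"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  structure(list(optics = optics, sweep = sweep, shear = shear,
                 shutter = shutter, noise = noise,
                 frame_origin = frame_origin, n_rows = n_rows),
            class = "acq_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "<optics_config> tilt %g deg, sheet sigma %g um, pixel %g um, z_max %g um\n",
    x$tilt_phi, x$sheet_sigma, x$pixel_pitch, x$z_max))
  invisible(x)
}

#' @export
print.shutter_config <- function(x, ...) {
  cat(sprintf("<shutter_config> width %g um, center %g um, delay %g s%s\n",
              x$width, x$center, x$delay,
              if (x$synchronized) ", synchronized" else ""))
  invisible(x)
}

#' @export
print.shear_waveform <- function(x, ...) {
  cat(sprintf("<shear_waveform> rate %g, offset %g um, %s\n", x$rate, x$offset,
              if (is.null(x$q)) "linear" else
                sprintf("nonlinear q on %d samples", nrow(x$q))))
  invisible(x)
}
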
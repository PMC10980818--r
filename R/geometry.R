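#' Slab specification
#'
#' The axial sub-volume selected by a synchronized rolling shutter: a slab
#' centered at `z_center` of depth `z_depth` (micrometers).
#'
#' @param z_center,z_depth Slab center and depth, micrometers.
#' @param weighting `"hard"` (top-hat membership, the oracle definition) or
#'   `"gaussian"` (smooth window of matched FWHM).
#' @return An object of class `slab_spec`.
#' @export
slab_spec <- function(z_center, z_depth, weighting = c("hard", "gaussian")) {
  weighting <- match.arg(weighting)
  if (z_depth < 0) stop("`z_depth` must be >= 0")
  structure(list(z_center = z_center, z_depth = z_depth,
                 weighting = weighting),
            class = "slab_spec")
}

#' @export
print.slab_spec <- function(x, ...) {
  cat(sprintf("<slab_spec> center %g um, depth %g um (%s)\n",
              x$z_center, x$z_depth, x$weighting))
  invisible(x)
}

#' Viewing-angle specification
#'
#' Signed viewing angle `psi` in degrees, measured from the z-axis in the x-z
#' plane. Projection rays run along `x = x0 + z * tan(psi)`, so a structure at
#' height z appears at image coordinate `x0 = x - z * tan(psi)`; `psi = 0` is
#' the top-down view.
#'
#' @param psi Viewing angle, degrees; `|psi| < 90`.
#' @return An object of class `view_spec`.
#' @export
view_spec <- function(psi = 0) {
  if (!is.finite(psi) || abs(psi) >= 90)
    stop("`psi` must satisfy |psi| < 90 degrees")
  structure(list(psi = psi), class = "view_spec")
}

#' Curved-surface specification
#'
#' A target surface `z*(x)` (invariant along y, matching the one-dimensional
#' shear of a single galvo) with a half-width defining the band
#' `z*(x) +/- half_width` that a curved projection integrates.
#'
#' @param x Strictly increasing sample positions, micrometers.
#' @param z Surface heights `z*(x)`, micrometers.
#' @param half_width Half thickness of the projected band, micrometers.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(x, z, half_width = 0) {
  if (length(x) != length(z)) stop("`x` and `z` must have equal length")
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  if (any(!is.finite(z))) stop("`z` must be finite")
  if (half_width < 0) stop("`half_width` must be >= 0")
  structure(list(x = x, z = z, half_width = half_width),
            class = "surface_spec")
}

#' Closed-form slab selection from shutter parameters
#'
#' For a synchronized shutter and a linear shear, a point at height z
#' illuminated at scan position `s = x - z tan(phi)` lands on camera row
#' `u = z / cos(phi) + g(s)`; the shutter center row is
#' `u_sh(s) = rate * s + center + v_u * delay`, so the row residual
#' `u - u_sh = z / cos(phi) + offset - center - v_u * delay` is independent of
#' x and of the shear rate. The selected slab is therefore
#' `z_depth = W cos(phi)` deep, centered at
#' `z_center = (center + v_u * delay - offset) cos(phi)`.
#'
#' @param shutter A [shutter_config()]; must be synchronized.
#' @param optics An [optics_config()].
#' @param sweep A [sweep_config()] (supplies the row speed `v_u`).
#' @param shear A [shear_waveform()]; must have no nonlinear component (use
#'   [predicted_surface()] for curved selections).
#' @return A [slab_spec()], clamped to `[0, z_max]` (with a warning if a
#'   finite slab lies partially outside).
#' @examples
#' opt <- optics_config(tilt_phi = 45, z_max = 10)
#' sw <- sweep_config(-10, 120)
#' sh <- shear_waveform(rate = 1 / sin(pi / 4))
#' slab_bounds(shutter_config(width = 3.536, center = 0), opt, sw, sh)
#' @export
slab_bounds <- function(shutter, optics, sweep, shear) {
  stopifnot(inherits(shutter, "shutter_config"),
            inherits(optics, "optics_config"))
  if (!shutter$synchronized)
    stop("only synchronized shutters are modeled by slab_bounds()")
  if (has_nonlinear_q(shear))
    stop("nonlinear shear waveform: use predicted_surface() instead")
  cphi <- cos(deg2rad(optics$tilt_phi))
  vu <- row_speed(shear, sweep)
  z_center <- (shutter$center + vu * shutter$delay - shear$offset) * cphi
  z_depth <- shutter$width * cphi
  lo <- z_center - z_depth / 2
  hi <- z_center + z_depth / 2
  if (is.infinite(z_depth)) {
    lo <- 0; hi <- optics$z_max
  } else if (lo < 0 || hi > optics$z_max) {
    warning(sprintf(
      "slab [%.3g, %.3g] um extends outside [0, %g]; clamping", lo, hi,
      optics$z_max))
    lo <- max(lo, 0); hi <- min(hi, optics$z_max)
    if (hi < lo) { lo <- hi <- min(max(z_center, 0), optics$z_max) }
  }
  slab_spec(z_center = (lo + hi) / 2, z_depth = hi - lo)
}

#' Viewing angle set by the shear rate
#'
#' Rows of the projected image are constant along sample lines
#' `x = x0 + z tan(psi)` with `tan(psi) = tan(phi) - 1 / (rate cos(phi))`.
#' `rate = 1 / sin(phi)` gives the top-down view (`psi = 0`).
#'
#' @param shear A [shear_waveform()] with no nonlinear component.
#' @param optics An [optics_config()].
#' @return A [view_spec()].
#' @export
viewing_angle <- function(shear, optics) {
  if (has_nonlinear_q(shear))
    stop("nonlinear shear waveform: the viewing angle varies along the sweep; ",
         "see local_view_angle()")
  phi <- deg2rad(optics$tilt_phi)
  view_spec(rad2deg(atan(tan(phi) - 1 / (shear$rate * cos(phi)))))
}

#' @rdname viewing_angle
#' @param psi Requested viewing angle, degrees; must be smaller than the tilt
#'   angle (angles `psi >= phi` would require a non-positive or infinite shear
#'   rate and are unreachable).
#' @return `shear_rate_for_view()`: the shear rate realizing `psi`; it
#'   round-trips through `viewing_angle()`.
#' @export
shear_rate_for_view <- function(psi, optics) {
  phi <- deg2rad(optics$tilt_phi)
  if (psi >= optics$tilt_phi)
    stop(sprintf(
      "viewing angle %g deg is unreachable: requires rate <= 0 or infinite (tilt %g deg)",
      psi, optics$tilt_phi))
  1 / (cos(phi) * (tan(phi) - tan(deg2rad(psi))))
}

#' Design a nonlinear shear waveform for a curved-surface projection
#'
#' Finds the nonlinear shear component `q(s)` that keeps the center of the
#' rolling-shutter-selected layer on a target surface `z*(x)`. Each surface
#' point is illuminated at `s(x) = x - z*(x) tan(phi)`; provided `s(x)` is
#' strictly increasing (guaranteed by the invertibility bound
#' `max |dz*/dx| tan(phi) < 1`), the inverse map `x(s)` exists and
#' `q(s) = center + v_u delay - offset - z*(x(s)) / cos(phi)` places the
#' shutter center on the surface.
#'
#' @param surface A [surface_spec()]; all heights must lie in `[0, z_max]`.
#' @param optics An [optics_config()].
#' @param shutter A [shutter_config()].
#' @param sweep A [sweep_config()]; `q` is resampled on the sweep's s-grid,
#'   which must cover the surface's illumination range.
#' @param shear_base A [shear_waveform()] providing the linear rate and offset.
#' @return A [shear_waveform()] with the designed nonlinear component;
#'   [predicted_surface()] of the result reproduces `z*(x)`.
#' @export
design_shear_waveform <- function(surface, optics, shutter, sweep,
                                  shear_base = shear_waveform()) {
  stopifnot(inherits(surface, "surface_spec"))
  phi <- deg2rad(optics$tilt_phi)
  if (any(surface$z < 0) || any(surface$z > optics$z_max))
    stop("surface heights must lie within [0, z_max]")
  slope <- diff(surface$z) / diff(surface$x)
  bad <- which(abs(slope) * tan(phi) >= 1)
  if (length(bad)) {
    stop(sprintf(
      "invertibility violated: |dz*/dx| tan(phi) >= 1 on x in [%g, %g] um (slope %.3g)",
      surface$x[bad[1]], surface$x[bad[1] + 1L], slope[bad[1]]))
  }
  s_x <- surface$x - surface$z * tan(phi)
  nb <- which(diff(s_x) <= 0)
  if (length(nb)) {
    stop(sprintf("s(x) not strictly increasing on x in [%g, %g] um",
                 surface$x[nb[1]], surface$x[nb[1] + 1L]))
  }
  if (min(s_x) < sweep$s_start || max(s_x) > sweep$s_end)
    stop(sprintf(
      "surface extends beyond the scan range: s(x) spans [%.3g, %.3g] but the sweep covers [%g, %g]",
      min(s_x), max(s_x), sweep$s_start, sweep$s_end))
  n <- sweep$n_steps %||% max(2L, ceiling((sweep$s_end - sweep$s_start) /
                                            optics$pixel_pitch) + 1L)
  s_grid <- seq(sweep$s_start, sweep$s_end, length.out = n)
  x_of_s <- approx(s_x, surface$x, xout = s_grid, rule = 2)$y
  z_of_s <- approx(surface$x, surface$z, xout = x_of_s, rule = 2)$y
  vu <- row_speed(shear_base, sweep)
  C <- shutter$center + vu * shutter$delay - shear_base$offset
  shear_waveform(rate = shear_base$rate, offset = shear_base$offset,
                 q = data.frame(s = s_grid, q = C - z_of_s / cos(phi)))
}

#' Surface selected by a (possibly nonlinear) shear waveform
#'
#' Inverts the waveform: the selected layer center `z_c(x)` solves
#' `z_c / cos(phi) = center + v_u delay - offset - q(x - z_c tan(phi))`.
#' Rather than iterating on that implicit equation (whose plain fixed-point
#' map stops contracting for surface slopes with
#' `dz*/dx tan(phi) > 1/2`), the equation is solved exactly by
#' parameterizing the selection along the sweep: at scan position s the
#' shutter center selects `z(s) = cos(phi) (C - q(s))` at lateral position
#' `x(s) = s + z(s) tan(phi)`; under the invertibility bound `x(s)` is
#' strictly increasing, and `z_c(x)` is read off by monotone interpolation.
#'
#' @param shear A [shear_waveform()].
#' @param optics An [optics_config()].
#' @param shutter A [shutter_config()].
#' @param sweep A [sweep_config()].
#' @param x_grid Positions at which to evaluate the surface, micrometers.
#' @param n_samples Sweep-parameter sampling density for the inversion.
#' @return A [surface_spec()] with `half_width = width * cos(phi) / 2`.
#' @export
predicted_surface <- function(shear, optics, shutter, sweep, x_grid,
                              n_samples = 4096L) {
  phi <- deg2rad(optics$tilt_phi)
  cphi <- cos(phi); tphi <- tan(phi)
  vu <- row_speed(shear, sweep)
  C <- shutter$center + vu * shutter$delay - shear$offset
  s <- seq(sweep$s_start, sweep$s_end, length.out = n_samples)
  z_s <- cphi * (C - eval_q(shear, s))
  x_s <- s + z_s * tphi
  if (any(diff(x_s) <= 0))
    stop("waveform violates the invertibility bound: x(s) is not strictly increasing")
  z <- approx(x_s, z_s, xout = x_grid, rule = 2)$y
  surface_spec(x_grid, z, half_width = shutter$width * cphi / 2)
}

#' Local viewing angle under a nonlinear waveform
#'
#' A nonlinear shear component perturbs the effective shear rate to
#' `rate + dq/ds`, and with it the local viewing angle. This diagnostic
#' evaluates that angle along the sweep.
#'
#' @param shear A [shear_waveform()].
#' @param optics An [optics_config()].
#' @param s Scan positions, micrometers.
#' @return Local viewing angles in degrees at each `s`.
#' @export
local_view_angle <- function(shear, optics, s) {
  phi <- deg2rad(optics$tilt_phi)
  h <- 1e-3
  dqds <- (eval_q(shear, s + h) - eval_q(shear, s - h)) / (2 * h)
  r_eff <- shear$rate + dqds
  if (any(r_eff <= 0))
    warning("effective shear rate non-positive at some s; angle undefined there")
  rad2deg(atan(tan(phi) - 1 / (r_eff * cos(phi))))
}
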
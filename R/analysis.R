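#' Relative fluorescence change (dF/F)
#'
#' `dFF = (F - F0) / F0` with the baseline `F0` estimated either as a
#' percentile of the trace (default: 20th, robust to sparse transients) or as
#' the mean over a stated time window. dF/F is invariant to global intensity
#' scaling of `F`.
#'
#' @param time Time stamps, seconds.
#' @param F Raw intensity trace (same length as `time`).
#' @param baseline_method `"percentile"` or `"window"`.
#' @param p Baseline percentile (0-100) for `"percentile"`.
#' @param window `c(t0, t1)` seconds for `"window"`; must lie inside the
#'   trace.
#' @return A list of class `calcium_trace` with `time`, `F`, `F0`, `dFF`.
#' @export
delta_f_over_f <- function(time, F, baseline_method = c("percentile",
                                                        "window"),
                           p = 20, window = NULL) {
  baseline_method <- match.arg(baseline_method)
  if (length(time) != length(F)) stop("`time` and `F` lengths differ")
  F0 <- if (baseline_method == "percentile") {
    unname(quantile(F, p / 100))
  } else {
    if (is.null(window) || length(window) != 2L)
      stop("`window` must be c(t0, t1)")
    if (window[1] < min(time) || window[2] > max(time))
      stop("baseline window lies outside the trace")
    sel <- time >= window[1] & time <= window[2]
    mean(F[sel])
  }
  if (!is.finite(F0) || F0 <= 0)
    stop(sprintf("baseline F0 = %g is not positive", F0))
  structure(list(time = time, F = F, F0 = F0, dFF = (F - F0) / F0),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d samples, F0 = %.4g, peak dF/F = %.4g\n",
              length(x$time), x$F0, max(x$dFF)))
  invisible(x)
}

#' Mean intensity over a region of interest
#'
#' @param frames List of [frame()]s (or matrices).
#' @param mask Logical matrix of the frame shape.
#' @return Numeric trace of per-frame ROI means.
#' @export
roi_trace <- function(frames, mask) {
  vapply(frames, function(f) {
    m <- if (inherits(f, "props_frame")) f$data else f
    mean(m[mask])
  }, numeric(1))
}

#' Kymograph along a polyline
#'
#' Samples each frame along a polyline (linear interpolation, ~1 px sample
#' spacing, averaged across `line_width_px` perpendicular offsets) and stacks
#' the profiles as columns: position x time.
#'
#' @param frames List of [frame()]s or matrices.
#' @param polyline Matrix or data frame with columns `row`, `col` (1-based
#'   pixel coordinates, >= 2 vertices); must lie inside the frames.
#' @param line_width_px Width to average across, pixels.
#' @return Matrix of shape (n_samples, n_frames).
#' @export
kymograph <- function(frames, polyline, line_width_px = 1) {
  polyline <- as.matrix(as.data.frame(polyline)[, c("row", "col")])
  if (nrow(polyline) < 2L) stop("polyline needs >= 2 vertices")
  m1 <- if (inherits(frames[[1]], "props_frame")) frames[[1]]$data else
    frames[[1]]
  if (any(polyline[, 1] < 1) || any(polyline[, 1] > nrow(m1)) ||
      any(polyline[, 2] < 1) || any(polyline[, 2] > ncol(m1)))
    stop("polyline lies outside the frame bounds")
  # densify to ~1 px spacing
  pts <- NULL
  for (i in seq_len(nrow(polyline) - 1L)) {
    seg <- polyline[i + c(0, 1), ]
    len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
    if (i > 1) tt <- tt[-1]
    pts <- rbind(pts, cbind(seg[1, 1] + tt * (seg[2, 1] - seg[1, 1]),
                            seg[1, 2] + tt * (seg[2, 2] - seg[1, 2])))
  }
  # unit normal per sample (from local tangent) for line width averaging
  tang <- rbind(pts[2, ] - pts[1, ], diff(pts))
  nrm <- cbind(-tang[, 2], tang[, 1])
  nl <- sqrt(rowSums(nrm^2))
  nl[nl == 0] <- 1
  nrm <- nrm / nl
  offs <- seq(-(line_width_px - 1) / 2, (line_width_px - 1) / 2,
              length.out = max(1L, line_width_px))
  bilinear <- function(m, r, c) {
    r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
    r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
    ar <- r - r0; ac <- c - c0
    m[cbind(r0, c0)] * (1 - ar) * (1 - ac) +
      m[cbind(r0 + 1, c0)] * ar * (1 - ac) +
      m[cbind(r0, c0 + 1)] * (1 - ar) * ac +
      m[cbind(r0 + 1, c0 + 1)] * ar * ac
  }
  out <- matrix(0, nrow(pts), length(frames))
  for (t in seq_along(frames)) {
    m <- if (inherits(frames[[t]], "props_frame")) frames[[t]]$data else
      frames[[t]]
    prof <- 0
    for (o in offs)
      prof <- prof + bilinear(m, pts[, 1] + o * nrm[, 1],
                              pts[, 2] + o * nrm[, 2])
    out[, t] <- prof / length(offs)
  }
  out
}

#' Subtract the static background from a movie
#'
#' Removes the per-pixel temporal median (or minimum) so that only dynamic
#' signal remains; negative residuals are clamped at 0 by default (the
#' display-oriented convention; set `clamp = FALSE` for the raw signed
#' residuals). Idempotent on noiseless input.
#'
#' @param frames List of [frame()]s or matrices (>= 3 frames).
#' @param method `"temporal_median"` or `"temporal_min"`.
#' @param clamp Clamp negative values at 0.
#' @return List of background-subtracted frames (same classes as the input).
#' @export
subtract_static_background <- function(frames,
                                       method = c("temporal_median",
                                                  "temporal_min"),
                                       clamp = TRUE) {
  method <- match.arg(method)
  if (length(frames) < 3L) stop("need >= 3 frames")
  mats <- lapply(frames, function(f)
    if (inherits(f, "props_frame")) f$data else f)
  stack <- simplify2array(mats)
  bg <- apply(stack, c(1, 2), if (method == "temporal_median") median else
    min)
  lapply(seq_along(frames), function(i) {
    res <- mats[[i]] - bg
    if (clamp) res[res < 0] <- 0
    if (inherits(frames[[i]], "props_frame")) {
      out <- frames[[i]]
      out$data <- res
      out
    } else res
  })
}

#' Signal-to-background ratio
#'
#' `SBR = mean(frame[fg]) / mean(frame[bg])` for disjoint, non-empty masks.
#'
#' @param fr A [frame()] or matrix.
#' @param fg_mask,bg_mask Logical masks of the frame shape.
#' @return The ratio.
#' @export
sbr <- function(fr, fg_mask, bg_mask) {
  m <- if (inherits(fr, "props_frame")) fr$data else fr
  if (!any(fg_mask) || !any(bg_mask)) stop("masks must be non-empty")
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint")
  mean(m[fg_mask]) / mean(m[bg_mask])
}

#' Shear-galvo calibration fit
#'
#' Ordinary least-squares line through measured image shifts versus galvo
#' command values, with residual diagnostics for assessing linearity.
#'
#' @param commands Galvo command values (arbitrary units); >= 3 points, not
#'   all equal.
#' @param measured_shifts_um Measured image shifts, micrometers.
#' @return A list of class `calibration_fit`: `slope` (micrometers per
#'   command unit), `intercept`, `r_squared`, `max_residual` (micrometers),
#'   `n_points`, `fit` (the `lm` object).
#' @export
calibrate_shear <- function(commands, measured_shifts_um) {
  if (length(commands) != length(measured_shifts_um))
    stop("input lengths differ")
  if (length(commands) < 3L) stop("need >= 3 calibration points")
  if (sd(commands) == 0)
    stop("rank-deficient input: commands are all equal")
  fit <- lm(measured_shifts_um ~ commands)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((measured_shifts_um - mean(measured_shifts_um))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 max_residual = max(abs(fit$residuals)),
                 n_points = length(commands), fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.5g um/unit, intercept %.4g um, r^2 %.6f, max residual %.3g um (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$max_residual, x$n_points))
  invisible(x)
}
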
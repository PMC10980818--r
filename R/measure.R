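#' Per-bead signal in a projection frame
#'
#' Looks up each bead's expected frame position (row
#' `x - z * tan(psi)`, column `y`) and returns the maximum intensity in a
#' small window around it.
#'
#' @param fr A [frame()].
#' @param beads Bead table with columns `x`, `y`, `z` (micrometers).
#' @param psi Viewing angle of the acquisition, degrees.
#' @param window_px Half-width of the search window, pixels.
#' @return Numeric vector of per-bead peak signals.
#' @export
bead_signals <- function(fr, beads, psi = 0, window_px = 3L) {
  stopifnot(inherits(fr, "props_frame"))
  m <- fr$data
  rows <- (beads$x - beads$z * tan(deg2rad(psi)) - fr$origin[1]) /
    fr$pixel_size[1] + 1
  cols <- (beads$y - fr$origin[2]) / fr$pixel_size[2] + 1
  vapply(seq_len(nrow(beads)), function(i) {
    r0 <- max(1, round(rows[i]) - window_px)
    r1 <- min(nrow(m), round(rows[i]) + window_px)
    c0 <- max(1, round(cols[i]) - window_px)
    c1 <- min(ncol(m), round(cols[i]) + window_px)
    if (r0 > r1 || c0 > c1) return(0)
    max(m[r0:r1, c0:c1])
  }, numeric(1))
}

bead_window_sum <- function(fr, beads, psi, row_px, col_px) {
  m <- fr$data
  rows <- (beads$x - beads$z * tan(deg2rad(psi)) - fr$origin[1]) /
    fr$pixel_size[1] + 1
  cols <- (beads$y - fr$origin[2]) / fr$pixel_size[2] + 1
  vapply(seq_len(nrow(beads)), function(i) {
    r0 <- max(1, round(rows[i]) - row_px)
    r1 <- min(nrow(m), round(rows[i]) + row_px)
    c0 <- max(1, round(cols[i]) - col_px)
    c1 <- min(ncol(m), round(cols[i]) + col_px)
    if (r0 > r1 || c0 > c1) return(0)
    sum(m[r0:r1, c0:c1])
  }, numeric(1))
}

#' Measure the selected slab from a bead ladder
#'
#' The brute-force slab measurement used to validate the closed-form
#' geometry: a bead counts as included when its frame signal -- the intensity
#' summed over a small window around its predicted position, a mass estimate
#' that is insensitive to pixel-phase effects -- exceeds `threshold` (default
#' 50%) of its signal in a reference acquisition of the same phantom with a
#' fully open shutter. Reports the z-range and mean z of the included beads.
#'
#' @param fr Frame from the slab acquisition.
#' @param reference Frame from the full-open reference acquisition (same
#'   phantom, same grid).
#' @param beads Bead table with columns `x`, `y`, `z`.
#' @param psi Viewing angle, degrees.
#' @param threshold Inclusion threshold on the signal ratio.
#' @param row_window_px,col_window_px Summation window half-widths, pixels;
#'   keep the column window below the bead lane spacing.
#' @return A list: `included` (logical per bead), `z_range`
#'   (`max(z) - min(z)` over included beads), `z_center` (mean included z),
#'   `ratio` (per-bead signal ratios).
#' @export
measure_slab <- function(fr, reference, beads, psi = 0, threshold = 0.5,
                         row_window_px = 2L, col_window_px = 1L) {
  sig <- bead_window_sum(fr, beads, psi, row_window_px, col_window_px)
  ref <- bead_window_sum(reference, beads, psi, row_window_px, col_window_px)
  ratio <- ifelse(ref > 0, sig / ref, 0)
  inc <- ratio > threshold
  list(included = inc,
       z_range = if (any(inc)) diff(range(beads$z[inc])) else 0,
       z_center = if (any(inc)) mean(beads$z[inc]) else NA_real_,
       ratio = ratio)
}

#' Intensity-weighted bead centroid along the frame row axis
#'
#' @param fr A [frame()].
#' @param threshold Fraction of the frame maximum below which pixels are
#'   ignored (suppresses background when localizing a single bead).
#' @return Centroid position in micrometers (row coordinate).
#' @export
frame_row_centroid_um <- function(fr, threshold = 0.05) {
  m <- fr$data
  m[m < threshold * max(m)] <- 0
  rows_um <- fr$origin[1] + (seq_len(nrow(m)) - 1) * fr$pixel_size[1]
  sum(rowSums(m) * rows_um) / sum(m)
}
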
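# TIFF storage: 32-bit samples scaled into [0, 1] by a power of two recorded
# (with voxel sizes) in a JSON sidecar <path>.json. The TIFF backend stores
# 32-bit integer samples, so a round trip is exact to one part in 2^32 of
# the intensity scale (absolute error <= scale * 2^-32); data already on
# that grid round-trips exactly.

pow2_scale <- function(x) {
  mx <- max(x, 0)
  if (mx <= 1) 1 else 2^ceiling(log2(mx))
}

sidecar_path <- function(path) paste0(path, ".json")

write_pages_tiff <- function(pages, path, meta) {
  scale <- pow2_scale(vapply(pages, max, numeric(1)))
  pages <- lapply(pages, function(p) p / scale)
  tmp <- paste0(path, ".tmp")
  tiff::writeTIFF(pages, tmp, bits.per.sample = 32L, compression = "none")
  file.rename(tmp, path)
  meta$intensity_scale <- scale
  tmpj <- paste0(sidecar_path(path), ".tmp")
  jsonlite::write_json(meta, tmpj, auto_unbox = TRUE, digits = NA)
  file.rename(tmpj, sidecar_path(path))
  invisible(path)
}

read_pages_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf("inconsistent page shapes in '%s' at page %d", path, i))
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  scale <- meta$intensity_scale %||% 1
  list(pages = lapply(pages, function(p) p * scale), meta = meta)
}

#' Read and write intensity volumes as multi-page TIFF
#'
#' Pages are z-planes (y rows, x columns), 32-bit samples; voxel sizes,
#' origin and the intensity scale (a power of two) live in a JSON sidecar
#' next to the file. Files are written atomically (temp-then-rename). The
#' round trip is lossless to the 32-bit quantization of the intensity scale
#' (absolute error at most `scale * 2^-32`).
#'
#' @param vol A [volume()].
#' @param path TIFF file path.
#' @return `write_volume()`: the path, invisibly. `read_volume()`: a
#'   [volume()]; without a sidecar the voxel size defaults to 1 micrometer
#'   with a warning.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "props_volume"))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(iz) vol$data[iz, , ])
  write_pages_tiff(pages, path,
                   list(kind = "volume", voxel_size_um = vol$voxel_size,
                        origin_um = vol$origin))
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  got <- read_pages_tiff(path)
  if (length(got$pages) < 2L)
    stop(sprintf(
      "'%s' has a single page: looks like a 2D frame, use read_frames()",
      path))
  if (is.null(got$meta$voxel_size_um)) {
    warning(sprintf("no voxel-size metadata for '%s'; defaulting to 1 um",
                    path))
    got$meta$voxel_size_um <- c(1, 1, 1)
    got$meta$origin_um <- c(0, 0, 0)
  }
  d <- dim(got$pages[[1]])
  arr <- array(0, dim = c(length(got$pages), d[1], d[2]))
  for (iz in seq_along(got$pages)) arr[iz, , ] <- got$pages[[iz]]
  volume(arr, voxel_size = got$meta$voxel_size_um,
         origin = got$meta$origin_um %||% c(0, 0, 0))
}

#' Read and write projection frames as (multi-page) TIFF
#'
#' One page per frame; pixel sizes, origin and intensity scale go to a JSON
#' sidecar. Writing is atomic.
#'
#' @param frames A [frame()] or list of frames of equal shape.
#' @param path TIFF file path.
#' @return `write_frames()`: the path, invisibly. `read_frames()`: a list of
#'   [frame()]s.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "props_frame")) frames <- list(frames)
  pages <- lapply(frames, function(f) f$data)
  write_pages_tiff(pages, path,
                   list(kind = "frames",
                        pixel_size_um = frames[[1]]$pixel_size,
                        origin_um = frames[[1]]$origin))
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  got <- read_pages_tiff(path)
  px <- got$meta$pixel_size_um
  if (is.null(px)) {
    warning(sprintf("no pixel-size metadata for '%s'; defaulting to 1 um",
                    path))
    px <- c(1, 1)
  }
  lapply(got$pages, frame, pixel_size = px,
         origin = got$meta$origin_um %||% c(0, 0))
}

#' Shear-waveform and surface CSV formats
#'
#' Waveforms are exported as a two-column CSV `s_um, g_um` (total image shift
#' `g(s) = rate * s + q(s) + offset` on the waveform's s-grid); surfaces as
#' `x_um, z_um`. Bead/blob tables round-trip through plain CSV with a header
#' row.
#'
#' @param shear A [shear_waveform()] (needs a sampled nonlinear grid, or
#'   supply `s`).
#' @param path CSV path.
#' @param s Optional s-grid for purely linear waveforms.
#' @return Readers return the parsed object; writers the path, invisibly.
#' @export
write_waveform_csv <- function(shear, path, s = NULL) {
  s <- s %||% shear$q$s
  if (is.null(s)) stop("supply `s`: the waveform has no sampled grid")
  g <- shear$rate * s + eval_q(shear, s) + shear$offset
  write.csv(data.frame(s_um = s, g_um = g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param rate,offset Linear components assumed when re-reading a waveform
#'   CSV (the file stores only the total shift).
#' @export
read_waveform_csv <- function(path, rate = 1, offset = 0) {
  df <- read.csv(path)
  if (!all(c("s_um", "g_um") %in% names(df)))
    stop(sprintf("'%s' is not a waveform CSV (needs s_um, g_um)", path))
  shear_waveform(rate = rate, offset = offset,
                 q = data.frame(s = df$s_um,
                                q = df$g_um - rate * df$s_um - offset))
}

#' @rdname write_waveform_csv
#' @param surface A [surface_spec()].
#' @export
write_surface_csv <- function(surface, path) {
  write.csv(data.frame(x_um = surface$x, z_um = surface$z), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param half_width Half-width to attach to the read surface, micrometers.
#' @export
read_surface_csv <- function(path, half_width = 0) {
  df <- read.csv(path)
  if (!all(c("x_um", "z_um") %in% names(df)))
    stop(sprintf("'%s' is not a surface CSV (needs x_um, z_um)", path))
  surface_spec(df$x_um, df$z_um, half_width = half_width)
}

#' Data-size ratio of a z-stack versus one projection frame
#'
#' Stored-bytes ratio `(n_planes * plane_pixels * stack_bytes) /
#' (frame_pixels * frame_bytes)`: the factor by which projection imaging
#' shrinks the data relative to conventional 3D stacking. For equal lateral
#' shape and sample type the ratio equals the number of planes.
#'
#' @param stack A [volume()] (z-stack, e.g. from [simulate_stack()]).
#' @param fr A [frame()].
#' @param stack_bytes,frame_bytes Bytes per stored sample (e.g. 2 for 16-bit,
#'   4 for 32-bit).
#' @return The ratio.
#' @export
data_size_ratio <- function(stack, fr, stack_bytes = 2, frame_bytes = 2) {
  stopifnot(inherits(stack, "props_volume"), inherits(fr, "props_frame"))
  d <- dim(stack$data)
  if (prod(d[2:3]) != prod(dim(fr$data)))
    stop(sprintf(
      "lateral shape mismatch: stack planes are %d x %d but the frame is %d x %d",
      d[2], d[3], nrow(fr$data), ncol(fr$data)))
  (d[1] * prod(d[2:3]) * stack_bytes) / (prod(dim(fr$data)) * frame_bytes)
}
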
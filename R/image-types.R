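#' IVUS-style image sequence
#'
#' A sequence of equally-sized grayscale frames with pixel spacing and frame
#' rate.  Frames are numeric matrices (rows = image y, growing downward;
#' columns = image x), intensities in arbitrary nonnegative gray units.
#' Most routines normalize intensities to \[0, 1\] before processing.
#'
#' @param frames list of H x W numeric matrices
#' @param pixel_spacing mm per pixel (0.016 mm for the IVUS studies emulated
#'   here)
#' @param frame_rate frames per second (Hz)
#' @param times optional acquisition times (s); defaults to index/frame_rate
#' @return an `image_sequence`
#' @export
image_sequence <- function(frames, pixel_spacing = 0.016, frame_rate = 30,
                           times = NULL) {
  stopifnot(length(frames) >= 1, pixel_spacing > 0, frame_rate > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same shape")
  if (any(dims < 2)) stop("frames must be at least 2 x 2")
  if (is.null(times)) times <- (seq_along(frames) - 1) / frame_rate
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 frame_rate = frame_rate, times = times),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_sequence: %d frames of %d x %d, %.3g mm/px, %g Hz\n",
              length(x$frames), d[1], d[2], x$pixel_spacing, x$frame_rate))
  invisible(x)
}

#' Normalize frame intensities to the unit interval
#' @param img numeric matrix
#' @param lo,hi optional fixed range (defaults to the image range)
#' @return matrix with values in \[0, 1\]
#' @export
normalize_intensity <- function(img, lo = min(img), hi = max(img)) {
  if (hi <= lo) return(img * 0)
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

#' Read an image sequence from a multi-page TIFF or a directory of PNGs
#'
#' @param path a `.tif`/`.tiff` file or a directory containing ordered
#'   `.png` frames
#' @inheritParams image_sequence
#' @return an `image_sequence`
#' @export
read_image_sequence <- function(path, pixel_spacing = 0.016, frame_rate = 30) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no .png frames found in ", path)
    frames <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- if (is.list(pages)) pages else list(pages)
    frames <- lapply(frames, function(a) if (length(dim(a)) == 3) a[, , 1] else a)
  }
  image_sequence(frames, pixel_spacing, frame_rate)
}

#' Write an image sequence as a multi-page TIFF (32-bit float)
#' @param seq an `image_sequence`
#' @param path output file
#' @export
write_image_sequence <- function(seq, path) {
  # frames are stored as IEEE float32 samples; values may exceed [0, 1]
  suppressWarnings(tiff::writeTIFF(seq$frames, path, bits.per.sample = 32L))
  invisible(path)
}

#' Dense displacement field between two frames
#'
#' Per-pixel 2D displacement, stored in pixel units (`u` along columns/x,
#' `v` along rows/y, y growing downward) together with the pixel spacing so
#' physical displacements (mm) can be recovered.
#'
#' @param u,v H x W matrices (pixels)
#' @param pixel_spacing mm per pixel
#' @param source_phase,target_phase labels carried for bookkeeping
#' @return a `displacement_field`
#' @export
displacement_field <- function(u, v, pixel_spacing = 0.016,
                               source_phase = NA, target_phase = NA) {
  stopifnot(all(dim(u) == dim(v)), all(is.finite(u)), all(is.finite(v)))
  structure(list(u = u, v = v, pixel_spacing = pixel_spacing,
                 source_phase = source_phase, target_phase = target_phase),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field %s -> %s: %d x %d, max |u| = %.3g px\n",
              x$source_phase, x$target_phase, nrow(x$u), ncol(x$u),
              max(abs(c(x$u, x$v)))))
  invisible(x)
}

#' Write a displacement field as a two-page 32-bit float TIFF (mm)
#' @param field a `displacement_field`
#' @param path output file
#' @export
write_displacement_field <- function(field, path) {
  # IEEE float32 samples; displacements are signed, which is fine for the
  # float sample format but outside the nominal display range
  suppressWarnings(tiff::writeTIFF(list(field$u * field$pixel_spacing,
                                        field$v * field$pixel_spacing),
                                   path, bits.per.sample = 32L))
  invisible(path)
}

#' Read a displacement field written by [write_displacement_field()]
#' @param path two-page TIFF, values in mm
#' @param pixel_spacing mm per pixel used to restore pixel units
#' @return a `displacement_field`
#' @export
read_displacement_field <- function(path, pixel_spacing = 0.016) {
  pg <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pg) == 2)
  displacement_field(pg[[1]] / pixel_spacing, pg[[2]] / pixel_spacing,
                     pixel_spacing)
}
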
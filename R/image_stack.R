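#' Image stack container
#'
#' A per-channel movie or calibration scan: `frames x pixel grid` of camera
#' counts with its pixel size and channel identity.  Data are stored as a
#' numeric array `dim = c(rows, cols, frames)`.  Continuous coordinates use
#' the field-of-view corner as origin; pixel `(r, c)` (1-based) spans
#' `x in [(c-1)*a, c*a)`, `y in [(r-1)*a, r*a)` for pixel size `a`.
#'
#' @param data numeric array `c(rows, cols, frames)` (a matrix is treated as
#'   a single frame).
#' @param pixel_size pixel size, nm.
#' @param channel channel identity (1 or 2).
#' @param exposure_ms exposure per frame, ms.
#' @return an `ImageStack`.
#' @export
image_stack <- function(data, pixel_size, channel = 1L, exposure_ms = NA) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, pixel_size > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 channel = as.integer(channel), exposure_ms = exposure_ms),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack ch%d: %d frames of %d x %d px @ %g nm\n",
              x$channel, d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Write / read an image stack as a 16-bit multi-page TIFF
#'
#' Counts are clipped to `[0, 65535]` on write, matching the 16-bit camera
#' range.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param pixel_size,channel,exposure_ms metadata to attach on read (TIFF
#'   files do not carry them).
#' @return `read_image_stack` returns an `ImageStack`.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(f) {
    m <- stack$data[, , f]
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size = 82, channel = 1L,
                             exposure_ms = NA) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535
  image_stack(arr, pixel_size = pixel_size, channel = channel,
              exposure_ms = exposure_ms)
}
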
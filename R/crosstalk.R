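#' Estimate the per-pixel crosstalk factor from donor-only frames
#'
#' With only the channel-1 (donor) fluorophore emitting, the bleed-through
#' into channel 2 gives, pixel by pixel, the crosstalk factor
#' `CF = I_ch2_crosstalk / I_ch1` on background-subtracted, channel-aligned
#' intensities.  Per pixel, the intensities are pooled over the calibration
#' frames in which the donor signal is above background (summed numerator over
#' summed denominator, i.e. a donor-intensity-weighted ratio, which is robust
#' to near-zero denominators in noisy frames); "above background" means above
#' the background level by three noise SDs of the donor frames.  The noise SD
#' is estimated one-sidedly, from the pixels below the background level only
#' (fluorescence only ever adds counts, so negative residuals are pure camera
#' noise; the half-normal median is rescaled to an SD).  Pixels that never
#' rise above background are left undefined (masked).
#'
#' @param donor_ch1,donor_ch2 [image_stack()]s of the same donor-only frames
#'   recorded in both channels.
#' @param alignment optional [fit_lwm()] transform mapping channel-2
#'   coordinates into the channel-1 frame, used to align the two pixel grids;
#'   `NULL` assumes already-aligned channels.
#' @param background per-channel background counts `c(ch1, ch2)`; default is
#'   the per-channel median of the calibration frames.
#' @return a `crosstalk_map`: per-pixel `cf` matrix (`NA` where masked), the
#'   backgrounds, the `fill` value (median of defined CF) used for pixels
#'   without calibration coverage, the alignment, and provenance.
#' @export
estimate_crosstalk <- function(donor_ch1, donor_ch2, alignment = NULL,
                               background = NULL) {
  d1 <- donor_ch1$data; d2 <- donor_ch2$data
  if (!identical(dim(d1), dim(d2)))
    stop("donor stacks have mismatched shapes")
  nf <- dim(d1)[3]
  if (is.null(background))
    background <- c(median(d1), median(d2))

  H <- dim(d1)[1]; W <- dim(d1)[2]
  warp <- warp_grid(alignment, H, W, donor_ch1$pixel_size)
  # One-sided noise scale: signal only adds counts, so residuals below the
  # background level are pure camera noise (half-normal; its median rescales
  # to an SD with the usual 1.4826 factor).  Zero for noise-free frames.
  neg <- background[1] - d1[d1 <= background[1]]
  noise_sd <- if (length(neg)) 1.4826 * median(neg) else 0
  num <- matrix(0, H, W); den_sum <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  for (f in seq_len(nf)) {
    ch1 <- align_ch1_to_ch2(d1[, , f], warp)
    den <- ch1 - background[1]
    sig <- d2[, , f] - background[2]
    ok <- den > 3 * noise_sd
    num <- num + sig * ok
    den_sum <- den_sum + den * ok
    cnt <- cnt + ok
  }
  if (all(cnt == 0)) stop("no donor signal above background")
  cf <- ifelse(cnt > 0, pmax(num, 0) / pmax(den_sum, 1e-12), NA_real_)
  structure(list(cf = cf, background = background,
                 fill = median(cf, na.rm = TRUE), alignment = alignment,
                 warp = warp, n_frames = nf,
                 pixel_size = donor_ch1$pixel_size),
            class = "crosstalk_map")
}

#' @export
print.crosstalk_map <- function(x, ...) {
  cat(sprintf(
    "crosstalk_map: %d x %d px, median CF = %.4f, %.1f%% pixels defined (%d frames)\n",
    nrow(x$cf), ncol(x$cf), x$fill, 100 * mean(!is.na(x$cf)), x$n_frames))
  invisible(x)
}

# The channel-1 pixel coordinates corresponding to every channel-2 pixel
# centre (the frame-independent part of the channel alignment, computed once
# per map rather than per frame).
warp_grid <- function(alignment, H, W, pixel_size) {
  if (is.null(alignment)) return(NULL)
  q <- cbind(x = rep((seq_len(W) - 0.5) * pixel_size, each = H),
             y = rep((seq_len(H) - 0.5) * pixel_size, W))
  p <- suppressWarnings(predict(alignment, q))
  list(x_px = p[, 1] / pixel_size, y_px = p[, 2] / pixel_size)
}

# Resample channel 1 onto the channel-2 pixel grid: for each channel-2 pixel
# centre, sample channel 1 (bilinear) at the registered channel-1 position.
align_ch1_to_ch2 <- function(frame1, warp) {
  if (is.null(warp)) return(frame1)
  matrix(bilinear_sample(frame1, warp$x_px, warp$y_px),
         nrow(frame1), ncol(frame1))
}

# Bilinear sampling at pixel-unit coordinates (FOV-corner origin); clamped at
# the border.
bilinear_sample <- function(img, x_px, y_px) {
  H <- nrow(img); W <- ncol(img)
  cx <- pmin(pmax(x_px - 0.5, 0), W - 1)   # pixel-centre coordinate space
  cy <- pmin(pmax(y_px - 0.5, 0), H - 1)
  c0 <- pmin(floor(cx), W - 2); r0 <- pmin(floor(cy), H - 2)
  fx <- cx - c0; fy <- cy - r0
  i00 <- r0 + 1 + H * c0
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + H] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy + img[i00 + H + 1] * fx * fy
  v
}

#' Subtract the predicted bleed-through from the acceptor channel
#'
#' Applies, pixel by pixel and frame by frame,
#' `I_ch2_corrected = I_ch2_measured - CF * I_ch1` with the background-
#' subtracted, channel-aligned donor intensity `I_ch1`.  The correction is
#' applied only where the recorded channel-1 intensity is above the average
#' background; corrected counts are floored at 0.  Pixels without calibration
#' coverage use the map's `fill` CF (the median of the defined pixels).
#'
#' @param measured_ch2 acceptor-channel [image_stack()] to correct.
#' @param measured_ch1 simultaneous donor-channel stack.
#' @param map a `crosstalk_map` from [estimate_crosstalk()].
#' @return the corrected channel-2 `ImageStack`.
#' @export
correct_frames <- function(measured_ch2, measured_ch1, map) {
  d2 <- measured_ch2$data; d1 <- measured_ch1$data
  if (!identical(dim(d1), dim(d2)))
    stop("channel stacks have mismatched shapes")
  if (!identical(dim(map$cf), dim(d2)[1:2]))
    stop("crosstalk map shape does not match the frames")
  cf <- map$cf
  cf[is.na(cf)] <- map$fill
  warp <- map$warp
  if (is.null(warp) && !is.null(map$alignment))
    warp <- warp_grid(map$alignment, dim(d2)[1], dim(d2)[2],
                      measured_ch1$pixel_size)
  out <- d2
  for (f in seq_len(dim(d2)[3])) {
    ch1 <- align_ch1_to_ch2(d1[, , f], warp)
    donor <- ch1 - map$background[1]
    apply_here <- ch1 > map$background[1]
    corr <- d2[, , f] - cf * donor * apply_here
    out[, , f] <- pmax(corr, 0)
  }
  image_stack(out, pixel_size = measured_ch2$pixel_size,
              channel = measured_ch2$channel,
              exposure_ms = measured_ch2$exposure_ms)
}

#' Serialize / deserialize a crosstalk map
#'
#' The CF map is written as a 32-bit TIFF whose samples span `[0, 1]`; the
#' affine encoding (`cf = scale * sample + offset`, masked pixels at the
#' `masked_value` sentinel) and the scalar metadata live in a JSON sidecar.
#' @param map a `crosstalk_map`.
#' @param tiff_path,json_path file paths.
#' @return `read_crosstalk_map` returns the `crosstalk_map` (without the
#'   channel-alignment transform, which is serialized separately by
#'   [write_lwm()]).
#' @export
write_crosstalk_map <- function(map, tiff_path, json_path) {
  cf <- map$cf
  cf[is.na(cf)] <- -1
  scale <- 2
  offset <- -1
  # a physical crosstalk fraction lies in [0, 1); clamp noise excursions
  cf <- pmin(pmax(cf, offset), offset + scale)
  tiff::writeTIFF((cf - offset) / scale, tiff_path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(background = map$background, fill = map$fill,
         n_frames = map$n_frames, pixel_size = map$pixel_size,
         masked_value = -1, scale = scale, offset = offset),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(map)
}

#' @rdname write_crosstalk_map
#' @export
read_crosstalk_map <- function(tiff_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cf <- tiff::readTIFF(tiff_path) * meta$scale + meta$offset
  cf[abs(cf - meta$masked_value) < 1e-6] <- NA_real_
  structure(list(cf = cf, background = meta$background, fill = meta$fill,
                 alignment = NULL, warp = NULL, n_frames = meta$n_frames,
                 pixel_size = meta$pixel_size),
            class = "crosstalk_map")
}
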
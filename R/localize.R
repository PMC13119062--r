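#' Detect candidate single-molecule spots
#'
#' Band-pass filters each frame (Gaussian smoothing minus a local boxcar
#' background) and returns local maxima above `threshold` times the robust
#' (MAD-based) noise SD of the filtered frame.  Nearby candidates are reduced
#' by non-maximum suppression.
#'
#' @param stack an [image_stack()].
#' @param threshold detection threshold in multiples of the filtered-noise SD.
#' @param sigma_px smoothing kernel SD in pixels (~PSF SD).
#' @param bg_radius boxcar radius (px) of the local background estimate.
#' @param min_sep minimum candidate separation (px).
#' @return data frame `frame`, `row`, `col` (1-based), `value`.
#' @export
detect_spots <- function(stack, threshold = 4, sigma_px = 1.3,
                         bg_radius = 6, min_sep = 3) {
  d <- dim(stack$data)
  if (prod(d) == 0) stop("empty image stack")
  cpp_detect_spots(stack$data, d[1], d[2], d[3], sigma_px, bg_radius,
                   threshold, min_sep)
}

#' Thompson-Larson-Webb localization uncertainty
#'
#' Closed-form lateral localization precision of a Gaussian-PSF fit:
#' `var = (s^2 + a^2/12) / N + 8 pi s^4 b^2 / (a^2 N^2)` with PSF SD `s`,
#' pixel size `a`, photon count `N` and background noise `b` (photons/pixel
#' RMS).
#'
#' @param sigma fitted PSF SD, nm.
#' @param pixel_size pixel size, nm.
#' @param photons detected photons.
#' @param bg_noise background noise, photons/pixel RMS.
#' @return uncertainty (SD), nm.
#' @export
thompson_uncertainty <- function(sigma, pixel_size, photons, bg_noise) {
  v <- (sigma^2 + pixel_size^2 / 12) / photons +
    8 * pi * sigma^4 * bg_noise^2 / (pixel_size^2 * photons^2)
  sqrt(v)
}

#' Fit candidate spots and build a localization table
#'
#' Least-squares integrated-Gaussian fit (constant background) of each
#' candidate: sub-pixel `x`, `y` in nm, photons, background and PSF widths.
#' In `"astig"` mode an elliptical Gaussian is fitted and the axial position
#' is assigned by matching `(sigma_x, sigma_y)` to the calibration defocus
#' curves; spots too far from the curves are rejected.  Each localization
#' carries its Thompson uncertainty.
#'
#' @param stack an [image_stack()] (counts).
#' @param mode `"2d"` (isotropic Gaussian) or `"astig"` (elliptical + z).
#' @param calibration an [calibrate_astigmatism()] object (3D mode only).
#' @param threshold,sigma_px,bg_radius,min_sep passed to [detect_spots()].
#' @param fit_window half-width of the fit window, px.
#' @param gain,offset camera calibration used to convert counts to photons.
#' @param min_photons localizations below this photon count are dropped.
#' @param sigma_range plausible fitted PSF SD range `c(min, max)` in nm;
#'   fits outside it (typically blends of several simultaneously active
#'   molecules, which fit wide, or noise spikes, which fit narrow) are
#'   rejected.
#' @param candidates optional pre-computed [detect_spots()] output.
#' @return a localization table (`loc_table`): `id`, `channel`, `frame`,
#'   `x`, `y`, `z` (nm; `z` is `NA` in 2D mode), `sigma_x`, `sigma_y`,
#'   `photons`, `background` (photons/px), `uncertainty` (nm),
#'   `merged_from`, `merged_sd`.
#' @export
localize_stack <- function(stack, mode = c("2d", "astig"),
                           calibration = NULL, threshold = 4,
                           sigma_px = 1.3, bg_radius = 6, min_sep = 3,
                           fit_window = 4, gain = 400, offset = 100,
                           min_photons = 100, sigma_range = c(0, Inf),
                           candidates = NULL) {
  mode <- match.arg(mode)
  if (mode == "astig" && is.null(calibration))
    stop("astigmatic mode requires an astigmatism calibration")
  d <- dim(stack$data)
  a <- stack$pixel_size
  if (is.null(candidates))
    candidates <- detect_spots(stack, threshold, sigma_px, bg_radius, min_sep)
  if (nrow(candidates) == 0) return(empty_loc_table(stack, mode))

  fits <- cpp_fit_spots(stack$data, d[1], d[2], d[3],
                        candidates$frame, candidates$row, candidates$col,
                        fit_window, mode == "astig", sigma_px,
                        max_iter = 60L)
  photons <- fits[, "amp"] / gain
  bg <- pmax(fits[, "bg"] - offset, 0) / gain
  s_nm <- sqrt(fits[, "sx_px"] * fits[, "sy_px"]) * a
  ok <- fits[, "ok"] == 1 & photons >= min_photons &
    s_nm >= sigma_range[1] & s_nm <= sigma_range[2]
  if (!any(ok)) return(empty_loc_table(stack, mode))
  tab <- data.frame(
    id = integer(sum(ok)), channel = stack$channel,
    frame = candidates$frame[ok],
    x = fits[ok, "x_px"] * a, y = fits[ok, "y_px"] * a, z = NA_real_,
    sigma_x = fits[ok, "sx_px"] * a, sigma_y = fits[ok, "sy_px"] * a,
    photons = photons[ok], background = bg[ok])
  s_eff <- sqrt(tab$sigma_x * tab$sigma_y)
  tab$uncertainty <- thompson_uncertainty(s_eff, a, tab$photons,
                                          sqrt(pmax(tab$background, 0)))
  if (mode == "astig") {
    zl <- lookup_z(calibration, tab$sigma_x, tab$sigma_y)
    tab$z <- zl$z
    tab <- tab[zl$ok, , drop = FALSE]
  }
  tab <- tab[order(tab$frame, tab$x), ]
  tab$id <- seq_len(nrow(tab))
  tab$merged_from <- 1L
  tab$merged_sd <- NA_real_
  as_loc_table(tab, pixel_size = a, dim_mode = if (mode == "astig") "3d" else "2d")
}

empty_loc_table <- function(stack, mode) {
  as_loc_table(
    data.frame(id = integer(0), channel = integer(0), frame = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               sigma_x = numeric(0), sigma_y = numeric(0),
               photons = numeric(0), background = numeric(0),
               uncertainty = numeric(0), merged_from = integer(0),
               merged_sd = numeric(0)),
    pixel_size = stack$pixel_size,
    dim_mode = if (mode == "astig") "3d" else "2d")
}

as_loc_table <- function(df, pixel_size = NA, dim_mode = c("2d", "3d")) {
  dim_mode <- match.arg(dim_mode)
  attr(df, "pixel_size") <- pixel_size
  attr(df, "dim_mode") <- dim_mode
  class(df) <- c("loc_table", "data.frame")
  df
}

loc_dim <- function(table) {
  dm <- attr(table, "dim_mode")
  if (!is.null(dm)) return(if (dm == "3d") 3L else 2L)
  if ("z" %in% names(table) && any(!is.na(table$z))) 3L else 2L
}

loc_coords <- function(table, dim = loc_dim(table)) {
  if (dim == 3) cbind(table$x, table$y, table$z) else cbind(table$x, table$y)
}

#' Calibrate the astigmatic defocus curves from a bead z-stack
#'
#' Fits each z-plane of a bead scan with an elliptical Gaussian, then fits
#' the defocus model `sigma(z) = s0 * sqrt(1 + ((z - c)/d)^2)` to the
#' per-plane widths of each axis.  The two curves must cross exactly once in
#' the calibrated range (the focal plane).
#'
#' @param bead_stack an [image_stack()] with one bead per frame, one frame
#'   per z-plane.
#' @param z_positions true stage z per frame, nm.
#' @param ... passed to [localize_stack()] detection/fitting.
#' @return an `astig_calibration`: per-axis curve parameters, the calibrated
#'   range, the focal crossing and the per-plane width samples.
#' @export
calibrate_astigmatism <- function(bead_stack, z_positions, ...) {
  stopifnot(length(z_positions) == dim(bead_stack$data)[3])
  d <- dim(bead_stack$data)
  # brightest candidate per plane, fitted with an elliptical Gaussian
  cand <- detect_spots(bead_stack, ...)
  cand <- do.call(rbind, lapply(split(cand, cand$frame),
                                function(g) g[which.max(g$value), ]))
  # wide window: the defocused PSF at the range edges is several pixels wide
  fits <- cpp_fit_spots(bead_stack$data, d[1], d[2], d[3], cand$frame,
                        cand$row, cand$col, 10L, TRUE, 1.8, 120L)
  a <- bead_stack$pixel_size
  samples <- data.frame(z = z_positions[cand$frame],
                        sx = fits[, "sx_px"] * a, sy = fits[, "sy_px"] * a)
  samples <- samples[fits[, "ok"] == 1, ]
  if (nrow(samples) < 5) stop("too few usable calibration planes")

  fit_axis <- function(s) {
    st <- list(s0 = min(s), c = samples$z[which.min(s)], d = diff(range(z_positions)) / 3)
    fit <- minpack.lm::nlsLM(s ~ s0 * sqrt(1 + ((z - c) / d)^2),
                             data = data.frame(z = samples$z, s = s),
                             start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(fit)
  }
  par_x <- fit_axis(samples$sx)
  par_y <- fit_axis(samples$sy)
  rng <- range(z_positions)
  curve_diff <- function(z)
    sigma_curve(z, par_x) - sigma_curve(z, par_y)
  lo <- curve_diff(rng[1]); hi <- curve_diff(rng[2])
  if (sign(lo) == sign(hi)) stop("no focal plane in range")
  crossing <- uniroot(curve_diff, rng)$root
  structure(list(par_x = par_x, par_y = par_y, range = rng,
                 crossing = crossing, samples = samples,
                 tolerance = 100),
            class = "astig_calibration")
}

sigma_curve <- function(z, par) {
  par[["s0"]] * sqrt(1 + ((z - par[["c"]]) / par[["d"]])^2)
}

#' @export
print.astig_calibration <- function(x, ...) {
  cat(sprintf(
    "astig_calibration: z in [%g, %g] nm, focal crossing at %.1f nm\n",
    x$range[1], x$range[2], x$crossing))
  invisible(x)
}

#' Assign axial positions from fitted PSF widths
#'
#' Minimizes the squared distance in `(sigma_x, sigma_y)` space to the
#' calibration curves over the calibrated range.
#'
#' @param calibration an `astig_calibration`.
#' @param sigma_x,sigma_y fitted widths, nm.
#' @return list with `z` (nm), `ok` (within `calibration$tolerance` of the
#'   curves) and `resid` (distance to the curves, nm).
#' @export
lookup_z <- function(calibration, sigma_x, sigma_y) {
  zg <- seq(calibration$range[1], calibration$range[2], length.out = 241)
  cx <- sigma_curve(zg, calibration$par_x)
  cy <- sigma_curve(zg, calibration$par_y)
  n <- length(sigma_x)
  z <- numeric(n); resid <- numeric(n)
  for (i in seq_len(n)) {
    cost <- (sigma_x[i] - cx)^2 + (sigma_y[i] - cy)^2
    k <- which.min(cost)
    lo <- zg[max(1, k - 1)]; hi <- zg[min(length(zg), k + 1)]
    op <- optimize(function(zz)
      (sigma_x[i] - sigma_curve(zz, calibration$par_x))^2 +
        (sigma_y[i] - sigma_curve(zz, calibration$par_y))^2,
      c(lo, hi))
    z[i] <- op$minimum
    resid[i] <- sqrt(op$objective)
  }
  list(z = z, ok = resid <= calibration$tolerance, resid = resid)
}
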
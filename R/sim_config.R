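#' Simulation configuration for the synthetic two-channel PALM generator
#'
#' Collects every knob of the bundled movie generator.  Defaults emulate the
#' dual-color PALM conditions the analysis is designed for: two
#' photoactivatable fluorescent proteins in an E. coli-sized cell at a total
#' fluorophore density of 6800 molecules/um^3, imaged on an EMCCD with 82 nm
#' pixels, 80 ms exposure and EM gain 400, with ~10% bleed-through of channel
#' 1 into channel 2 and a smooth chromatic aberration field of up to a few
#' hundred nanometres displacing channel 2.
#'
#' @param density total fluorophore density, molecules/um^3 (both channels).
#' @param pair_mode `"random"` (channels placed independently) or `"paired"`
#'   (every channel-1 molecule has a channel-2 partner at a truncated-normal
#'   3D distance).
#' @param pair_distance_mean,pair_distance_sd mean and SD (nm) of the
#'   partner-distance law, a normal truncated at 0.
#' @param n_frames number of movie frames.
#' @param exposure_ms camera exposure per frame.
#' @param activation_efficiency fraction of molecules that are
#'   photoactivatable at all.  Photoactivatable fluorescent proteins are well
#'   documented to photoconvert with roughly 40-60% efficiency, so only about
#'   half of the placed molecules ever yield a localization.
#' @param activation_prob per-frame photoactivation probability of an
#'   activatable molecule (geometric waiting time).
#' @param on_survival probability that an emitting molecule stays on in the
#'   next frame (geometric on-times, mean `1/(1 - on_survival)` frames).
#' @param reappear_prob probability that a bleached-looking molecule blinks
#'   back once after a short dark gap.
#' @param max_dark_gap maximum dark gap (frames) before a reappearance.
#' @param photons_mean,photons_sd per-frame emitted photons (normal,
#'   truncated at 50).
#' @param psf_sigma0 in-focus PSF standard deviation, nm.
#' @param astig_c,astig_d astigmatism parameters (nm): the defocus curves are
#'   `sigma_x(z) = psf_sigma0 * sqrt(1 + ((z - astig_c)/astig_d)^2)` and
#'   `sigma_y(z)` with `+astig_c`, so the curves cross at the focal plane.
#' @param z_range calibrated axial half-range, nm.
#' @param pixel_size camera pixel size, nm.
#' @param fov_px field of view `(rows, cols)` in pixels.
#' @param em_gain EMCCD electron-multiplying gain (counts per photon).
#' @param read_noise camera read noise, counts RMS.
#' @param offset camera count offset.
#' @param background_photons uniform background, photons/pixel/frame.
#' @param crosstalk fraction of channel-1 signal bleeding into channel 2;
#'   either a scalar or a function `f(x_nm, y_nm)` for a spatially varying
#'   bleed-through.
#' @param aberration_ch2 chromatic displacement field of channel 2 relative
#'   to channel 1: list with components `x`, `y`, `z`, each a length-6
#'   coefficient vector `c(1, u, v, u^2, u*v, v^2)` in nm, where `u`, `v` are
#'   field coordinates normalized to `[0, 1]`.
#' @param retention per-channel probability that a fluorophore survives
#'   sample processing (relevant for expansion protocols).
#' @param bead_photons photons emitted by a calibration bead per frame.
#' @param noise `"emccd"` for the full camera model or `"none"` for a
#'   noiseless, linear render (counts = gain x photons + offset).
#' @param cell the imaged [cell_model()]; `NULL` (default) places an
#'   E. coli-sized spherocylinder at the centre of the field of view.
#' @param seed integer seed used by [simulate_movie()].
#' @return a validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(pair_mode = "paired", n_frames = 100)
#' @export
sim_config <- function(density = 6800,
                       pair_mode = c("random", "paired"),
                       pair_distance_mean = 10,
                       pair_distance_sd = 5,
                       n_frames = 2000,
                       exposure_ms = 80,
                       activation_efficiency = 0.5,
                       activation_prob = 0.0025,
                       on_survival = 1 / 3,
                       reappear_prob = 0.3,
                       max_dark_gap = 5,
                       photons_mean = 1300,
                       photons_sd = 260,
                       psf_sigma0 = 150,
                       astig_c = 400,
                       astig_d = 400,
                       z_range = 600,
                       pixel_size = 82,
                       fov_px = c(128, 128),
                       em_gain = 400,
                       read_noise = 10,
                       offset = 100,
                       background_photons = 2,
                       crosstalk = 0.10,
                       aberration_ch2 = default_aberration(),
                       retention = c(1, 1),
                       bead_photons = 20000,
                       noise = c("emccd", "none"),
                       cell = NULL,
                       seed = NULL) {
  pair_mode <- match.arg(pair_mode)
  noise <- match.arg(noise)
  stopifnot(length(fov_px) == 2, length(retention) == 2)
  cfg <- list(density = density, pair_mode = pair_mode,
              pair_distance_mean = pair_distance_mean,
              pair_distance_sd = pair_distance_sd,
              n_frames = as.integer(n_frames), exposure_ms = exposure_ms,
              activation_efficiency = activation_efficiency,
              activation_prob = activation_prob, on_survival = on_survival,
              reappear_prob = reappear_prob,
              max_dark_gap = as.integer(max_dark_gap),
              photons_mean = photons_mean, photons_sd = photons_sd,
              psf_sigma0 = psf_sigma0, astig_c = astig_c, astig_d = astig_d,
              z_range = z_range, pixel_size = pixel_size,
              fov_px = as.integer(fov_px), em_gain = em_gain,
              read_noise = read_noise, offset = offset,
              background_photons = background_photons, crosstalk = crosstalk,
              aberration_ch2 = aberration_ch2, retention = retention,
              bead_photons = bead_photons, noise = noise, cell = cell,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default chromatic aberration field of channel 2
#'
#' A smooth offset + linear + quadratic displacement, a few hundred nm at the
#' field edges laterally, plus a constant axial focal shift of 9.8 nm.
#' @return list with `x`, `y`, `z` coefficient vectors (see [sim_config()]).
#' @export
default_aberration <- function() {
  list(x = c(120, -180, 60, 90, -40, 30),
       y = c(-90, 70, -150, -50, 80, 60),
       z = c(9.8, 0, 0, 0, 0, 0))
}

validate_sim_config <- function(cfg) {
  if (cfg$density <= 0) stop("density must be > 0")
  if (cfg$pair_distance_sd < 0) stop("pair distance sd must be >= 0")
  if (cfg$pair_distance_mean < 0) stop("pair distance mean must be >= 0")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (cfg$pixel_size <= 0) stop("pixel size must be > 0")
  probs <- c(cfg$activation_efficiency, cfg$activation_prob,
             cfg$on_survival, cfg$reappear_prob)
  if (any(probs < 0 | probs > 1)) stop("all rates must be probabilities in [0, 1]")
  if (is.numeric(cfg$crosstalk) &&
      (cfg$crosstalk < 0 || cfg$crosstalk >= 1))
    stop("crosstalk fraction must lie in [0, 1)")
  if (any(cfg$retention <= 0 | cfg$retention > 1))
    stop("retention must lie in (0, 1]")
  if (!is.null(cfg$cell) && !inherits(cfg$cell, "cell_model"))
    stop("cell must be a cell_model")
  invisible(cfg)
}

# The configured cell, defaulting to one centred in the field of view.
config_cell <- function(config) {
  if (!is.null(config$cell)) return(config$cell)
  fov_nm <- config$fov_px * config$pixel_size
  cell_model(center = c(fov_nm[2] / 2, fov_nm[1] / 2, 0))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s mode, %g molecules/um^3, %d frames, %dx%d px @ %g nm\n",
    x$pair_mode, x$density, x$n_frames, x$fov_px[1], x$fov_px[2],
    x$pixel_size))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$fov_px <- as.integer(plain$fov_px)
  if (is.function(plain$crosstalk))
    stop("spatially varying crosstalk functions cannot be serialized")
  if (!is.null(plain$cell)) plain$cell <- unclass(plain$cell)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$aberration_ch2 <- lapply(lst$aberration_ch2, as.numeric)
  lst$retention <- as.numeric(lst$retention)
  lst$fov_px <- as.integer(lst$fov_px)
  if (!is.null(lst$cell))
    lst$cell <- cell_model(lst$cell$length, lst$cell$diameter,
                           as.numeric(lst$cell$center),
                           as.numeric(lst$cell$axis))
  do.call(sim_config, lst)
}

# Evaluate a length-6 polynomial displacement field (nm) at positions (nm).
eval_field <- function(coefs, x, y, fov_nm) {
  if (is.null(coefs)) return(rep(0, length(x)))
  u <- x / fov_nm[2]
  v <- y / fov_nm[1]
  coefs[1] + coefs[2] * u + coefs[3] * v + coefs[4] * u^2 +
    coefs[5] * u * v + coefs[6] * v^2
}

# Displacement of a channel at positions (nm): channel 1 is the reference.
channel_displacement <- function(cfg, channel, x, y) {
  fov_nm <- cfg$fov_px * cfg$pixel_size
  if (channel == 1) {
    cbind(dx = rep(0, length(x)), dy = rep(0, length(x)),
          dz = rep(0, length(x)))
  } else {
    ab <- cfg$aberration_ch2
    cbind(dx = eval_field(ab$x, x, y, fov_nm),
          dy = eval_field(ab$y, x, y, fov_nm),
          dz = eval_field(ab$z, x, y, fov_nm))
  }
}

# Astigmatic defocus curves of the generator (and of calibration fits).
astig_sigma <- function(z, sigma0, c0, d0) {
  cbind(sx = sigma0 * sqrt(1 + ((z - c0) / d0)^2),
        sy = sigma0 * sqrt(1 + ((z + c0) / d0)^2))
}
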
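#' Render a two-channel PALM movie from a ground-truth scene
#'
#' Every emitting molecule is rendered as an integrated 2D Gaussian at its
#' true position displaced by the channel's chromatic aberration field
#' (channel 1 is the reference and has zero displacement).  Channel-1
#' emitters additionally deposit `crosstalk x photons` into channel 2, at the
#' channel-2 (aberrated) position, emulating spectral bleed-through.  In
#' `"3d"` mode the PSF widths follow the astigmatic defocus curves; in
#' `"2d"` mode the PSF is isotropic with SD `psf_sigma0`.  Camera counts
#' follow the EMCCD model (Poisson photons, Gamma EM gain, Gaussian read
#' noise, constant offset) or, with `noise = "none"`, the linear map
#' `counts = gain x photons + offset`.
#'
#' @param truth an `emitter_truth` with appearances filled
#'   ([simulate_photophysics()]).
#' @param config a [sim_config()].
#' @param mode `"2d"` or `"3d"` (astigmatic).
#' @return list with `ch1`, `ch2` ([image_stack()]s) and `clipped`, the ids
#'   of molecules whose rendered position falls outside the field of view
#'   (they are clipped from the movie but kept in the ground truth).
#' @export
render_movies <- function(truth, config = truth$config,
                          mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (is.null(truth$emission))
    stop("appearances not filled; run simulate_photophysics() first")
  H <- config$fov_px[1]; W <- config$fov_px[2]
  a <- config$pixel_size
  fov_nm <- c(H, W) * a
  nf <- config$n_frames
  mol <- truth$molecules
  em <- truth$emission
  mi <- match(em$mol_id, mol$id)

  clipped <- integer(0)
  mean_imgs <- list()
  for (ch in 1:2) {
    img <- array(config$background_photons, dim = c(H, W, nf))
    sel <- mol$channel[mi] == ch
    if (any(sel)) {
      r <- spot_geometry(mol[mi[sel], ], config, ch, mode)
      img <- cpp_render_spots(img, H, W, nf, r$x / a, r$y / a,
                              r$sx / a, r$sy / a, em$photons[sel],
                              em$frame[sel] - 1L)
      out <- r$x < 0 | r$x > fov_nm[2] | r$y < 0 | r$y > fov_nm[1]
      clipped <- c(clipped, unique(em$mol_id[sel][out]))
    }
    if (ch == 2) {
      # bleed-through of channel-1 emitters, at their channel-2 position
      sel1 <- mol$channel[mi] == 1
      if (any(sel1) && !identical(config$crosstalk, 0)) {
        r <- spot_geometry(mol[mi[sel1], ], config, 2, mode)
        ct <- if (is.function(config$crosstalk))
          config$crosstalk(r$x, r$y) else config$crosstalk
        img <- cpp_render_spots(img, H, W, nf, r$x / a, r$y / a,
                                r$sx / a, r$sy / a,
                                em$photons[sel1] * ct, em$frame[sel1] - 1L)
      }
    }
    mean_imgs[[ch]] <- img
  }

  stacks <- lapply(1:2, function(ch) {
    counts <- apply_camera(mean_imgs[[ch]], config)
    image_stack(counts, pixel_size = a, channel = ch,
                exposure_ms = config$exposure_ms)
  })
  list(ch1 = stacks[[1]], ch2 = stacks[[2]], clipped = sort(clipped))
}

# Rendered position and PSF widths (nm) of molecules as seen by `channel`.
spot_geometry <- function(mol, config, channel, mode) {
  disp <- channel_displacement(config, channel, mol$x, mol$y)
  x <- mol$x + disp[, "dx"]
  y <- mol$y + disp[, "dy"]
  z <- mol$z + disp[, "dz"]
  if (mode == "2d") {
    sx <- sy <- rep(config$psf_sigma0, length(x))
  } else {
    s <- astig_sigma(z, config$psf_sigma0, config$astig_c, config$astig_d)
    sx <- s[, "sx"]; sy <- s[, "sy"]
  }
  list(x = x, y = y, z = z, sx = sx, sy = sy)
}

apply_camera <- function(mean_photons, config) {
  if (config$noise == "none") {
    config$em_gain * mean_photons + config$offset
  } else {
    d <- dim(mean_photons)
    array(cpp_emccd_noise(as.numeric(mean_photons), config$em_gain,
                          config$read_noise, config$offset), dim = d)
  }
}

#' Simulate one complete two-channel acquisition
#'
#' Convenience wrapper: seeds the RNG from `config$seed` (when set), places
#' molecules, runs the photophysics and renders the movie.  Identical config
#' and seed give bit-identical movies.
#'
#' @inheritParams render_movies
#' @param cell a [cell_model()]; defaults to the config's cell (a
#'   spherocylinder centred in the field of view when unset).
#' @return list with `truth` and the rendered `movies`.
#' @export
simulate_movie <- function(config, cell = config_cell(config),
                           mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- place_molecules(config, cell)
  truth <- simulate_photophysics(truth, config)
  movies <- render_movies(truth, config, mode)
  list(truth = truth, movies = movies)
}

#' Generate calibration bead scan stacks
#'
#' Images one multi-emission bead, visible in both channels, at every node of
#' a regular scan grid (one frame per node), emulating the piezo scan of a
#' bead calibration sample.  Channel-2 positions are displaced by the
#' configured chromatic aberration field.  With `nz > 1` the bead is also
#' scanned axially and rendered with the astigmatic PSF.
#'
#' @param grid list with `nx`, `ny` (lateral node counts), optional `nz`
#'   (axial planes, default 1), `step_xy` and `step_z` (nm, default 600).
#' @param config a [sim_config()].
#' @param render if `FALSE`, skip rendering and return only the true
#'   positions table (useful for scan design checks).
#' @return list with `ch1`, `ch2` image stacks (when rendered) and
#'   `positions`: one row per frame with the true bead position in each
#'   channel.
#' @export
generate_bead_stacks <- function(grid, config, render = TRUE) {
  nx <- grid$nx; ny <- grid$ny
  nz <- if (is.null(grid$nz)) 1L else grid$nz
  step_xy <- if (is.null(grid$step_xy)) 600 else grid$step_xy
  step_z <- if (is.null(grid$step_z)) 600 else grid$step_z
  if (step_xy <= 0 || step_z <= 0) stop("scan step sizes must be > 0")
  H <- config$fov_px[1]; W <- config$fov_px[2]
  a <- config$pixel_size
  margin <- 6 * config$psf_sigma0
  span_x <- (nx - 1) * step_xy
  span_y <- (ny - 1) * step_xy
  if (span_x > W * a - 2 * margin)
    stop("scan grid exceeds the field of view along x")
  if (span_y > H * a - 2 * margin)
    stop("scan grid exceeds the field of view along y")

  xs <- W * a / 2 + (seq_len(nx) - (nx + 1) / 2) * step_xy
  ys <- H * a / 2 + (seq_len(ny) - (ny + 1) / 2) * step_xy
  zs <- (seq_len(nz) - (nz + 1) / 2) * step_z
  nodes <- expand.grid(x = xs, y = ys, z = zs)
  nfr <- nrow(nodes)
  disp <- channel_displacement(config, 2, nodes$x, nodes$y)
  pos <- data.frame(frame = seq_len(nfr),
                    x = nodes$x, y = nodes$y, z = nodes$z,
                    x2 = nodes$x + disp[, "dx"], y2 = nodes$y + disp[, "dy"],
                    z2 = nodes$z + disp[, "dz"])
  out <- list(positions = pos, grid = list(nx = nx, ny = ny, nz = nz,
                                           step_xy = step_xy,
                                           step_z = step_z))
  if (!render) return(out)

  mode3d <- nz > 1
  for (ch in 1:2) {
    img <- array(config$background_photons, dim = c(H, W, nfr))
    if (ch == 1) { px <- pos$x; py <- pos$y; pz <- pos$z }
    else { px <- pos$x2; py <- pos$y2; pz <- pos$z2 }
    if (mode3d) {
      s <- astig_sigma(pz, config$psf_sigma0, config$astig_c, config$astig_d)
      sx <- s[, "sx"]; sy <- s[, "sy"]
    } else {
      sx <- sy <- rep(config$psf_sigma0, nfr)
    }
    img <- cpp_render_spots(img, H, W, nfr, px / a, py / a, sx / a, sy / a,
                            rep(config$bead_photons, nfr),
                            pos$frame - 1L)
    out[[paste0("ch", ch)]] <- image_stack(
      apply_camera(img, config), pixel_size = a, channel = ch)
  }
  out
}

#' Generate donor-only calibration frames
#'
#' Frames in which only channel-1 fluorophores emit, as acquired at the start
#' of a dual-color experiment to measure the bleed-through into channel 2.
#'
#' @param config a [sim_config()].
#' @param cell a [cell_model()]; emitters are drawn inside it (pass `NULL`
#'   to scatter emitters over the whole field of view).
#' @param n_frames number of calibration frames.
#' @param emitters_per_frame active channel-1 emitters per frame.
#' @return list with `ch1` and `ch2` image stacks.
#' @export
make_donor_frames <- function(config, cell = config_cell(config), n_frames = 15,
                              emitters_per_frame = 40) {
  H <- config$fov_px[1]; W <- config$fov_px[2]
  a <- config$pixel_size
  n <- n_frames * emitters_per_frame
  if (is.null(cell)) {
    m <- 4 * config$psf_sigma0
    pos <- cbind(x = runif(n, m, W * a - m), y = runif(n, m, H * a - m),
                 z = 0)
  } else {
    pos <- sample_in_cell(cell, n)
  }
  frame <- rep(seq_len(n_frames), each = emitters_per_frame)
  photons <- pmax(rnorm(n, config$photons_mean, config$photons_sd), 50)
  disp <- channel_displacement(config, 2, pos[, 1], pos[, 2])
  ct <- if (is.function(config$crosstalk))
    config$crosstalk(pos[, 1] + disp[, "dx"], pos[, 2] + disp[, "dy"])
  else config$crosstalk
  s0 <- config$psf_sigma0 / a

  img1 <- array(config$background_photons, dim = c(H, W, n_frames))
  img1 <- cpp_render_spots(img1, H, W, n_frames, pos[, 1] / a, pos[, 2] / a,
                           rep(s0, n), rep(s0, n), photons, frame - 1L)
  img2 <- array(config$background_photons, dim = c(H, W, n_frames))
  img2 <- cpp_render_spots(img2, H, W, n_frames,
                           (pos[, 1] + disp[, "dx"]) / a,
                           (pos[, 2] + disp[, "dy"]) / a,
                           rep(s0, n), rep(s0, n), photons * ct, frame - 1L)
  list(ch1 = image_stack(apply_camera(img1, config), a, channel = 1L),
       ch2 = image_stack(apply_camera(img2, config), a, channel = 2L))
}
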
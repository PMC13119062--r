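#' Place molecules inside a cell
#'
#' Draws the ground-truth molecule positions for one acquisition.  The number
#' of molecules is `round(density x volume)`, split between the two channels.
#' In `"paired"` mode each channel-1 molecule receives a channel-2 partner at
#' a truncated-normal 3D distance (mean `pair_distance_mean`, SD
#' `pair_distance_sd`, truncated at 0) in a uniformly random direction;
#' partners falling outside the cell are re-drawn.
#'
#' @param config a [sim_config()].
#' @param cell a [cell_model()].
#' @return an `emitter_truth` object: a list with a `molecules` data frame
#'   (`id`, `channel`, `x`, `y`, `z` nm, `partner_id`) and the `cell` and
#'   `config` used.
#' @examples
#' set.seed(1)
#' tr <- place_molecules(sim_config(pair_mode = "paired"), cell_model())
#' head(tr$molecules)
#' @export
place_molecules <- function(config, cell) {
  validate_sim_config(config)
  n_total <- round(config$density * cell_volume_um3(cell))
  if (n_total < 1)
    stop("empty scene: density x cell volume yields zero molecules")

  if (config$pair_mode == "random") {
    pos <- sample_in_cell(cell, n_total)
    channel <- rbinom(n_total, 1, 0.5) + 1L
    mol <- data.frame(id = seq_len(n_total), channel = channel,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      partner_id = NA_integer_)
  } else {
    n_pairs <- max(1L, round(n_total / 2))
    a <- sample_in_cell(cell, n_pairs)
    b <- matrix(NA_real_, n_pairs, 3)
    todo <- seq_len(n_pairs)
    tries <- 0
    while (length(todo) > 0) {
      m <- length(todo)
      d <- rtruncnorm_pos(m, config$pair_distance_mean,
                          config$pair_distance_sd)
      dir <- random_directions(m)
      cand <- a[todo, , drop = FALSE] + dir * d
      ok <- point_in_cell(cell, cand)
      b[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
      tries <- tries + 1
      if (tries > 200 && length(todo) > 0) {
        # pathological geometry (pair distance >> cell): re-draw the anchors
        a[todo, ] <- sample_in_cell(cell, length(todo))
        tries <- 0
      }
    }
    mol <- data.frame(
      id = seq_len(2 * n_pairs),
      channel = rep(c(1L, 2L), each = n_pairs),
      x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]), z = c(a[, 3], b[, 3]),
      partner_id = c(n_pairs + seq_len(n_pairs), seq_len(n_pairs)))
  }
  structure(list(molecules = mol, cell = cell, config = config,
                 appearances = NULL, emission = NULL),
            class = "emitter_truth")
}

# Normal truncated at 0 by rejection; degenerate SD returns the mean.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd < 0) stop("pair distance sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  while (any(bad <- out < 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

# Uniform directions on the unit sphere.
random_directions <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' @export
print.emitter_truth <- function(x, ...) {
  cat(sprintf("emitter_truth: %d molecules (%d ch1, %d ch2)%s\n",
              nrow(x$molecules), sum(x$molecules$channel == 1),
              sum(x$molecules$channel == 2),
              if (is.null(x$appearances)) "" else
                sprintf(", %d appearances", nrow(x$appearances))))
  invisible(x)
}

#' Simulate photoactivation, blinking and bleaching
#'
#' Minimal activate-blink-bleach kinetics: a molecule survives sample
#' processing with the per-channel retention probability, is photoactivatable
#' with probability `activation_efficiency`, waits a geometric number of
#' frames to switch on, emits for a geometric number of frames (per-frame
#' survival `on_survival`), may blink back once after a dark gap of at most
#' `max_dark_gap` frames with probability `reappear_prob`, and then bleaches
#' permanently.
#'
#' @param truth output of [place_molecules()].
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return `truth` with `appearances` (one row per on-stretch: `mol_id`,
#'   `frame_start`, `frame_end`, `photons`) and `emission` (one row per
#'   molecule-frame with its emitted photons) filled in.
#' @export
simulate_photophysics <- function(truth, config = truth$config) {
  validate_sim_config(config)
  mol <- truth$molecules
  n <- nrow(mol)
  nf <- config$n_frames

  retained <- runif(n) < config$retention[mol$channel]
  activatable <- runif(n) < config$activation_efficiency
  t_on <- if (config$activation_prob >= 1) rep(1L, n) else
    rgeom(n, config$activation_prob) + 1L
  alive <- retained & activatable & t_on <= nf

  idx <- which(alive)
  on1 <- rgeom(length(idx), 1 - config$on_survival) + 1L
  reapp <- runif(length(idx)) < config$reappear_prob & config$max_dark_gap > 0
  gap <- integer(length(idx))
  gap[reapp] <- sample.int(config$max_dark_gap, sum(reapp), replace = TRUE)
  on2 <- integer(length(idx))
  on2[reapp] <- rgeom(sum(reapp), 1 - config$on_survival) + 1L

  app <- data.frame(mol_id = integer(0), frame_start = integer(0),
                    frame_end = integer(0))
  if (length(idx) > 0) {
    s1 <- t_on[idx]
    e1 <- pmin(s1 + on1 - 1L, nf)
    app1 <- data.frame(mol_id = mol$id[idx], frame_start = s1, frame_end = e1)
    s2 <- e1 + gap + 1L
    keep2 <- reapp & s2 <= nf
    app2 <- data.frame(mol_id = mol$id[idx][keep2], frame_start = s2[keep2],
                       frame_end = pmin(s2[keep2] + on2[keep2] - 1L, nf))
    app <- rbind(app1, app2)
    app <- app[order(app$mol_id, app$frame_start), ]
  }

  # per-frame photon emission
  if (nrow(app) > 0) {
    reps <- app$frame_end - app$frame_start + 1L
    em <- data.frame(
      mol_id = rep(app$mol_id, reps),
      frame = unlist(mapply(seq.int, app$frame_start, app$frame_end,
                            SIMPLIFY = FALSE), use.names = FALSE))
    ph <- rnorm(nrow(em), config$photons_mean, config$photons_sd)
    em$photons <- pmax(ph, 50)
    key_em <- rep(seq_len(nrow(app)), reps)
    app$photons <- as.numeric(rowsum(em$photons, key_em))
  } else {
    em <- data.frame(mol_id = integer(0), frame = integer(0),
                     photons = numeric(0))
    app$photons <- numeric(0)
  }

  truth$appearances <- app
  truth$emission <- em
  truth$config <- config
  truth
}

#' Apply an isotropic expansion to a ground-truth scene
#'
#' Scales all coordinates about the cell centre by `factor`, emulating the
#' physical magnification of an expanded hydrogel.  With `jitter > 0` each
#' axis receives its own factor `factor * (1 + N(0, jitter))`, emulating
#' slightly anisotropic gel swelling.  Pairwise distances scale by `factor`
#' when `jitter = 0`; the molecular density drops by `factor^-3`.
#'
#' @param truth an `emitter_truth`.
#' @param factor expansion factor, >= 1.
#' @param jitter per-axis relative anisotropy SD (0 = perfectly isotropic).
#' @return the expanded `emitter_truth` (cell dimensions scaled too).
#' @export
apply_expansion <- function(truth, factor, jitter = 0) {
  if (factor < 1) stop("expansion factor must be >= 1")
  f <- factor * (1 + if (jitter > 0) rnorm(3, 0, jitter) else c(0, 0, 0))
  ctr <- truth$cell$center
  mol <- truth$molecules
  mol$x <- ctr[1] + (mol$x - ctr[1]) * f[1]
  mol$y <- ctr[2] + (mol$y - ctr[2]) * f[2]
  mol$z <- ctr[3] + (mol$z - ctr[3]) * f[3]
  truth$molecules <- mol
  truth$cell$length <- truth$cell$length * factor
  truth$cell$diameter <- truth$cell$diameter * factor
  truth$expansion_factor <- factor
  truth
}

#' Effective molecular density of a scene
#' @param truth an `emitter_truth`.
#' @return molecules per um^3 inside the (possibly expanded) cell.
#' @export
scene_density <- function(truth) {
  nrow(truth$molecules) / cell_volume_um3(truth$cell)
}

#' Write ground truth to CSV
#' @param truth an `emitter_truth` (after [simulate_photophysics()] if
#'   appearance columns are wanted).
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  mol <- truth$molecules
  names(mol) <- c("id", "channel", "x_nm", "y_nm", "z_nm", "partner_id")
  if (!is.null(truth$appearances) && nrow(truth$appearances) > 0) {
    first <- truth$appearances[!duplicated(truth$appearances$mol_id), ]
    last <- truth$appearances[rev(!duplicated(rev(truth$appearances$mol_id))), ]
    tot <- rowsum(truth$appearances$photons, truth$appearances$mol_id)
    i <- match(mol$id, first$mol_id)
    mol$frame_start <- first$frame_start[i]
    mol$frame_end <- last$frame_end[match(mol$id, last$mol_id)]
    mol$photons <- tot[match(mol$id, rownames(tot))]
  } else {
    mol$frame_start <- NA_integer_
    mol$frame_end <- NA_integer_
    mol$photons <- NA_real_
  }
  write.csv(mol, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
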
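# Shared fixtures and small constructors used across the test files.
# Expensive fixtures are memoized so several files can reuse one computation.

.expalm_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .expalm_cache, inherits = FALSE))
    assign(name, force(expr), envir = .expalm_cache)
  get(name, envir = .expalm_cache, inherits = FALSE)
}

zero_aberration <- function() list(x = rep(0, 6), y = rep(0, 6), z = rep(0, 6))

# Identity LWM transform: one center at the origin with a huge radius of
# influence, whose local polynomial is the identity map.  Feeding it to
# compute_fre() makes the residuals exactly the raw point differences,
# which is what the hand-computable FRE oracles need (a fitted transform
# would absorb part of the residuals).
identity_lwm <- function(d = 2) {
  ncoef <- if (d == 2) 6L else 10L
  radius <- 1e7
  coefs <- array(0, dim = c(1, ncoef, d))
  for (j in seq_len(d)) coefs[1, 1 + j, j] <- radius
  structure(list(centers = matrix(0, 1, d), coefs = coefs, radius = radius,
                 dim = d, neighbors = if (d == 2) 8L else 16L, order = 2,
                 weight = "w(R) = 1 - 3R^2 + 2R^3 on [0,1], 0 beyond",
                 n_points = 1L),
            class = "lwm_transform")
}

# Control point set without the >= 6 points constructor check, for
# hand-computable FRE arithmetic on tiny sets.
tiny_control_points <- function(p1, p2) {
  d <- ncol(p1)
  df <- data.frame(p1, p2)
  names(df) <- c(paste0(c("x", "y", "z")[1:d], 1),
                 paste0(c("x", "y", "z")[1:d], 2))
  class(df) <- c("control_points", "data.frame")
  df
}

# Hand-built ground-truth scene: molecules at given positions with
# deterministic appearance windows; per-frame photons are constant within
# each on-stretch.
manual_truth <- function(mol, appearances, config,
                         cell = cell_model(center = c(
                           config$fov_px[2] * config$pixel_size / 2,
                           config$fov_px[1] * config$pixel_size / 2, 0))) {
  reps <- appearances$frame_end - appearances$frame_start + 1L
  emission <- data.frame(
    mol_id = rep(appearances$mol_id, reps),
    frame = unlist(mapply(seq.int, appearances$frame_start,
                          appearances$frame_end, SIMPLIFY = FALSE),
                   use.names = FALSE),
    photons = rep(appearances$photons, reps))
  appearances$photons <- appearances$photons * reps
  structure(list(molecules = mol, cell = cell, config = config,
                 appearances = appearances, emission = emission),
            class = "emitter_truth")
}

# Build a localization table directly from coordinates.
loc_df <- function(x, y, z = NA_real_, channel = 1L, frame = 1L,
                   photons = 1000, uncertainty = 5, pixel_size = 82) {
  n <- length(x)
  tab <- data.frame(
    id = seq_len(n), channel = as.integer(channel), frame = as.integer(frame),
    x = x, y = y, z = z,
    sigma_x = 150, sigma_y = 150,
    photons = photons, background = 1,
    uncertainty = uncertainty, merged_from = 1L, merged_sd = NA_real_)
  expalm:::as_loc_table(tab, pixel_size = pixel_size,
                        dim_mode = if (any(!is.na(tab$z))) "3d" else "2d")
}

# CDF of a normal truncated at 0 (the pair-distance law of the generator).
ptrunc0 <- function(q, mean, sd) {
  p <- (pnorm(q, mean, sd) - pnorm(0, mean, sd)) / (1 - pnorm(0, mean, sd))
  pmin(pmax(p, 0), 1)
}

mean_trunc0 <- function(mean, sd) {
  mean + sd * dnorm(mean / sd) / pnorm(mean / sd)
}

# Ghost-drop measurement for the crosstalk oracle: counts ch2 localizations
# attributable to ch1 emitters (a ch1 emitter active in that frame within
# 1 px and no active ch2 emitter within 2 px), before and after correction.
# The width filter sigma_range rejects multi-emitter blends identically on
# both sides; ghosts carry ~10% of 1300 photons, hence the low photon floor.
crosstalk_drop <- function(seed = 42L, n_frames = 400) {
  cfg <- sim_config(fov_px = c(64, 64), n_frames = n_frames,
                    aberration_ch2 = zero_aberration())
  cfg$seed <- seed
  set.seed(seed)
  sim <- simulate_movie(cfg)
  donor <- make_donor_frames(cfg)
  map <- estimate_crosstalk(donor$ch1, donor$ch2, background = c(900, 900))
  ch2c <- correct_frames(sim$movies$ch2, sim$movies$ch1, map)
  loc_args <- list(threshold = 4, min_photons = 50, sigma_range = c(100, 250))
  lraw <- do.call(localize_stack, c(list(sim$movies$ch2), loc_args))
  lcor <- do.call(localize_stack, c(list(ch2c), loc_args))

  mol <- sim$truth$molecules
  em <- sim$truth$emission
  em$channel <- mol$channel[match(em$mol_id, mol$id)]
  em$x <- mol$x[match(em$mol_id, mol$id)]
  em$y <- mol$y[match(em$mol_id, mol$id)]
  count_attributable <- function(l) {
    n <- 0L
    for (i in seq_len(nrow(l))) {
      e <- em[em$frame == l$frame[i], ]
      d1 <- suppressWarnings(min(sqrt(
        (e$x[e$channel == 1] - l$x[i])^2 + (e$y[e$channel == 1] - l$y[i])^2)))
      d2 <- suppressWarnings(min(sqrt(
        (e$x[e$channel == 2] - l$x[i])^2 + (e$y[e$channel == 2] - l$y[i])^2)))
      if (is.finite(d1) && d1 <= 82 && (!is.finite(d2) || d2 > 164))
        n <- n + 1L
    }
    n
  }
  c(before = count_attributable(lraw), after = count_attributable(lcor))
}

# The 60 + 60 acquisition studies shared by acceptance criteria 1 and 2.
# Seeds fixed a priori: 1 (positive / paired), 2 (negative / random).
acceptance_studies <- function() {
  cached("acceptance_studies", {
    list(pos = run_colocalization_study(60, "paired", seed = 1L),
         neg = run_colocalization_study(60, "random", seed = 2L))
  })
}

# A small noisy bead-scan registration fixture (64 px, 600 nm grid).
bead_fixture <- function() {
  cached("bead_fixture", {
    cfg <- sim_config(fov_px = c(64, 64))
    cfg$seed <- 11L
    set.seed(11L)
    grid <- expalm:::max_grid_for_fov(600, cfg)
    beads <- generate_bead_stacks(grid, cfg)
    list(cfg = cfg, grid = grid, beads = beads)
  })
}
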
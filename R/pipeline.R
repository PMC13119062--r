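#' Pipeline run configuration
#'
#' Bundles the file paths and per-stage parameter blocks of a full analysis
#' run: (i) crosstalk correction, (ii) single-molecule localization,
#' (iii) chromatic aberration correction, (iv) merging of reappearing
#' molecules, then co-localization.
#'
#' @param mode `"2D-PALM"`, `"2D-ExPALM"` or `"3D-ExPALM"`.
#' @param movies list with paths `ch1`, `ch2` of the acquisition TIFFs.
#' @param donor list with paths `ch1`, `ch2` of donor-only calibration TIFFs.
#' @param beads list with paths `ch1`, `ch2` of the bead scan TIFFs recorded
#'   before the acquisition.
#' @param astig list with `stack` (bead z-stack TIFF) and `z_positions`
#'   (stage z per frame, nm) — required in 3D mode.
#' @param localize,register,merge,coloc per-stage parameter lists (arguments
#'   of [localize_stack()], [fit_lwm()], [merge_reappearances()],
#'   [coloc_params()]).
#' @param pixel_size camera pixel size of the recorded TIFFs, nm.
#' @param seed integer seed making the run reproducible.
#' @param out_dir output directory (created on run).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("2D-PALM", "2D-ExPALM", "3D-ExPALM"),
                            movies, donor, beads, astig = NULL,
                            localize = list(), register = list(),
                            merge = list(), coloc = list(),
                            pixel_size = 82, seed = 1L,
                            out_dir = "expalm-run") {
  mode <- match.arg(mode)
  cfg <- structure(list(mode = mode, movies = movies, donor = donor,
                        beads = beads, astig = astig, localize = localize,
                        register = register, merge = merge, coloc = coloc,
                        pixel_size = pixel_size,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  need <- list(`movies$ch1` = config$movies$ch1,
               `movies$ch2` = config$movies$ch2,
               `donor$ch1` = config$donor$ch1,
               `donor$ch2` = config$donor$ch2,
               `beads$ch1` = config$beads$ch1,
               `beads$ch2` = config$beads$ch2)
  if (config$mode == "3D-ExPALM") {
    if (is.null(config$astig$stack) || is.null(config$astig$z_positions))
      stop("3D-ExPALM requires an astigmatism calibration ",
           "(astig$stack and astig$z_positions)")
    need$`astig$stack` <- config$astig$stack
  }
  for (nm in names(need)) {
    if (is.null(need[[nm]])) stop("missing required path: ", nm)
    if (!file.exists(need[[nm]]))
      stop("referenced file does not exist: ", nm, " = ", need[[nm]])
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [pipeline_config()] arguments.
#'   Relative paths are resolved against the YAML file's directory.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (blk in c("movies", "donor", "beads"))
    y[[blk]] <- lapply(y[[blk]], fix)
  if (!is.null(y$astig)) y$astig$stack <- fix(y$astig$stack)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  flush(con)
}

#' Run the full analysis pipeline on recorded files
#'
#' Executes crosstalk correction, localization of both channels, chromatic
#' aberration correction (global axial shift plus 3D LWM in 3D mode, 2D LWM
#' otherwise), merging of reappearing molecules, and the co-localization
#' analysis.  Every stage writes its intermediate artifact into the run
#' directory and appends a JSON log line (parameters, counts, timing) to
#' `pipeline.log`; re-running with the same config and seed reproduces every
#' output.
#'
#' @param config a [pipeline_config()] (validated again before any
#'   computation; a missing calibration aborts the run with no outputs).
#' @return the run directory path (invisibly); artifacts: `crosstalk_map.*`,
#'   `locs_ch1.csv`, `locs_ch2.csv`, `locs_ch2_registered.csv`,
#'   `locs_ch1_merged.csv`, `locs_ch2_merged.csv`, `registration.json`,
#'   `coloc_result.json`, `pipeline.log`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(con))
  mode3d <- config$mode == "3D-ExPALM"
  loc_mode <- if (mode3d) "astig" else "2d"

  calib <- NULL
  if (mode3d) {
    t0 <- proc.time()[3]
    calib <- calibrate_astigmatism(read_image_stack(config$astig$stack,
                                                    config$pixel_size),
                                   config$astig$z_positions)
    log_stage(con, "astig_calibration",
              crossing_nm = calib$crossing, planes = nrow(calib$samples),
              seconds = round(proc.time()[3] - t0, 2))
  }

  # (iii)-calibration first: the registration also aligns the crosstalk map
  t0 <- proc.time()[3]
  beads1 <- read_image_stack(config$beads$ch1, config$pixel_size)
  beads2 <- read_image_stack(config$beads$ch2, config$pixel_size, channel = 2)
  reg <- do.call(build_registration,
                 c(list(beads1, beads2, calibration = calib),
                   config$register))
  write_lwm(reg$transform, file.path(config$out_dir, "registration.json"))
  log_stage(con, "registration_calibration",
            n_control_points = reg$fre$n, fre_total_nm = reg$fre$total,
            axial_shift_nm = reg$axial_shift,
            seconds = round(proc.time()[3] - t0, 2))

  # (i) crosstalk correction
  t0 <- proc.time()[3]
  donor1 <- read_image_stack(config$donor$ch1, config$pixel_size)
  donor2 <- read_image_stack(config$donor$ch2, config$pixel_size, channel = 2)
  xmap <- estimate_crosstalk(donor1, donor2, alignment = reg$transform_2d)
  write_crosstalk_map(xmap, file.path(config$out_dir, "crosstalk_map.tiff"),
                      file.path(config$out_dir, "crosstalk_map.json"))
  mov1 <- read_image_stack(config$movies$ch1, config$pixel_size)
  mov2 <- read_image_stack(config$movies$ch2, config$pixel_size, channel = 2)
  mov2c <- correct_frames(mov2, mov1, xmap)
  log_stage(con, "crosstalk_correction", median_cf = xmap$fill,
            frames = dim(mov2$data)[3],
            seconds = round(proc.time()[3] - t0, 2))

  # (ii) localization
  t0 <- proc.time()[3]
  loc1 <- do.call(localize_stack, c(list(mov1, mode = loc_mode,
                                         calibration = calib),
                                    config$localize))
  loc2 <- do.call(localize_stack, c(list(mov2c, mode = loc_mode,
                                         calibration = calib),
                                    config$localize))
  write_locs(loc1, file.path(config$out_dir, "locs_ch1.csv"))
  write_locs(loc2, file.path(config$out_dir, "locs_ch2.csv"))
  log_stage(con, "localization", n_ch1 = nrow(loc1), n_ch2 = nrow(loc2),
            mode = loc_mode, seconds = round(proc.time()[3] - t0, 2))

  # (iii) chromatic aberration correction
  t0 <- proc.time()[3]
  loc2r <- apply_registration(reg, loc2)
  write_locs(loc2r, file.path(config$out_dir, "locs_ch2_registered.csv"))
  log_stage(con, "chromatic_correction", n_ch2 = nrow(loc2r),
            fre_total_nm = reg$fre$total,
            seconds = round(proc.time()[3] - t0, 2))

  # (iv) merging of reappearing molecules
  t0 <- proc.time()[3]
  m1 <- do.call(merge_reappearances, c(list(loc1), config$merge))
  m2 <- do.call(merge_reappearances, c(list(loc2r), config$merge))
  write_locs(m1, file.path(config$out_dir, "locs_ch1_merged.csv"))
  write_locs(m2, file.path(config$out_dir, "locs_ch2_merged.csv"))
  log_stage(con, "merging", n_ch1 = nrow(m1), n_ch2 = nrow(m2),
            seconds = round(proc.time()[3] - t0, 2))

  # co-localization
  t0 <- proc.time()[3]
  params <- do.call(coloc_params, config$coloc)
  res <- classify_and_measure(rbind_locs(m1, m2), 1, 2, params)
  summary <- coloc_summary(res)
  jsonlite::write_json(summary, file.path(config$out_dir, "coloc_result.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(con, "colocalization", dB_nm = params$dB,
            Nc = res$Nc, Nnc = res$Nnc, pct_coloc = res$pct_coloc,
            seconds = round(proc.time()[3] - t0, 2))

  cat(sprintf(
    "run complete: %d + %d molecules, %.1f%% co-localizing, d = %.2f nm\n",
    res$Nc + res$Nnc, nrow(m2), res$pct_coloc, summary$d))
  invisible(config$out_dir)
}

rbind_locs <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out$id <- seq_len(nrow(out))
  as_loc_table(out, attr(a, "pixel_size"), attr(a, "dim_mode"))
}

coloc_summary <- function(res) {
  list(mean_ci = mean(res$molecules$ci), pct_coloc = res$pct_coloc,
       Nc = res$Nc, Nnc = res$Nnc, dc = res$dc, dnc = res$dnc,
       d = mean_pair_distance(res), dB_nm = res$params$dB)
}

#' Calibrate the chromatic registration from a paired bead scan
#'
#' Extracts paired control points from the two channels of a bead scan and
#' fits the LWM transform; in 3D the global axial focal shift is estimated
#' and removed before the 3D fit.
#'
#' @param beads_ch1,beads_ch2 bead scan [image_stack()]s.
#' @param calibration optional astigmatism calibration (enables 3D).
#' @param ... passed to [fit_lwm()] (e.g. `neighbors`).
#' @return a `registration` list: `transform`, `axial_shift` (nm; 0 in 2D),
#'   `fre` ([compute_fre()] report), `points`, and `transform_2d` (the
#'   lateral transform used for pixel-grid alignment).
#' @export
build_registration <- function(beads_ch1, beads_ch2, calibration = NULL,
                               ...) {
  pts <- extract_control_points(beads_ch1, beads_ch2,
                                calibration = calibration)
  shift <- 0
  if (cp_dim(pts) == 3) {
    shift <- estimate_axial_shift(pts)
    pts$z2 <- pts$z2 + shift
    pts2d <- control_point_set(cp_mat(pts, 1)[, 1:2], cp_mat(pts, 2)[, 1:2])
    transform_2d <- fit_lwm(pts2d, ...)
  }
  tr <- fit_lwm(pts, ...)
  if (cp_dim(pts) == 2) transform_2d <- tr
  structure(list(transform = tr, transform_2d = transform_2d,
                 axial_shift = shift, fre = compute_fre(pts, tr),
                 points = pts),
            class = "registration")
}

#' @rdname build_registration
#' @param registration a `registration`.
#' @param table a localization table from channel 2.
#' @export
apply_registration <- function(registration, table) {
  if (registration$transform$dim == 3 && nrow(table) > 0)
    table$z <- table$z + registration$axial_shift
  apply_transform(registration$transform, table)
}

#' Write the canonical test fixtures
#'
#' Generates the small canonical scenes used by the tests: simulated
#' acquisitions (movies, ground truth, expected-summary JSON), bead
#' calibration scans, or donor-only crosstalk frames.
#'
#' @param scenario `"positive"` (paired emitters, 10 +/- 5 nm),
#'   `"negative"` (identical configuration with pairing off), `"beads"`
#'   (600 nm-step scan stacks for 2D registration plus a z-stack for the
#'   astigmatism calibration), or `"crosstalk"` (donor-only frames).
#' @param seed integer seed.
#' @param dir output directory.
#' @param config optional [sim_config()] override (defaults to
#'   [fixture_config()]).
#' @return named list of the written file paths (invisibly returns the same).
#' @export
make_fixtures <- function(scenario = c("positive", "negative", "beads",
                                       "crosstalk"),
                          seed = 1L, dir = tempfile("fixtures"),
                          config = NULL) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- fixture_config(seed)
  paths <- list()
  if (scenario %in% c("positive", "negative")) {
    config$pair_mode <- if (scenario == "positive") "paired" else "random"
    config$seed <- seed
    sim <- simulate_movie(config)
    paths$ch1 <- file.path(dir, paste0(scenario, "_ch1.tiff"))
    paths$ch2 <- file.path(dir, paste0(scenario, "_ch2.tiff"))
    paths$truth <- file.path(dir, paste0(scenario, "_truth.csv"))
    paths$summary <- file.path(dir, paste0(scenario, "_expected.json"))
    write_image_stack(sim$movies$ch1, paths$ch1)
    write_image_stack(sim$movies$ch2, paths$ch2)
    write_ground_truth(sim$truth, paths$truth)
    jsonlite::write_json(
      list(scenario = scenario, seed = seed,
           n_molecules = nrow(sim$truth$molecules),
           n_ch1 = sum(sim$truth$molecules$channel == 1),
           n_ch2 = sum(sim$truth$molecules$channel == 2),
           n_appearances = nrow(sim$truth$appearances),
           density_per_um3 = config$density,
           pair_mode = config$pair_mode),
      paths$summary, auto_unbox = TRUE, digits = NA)
  } else if (scenario == "beads") {
    config$seed <- seed
    g2d <- max_grid_for_fov(600, config)
    beads <- generate_bead_stacks(g2d, config)
    paths$beads_ch1 <- file.path(dir, "beads_ch1.tiff")
    paths$beads_ch2 <- file.path(dir, "beads_ch2.tiff")
    paths$positions <- file.path(dir, "beads_positions.csv")
    write_image_stack(beads$ch1, paths$beads_ch1)
    write_image_stack(beads$ch2, paths$beads_ch2)
    write.csv(beads$positions, paths$positions, row.names = FALSE)
    zg <- list(nx = 1, ny = 1, nz = 21, step_xy = 600, step_z = 60)
    zstack <- generate_bead_stacks(zg, config)
    paths$astig_stack <- file.path(dir, "astig_beads.tiff")
    paths$astig_z <- file.path(dir, "astig_z.csv")
    write_image_stack(zstack$ch1, paths$astig_stack)
    write.csv(data.frame(frame = zstack$positions$frame,
                         z = zstack$positions$z),
              paths$astig_z, row.names = FALSE)
  } else {
    set.seed(seed)
    cell <- cell_model()
    donor <- make_donor_frames(config, cell)
    paths$donor_ch1 <- file.path(dir, "donor_ch1.tiff")
    paths$donor_ch2 <- file.path(dir, "donor_ch2.tiff")
    write_image_stack(donor$ch1, paths$donor_ch1)
    write_image_stack(donor$ch2, paths$donor_ch2)
  }
  invisible(paths)
}

#' Scaled-down simulation settings used by the fixtures
#'
#' Same physics as the full-scale defaults but a smaller field of view and
#' fewer frames so fixture generation stays fast.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
fixture_config <- function(seed = 1L) {
  sim_config(fov_px = c(48, 48), n_frames = 150,
             cell = cell_model(length = 1200, diameter = 600,
                               center = c(48 * 82 / 2, 48 * 82 / 2, 0)),
             seed = seed)
}

#' Analyze one simulated acquisition in memory
#'
#' The in-memory core of [run_pipeline()]: crosstalk-corrects channel 2,
#' localizes both channels, maps channel 2 into the channel-1 frame, merges
#' reappearing molecules, and runs the co-localization analysis.
#'
#' @param movies list with [image_stack()]s `ch1`, `ch2`.
#' @param crosstalk_map an [estimate_crosstalk()] map.
#' @param registration a [build_registration()] object.
#' @param calibration astigmatism calibration for 3D localization (`NULL`
#'   for 2D).
#' @param localize,merge,coloc per-stage parameter lists.
#' @return list with the merged tables (`ch1`, `ch2`), the `coloc_result`,
#'   and the scalar `summary` (mean CI, percent co-localizing, Nc, Nnc, dc,
#'   dnc, d).
#' @export
analyze_acquisition <- function(movies, crosstalk_map, registration,
                                calibration = NULL, localize = list(),
                                merge = list(), coloc = list()) {
  mode <- if (is.null(calibration)) "2d" else "astig"
  ch2c <- correct_frames(movies$ch2, movies$ch1, crosstalk_map)
  loc1 <- do.call(localize_stack,
                  c(list(movies$ch1, mode = mode, calibration = calibration),
                    localize))
  loc2 <- do.call(localize_stack,
                  c(list(ch2c, mode = mode, calibration = calibration),
                    localize))
  loc2 <- apply_registration(registration, loc2)
  m1 <- do.call(merge_reappearances, c(list(loc1), merge))
  m2 <- do.call(merge_reappearances, c(list(loc2), merge))
  params <- do.call(coloc_params, coloc)
  res <- classify_and_measure(rbind_locs(m1, m2), 1, 2, params)
  list(ch1 = m1, ch2 = m2, result = res, summary = coloc_summary(res))
}

#' Run a replicated co-localization simulation study
#'
#' Simulates `n_acq` acquisitions of one scenario (shared crosstalk and
#' registration calibrations, as one calibration sample precedes the
#' acquisitions of a session), runs the full analysis on each, and collects
#' the per-acquisition summaries used for group comparisons.
#'
#' @param n_acq number of acquisitions.
#' @param pair_mode `"paired"` (positive control) or `"random"` (negative
#'   control).
#' @param config base [sim_config()]; its `pair_mode` and `seed` are
#'   overridden.  The default compresses an acquisition into 500 frames with
#'   the photoactivation rate that maximizes the number of recovered
#'   molecules at that length (calibrated against simulation ground truth).
#' @param seed study seed; acquisition seeds are derived from it.
#' @param dB co-localization radius, nm.
#' @param localize,merge per-stage parameter lists.  The defaults were
#'   calibrated on ground-truth fixtures: a 5-sigma detection threshold and a
#'   500-photon floor (3 sigma below the emitter brightness) suppress camera-
#'   noise artifacts and bleed-through ghosts; the 20 nm `"palm"` merge
#'   radius is the customary choice for unexpanded PALM data.
#' @param progress print one line per acquisition.
#' @return data frame of per-acquisition summaries (`mean_ci`, `pct_coloc`,
#'   `Nc`, `Nnc`, `dc`, `dnc`, `d`), with the calibration objects in
#'   attributes `registration` and `crosstalk_map`.
#' @export
run_colocalization_study <- function(n_acq = 60, pair_mode = c("paired",
                                                               "random"),
                                     config = sim_config(
                                       n_frames = 500,
                                       activation_prob = 0.004),
                                     seed = 1L, dB = 50,
                                     localize = list(threshold = 5,
                                                     min_photons = 500),
                                     merge = list(radius = "palm"),
                                     progress = FALSE) {
  pair_mode <- match.arg(pair_mode)
  config$pair_mode <- pair_mode
  base_seed <- as.integer(seed)

  # one calibration session per study
  cal_cfg <- config
  cal_cfg$seed <- base_seed
  set.seed(base_seed)
  beads <- generate_bead_stacks(max_grid_for_fov(600, cal_cfg), cal_cfg)
  reg <- build_registration(beads$ch1, beads$ch2)
  donor <- make_donor_frames(cal_cfg)
  xmap <- estimate_crosstalk(donor$ch1, donor$ch2,
                             alignment = reg$transform_2d)

  rows <- vector("list", n_acq)
  for (i in seq_len(n_acq)) {
    acq_cfg <- config
    acq_cfg$seed <- base_seed + 1000L * i
    sim <- simulate_movie(acq_cfg)
    out <- analyze_acquisition(sim$movies, xmap, reg,
                               localize = localize, merge = merge,
                               coloc = list(dB = dB))
    rows[[i]] <- as.data.frame(c(list(acq = i, seed = acq_cfg$seed),
                                 out$summary))
    if (progress)
      cat(sprintf("acq %d/%d [%s]: %.1f%% coloc, d = %.2f nm\n",
                  i, n_acq, pair_mode, out$summary$pct_coloc,
                  out$summary$d))
  }
  res <- do.call(rbind, rows)
  attr(res, "registration") <- reg
  attr(res, "crosstalk_map") <- xmap
  attr(res, "pair_mode") <- pair_mode
  res
}

#' Command-line entry point
#'
#' Dispatches `expalm <command> --config run.yaml [--seed N] [--out DIR]`.
#' Commands: `run` (full pipeline), `fixtures --scenario S`, `simulate`,
#' `crosstalk`, `localize`, `register`, `merge`, `coloc` — each runs the
#' corresponding stage of [run_pipeline()] on the files named in the YAML
#' config.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
expalm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: expalm <run|fixtures|simulate|crosstalk|localize|register|merge|coloc>",
    "[--config run.yaml] [--scenario S] [--seed N] [--out DIR]")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  out <- opt$out %||% "expalm-out"
  get_cfg <- function() {
    if (is.null(opt$config)) stop("--config is required for this command")
    cfg <- read_pipeline_config(opt$config)
    if (!is.null(opt$seed)) cfg$seed <- seed
    if (!is.null(opt$out)) cfg$out_dir <- out
    cfg
  }
  switch(cmd,
    run = run_pipeline(get_cfg()),
    fixtures = make_fixtures(opt$scenario %||% "positive", seed = seed,
                             dir = out),
    simulate = {
      sim <- simulate_movie(sim_config(seed = seed))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_image_stack(sim$movies$ch1, file.path(out, "sim_ch1.tiff"))
      write_image_stack(sim$movies$ch2, file.path(out, "sim_ch2.tiff"))
      write_ground_truth(sim$truth, file.path(out, "sim_truth.csv"))
    },
    crosstalk = , localize = , register = , merge = , coloc = {
      cfg <- get_cfg()
      run_stage(cmd, cfg)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (grepl("^--", args[i]) && i < length(args)) {
      opt[[sub("^--", "", args[i])]] <- args[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  opt
}

# single-stage CLI commands: run the pipeline's stage on the config's files
run_stage <- function(stage, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  reg <- function() {
    build_registration(
      read_image_stack(cfg$beads$ch1, cfg$pixel_size),
      read_image_stack(cfg$beads$ch2, cfg$pixel_size, channel = 2))
  }
  switch(stage,
    crosstalk = {
      m <- estimate_crosstalk(
        read_image_stack(cfg$donor$ch1, cfg$pixel_size),
        read_image_stack(cfg$donor$ch2, cfg$pixel_size, channel = 2))
      write_crosstalk_map(m, file.path(cfg$out_dir, "crosstalk_map.tiff"),
                          file.path(cfg$out_dir, "crosstalk_map.json"))
    },
    localize = {
      for (ch in 1:2) {
        st <- read_image_stack(cfg$movies[[paste0("ch", ch)]],
                               cfg$pixel_size, channel = ch)
        loc <- do.call(localize_stack, c(list(st), cfg$localize))
        write_locs(loc, file.path(cfg$out_dir,
                                  sprintf("locs_ch%d.csv", ch)))
      }
    },
    register = {
      r <- reg()
      write_lwm(r$transform, file.path(cfg$out_dir, "registration.json"))
    },
    merge = {
      for (ch in 1:2) {
        loc <- read_locs(file.path(cfg$out_dir, sprintf("locs_ch%d.csv", ch)),
                         channel = ch)
        m <- do.call(merge_reappearances, c(list(loc), cfg$merge))
        write_locs(m, file.path(cfg$out_dir,
                                sprintf("locs_ch%d_merged.csv", ch)))
      }
    },
    coloc = {
      m1 <- read_locs(file.path(cfg$out_dir, "locs_ch1_merged.csv"), 1)
      m2 <- read_locs(file.path(cfg$out_dir, "locs_ch2_merged.csv"), 2)
      params <- do.call(coloc_params, cfg$coloc)
      res <- classify_and_measure(rbind_locs(m1, m2), 1, 2, params)
      jsonlite::write_json(coloc_summary(res),
                           file.path(cfg$out_dir, "coloc_result.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  invisible(cfg$out_dir)
}
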
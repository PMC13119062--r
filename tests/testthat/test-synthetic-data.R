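test_that("sim_config validates its invariants", {
  expect_error(sim_config(density = 0), "density")
  expect_error(sim_config(crosstalk = 1), "crosstalk")
  expect_error(sim_config(retention = c(0, 1)), "retention")
  expect_error(sim_config(activation_prob = 1.5), "probabilities")
  expect_error(sim_config(pixel_size = -1), "pixel size")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("sim_config YAML round trip preserves the configuration", {
  cfg <- sim_config(fov_px = c(48, 64), n_frames = 10, crosstalk = 0.07,
                    cell = cell_model(1500, 700, center = c(1, 2, 3)))
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$fov_px, cfg$fov_px)
  expect_equal(back$crosstalk, 0.07)
  expect_equal(back$cell$length, 1500)
  expect_error(write_sim_config(sim_config(crosstalk = function(x, y) 0.1),
                                path),
               "serialized")
})

test_that("cell model volume and membership are geometrically correct", {
  cell <- cell_model(length = 2000, diameter = 800, center = c(0, 0, 0))
  r <- 400
  # `length` is the straight (cylindrical) part; hemispherical caps of radius
  # r extend the total pole-to-pole length to length + diameter
  vol_nm3 <- pi * r^2 * 2000 + 4 / 3 * pi * r^3
  expect_equal(cell_volume_um3(cell), vol_nm3 / 1e9, tolerance = 1e-12)
  # on-axis points inside up to the cap pole at length/2 + r = 1400
  expect_true(point_in_cell(cell, cbind(1399, 0, 0)))
  expect_false(point_in_cell(cell, cbind(1401, 0, 0)))
  expect_true(point_in_cell(cell, cbind(0, 399, 0)))
  expect_false(point_in_cell(cell, cbind(0, 401, 0)))
  # just off the cylinder end, inside/outside of the hemispherical cap
  expect_true(point_in_cell(cell, cbind(1100, 380, 0)))
  expect_false(point_in_cell(cell, cbind(1100, 399, 0)))
  set.seed(1)
  p <- sample_in_cell(cell, 2000)
  expect_true(all(point_in_cell(cell, p)))
  expect_gt(max(abs(p[, 1])), 1000)  # the caps get sampled too
})

test_that("paired placement follows the truncated-normal distance law", {
  set.seed(2)
  # a cell much larger than the pair distance keeps boundary re-draws rare
  cell <- cell_model(length = 4000, diameter = 2000, center = c(0, 0, 0))
  cfg <- sim_config(density = 1300, pair_mode = "paired")
  tr <- place_molecules(cfg, cell)
  mol <- tr$molecules
  a <- mol[mol$channel == 1, ]
  b <- mol[match(a$partner_id, mol$id), ]
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  expect_gt(length(d), 5000)
  expect_true(all(d > 0))
  m <- mean_trunc0(10, 5)
  expect_lt(abs(mean(d) - m), 3 * sd(d) / sqrt(length(d)))
  ks <- suppressWarnings(ks.test(d, function(q) ptrunc0(q, 10, 5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("random placement splits channels independently", {
  set.seed(3)
  cfg <- sim_config(pair_mode = "random")
  tr <- place_molecules(cfg, cell_model(center = c(0, 0, 0)))
  expect_true(all(is.na(tr$molecules$partner_id)))
  n <- nrow(tr$molecules)
  n1 <- sum(tr$molecules$channel == 1)
  expect_lt(abs(n1 - n / 2), 4 * sqrt(n) / 2)
})

test_that("photophysics produces valid appearance windows", {
  set.seed(4)
  cfg <- sim_config(n_frames = 100, activation_efficiency = 1,
                    activation_prob = 0.05, on_survival = 0,
                    reappear_prob = 1, max_dark_gap = 5)
  tr <- place_molecules(cfg, cell_model(center = c(0, 0, 0)))
  tr <- simulate_photophysics(tr, cfg)
  app <- tr$appearances
  expect_true(all(app$frame_start >= 1 & app$frame_end <= 100))
  expect_true(all(app$frame_end >= app$frame_start))
  expect_true(all(app$frame_end == app$frame_start))  # on_survival = 0
  # reappearances stay within the dark-gap bound
  by_mol <- split(app, app$mol_id)
  two <- Filter(function(g) nrow(g) == 2, by_mol)
  expect_gt(length(two), 0)
  gaps <- vapply(two, function(g) g$frame_start[2] - g$frame_end[1] - 1L,
                 integer(1))
  expect_true(all(gaps >= 1 & gaps <= 5))
  # emitted photons floor and emission/appearance consistency
  expect_true(all(tr$emission$photons >= 50))
  tot <- rowsum(tr$emission$photons, tr$emission$mol_id)
  expect_equal(as.numeric(tot[match(unique(app$mol_id), rownames(tot))]),
               as.numeric(rowsum(app$photons, app$mol_id)))
})

test_that("activation efficiency controls the fraction that ever appears", {
  set.seed(5)
  cfg <- sim_config(n_frames = 2000, activation_efficiency = 0.5,
                    activation_prob = 0.05)
  tr <- place_molecules(cfg, cell_model(center = c(0, 0, 0)))
  tr <- simulate_photophysics(tr, cfg)
  frac <- length(unique(tr$appearances$mol_id)) / nrow(tr$molecules)
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("rendering is photon-linear without noise", {
  cfg <- sim_config(fov_px = c(48, 48), n_frames = 3, noise = "none",
                    background_photons = 0, crosstalk = 0.1,
                    aberration_ch2 = zero_aberration())
  ctr <- 48 * 82 / 2
  mol <- data.frame(id = 1:2, channel = c(1L, 2L),
                    x = ctr + c(-400, 400), y = ctr, z = 0,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1:2, frame_start = 1L, frame_end = 3L,
                    photons = c(800, 1200))
  truth <- manual_truth(mol, app, cfg)
  mov <- render_movies(truth, cfg)
  ph1 <- sum(mov$ch1$data - cfg$offset) / cfg$em_gain
  ph2 <- sum(mov$ch2$data - cfg$offset) / cfg$em_gain
  expect_equal(ph1, 3 * 800, tolerance = 1e-3)
  expect_equal(ph2, 3 * 1200 + 0.1 * 3 * 800, tolerance = 1e-3)
})

test_that("bleed-through deposits exactly the crosstalk fraction", {
  cfg <- sim_config(fov_px = c(48, 48), n_frames = 1, noise = "none",
                    background_photons = 0, crosstalk = 0.1,
                    aberration_ch2 = zero_aberration())
  ctr <- 48 * 82 / 2
  mol <- data.frame(id = 1L, channel = 1L, x = ctr, y = ctr, z = 0,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1L, frame_start = 1L, frame_end = 1L,
                    photons = 1000)
  mov <- render_movies(manual_truth(mol, app, cfg), cfg)
  s1 <- sum(mov$ch1$data - cfg$offset)
  s2 <- sum(mov$ch2$data - cfg$offset)
  expect_equal(s2 / s1, 0.1, tolerance = 1e-9)
})

test_that("EMCCD noise has the expected mean and excess variance", {
  set.seed(6)
  cfg <- sim_config(fov_px = c(96, 96), n_frames = 6)
  img <- array(cfg$background_photons, dim = c(96, 96, 6))
  counts <- expalm:::apply_camera(img, cfg)
  mu <- cfg$offset + cfg$em_gain * cfg$background_photons
  expect_lt(abs(mean(counts) - mu) / mu, 0.01)
  # EM multiplication doubles the Poisson variance (excess noise factor ~ 2)
  ratio <- var(as.numeric(counts)) /
    (cfg$em_gain^2 * cfg$background_photons)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("movies are reproducible from the seed", {
  cfg <- sim_config(fov_px = c(32, 32), n_frames = 5)
  cfg$seed <- 99L
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movies$ch1$data, b$movies$ch1$data)
  expect_identical(a$truth$molecules, b$truth$molecules)
  cfg$seed <- 100L
  c3 <- simulate_movie(cfg)
  expect_false(identical(a$movies$ch1$data, c3$movies$ch1$data))
})

test_that("expansion scales distances and dilutes density", {
  set.seed(7)
  cfg <- sim_config()
  tr <- place_molecules(cfg, cell_model(center = c(0, 0, 0)))
  d0 <- as.numeric(dist(tr$molecules[1:50, c("x", "y", "z")]))
  ex <- apply_expansion(tr, 4)
  d1 <- as.numeric(dist(ex$molecules[1:50, c("x", "y", "z")]))
  expect_equal(d1, 4 * d0, tolerance = 1e-12)
  expect_equal(scene_density(ex) / scene_density(tr), 4^-3,
               tolerance = 1e-12)
  expect_error(apply_expansion(tr, 0.5), "factor")
})

test_that("bead scans respect the field of view and the grid geometry", {
  cfg <- sim_config(fov_px = c(48, 48))
  expect_error(generate_bead_stacks(list(nx = 20, ny = 2, step_xy = 600), cfg),
               "field of view")
  out <- generate_bead_stacks(list(nx = 3, ny = 2, nz = 5, step_xy = 600,
                                   step_z = 100),
                              cfg, render = FALSE)
  expect_equal(nrow(out$positions), 3 * 2 * 5)
  expect_equal(sort(unique(out$positions$z)), c(-200, -100, 0, 100, 200))
  expect_null(out$ch1)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  set.seed(8)
  st <- image_stack(array(runif(32 * 32 * 3, 0, 7e4), dim = c(32, 32, 3)),
                    pixel_size = 82, channel = 2L)
  path <- tempfile(fileext = ".tiff")
  write_image_stack(st, path)
  back <- read_image_stack(path, pixel_size = 82, channel = 2L)
  expect_equal(dim(back$data), dim(st$data))
  clipped <- pmin(pmax(st$data, 0), 65535)
  expect_lt(max(abs(back$data - clipped)), 1)
})

test_that("ground truth CSV carries positions and appearance summaries", {
  set.seed(9)
  cfg <- sim_config(fov_px = c(32, 32), n_frames = 50,
                    activation_prob = 0.05)
  sim <- simulate_movie(cfg)
  path <- tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, path)
  gt <- read.csv(path)
  expect_equal(nrow(gt), nrow(sim$truth$molecules))
  expect_true(all(c("x_nm", "y_nm", "z_nm", "channel", "frame_start",
                    "photons") %in% names(gt)))
})
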
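test_that("detect_spots finds isolated emitters at their pixels", {
  cfg <- sim_config(fov_px = c(48, 48), n_frames = 1, noise = "none",
                    crosstalk = 0, aberration_ch2 = zero_aberration())
  xs <- c(1000, 2800); ys <- c(1200, 3000)
  mol <- data.frame(id = 1:2, channel = 1L, x = xs, y = ys, z = 0,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1:2, frame_start = 1L, frame_end = 1L,
                    photons = 1000)
  mov <- render_movies(manual_truth(mol, app, cfg), cfg)
  cand <- detect_spots(mov$ch1)
  expect_equal(nrow(cand), 2)
  cand <- cand[order(cand$col), ]
  expect_equal((cand$col - 0.5) * 82, xs, tolerance = 82)
  expect_equal((cand$row - 0.5) * 82, ys, tolerance = 82)
  expect_error(detect_spots(image_stack(array(0, c(0, 0, 0)), 82)), "empty")
})

test_that("noiseless fits recover position and photons almost exactly", {
  cfg <- sim_config(fov_px = c(32, 32), n_frames = 1, noise = "none",
                    crosstalk = 0, aberration_ch2 = zero_aberration())
  x0 <- 15.3 * 82; y0 <- 16.7 * 82
  mol <- data.frame(id = 1L, channel = 1L, x = x0, y = y0, z = 0,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1L, frame_start = 1L, frame_end = 1L,
                    photons = 2000)
  mov <- render_movies(manual_truth(mol, app, cfg), cfg)
  loc <- localize_stack(mov$ch1)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x - x0), 1e-6)
  expect_lt(abs(loc$y - y0), 1e-6)
  expect_equal(loc$photons, 2000, tolerance = 1e-2)
  expect_equal(loc$sigma_x, 150, tolerance = 1e-3)
  expect_true(is.na(loc$z))
  expect_equal(loc$merged_from, 1L)
})

test_that("the Thompson uncertainty formula matches its closed form", {
  expect_equal(thompson_uncertainty(150, 82, 1000, 1), 4.995255506,
               tolerance = 1e-8)
  # photon scaling in the shot-noise limit
  expect_equal(thompson_uncertainty(150, 82, 4000, 0),
               thompson_uncertainty(150, 82, 1000, 0) / 2,
               tolerance = 1e-12)
})

test_that("photon and width filters reject dim spots and blends", {
  cfg <- sim_config(fov_px = c(48, 48), n_frames = 1, noise = "none",
                    crosstalk = 0, aberration_ch2 = zero_aberration())
  mol <- data.frame(id = 1:2, channel = 1L, x = c(1000, 2800),
                    y = c(1200, 3000), z = 0, partner_id = NA_integer_)
  app <- data.frame(mol_id = 1:2, frame_start = 1L, frame_end = 1L,
                    photons = c(200, 2000))
  mov <- render_movies(manual_truth(mol, app, cfg), cfg)
  expect_equal(nrow(localize_stack(mov$ch1, min_photons = 100)), 2)
  loc <- localize_stack(mov$ch1, min_photons = 500)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$photons, 2000, tolerance = 1e-2)
  # width gate: the 150 nm PSF passes c(100, 250) and fails c(100, 140)
  expect_equal(nrow(localize_stack(mov$ch1, min_photons = 100,
                                   sigma_range = c(100, 250))), 2)
  expect_equal(nrow(localize_stack(mov$ch1, min_photons = 100,
                                   sigma_range = c(100, 140))), 0)
})

test_that("pre-computed candidates are honored", {
  cfg <- sim_config(fov_px = c(32, 32), n_frames = 1, noise = "none",
                    crosstalk = 0, aberration_ch2 = zero_aberration())
  mol <- data.frame(id = 1L, channel = 1L, x = 1300, y = 1300, z = 0,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1L, frame_start = 1L, frame_end = 1L,
                    photons = 2000)
  mov <- render_movies(manual_truth(mol, app, cfg), cfg)
  cand <- detect_spots(mov$ch1)
  loc <- localize_stack(mov$ch1, candidates = cand)
  expect_equal(loc, localize_stack(mov$ch1))
  none <- localize_stack(mov$ch1, candidates = cand[0, ])
  expect_equal(nrow(none), 0)
})

test_that("astigmatism calibration recovers the generator's defocus curves", {
  cal <- cached("astig_calibration", {
    cfg <- sim_config(fov_px = c(32, 32), noise = "none")
    zstack <- generate_bead_stacks(list(nx = 1, ny = 1, nz = 21,
                                        step_xy = 600, step_z = 60), cfg)
    calibrate_astigmatism(zstack$ch1,
                          sort(unique(zstack$positions$z)))
  })
  expect_lt(abs(cal$crossing), 5)
  expect_equal(unname(cal$par_x[["s0"]]), 150, tolerance = 0.01)
  expect_equal(unname(cal$par_x[["c"]]), 400, tolerance = 0.01)
  expect_equal(unname(cal$par_x[["d"]]), 400, tolerance = 0.01)
  expect_equal(unname(cal$par_y[["c"]]), -400, tolerance = 0.01)

  # a one-sided z range has no focal crossing
  cfg <- sim_config(fov_px = c(32, 32), noise = "none")
  zstack <- generate_bead_stacks(list(nx = 1, ny = 1, nz = 21,
                                      step_xy = 600, step_z = 60), cfg)
  zs <- sort(unique(zstack$positions$z))
  upper <- zs > 80
  sub <- image_stack(zstack$ch1$data[, , which(zstack$positions$z > 80),
                                     drop = FALSE],
                     pixel_size = zstack$ch1$pixel_size)
  expect_error(calibrate_astigmatism(sub, zs[upper]), "no focal plane")
})

test_that("astigmatic localization recovers the axial position", {
  cal <- cached("astig_calibration", stop("populated by the previous test"))
  cfg <- sim_config(fov_px = c(32, 32), n_frames = 1, noise = "none",
                    crosstalk = 0, aberration_ch2 = zero_aberration())
  mol <- data.frame(id = 1L, channel = 1L, x = 16 * 82, y = 16 * 82, z = 300,
                    partner_id = NA_integer_)
  app <- data.frame(mol_id = 1L, frame_start = 1L, frame_end = 1L,
                    photons = 5000)
  mov <- render_movies(manual_truth(mol, app, cfg), cfg, mode = "3d")
  loc <- localize_stack(mov$ch1, mode = "astig", calibration = cal,
                        fit_window = 7)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$z - 300), 1)
  expect_error(localize_stack(mov$ch1, mode = "astig"), "calibration")
})

test_that("lookup_z flags widths far from the calibration curves", {
  cal <- cached("astig_calibration", stop("populated earlier"))
  good <- expalm:::astig_sigma(200, 150, 400, 400)
  res <- lookup_z(cal, good[, "sx"], good[, "sy"])
  expect_true(res$ok)
  expect_lt(abs(res$z - 200), 2)
  bad <- lookup_z(cal, 800, 900)
  expect_false(bad$ok)
})
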
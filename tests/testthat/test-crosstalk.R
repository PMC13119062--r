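test_that("the crosstalk factor is recovered exactly on clean frames", {
  mk <- function(v) image_stack(array(v, dim = c(6, 6, 3)), pixel_size = 82)
  map <- estimate_crosstalk(mk(200), mk(16), background = c(0, 0))
  expect_equal(as.numeric(map$cf), rep(0.08, 36), tolerance = 1e-12)
  expect_equal(unname(map$fill), 0.08, tolerance = 1e-12)
  expect_s3_class(map, "crosstalk_map")
})

test_that("pixels without donor signal are masked and filled on application", {
  H <- 8; W <- 8
  d1 <- array(0, dim = c(H, W, 2))
  d1[, 1:4, ] <- 500                      # donor light in the left half only
  d2 <- 0.1 * d1
  map <- estimate_crosstalk(image_stack(d1, 82), image_stack(d2, 82),
                            background = c(0, 0))
  expect_true(all(is.na(map$cf[, 5:8])))
  expect_equal(as.numeric(map$cf[, 1:4]), rep(0.1, H * 4), tolerance = 1e-12)
  # the masked half is corrected with the fill value
  m2 <- array(50, dim = c(H, W, 1))
  m1 <- array(100, dim = c(H, W, 1))
  corr <- correct_frames(image_stack(m2, 82), image_stack(m1, 82), map)
  expect_equal(as.numeric(corr$data), rep(40, H * W), tolerance = 1e-9)
  # no donor anywhere is an error
  expect_error(estimate_crosstalk(image_stack(array(0, dim = c(4, 4, 1)), 82),
                                  image_stack(array(0, dim = c(4, 4, 1)), 82),
                                  background = c(0, 0)),
               "no donor signal")
})

test_that("a spatially varying crosstalk factor is mapped per pixel", {
  H <- 10; W <- 20
  cf_col <- 0.05 + 0.1 * (seq_len(W) - 1) / (W - 1)
  S <- 400
  d1 <- array(10 + S, dim = c(H, W, 2))
  d2 <- array(rep(rep(5 + cf_col * S, each = H), 2), dim = c(H, W, 2))
  map <- estimate_crosstalk(image_stack(d1, 82), image_stack(d2, 82),
                            background = c(10, 5))
  expect_equal(map$cf, matrix(rep(cf_col, each = H), H, W),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the pooled estimator is robust to camera noise on donor frames", {
  cfg <- sim_config(fov_px = c(64, 64), aberration_ch2 = zero_aberration())
  set.seed(21)
  donor <- make_donor_frames(cfg)
  map <- estimate_crosstalk(donor$ch1, donor$ch2)
  expect_lt(abs(map$fill - 0.10), 0.025)
  expect_gt(mean(!is.na(map$cf)), 0.2)  # the cell region gets calibrated
})

test_that("correction is gated by donor presence and floored at zero", {
  H <- 4; W <- 4
  map <- estimate_crosstalk(image_stack(array(100, dim = c(H, W, 1)), 82),
                            image_stack(array(50, dim = c(H, W, 1)), 82),
                            background = c(0, 0))
  # CF = 0.5; a frame whose donor is at (or below) background is untouched
  m1 <- array(0, dim = c(H, W, 1))
  m2 <- array(30, dim = c(H, W, 1))
  corr <- correct_frames(image_stack(m2, 82), image_stack(m1, 82), map)
  expect_equal(as.numeric(corr$data), rep(30, H * W))
  # over-subtraction is floored at 0
  m1[] <- 200
  corr <- correct_frames(image_stack(m2, 82), image_stack(m1, 82), map)
  expect_equal(as.numeric(corr$data), rep(0, H * W))
})

test_that("shape mismatches are rejected", {
  a <- image_stack(array(1, dim = c(4, 4, 2)), 82)
  b <- image_stack(array(1, dim = c(4, 5, 2)), 82)
  expect_error(estimate_crosstalk(a, b), "mismatched")
  map <- estimate_crosstalk(a, a, background = c(0, 0))
  expect_error(correct_frames(b, b, map), "shape")
  expect_error(correct_frames(a, b, map), "mismatched")
})

test_that("crosstalk maps serialize to TIFF + JSON and read back", {
  H <- 8; W <- 8
  d1 <- array(0, dim = c(H, W, 2))
  d1[, 1:4, ] <- 500
  d2 <- 0.1 * d1
  map <- estimate_crosstalk(image_stack(d1, 82), image_stack(d2, 82),
                            background = c(0, 0))
  tp <- tempfile(fileext = ".tiff")
  jp <- tempfile(fileext = ".json")
  write_crosstalk_map(map, tp, jp)
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(meta$fill, 0.1, tolerance = 1e-6)
  expect_equal(meta$background, c(0, 0))
  expect_equal(meta$masked_value, -1)
  back <- read_crosstalk_map(tp, jp)
  expect_equal(back$cf[, 1:4], map$cf[, 1:4], tolerance = 1e-6)
  expect_true(all(is.na(back$cf[, 5:8])))
  expect_equal(back$fill, map$fill, tolerance = 1e-9)
  # the deserialized map corrects frames like the original
  m2 <- image_stack(array(50, dim = c(H, W, 1)), 82)
  m1 <- image_stack(array(100, dim = c(H, W, 1)), 82)
  expect_equal(correct_frames(m2, m1, back)$data,
               correct_frames(m2, m1, map)$data, tolerance = 1e-6)
})

test_that("channel alignment is honored when estimating and applying", {
  # donor frames rendered with the default chromatic aberration: an aligned
  # map recovers ~0.10 while ignoring the (multi-pixel) misalignment biases
  # the per-pixel ratio
  cfg <- sim_config(fov_px = c(64, 64))
  set.seed(22)
  grid <- expalm:::max_grid_for_fov(600, cfg)
  beads <- generate_bead_stacks(grid, cfg)
  reg <- expalm:::build_registration(beads$ch1, beads$ch2)
  donor <- make_donor_frames(cfg)
  aligned <- estimate_crosstalk(donor$ch1, donor$ch2,
                                alignment = reg$transform_2d)
  naive <- estimate_crosstalk(donor$ch1, donor$ch2)
  expect_lt(abs(aligned$fill - 0.10), 0.03)
  expect_lt(abs(aligned$fill - 0.10), abs(naive$fill - 0.10))
})
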
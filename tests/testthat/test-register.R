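quadratic_warp <- function(P2, L = 10000) {
  u <- P2[, 1] / L
  v <- P2[, 2] / L
  P2 + cbind(120 - 180 * u + 60 * v + 90 * u^2 - 40 * u * v + 30 * v^2,
             -90 + 70 * u - 150 * v - 50 * u^2 + 80 * u * v + 60 * v^2)
}

test_that("control point sets validate their shape", {
  p <- matrix(runif(12), 6, 2)
  expect_s3_class(control_point_set(p, p), "control_points")
  expect_error(control_point_set(p[1:5, ], p[1:5, ]), "too few")
  expect_error(control_point_set(p, p[1:5, ]), "one-to-one")
  q <- matrix(runif(27), 9, 3)
  expect_error(control_point_set(q, q), "too few")
  expect_error(control_point_set(p[, 1, drop = FALSE],
                                 p[, 1, drop = FALSE]), "2D or 3D")
})

test_that("LWM recovers an exact polynomial warp in 2D and 3D", {
  set.seed(51)
  P2 <- cbind(runif(300, 0, 10000), runif(300, 0, 10000))
  pts <- control_point_set(quadratic_warp(P2), P2)
  tr <- fit_lwm(pts)
  expect_lt(compute_fre(pts, tr)$total, 1e-6)
  # prediction is exact away from the control points too
  Q <- cbind(runif(50, 500, 9500), runif(50, 500, 9500))
  expect_lt(max(abs(predict(tr, Q) - quadratic_warp(Q))), 1e-6)

  # 3D: a quadratic warp of all three coordinates
  P2 <- cbind(runif(300, 0, 10000), runif(300, 0, 10000),
              runif(300, -600, 600))
  w <- 5 + 0.002 * P2[, 1] + 1e-8 * P2[, 3]^2
  P1 <- P2 + cbind(w, -w / 2, 10 + 1e-8 * P2[, 1]^2)
  pts3 <- control_point_set(P1, P2)
  expect_lt(compute_fre(pts3, fit_lwm(pts3))$total, 1e-6)
})

test_that("a 3D fit of coplanar points reproduces the 2D lateral fit", {
  set.seed(52)
  P2 <- cbind(runif(120, 0, 10000), runif(120, 0, 10000))
  P1 <- quadratic_warp(P2)
  tr2 <- fit_lwm(control_point_set(P1, P2))
  tr3 <- fit_lwm(control_point_set(cbind(P1, 0), cbind(P2, 0)))
  Q <- cbind(runif(40, 500, 9500), runif(40, 500, 9500))
  m2 <- predict(tr2, Q)
  m3 <- predict(tr3, cbind(Q, 0))
  expect_lt(max(abs(m3[, 1:2] - m2)), 1e-6)
})

test_that("extrapolation falls back to the nearest polynomial with a warning", {
  set.seed(53)
  P2 <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  pts <- control_point_set(P2 + 10, P2)
  tr <- fit_lwm(pts)
  expect_warning(m <- predict(tr, cbind(50000, 50000)), "outside")
  expect_true(attr(m, "extrapolated"))
  inside <- suppressWarnings(predict(tr, cbind(1000, 1000)))
  expect_equal(as.numeric(inside), c(1010, 1010), tolerance = 1e-6)
})

test_that("apply_transform maps tables and rejects dimension mismatches", {
  set.seed(54)
  P2 <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  tr <- fit_lwm(control_point_set(P2 + 10, P2))
  tab <- loc_df(x = c(500, 900), y = c(700, 1500))
  out <- apply_transform(tr, tab)
  expect_equal(out$x, tab$x + 10, tolerance = 1e-6)
  expect_equal(out$y, tab$y + 10, tolerance = 1e-6)
  tab3 <- loc_df(x = 500, y = 700, z = 100)
  expect_error(apply_transform(tr, tab3), "2D transform")
  P23 <- cbind(P2, runif(50, -500, 500))
  tr3 <- fit_lwm(control_point_set(P23, P23))
  expect_error(apply_transform(tr3, tab), "3D transform")
})

test_that("control points extracted from noisy bead scans register the channels", {
  fx <- bead_fixture()
  pts <- extract_control_points(fx$beads$ch1, fx$beads$ch2)
  expect_equal(nrow(pts) + attr(pts, "n_outliers"),
               fx$grid$nx * fx$grid$ny - attr(pts, "n_skipped"))
  expect_gte(nrow(pts), 30)
  tr <- fit_lwm(pts)
  fre <- compute_fre(pts, tr)
  expect_lt(fre$total, 5)
  # the fitted map moves true channel-2 positions onto channel 1
  true2 <- as.matrix(fx$beads$positions[, c("x2", "y2")])
  true1 <- as.matrix(fx$beads$positions[, c("x", "y")])
  mapped <- suppressWarnings(predict(tr, true2))
  offs <- sqrt(rowSums((mapped - true1)^2))
  expect_lt(mean(offs), 5)
})

test_that("the blended map is continuous across radii of influence", {
  fx <- bead_fixture()
  pts <- extract_control_points(fx$beads$ch1, fx$beads$ch2)
  tr <- fit_lwm(pts)
  # walk a line through the field; successive mapped points stay close
  t <- seq(0, 1, length.out = 400)
  Q <- cbind(1200 + t * 2800, 1100 + t * 2900)
  m <- suppressWarnings(predict(tr, Q))
  step_in <- sqrt(rowSums(diff(Q)^2))
  step_out <- sqrt(rowSums(diff(m)^2))
  expect_lt(max(abs(step_out - step_in)), 1)
})

test_that("FRE supports a leave-one-out variant", {
  set.seed(55)
  P2 <- cbind(runif(60, 0, 6000), runif(60, 0, 6000))
  P1 <- quadratic_warp(P2) + matrix(rnorm(120, 0, 2), 60, 2)
  pts <- control_point_set(P1, P2)
  tr <- fit_lwm(pts)
  fre_in <- compute_fre(pts, tr)
  fre_cv <- compute_fre(pts, tr, leave_one_out = TRUE)
  expect_gt(fre_cv$total, fre_in$total)  # in-sample FRE is optimistic
  expect_lt(fre_cv$total, 20)
  expect_error(compute_fre(pts[0, ], tr), "empty")
})

test_that("step-size selection prefers low median FRE, then low spread", {
  sel <- select_step_size(c(600, 900),
                          fre_values = list(c(2.0, 2.1, 1.9),
                                            c(2.5, 2.6, 2.4)))
  expect_equal(sel$chosen, 600)
  tie <- select_step_size(c(600, 900),
                          fre_values = list(c(2.0, 2.2, 1.8),
                                            c(2.0, 2.0, 2.0)))
  expect_equal(tie$chosen, 900)
  expect_warning(select_step_size(c(600, 900),
                                  fre_values = list(2, 3)),
                 "single replicate")
  expect_error(select_step_size(600, fre_values = list(c(1, 2))),
               "at least 2")
})

test_that("axial shift estimation requires and uses 3D points", {
  set.seed(56)
  P2 <- cbind(runif(20, 0, 5000), runif(20, 0, 5000), runif(20, -500, 500))
  P1 <- P2
  P1[, 3] <- P1[, 3] + 9.8
  pts <- control_point_set(P1, P2)
  expect_equal(estimate_axial_shift(pts), 9.8, tolerance = 1e-9)
  pts2 <- control_point_set(P1[, 1:2], P2[, 1:2])
  expect_error(estimate_axial_shift(pts2), "3D")
})

test_that("LWM transforms serialize losslessly to JSON", {
  set.seed(57)
  P2 <- cbind(runif(60, 0, 6000), runif(60, 0, 6000))
  pts <- control_point_set(quadratic_warp(P2), P2)
  tr <- fit_lwm(pts)
  path <- tempfile(fileext = ".json")
  write_lwm(tr, path)
  back <- read_lwm(path)
  Q <- cbind(runif(30, 500, 5500), runif(30, 500, 5500))
  expect_equal(suppressWarnings(predict(back, Q)),
               suppressWarnings(predict(tr, Q)), tolerance = 1e-9)
})
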
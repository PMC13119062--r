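test_that("coloc_params validates its arguments", {
  expect_equal(coloc_params()$dB, 50)
  expect_error(coloc_params(dB = 0), "positive")
  expect_error(coloc_params(dB = c(1, 2)), "positive")
  expect_error(coloc_params(reference = "nope"))
})

test_that("a five-point scene matches the brute-force analysis", {
  tab <- expalm:::rbind_locs(
    loc_df(x = c(0, 200, 500), y = c(0, 0, 500), channel = 1L),
    loc_df(x = c(30, 60), y = c(0, 0), channel = 2L))
  params <- coloc_params(dB = 50)
  res <- suppressWarnings(classify_and_measure(tab, 1, 2, params))
  A <- res$molecules

  # brute force: B neighbors of each A within 50 nm
  expect_equal(A$n_within, c(1L, 0L, 0L))
  # self reference: B-B neighbors within 50 (they are 30 nm apart) -> 1 each
  expect_equal(A$ci, c(1, 0, 0))
  expect_equal(A$colocalizing, c(TRUE, FALSE, FALSE))
  d3 <- sqrt((500 - 60)^2 + 500^2)
  expect_equal(A$nn_dist, c(30, 140, d3), tolerance = 1e-9)
  expect_equal(res$Nc, 1)
  expect_equal(res$Nnc, 2)
  expect_equal(res$dc, 30)
  expect_equal(res$dnc, (140 + d3) / 2, tolerance = 1e-9)
  expect_equal(res$pct_coloc, 100 / 3, tolerance = 1e-9)
  expect_equal(mean_pair_distance(res), (30 + 140 + d3) / 3, tolerance = 1e-9)

  # the B side is annotated too: A neighbors of B1 = 1 (A1 at 30 nm), of
  # B2 = 0; the A-A reference density is zero, so counts are reported
  expect_equal(res$molecules_b$n_within, c(1L, 0L))
  expect_equal(res$molecules_b$ci, c(1, 0))
})

test_that("the uniform reference normalizes by the partner density", {
  set.seed(61)
  n <- 5000
  L <- 5000
  tab <- expalm:::rbind_locs(
    loc_df(runif(n, 0, L), runif(n, 0, L), channel = 1L),
    loc_df(runif(n, 0, L), runif(n, 0, L), channel = 2L))
  A <- compute_ci(tab, 1, 2, coloc_params(dB = 50, reference = "uniform"))
  expect_lt(abs(mean(A$ci) - 1), 0.1)
})

test_that("degenerate inputs are reported", {
  tab <- expalm:::rbind_locs(loc_df(0, 0, channel = 1L),
                             loc_df(10, 0, channel = 2L))
  expect_warning(compute_ci(tab, 1, 2, coloc_params(dB = 50)), "extent")
  only1 <- loc_df(c(0, 10), c(0, 0), channel = 1L)
  expect_error(compute_ci(only1, 1, 2), "channel B")
  expect_error(compute_ci(only1, 2, 1), "channel A")
})

test_that("edge molecules are flagged but kept", {
  tab <- expalm:::rbind_locs(
    loc_df(x = c(10, 500), y = c(500, 500), channel = 1L),
    loc_df(x = c(20, 510, 1000, 200), y = c(500, 505, 1000, 100),
           channel = 2L))
  res <- suppressWarnings(classify_and_measure(tab, 1, 2,
                                               coloc_params(dB = 50)))
  expect_equal(res$molecules$edge, c(TRUE, FALSE))
  expect_equal(res$Nc + res$Nnc, 2)
})

test_that("mean_pair_distance handles one-sided populations", {
  expect_equal(mean_pair_distance(2, 5, 3, 10), 8)
  expect_equal(mean_pair_distance(0, NA_real_, 3, 10), 10)
  expect_equal(mean_pair_distance(4, 7, 0, NA_real_), 7)
  expect_error(mean_pair_distance(0, NA_real_, 0, NA_real_), "no molecules")
})

test_that("expansion factor estimation and rescaling are consistent", {
  est <- estimate_expansion_factor(pre = c(10, 20, 30), post = c(40, 80, 120))
  expect_equal(est$factor, 4, tolerance = 1e-12)
  expect_equal(est$n, 3)
  f <- 4
  expect_equal(est$sd, f * sqrt((sd(c(10, 20, 30)) / 20)^2 +
                                  (sd(c(40, 80, 120)) / 80)^2),
               tolerance = 1e-12)
  expect_error(estimate_expansion_factor(1:3, 1:2), "one-to-one")
  expect_error(estimate_expansion_factor(c(0, 1), c(1, 2)), "positive")
  expect_equal(rescale_to_biological(c(40, 80), 4), c(10, 20))
  expect_error(rescale_to_biological(1, 0), "positive")
})

test_that("group comparison reproduces a hand-checked Welch test", {
  g1 <- c(1, 2, 3, 4)
  g2 <- c(3, 5, 7, 9)
  cmp <- compare_groups(g1, g2)
  ref <- t.test(g1, g2)
  expect_equal(cmp$mean1, 2.5)
  expect_equal(cmp$mean2, 6)
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  expect_false(cmp$degenerate)

  deg <- compare_groups(c(2, 2), c(3, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("nearest-neighbor search matches brute force", {
  set.seed(62)
  A <- cbind(runif(200, 0, 5000), runif(200, 0, 5000))
  B <- cbind(runif(300, 0, 5000), runif(300, 0, 5000))
  nn <- expalm:::cpp_nn(A, B, 50)
  for (i in sample(200, 25)) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)
    expect_equal(nn$index[i], which.min(d))
    expect_equal(nn$dist[i], min(d), tolerance = 1e-9)
  }
  cnt <- expalm:::cpp_count_within(A, B, 100, FALSE)
  for (i in sample(200, 25)) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)
    expect_equal(cnt[i], sum(d <= 100))
  }
})
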
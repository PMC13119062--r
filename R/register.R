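#' Paired control points for chromatic registration
#'
#' @param p1,p2 matrices of corresponding positions (nm) observed in channel
#'   1 and channel 2; 2 columns (x, y) or 3 (x, y, z).  Pairs are row-wise.
#' @param source optional provenance (scan metadata).
#' @return a `control_points` data frame with columns `x1, y1[, z1],
#'   x2, y2[, z2]`.
#' @export
control_point_set <- function(p1, p2, source = NULL) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  if (!identical(dim(p1), dim(p2)))
    stop("control point sets must pair one-to-one")
  d <- ncol(p1)
  if (!d %in% 2:3) stop("control points must be 2D or 3D")
  if (nrow(p1) < if (d == 2) 6 else 10)
    stop("too few control points for local polynomial fits")
  df <- data.frame(p1, p2)
  names(df) <- c(paste0(c("x", "y", "z")[1:d], 1),
                 paste0(c("x", "y", "z")[1:d], 2))
  attr(df, "source") <- source
  class(df) <- c("control_points", "data.frame")
  df
}

cp_dim <- function(points) if ("z1" %in% names(points)) 3L else 2L

cp_mat <- function(points, which) {
  d <- cp_dim(points)
  as.matrix(points[paste0(c("x", "y", "z")[1:d], which)])
}

#' Extract control points from a bead calibration scan
#'
#' Localizes the calibration bead in both channels of every scan frame,
#' pairs the localizations by frame, and rejects outlier pairs whose residual
#' after a provisional global affine fit exceeds 5x the median residual.
#'
#' @param bead_ch1,bead_ch2 bead scan [image_stack()]s
#'   ([generate_bead_stacks()]).
#' @param calibration optional [calibrate_astigmatism()] result; when given,
#'   beads are fitted astigmatically and control points carry z.
#' @param threshold detection threshold (beads are bright; keep it high).
#' @param ... further arguments to [localize_stack()].
#' @return a [control_point_set()]; attributes `n_skipped` (frames without a
#'   bead in one channel) and `n_outliers` report the dropped positions.
#' @export
extract_control_points <- function(bead_ch1, bead_ch2, calibration = NULL,
                                   threshold = 8, ...) {
  mode <- if (is.null(calibration)) "2d" else "astig"
  loc1 <- brightest_per_frame(localize_stack(bead_ch1, mode = mode,
                                             calibration = calibration,
                                             threshold = threshold, ...))
  loc2 <- brightest_per_frame(localize_stack(bead_ch2, mode = mode,
                                             calibration = calibration,
                                             threshold = threshold, ...))
  frames <- intersect(loc1$frame, loc2$frame)
  n_skipped <- dim(bead_ch1$data)[3] - length(frames)
  if (n_skipped > 0)
    warning(sprintf("%d scan positions skipped (bead missing in a channel)",
                    n_skipped))
  i1 <- match(frames, loc1$frame); i2 <- match(frames, loc2$frame)
  d <- if (mode == "astig") 3 else 2
  cols <- c("x", "y", "z")[1:d]
  p1 <- as.matrix(loc1[i1, cols, drop = FALSE])
  p2 <- as.matrix(loc2[i2, cols, drop = FALSE])

  # provisional global affine for outlier rejection
  fitres <- p1
  for (k in seq_len(d)) fitres[, k] <- lm.fit(cbind(1, p2), p1[, k])$residuals
  rn <- sqrt(rowSums(fitres^2))
  keep <- rn <= 5 * median(rn) | rn < 1e-9
  pts <- control_point_set(p1[keep, , drop = FALSE], p2[keep, , drop = FALSE])
  attr(pts, "n_skipped") <- n_skipped
  attr(pts, "n_outliers") <- sum(!keep)
  pts
}

brightest_per_frame <- function(locs) {
  if (nrow(locs) == 0) return(locs)
  keep <- unlist(lapply(split(seq_len(nrow(locs)), locs$frame),
                        function(i) i[which.max(locs$photons[i])]))
  locs[keep, , drop = FALSE]
}

# polynomial basis of total order <= 2 on centred/scaled coordinates
poly_basis <- function(U) {
  if (ncol(U) == 2) {
    cbind(1, U[, 1], U[, 2], U[, 1]^2, U[, 1] * U[, 2], U[, 2]^2)
  } else {
    cbind(1, U[, 1], U[, 2], U[, 3],
          U[, 1]^2, U[, 2]^2, U[, 3]^2,
          U[, 1] * U[, 2], U[, 1] * U[, 3], U[, 2] * U[, 3])
  }
}

#' Fit a local-weighted-mean (LWM) transform between two channels
#'
#' For every control point a second-order polynomial mapping (one per output
#' coordinate) is least-squares fitted on the point and its nearest
#' neighbors; the distance to the farthest neighbor used defines the point's
#' radius of influence.  Evaluating the transform anywhere blends the local
#' polynomials whose radii cover the query with weights
#' `w(R) = 1 - 3R^2 + 2R^3` (R = distance/radius), which fall smoothly to
#' zero at the radius so each polynomial only acts within its radius of
#' influence and the global mapping is continuous.  The transform maps
#' channel-2 coordinates into the channel-1 frame.
#'
#' @param points a [control_point_set()].
#' @param neighbors neighbors per local fit; defaults to 8 in 2D and 16 in 3D
#'   (a trivariate quadratic needs at least 10 points).
#' @param order local polynomial order (only 2 is implemented — the classic
#'   local-weighted-mean choice).
#' @return an `lwm_transform`; use [predict.lwm_transform()] or
#'   [apply_transform()] to map coordinates.
#' @export
fit_lwm <- function(points, neighbors = NULL, order = 2) {
  if (order != 2) stop("only second-order local polynomials are implemented")
  d <- cp_dim(points)
  if (is.null(neighbors)) neighbors <- if (d == 2) 8L else 16L
  n <- nrow(points)
  ncoef <- if (d == 2) 6L else 10L
  if (neighbors + 1 < ncoef)
    stop(sprintf("need at least %d neighbors for the local fits", ncoef - 1))
  if (n <= neighbors) stop("more control points than neighbors required")

  P2 <- cp_mat(points, 2)
  P1 <- cp_mat(points, 1)
  D <- as.matrix(dist(P2))
  # rank achievable by the basis on this point configuration (degenerate
  # geometries, e.g. all points coplanar in 3D, cap it below ncoef)
  Uall <- sweep(P2, 2, colMeans(P2))
  Uall <- Uall / max(abs(Uall), 1)
  target_rank <- min(ncoef, qr(poly_basis(Uall))$rank)
  coefs <- array(NA_real_, dim = c(n, ncoef, d))
  radius <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    k <- neighbors + 1L            # the point itself plus its neighbors
    repeat {
      idx <- ord[seq_len(min(k, n))]
      r <- max(D[i, idx])
      U <- sweep(P2[idx, , drop = FALSE], 2, P2[i, ]) / r
      X <- poly_basis(U)
      q <- qr(X)
      if (q$rank >= target_rank || k >= n) break
      k <- k + 1L                  # widen a rank-deficient neighborhood
    }
    radius[i] <- r
    for (j in seq_len(d)) coefs[i, , j] <- qr.coef(q, P1[idx, j])
    if (anyNA(coefs[i, , ])) coefs[i, , ][is.na(coefs[i, , ])] <- 0
  }
  structure(list(centers = P2, coefs = coefs, radius = radius,
                 dim = d, neighbors = neighbors, order = order,
                 weight = "w(R) = 1 - 3R^2 + 2R^3 on [0,1], 0 beyond",
                 n_points = n),
            class = "lwm_transform")
}

#' @export
print.lwm_transform <- function(x, ...) {
  cat(sprintf(
    "lwm_transform: %dD, %d control points, order %d, %d neighbors, radii %.0f-%.0f nm\n",
    x$dim, x$n_points, x$order, x$neighbors, min(x$radius), max(x$radius)))
  invisible(x)
}

#' Evaluate an LWM transform at query coordinates
#'
#' Queries covered by no radius of influence fall back to the nearest control
#' point's polynomial (extrapolation); a warning is emitted and the rows are
#' flagged in the `"extrapolated"` attribute.
#'
#' @param object an [fit_lwm()] transform.
#' @param newdata numeric matrix of channel-2 coordinates (columns x, y[, z],
#'   nm).
#' @param ... unused.
#' @return matrix of mapped coordinates in the channel-1 frame.
#' @export
predict.lwm_transform <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  if (ncol(Q) != object$dim)
    stop(sprintf("transform is %dD but query points are %dD",
                 object$dim, ncol(Q)))
  nq <- nrow(Q)
  out <- matrix(0, nq, object$dim)
  wsum <- numeric(nq)
  extrapolated <- rep(FALSE, nq)

  # distances query x control point, chunked to bound memory
  chunk <- max(1L, as.integer(2e6 / object$n_points))
  for (s in seq(1, nq, by = chunk)) {
    rows <- s:min(nq, s + chunk - 1L)
    Qc <- Q[rows, , drop = FALSE]
    D2 <- outer(rowSums(Qc^2), rep(1, object$n_points)) -
      2 * Qc %*% t(object$centers) +
      outer(rep(1, length(rows)), rowSums(object$centers^2))
    D2[D2 < 0] <- 0
    R <- sqrt(D2) / matrix(object$radius, length(rows), object$n_points,
                           byrow = TRUE)
    W <- 1 - 3 * R^2 + 2 * R^3
    W[R >= 1] <- 0
    cov <- W > 0
    for (j in which(colSums(cov) > 0)) {
      qi <- which(cov[, j])
      U <- sweep(Qc[qi, , drop = FALSE], 2, object$centers[j, ]) /
        object$radius[j]
      vals <- poly_basis(U) %*% object$coefs[j, , ]
      w <- W[qi, j]
      out[rows[qi], ] <- out[rows[qi], ] + vals * w
      wsum[rows[qi]] <- wsum[rows[qi]] + w
    }
    # fallback: nearest local polynomial for uncovered queries
    unc <- which(rowSums(cov) == 0)
    for (qi in unc) {
      j <- which.min(D2[qi, ])
      U <- matrix((Qc[qi, ] - object$centers[j, ]) / object$radius[j], 1)
      out[rows[qi], ] <- poly_basis(U) %*% object$coefs[j, , ]
      wsum[rows[qi]] <- 1
      extrapolated[rows[qi]] <- TRUE
    }
  }
  if (any(extrapolated))
    warning(sprintf("%d points outside all radii of influence were mapped by their nearest local polynomial",
                    sum(extrapolated)))
  res <- out / wsum
  colnames(res) <- c("x", "y", "z")[seq_len(object$dim)]
  attr(res, "extrapolated") <- extrapolated
  res
}

#' Map a localization table into the reference channel's frame
#'
#' @param transform an [fit_lwm()] transform (channel 2 -> channel 1).
#' @param table a localization table.
#' @return the table with mapped coordinates; all other fields preserved.
#'   The mapping is recorded in the `"registered"` attribute.
#' @export
apply_transform <- function(transform, table) {
  d <- loc_dim(table)
  if (transform$dim == 3 && d == 2)
    stop("3D transform applied to a 2D localization table")
  if (transform$dim == 2 && d == 3)
    stop("2D transform applied to a 3D localization table")
  if (nrow(table) == 0) return(table)
  mapped <- predict(transform, loc_coords(table, d))
  table$x <- mapped[, 1]
  table$y <- mapped[, 2]
  if (d == 3) table$z <- mapped[, 3]
  attr(table, "registered") <- "channel 2 mapped into channel 1 frame"
  table
}

#' Fiducial registration error of a fitted transform
#'
#' Per axis, the root mean square of the differences between the channel-1
#' control points and the transformed channel-2 control points; the total is
#' the quadratic sum of the per-axis components.  As customary this is an
#' in-sample metric evaluated on the fitted control points; set
#' `leave_one_out = TRUE` for a cross-validated variant.
#'
#' @param points the [control_point_set()] used for fitting.
#' @param transform the fitted [fit_lwm()] transform.
#' @param leave_one_out refit without each point before evaluating it
#'   (slower; not the default).
#' @param ... passed to [fit_lwm()] when `leave_one_out = TRUE`.
#' @return a `registration_report`: per-axis FRE, total FRE, N, in nm.
#' @export
compute_fre <- function(points, transform, leave_one_out = FALSE, ...) {
  if (nrow(points) == 0) stop("empty control point set")
  d <- cp_dim(points)
  P1 <- cp_mat(points, 1)
  P2 <- cp_mat(points, 2)
  if (leave_one_out) {
    mapped <- P1 * NA
    for (i in seq_len(nrow(points))) {
      tr <- fit_lwm(points[-i, , drop = FALSE], ...)
      mapped[i, ] <- suppressWarnings(predict(tr, P2[i, , drop = FALSE]))
    }
  } else {
    mapped <- suppressWarnings(predict(transform, P2))
  }
  res <- P1 - mapped
  per_axis <- sqrt(colMeans(res^2))
  names(per_axis) <- paste0("FRE", c("x", "y", "z")[1:d])
  structure(list(per_axis = per_axis, total = sqrt(sum(per_axis^2)),
                 n = nrow(points)),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("FRE: total %.2f nm (%s) on %d control points\n", x$total,
              paste(sprintf("%s = %.2f", names(x$per_axis), x$per_axis),
                    collapse = ", "), x$n))
  invisible(x)
}

#' Select the optimal calibration scan step size
#'
#' Repeats the bead calibration for each candidate step size and compares the
#' total FRE across replicates: the candidate with the lowest median FRE
#' wins; ties go to the candidate with the lower FRE standard deviation
#' (larger variability at equal medians indicates a less reliable
#' calibration).
#'
#' @param step_sizes candidate scan steps, nm (at least 2).
#' @param replicates calibration acquisitions per candidate.
#' @param config a [sim_config()] used to simulate the calibration scans.
#' @param fre_values optional list (one numeric vector of total FREs per
#'   candidate) to ingest instead of simulating.
#' @param neighbors passed to [fit_lwm()].
#' @return list with the `chosen` step (nm) and a `summary` data frame
#'   (median and SD of total FRE per candidate).
#' @export
select_step_size <- function(step_sizes, replicates = 5, config = NULL,
                             fre_values = NULL, neighbors = NULL) {
  if (length(step_sizes) < 2) stop("need at least 2 candidate step sizes")
  if (is.null(fre_values)) {
    if (is.null(config)) stop("supply either a config or fre_values")
    fre_values <- lapply(step_sizes, function(step) {
      vapply(seq_len(replicates), function(r) {
        g <- max_grid_for_fov(step, config)
        beads <- generate_bead_stacks(g, config)
        pts <- extract_control_points(beads$ch1, beads$ch2)
        tr <- fit_lwm(pts, neighbors = neighbors)
        compute_fre(pts, tr)$total
      }, numeric(1))
    })
  }
  if (any(lengths(fre_values) == 1))
    warning("single replicate: variability cannot be assessed")
  med <- vapply(fre_values, median, numeric(1))
  sdev <- vapply(fre_values, sd, numeric(1))
  sdev[is.na(sdev)] <- Inf
  best <- which(med <= min(med) + 1e-12)
  chosen <- best[which.min(sdev[best])]
  list(chosen = step_sizes[chosen],
       summary = data.frame(step = step_sizes, median_fre = med,
                            sd_fre = sdev))
}

# largest lateral grid of the given step fitting the configured field of view
max_grid_for_fov <- function(step, config) {
  a <- config$pixel_size
  margin <- 6 * config$psf_sigma0
  nx <- floor((config$fov_px[2] * a - 2 * margin) / step) + 1
  ny <- floor((config$fov_px[1] * a - 2 * margin) / step) + 1
  list(nx = max(nx, 2), ny = max(ny, 2), nz = 1, step_xy = step)
}

#' Estimate the global axial focal shift between channels
#'
#' The mean of the per-bead axial differences between the two channels — a
#' single global z offset applied before the full 3D LWM correction.
#'
#' @param points a 3D [control_point_set()].
#' @return the focal shift (nm) to add to channel-2 z to match channel 1.
#' @export
estimate_axial_shift <- function(points) {
  if (cp_dim(points) != 3) stop("axial shift requires 3D control points")
  mean(points$z1 - points$z2)
}

#' Serialize / deserialize an LWM transform as JSON
#' @param transform an [fit_lwm()] transform.
#' @param path file path.
#' @return `read_lwm` returns the transform.
#' @export
write_lwm <- function(transform, path) {
  obj <- list(dim = transform$dim, neighbors = transform$neighbors,
              order = transform$order, weight = transform$weight,
              n_points = transform$n_points,
              centers = transform$centers, radius = transform$radius,
              coefs = as.numeric(transform$coefs),
              coef_dim = dim(transform$coefs))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_lwm
#' @export
read_lwm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = matrix(obj$centers, ncol = obj$dim),
                 coefs = array(obj$coefs, dim = obj$coef_dim),
                 radius = obj$radius, dim = obj$dim,
                 neighbors = obj$neighbors, order = obj$order,
                 weight = obj$weight, n_points = obj$n_points),
            class = "lwm_transform")
}
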
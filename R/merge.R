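#' Merge reappearing molecules
#'
#' The same photoactivated molecule often reappears for a few frames before
#' bleaching permanently, which would be counted as several molecules.
#' Localizations of the same channel closer than `radius` to a chain's
#' intensity-weighted position, and separated by fewer than `max_gap` frames
#' from the chain's initial appearance, are merged into one molecule:
#' coordinates are intensity-weighted means, photons are summed, and the
#' merged uncertainty is the quadratic sum of the per-axis standard
#' deviations of the duplicate positions.  Merging is iterated to a fixed
#' point so the output contains no pair still satisfying the merge predicate
#' (merging an already-merged table changes nothing).
#'
#' @param table a localization table ([localize_stack()]).
#' @param max_gap maximum frame gap from the initial appearance (default 10,
#'   i.e. a chain closes 10 frames after its first member).
#' @param radius merge radius in nm; `"auto"` for the mean Thompson
#'   uncertainty of the table, or the presets `"palm"` (20 nm) and
#'   `"expalm"` (11.5 nm, the midpoint of the 10-13 nm range customary for
#'   expanded samples).
#' @return the merged localization table (`merged_from` counts constituents).
#' @export
merge_reappearances <- function(table, max_gap = 10, radius = "auto") {
  radius <- resolve_merge_radius(radius, table)
  if (radius < 0) stop("merge radius must be >= 0")
  if (nrow(table) == 0) return(table)

  out <- table
  repeat {
    merged <- merge_pass(out, max_gap, radius)
    if (nrow(merged) == nrow(out)) break
    out <- merged
  }
  out$id <- seq_len(nrow(out))
  as_loc_table(out, attr(table, "pixel_size"),
               if (loc_dim(table) == 3) "3d" else "2d")
}

resolve_merge_radius <- function(radius, table) {
  if (is.character(radius)) {
    radius <- switch(radius,
      auto = {
        r <- mean(table$uncertainty, na.rm = TRUE)
        if (is.finite(r)) r else 0
      },
      palm = 20,
      expalm = 11.5,
      stop("unknown merge radius preset: ", radius))
  }
  radius
}

merge_pass <- function(table, max_gap, radius) {
  dim <- loc_dim(table)
  pieces <- lapply(split(seq_len(nrow(table)), table$channel), function(idx) {
    sub <- table[idx, , drop = FALSE]
    o <- order(sub$frame)
    sub <- sub[o, , drop = FALSE]
    ids <- cpp_merge_chains(sub$frame, loc_coords(sub, dim), sub$photons,
                            radius, as.integer(max_gap))
    aggregate_chains(sub, ids, dim)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$frame, out$x), , drop = FALSE]
}

aggregate_chains <- function(sub, ids, dim) {
  w <- pmax(sub$photons, 1e-12)
  sw <- as.numeric(rowsum(w, ids))
  uid <- sort(unique(ids))
  wmean <- function(v) as.numeric(rowsum(w * v, ids)) / sw
  n <- as.numeric(rowsum(rep(1, length(ids)), ids))
  x <- wmean(sub$x); y <- wmean(sub$y)
  z <- if (dim == 3) wmean(sub$z) else rep(NA_real_, length(uid))

  # per-axis SDs of duplicate positions (sample SD; 0 for singletons)
  sd_axis <- function(v, m) {
    ss <- as.numeric(rowsum((v - m[match(ids, uid)])^2, ids))
    ifelse(n > 1, sqrt(ss / (n - 1)), 0)
  }
  msd <- sqrt(sd_axis(sub$x, x)^2 + sd_axis(sub$y, y)^2 +
                if (dim == 3) sd_axis(sub$z, z)^2 else 0)

  base_unc <- wmean(sub$uncertainty)
  prior_from <- as.numeric(rowsum(as.numeric(sub$merged_from), ids))
  fid <- factor(ids, levels = uid)
  first_frame <- as.integer(tapply(sub$frame, fid, min))
  data.frame(
    id = uid, channel = sub$channel[1],
    frame = first_frame,
    x = x, y = y, z = z,
    sigma_x = wmean(sub$sigma_x), sigma_y = wmean(sub$sigma_y),
    photons = as.numeric(rowsum(sub$photons, ids)),
    background = wmean(sub$background),
    uncertainty = ifelse(n > 1, msd, base_unc),
    merged_from = as.integer(prior_from),
    merged_sd = ifelse(n > 1, msd, NA_real_))
}

#' Estimate localization precision from repeated localizations
#'
#' Repeated localizations (molecules reappearing within `max_gap` frames at
#' distances below the merge radius) are grouped with the merge predicate,
#' each group is centred on its centre of mass, and the pooled per-axis
#' deviation histograms are fitted with Gaussian functions; the precision per
#' axis is the fitted SD.  Run this on the un-merged table.
#'
#' @inheritParams merge_reappearances
#' @param min_groups below this number of duplicate groups a warning is
#'   emitted and no estimate is returned.
#' @return a data frame per channel and axis with the fitted `precision`
#'   (nm) and the number of duplicate groups, or `NULL` if too few groups.
#' @export
estimate_precision <- function(table, max_gap = 10, radius = "auto",
                               min_groups = 20) {
  radius <- resolve_merge_radius(radius, table)
  dim <- loc_dim(table)
  res <- list()
  for (ch in sort(unique(table$channel))) {
    sub <- table[table$channel == ch, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    ids <- cpp_merge_chains(sub$frame, loc_coords(sub, dim), sub$photons,
                            radius, as.integer(max_gap))
    size <- table(ids)
    keep <- ids %in% as.integer(names(size[size >= 2]))
    n_groups <- sum(size >= 2)
    if (n_groups < min_groups) {
      warning(sprintf(
        "channel %s: only %d duplicate groups (< %d); no precision estimate",
        ch, n_groups, min_groups))
      next
    }
    g <- ids[keep]
    dev <- function(v) v[keep] - ave(v[keep], g)
    axes <- list(x = dev(sub$x), y = dev(sub$y))
    if (dim == 3) axes$z <- dev(sub$z)
    for (ax in names(axes)) {
      res[[length(res) + 1]] <- data.frame(
        channel = ch, axis = ax,
        precision = gaussian_hist_sd(axes[[ax]]),
        n_groups = n_groups)
    }
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

# SD of a Gaussian fitted to the histogram of `dev`; degenerate spreads are
# reported as 0 (below one bin width).
gaussian_hist_sd <- function(dev) {
  s0 <- sd(dev)
  if (!is.finite(s0) || s0 == 0) return(0)
  h <- graphics::hist(dev, breaks = "FD", plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(A = max(df$y), mu = 0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(fit, "try-error")) return(s0)
  abs(coef(fit)[["s"]])
}
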
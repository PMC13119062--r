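#' Co-localization analysis parameters
#'
#' @param dB neighborhood radius (nm) of the co-localization index.
#' @param reference density reference for the expected neighbor count:
#'   `"self"` uses the mean number of same-channel neighbors within `dB`
#'   around the molecules of the probed channel (excluding the molecule
#'   itself), `"uniform"` uses the global density of the probed channel times
#'   the neighborhood area/volume.
#' @return a `coloc_params` list.
#' @export
coloc_params <- function(dB = 50, reference = c("self", "uniform")) {
  reference <- match.arg(reference)
  if (!is.numeric(dB) || length(dB) != 1 || dB <= 0)
    stop("dB must be a positive scalar (nm)")
  structure(list(dB = dB, reference = reference), class = "coloc_params")
}

#' Co-localization index of every molecule
#'
#' For each molecule of channel A, the co-localization index is
#' `CI = N_AiB(dB) / (L * mean(D_B))`: the number of channel-B molecules
#' within `dB`, normalized by the mean channel-B neighbor count expected from
#' the channel-B density alone (`L = 1`).  `CI > 0` means at least one B
#' molecule within `dB`; `CI ~ 1` marks densities compatible with chance for
#' molecules that do have neighbors.
#'
#' @param table a merged, registered localization table with both channels.
#' @param channel_a,channel_b channel ids of the probed (A) and the partner
#'   (B) molecules.
#' @param params a [coloc_params()].
#' @return the channel-A rows with columns `n_within` and `ci` appended.
#' @export
compute_ci <- function(table, channel_a = 1, channel_b = 2,
                       params = coloc_params()) {
  A <- table[table$channel == channel_a, , drop = FALSE]
  B <- table[table$channel == channel_b, , drop = FALSE]
  if (nrow(A) == 0) stop("no molecules in channel A")
  if (nrow(B) == 0) stop("no molecules in channel B")
  d <- loc_dim(table)
  ext <- apply(loc_coords(table, d), 2, function(v) diff(range(v)))
  if (params$dB > min(ext))
    warning("dB exceeds the data extent along at least one axis")

  PA <- loc_coords(A, d)
  PB <- loc_coords(B, d)
  n_ab <- cpp_count_within(PA, PB, params$dB, FALSE)
  dens_ref <- if (params$reference == "self") {
    mean(cpp_count_within(PB, PB, params$dB, TRUE))
  } else {
    vol <- if (d == 3) 4 / 3 * pi * params$dB^3 else pi * params$dB^2
    nrow(B) / prod(ext[ext > 0]) * vol
  }
  if (dens_ref <= 0) {
    warning("density reference is zero; CI reported as neighbor count")
    dens_ref <- 1
  }
  A$n_within <- n_ab
  A$ci <- n_ab / dens_ref
  A
}

#' Classify molecules and measure pair distances
#'
#' Molecules of channel A with `CI > 0` (at least one channel-B molecule
#' within `dB`) are classified as co-localizing.  Every channel-A molecule is
#' paired with its nearest channel-B neighbor; `dc`/`dnc` are the mean
#' nearest-neighbor distances of the co-localizing and non-co-localizing
#' groups.
#'
#' @inheritParams compute_ci
#' @return a `coloc_result`: the annotated channel-A table (`ci`,
#'   `colocalizing`, `nn_dist`, `nn_id`, `edge`), the channel-B table with
#'   its own CI (`molecules_b`), the counts `Nc`/`Nnc`, the
#'   group means `dc`/`dnc`, `pct_coloc` and the parameters.  Molecules
#'   within `dB` of the bounding box of all localizations are flagged `edge`
#'   (their neighborhoods are truncated) but are not excluded.
#' @export
classify_and_measure <- function(table, channel_a = 1, channel_b = 2,
                                 params = coloc_params()) {
  A <- compute_ci(table, channel_a, channel_b, params)
  B <- suppressWarnings(compute_ci(table, channel_b, channel_a, params))
  d <- loc_dim(table)
  nn <- cpp_nn(loc_coords(A, d), loc_coords(B, d), params$dB)
  A$colocalizing <- A$ci > 0
  A$nn_dist <- nn$dist
  A$nn_id <- B$id[nn$index]

  box <- apply(loc_coords(table, d), 2, range)
  PA <- loc_coords(A, d)
  edge <- rep(FALSE, nrow(A))
  for (k in seq_len(d))
    edge <- edge | PA[, k] - box[1, k] < params$dB |
      box[2, k] - PA[, k] < params$dB
  A$edge <- edge

  Nc <- sum(A$colocalizing)
  Nnc <- sum(!A$colocalizing)
  structure(list(
    molecules = A, molecules_b = B,
    Nc = Nc, Nnc = Nnc,
    dc = if (Nc > 0) mean(A$nn_dist[A$colocalizing]) else NA_real_,
    dnc = if (Nnc > 0) mean(A$nn_dist[!A$colocalizing]) else NA_real_,
    pct_coloc = 100 * Nc / (Nc + Nnc),
    params = params, channel_a = channel_a, channel_b = channel_b),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d/%d molecules co-localizing (%.1f%%), dc = %s, dnc = %s nm, d = %.2f nm (dB = %g nm)\n",
    x$Nc, x$Nc + x$Nnc, x$pct_coloc,
    if (is.na(x$dc)) "NA" else sprintf("%.2f", x$dc),
    if (is.na(x$dnc)) "NA" else sprintf("%.2f", x$dnc),
    mean_pair_distance(x), x$params$dB))
  invisible(x)
}

#' Population mean pair distance
#'
#' The count-weighted mean `d = (Nc * dc + Nnc * dnc) / (Nc + Nnc)` of the
#' co-localizing and non-co-localizing group distances — the mean
#' nearest-neighbor distance over all probed molecules.
#'
#' @param result a `coloc_result`, or the count `Nc` when the four scalars
#'   are given directly.
#' @param dc,Nnc,dnc group mean distances (nm) and counts.
#' @return mean pair distance, nm.
#' @export
mean_pair_distance <- function(result, dc = NULL, Nnc = NULL, dnc = NULL) {
  if (inherits(result, "coloc_result")) {
    Nc <- result$Nc; dc <- result$dc; Nnc <- result$Nnc; dnc <- result$dnc
  } else {
    Nc <- result
  }
  if (Nc + Nnc == 0) stop("no molecules in either group")
  if (Nc == 0) return(dnc)
  if (Nnc == 0) return(dc)
  (Nc * dc + Nnc * dnc) / (Nc + Nnc)
}

#' Estimate the expansion factor from paired pre/post measurements
#'
#' The mean ratio of post- to pre-expansion lengths of the same structures.
#' The standard deviation combines the relative spreads of both measurement
#' sets in quadrature.
#'
#' @param pre,post paired structure sizes before and after expansion (same
#'   units).
#' @return list with `factor`, `sd`, `n`.
#' @export
estimate_expansion_factor <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must pair one-to-one")
  if (any(pre <= 0)) stop("pre-expansion sizes must be positive")
  f <- mean(post / pre)
  s <- if (length(pre) > 1)
    f * sqrt((sd(pre) / mean(pre))^2 + (sd(post) / mean(post))^2)
  else NA_real_
  list(factor = f, sd = s, n = length(pre))
}

#' Rescale expanded-sample distances to biological scale
#'
#' @param d distances measured in the expanded sample, nm.
#' @param factor expansion factor (> 0).
#' @return distances divided by the expansion factor.
#' @export
rescale_to_biological <- function(d, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("expansion factor must be a positive scalar")
  d / factor
}

#' Compare a per-acquisition statistic between two experimental groups
#'
#' Welch two-sample t-test on per-acquisition summary values (e.g. percent
#' co-localizing molecules, mean pair distance).
#'
#' @param group1,group2 per-acquisition values.
#' @param alternative passed to [stats::t.test()].
#' @return list with the group means and SDs, `t`, `df`, `p_value` and a
#'   `degenerate` flag (constant values in both groups, where the t-test is
#'   undefined and `p_value` is `NA`).
#' @export
compare_groups <- function(group1, group2,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(group1) < 2 || length(group2) < 2)
    stop("need at least 2 acquisitions per group")
  degenerate <- var(group1) == 0 && var(group2) == 0
  if (degenerate) {
    return(list(mean1 = mean(group1), mean2 = mean(group2),
                sd1 = 0, sd2 = 0, t = NA_real_, df = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(group1, group2, alternative = alternative)
  list(mean1 = mean(group1), mean2 = mean(group2),
       sd1 = sd(group1), sd2 = sd(group2),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
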
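#' Read and write localization tables (ThunderSTORM-compatible CSV)
#'
#' The CSV dialect uses the header
#' `frame,"x [nm]","y [nm]","z [nm]","sigma1 [nm]","sigma2 [nm]",
#' "intensity [photon]","offset [photon]","uncertainty_xy [nm]"`.
#' Genuine ThunderSTORM exports are accepted on import; missing columns are
#' tolerated with a warning and filled with `NA`.
#'
#' @param table a localization table.
#' @param path file path.
#' @param channel channel id to attach on read (not stored in the CSV).
#' @param pixel_size pixel size (nm) to attach on read.
#' @return `read_locs` returns a `loc_table`.
#' @export
write_locs <- function(table, path) {
  out <- data.frame(
    frame = table$frame,
    `x [nm]` = table$x, `y [nm]` = table$y, `z [nm]` = table$z,
    `sigma1 [nm]` = table$sigma_x, `sigma2 [nm]` = table$sigma_y,
    `intensity [photon]` = table$photons,
    `offset [photon]` = table$background,
    `uncertainty_xy [nm]` = table$uncertainty,
    check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locs
#' @export
read_locs <- function(path, channel = 1L, pixel_size = NA) {
  raw <- read.csv(path, check.names = FALSE)
  want <- c(frame = "frame", x = "x [nm]", y = "y [nm]", z = "z [nm]",
            sigma_x = "sigma1 [nm]", sigma_y = "sigma2 [nm]",
            photons = "intensity [photon]", background = "offset [photon]",
            uncertainty = "uncertainty_xy [nm]")
  # ThunderSTORM variants: a single "sigma [nm]" column, "uncertainty [nm]"
  alias <- list(sigma_x = "sigma [nm]", sigma_y = "sigma [nm]",
                uncertainty = "uncertainty [nm]")
  tab <- data.frame(row.names = seq_len(nrow(raw)))
  missing <- character(0)
  for (nm in names(want)) {
    col <- want[[nm]]
    if (!col %in% names(raw) && nm %in% names(alias) &&
        alias[[nm]] %in% names(raw))
      col <- alias[[nm]]
    if (col %in% names(raw)) {
      tab[[nm]] <- raw[[col]]
    } else {
      tab[[nm]] <- NA_real_
      missing <- c(missing, want[[nm]])
    }
  }
  if (length(missing) > 0)
    warning("missing columns filled with NA: ",
            paste(unique(missing), collapse = ", "))
  tab$id <- seq_len(nrow(tab))
  tab$channel <- as.integer(channel)
  tab$merged_from <- 1L
  tab$merged_sd <- NA_real_
  tab <- tab[c("id", "channel", "frame", "x", "y", "z", "sigma_x", "sigma_y",
               "photons", "background", "uncertainty", "merged_from",
               "merged_sd")]
  as_loc_table(tab, pixel_size = pixel_size,
               dim_mode = if (any(!is.na(tab$z))) "3d" else "2d")
}
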
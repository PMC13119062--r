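#' Spherocylindrical cell model
#'
#' Rod-shaped bacteria such as E. coli are modeled as a spherocylinder: a
#' cylinder of length `length` and diameter `diameter` capped by two
#' hemispheres.  All dimensions are in nanometres.
#'
#' @param length cylindrical (straight) part length, nm.
#' @param diameter cell diameter, nm.
#' @param center cell centre `(x, y, z)`, nm.
#' @param axis orientation of the long axis (normalized internally).
#' @return an object of class `cell_model`.
#' @examples
#' cell <- cell_model(length = 2000, diameter = 800)
#' cell_volume_um3(cell)
#' @export
cell_model <- function(length = 2000, diameter = 800,
                       center = c(0, 0, 0), axis = c(1, 0, 0)) {
  if (length <= 0) stop("cell length must be > 0")
  if (diameter <= 0) stop("cell diameter must be > 0")
  if (length(center) != 3) stop("center must have 3 coordinates")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a non-zero vector")
  structure(list(length = length, diameter = diameter,
                 center = as.numeric(center), axis = axis / nrm),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("spherocylinder: L = %g nm, d = %g nm, V = %.3f um^3\n",
              x$length, x$diameter, cell_volume_um3(x)))
  invisible(x)
}

#' Spherocylinder volume in cubic micrometres
#' @param cell a [cell_model()].
#' @return volume in um^3.
#' @export
cell_volume_um3 <- function(cell) {
  r <- cell$diameter / 2
  (pi * r^2 * cell$length + 4 / 3 * pi * r^3) / 1e9
}

# Orthonormal basis whose first vector is the cell axis.
cell_basis <- function(cell) {
  a <- cell$axis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b <- ref - sum(ref * a) * a
  b <- b / sqrt(sum(b^2))
  cbind(a, b, c(a[2] * b[3] - a[3] * b[2],
                a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1]))
}

#' Test whether points lie inside a cell
#'
#' @param cell a [cell_model()].
#' @param pts numeric matrix with columns x, y, z (nm).
#' @return logical vector.
#' @export
point_in_cell <- function(cell, pts) {
  pts <- matrix(pts, ncol = 3)
  B <- cell_basis(cell)
  loc <- sweep(pts, 2, cell$center) %*% B   # axis, radial1, radial2
  r <- cell$diameter / 2
  h <- cell$length / 2
  ax <- pmax(abs(loc[, 1]) - h, 0)          # distance beyond the cylinder
  ax^2 + loc[, 2]^2 + loc[, 3]^2 <= r^2
}

#' Draw uniform points inside a cell
#'
#' Rejection sampling from the bounding box of the spherocylinder.
#'
#' @param cell a [cell_model()].
#' @param n number of points.
#' @return n x 3 matrix of coordinates (nm).
#' @export
sample_in_cell <- function(cell, n) {
  if (n == 0) return(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("x", "y", "z"))))
  r <- cell$diameter / 2
  h <- cell$length / 2 + r
  out <- matrix(NA_real_, n, 3)
  got <- 0
  B <- cell_basis(cell)
  while (got < n) {
    m <- ceiling((n - got) * 1.8) + 8
    loc <- cbind(runif(m, -h, h), runif(m, -r, r), runif(m, -r, r))
    ax <- pmax(abs(loc[, 1]) - cell$length / 2, 0)
    keep <- ax^2 + loc[, 2]^2 + loc[, 3]^2 <= r^2
    loc <- loc[keep, , drop = FALSE]
    take <- min(nrow(loc), n - got)
    if (take > 0) {
      world <- sweep(loc[seq_len(take), , drop = FALSE] %*% t(B), 2,
                     -cell$center)
      out[got + seq_len(take), ] <- world
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}
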
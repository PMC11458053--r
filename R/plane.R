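#' Fit a plane to 3-D points by total (orthogonal) least squares
#'
#' Fits the plane minimising the sum of squared *orthogonal* distances from
#' the points, via the smallest principal direction of the centred point
#' cloud. Orthogonal regression (rather than regressing z on x,y) is used
#' because downstream steps project points orthogonally onto this plane;
#' only the total-least-squares plane makes those two operations consistent.
#'
#' The normal is reported with a deterministic sign: its z component is
#' non-negative (superior-pointing in an LPS world); if the z component is
#' zero the y component breaks the tie, then x.
#'
#' @param points at least three 3-D points: an n x 3 matrix, a data frame
#'   with `x`,`y`,`z` columns, or a list of length-3 vectors. Millimetres.
#' @return an object of class `lscc_plane`: a list with `normal` (unit
#'   3-vector), `centroid` (mean of the input points, a point on the plane),
#'   `rms_residual` (root-mean-square orthogonal distance, mm).
#' @examples
#' fit_plane(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0)))
#' @export
fit_plane <- function(points) {
  pts <- as_point_matrix(points, "plane points")
  n <- nrow(pts)
  if (n < 3L) stop_input("plane fitting needs at least 3 points, got ", n)

  centroid <- colMeans(pts)
  centred <- sweep(pts, 2L, centroid)
  scale <- max(sqrt(rowSums(centred^2)))
  if (scale < .tol$collinear)
    stop_degenerate("degenerate geometry: the ", n, " points are coincident ",
                    "(max spread ", format(scale), " mm)")

  sv <- svd(centred)
  # singular values sorted decreasingly; collinear points have sv$d[2] ~ 0
  if (sv$d[2] / sv$d[1] < .tol$collinear)
    stop_degenerate("degenerate geometry: the ", n,
                    " points are collinear, no unique plane")
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  normal <- orient_normal(normal)

  res <- centred %*% normal
  structure(list(normal = as.numeric(normal),
                 centroid = as.numeric(centroid),
                 rms_residual = sqrt(mean(res^2))),
            class = "lscc_plane")
}

# Deterministic sign convention: z >= 0, ties broken by y then x.
orient_normal <- function(n) {
  eps <- .tol$unit_norm
  flip <- if (abs(n[3L]) > eps) n[3L] < 0
          else if (abs(n[2L]) > eps) n[2L] < 0
          else n[1L] < 0
  if (flip) -n else n
}

#' Orthogonal projection of points onto a plane
#'
#' @param p a 3-D point or n x 3 matrix of points (mm).
#' @param plane an `lscc_plane` from [fit_plane()].
#' @return points of the same shape as `p`, lying on the plane.
#' @export
project_onto_plane <- function(p, plane) {
  stopifnot(inherits(plane, "lscc_plane"))
  single <- is.numeric(p) && is.null(dim(p))
  pts <- as_point_matrix(p, "points to project")
  d <- sweep(pts, 2L, plane$centroid) %*% plane$normal
  q <- pts - d %*% t(plane$normal)
  if (single) as.numeric(q) else q
}

#' Signed orthogonal distance from points to a plane
#'
#' Positive on the side the normal points to (superior, under the package's
#' sign convention).
#' @inheritParams project_onto_plane
#' @return numeric vector of distances in mm.
#' @export
plane_distance <- function(p, plane) {
  stopifnot(inherits(plane, "lscc_plane"))
  pts <- as_point_matrix(p, "points")
  as.numeric(sweep(pts, 2L, plane$centroid) %*% plane$normal)
}

#' @export
print.lscc_plane <- function(x, ...) {
  cat("Total-least-squares plane\n")
  cat("  normal  :", format(x$normal, digits = 6), "\n")
  cat("  centroid:", format(x$centroid, digits = 6), "mm\n")
  cat("  RMS orthogonal residual:", format(x$rms_residual, digits = 4), "mm\n")
  invisible(x)
}
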
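#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis unit 3-vector (checked to within 1e-6 of unit length; exact
#'   normalisation is applied).
#' @param degrees rotation angle in degrees; positive follows the right-hand
#'   rule about `axis`.
#' @return a 3 x 3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_about_axis <- function(axis, degrees) {
  a <- as_point3(axis, "rotation axis")
  nrm <- sqrt(sum(a^2))
  if (nrm < 1e-12) stop_input("rotation axis must be non-zero")
  if (abs(nrm - 1) > 1e-6)
    stop_input("rotation axis must be a unit vector (|axis| = ", format(nrm), ")")
  a <- a / nrm
  if (!is.finite(degrees)) stop_input("rotation angle must be finite")
  th <- degrees * pi / 180
  K <- rbind(c(0, -a[3], a[2]),
             c(a[3], 0, -a[1]),
             c(-a[2], a[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

check_rotation <- function(R, what = "rotation") {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
    stop_input(what, " must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > .tol$orthonormal)
    stop_input(what, " is not orthonormal within tolerance")
  if (abs(det(R) - 1) > .tol$orthonormal)
    stop_input(what, " must be proper (det = +1); reflections are not rigid")
  unname(R)
}

#' Rigid transform (rotation + translation)
#'
#' Represents the map `p -> R p + t` on world points in millimetres.
#' The world-to-frame map of an LSCC frame is obtained with
#' [world_to_frame_transform()], whose rotation is the transpose of the
#' frame's axis matrix.
#'
#' @param rotation 3 x 3 orthonormal matrix, determinant +1.
#' @param translation 3-vector, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  structure(list(rotation = check_rotation(rotation),
                 translation = as_point3(translation, "translation")),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param p a 3-D point or n x 3 matrix.
#' @return transformed point(s), same shape as `p`.
#' @export
transform_points <- function(transform, p) {
  stopifnot(inherits(transform, "rigid_transform"))
  single <- is.numeric(p) && is.null(dim(p))
  pts <- as_point_matrix(p, "points")
  out <- pts %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (single) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the map `p -> a(b(p))`.
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Convert a rigid transform to/from a 4 x 4 homogeneous matrix
#' @param transform a `rigid_transform`.
#' @return `as_homogeneous`: a 4 x 4 matrix; `from_homogeneous`: a
#'   `rigid_transform`.
#' @export
as_homogeneous <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname as_homogeneous
#' @param m a 4 x 4 homogeneous rigid matrix.
#' @export
from_homogeneous <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L)) || max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop_input("not a homogeneous rigid matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Read/write a rigid transform as a JSON sidecar
#'
#' The sidecar stores the 4 x 4 homogeneous matrix row-major, in
#' millimetres, with a convention tag recording that world axes follow the
#' LPS (+x left, +y posterior, +z superior) convention.
#'
#' @param transform a `rigid_transform`.
#' @param path file path for the JSON sidecar.
#' @export
write_transform_json <- function(transform, path) {
  m <- as_homogeneous(transform)
  jsonlite::write_json(
    list(convention = "LPS", units = "mm", order = "row-major",
         matrix = as.vector(t(m))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) stop_input("transform sidecar not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$convention, "LPS"))
    stop_input("transform sidecar has convention '", x$convention,
               "', expected 'LPS'")
  from_homogeneous(matrix(as.numeric(x$matrix), 4, 4, byrow = TRUE))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm, LPS world)\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", format(x$translation, digits = 6), "\n")
  invisible(x)
}
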
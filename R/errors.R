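#' @keywords internal
"_PACKAGE"

# Condition helpers. Two error classes are distinguished so callers (and the
# command-line driver) can map them to distinct exit statuses:
#   lsccframe_input_error     - malformed tables, missing files, bad arguments
#   lsccframe_degenerate_geometry - collinear/coincident landmark configurations
stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("lsccframe_input_error", "error")))
}

stop_degenerate <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("lsccframe_degenerate_geometry",
                                "lsccframe_input_error", "error")))
}

# Numeric tolerances are fixed package constants, not user configuration.
.tol <- list(
  unit_norm   = 1e-12,  # |n| = 1 for plane normals
  orthonormal = 1e-10,  # R'R = I, det(R) = 1
  on_plane    = 1e-10,  # projected point lies on plane
  collinear   = 1e-9    # relative spread threshold for degeneracy
)

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stop_input(what, " must be a finite numeric vector of length 3")
  p
}

# Accept an n x 3 matrix, a data frame with x/y/z, or a list of length-3
# vectors; return an n x 3 numeric matrix.
as_point_matrix <- function(points, what = "points") {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) != 3L) stop_input(what, " data frame needs x, y, z columns")
    points <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, as_point3, what = what))
  } else if (is.numeric(points) && is.null(dim(points))) {
    points <- matrix(as_point3(points, what), nrow = 1L)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || !all(is.finite(points)))
    stop_input(what, " must be an n x 3 matrix of finite coordinates")
  points
}
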
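#' LSCC landmark set
#'
#' The four labelled landmarks on the lateral semicircular canals that
#' define the coordinate system: the anterior and posterior junctions of
#' each LSCC with the vestibule. Coordinates are world millimetres in an
#' LPS-like right-handed convention (+x right-to-left, +y
#' anterior-to-posterior, +z inferior-to-superior).
#'
#' Left landmarks must have strictly greater x than right landmarks; a
#' violation is an error rather than a silent relabelling, since swapped
#' sides in a clinical table indicate a data-entry problem.
#'
#' @param left_anterior,left_posterior,right_anterior,right_posterior
#'   3-vectors, world mm.
#' @return an object of class `lscc_landmark_set`: a 4 x 3 matrix with rows
#'   `left_anterior`, `left_posterior`, `right_anterior`, `right_posterior`.
#' @export
lscc_landmark_set <- function(left_anterior, left_posterior,
                              right_anterior, right_posterior) {
  m <- rbind(left_anterior  = as_point3(left_anterior, "left_anterior"),
             left_posterior = as_point3(left_posterior, "left_posterior"),
             right_anterior = as_point3(right_anterior, "right_anterior"),
             right_posterior = as_point3(right_posterior, "right_posterior"))
  colnames(m) <- c("x", "y", "z")
  if (min(m[1:2, "x"]) <= max(m[3:4, "x"]))
    stop_input("left landmarks must have strictly greater x than right ",
               "landmarks (+x = left); check side labels in the input")
  # collinearity is caught here rather than deferred to the plane fit so the
  # error names the landmark configuration
  centred <- sweep(m, 2L, colMeans(m))
  sv <- svd(centred)$d
  if (sv[1] < .tol$collinear || sv[2] / sv[1] < .tol$collinear)
    stop_degenerate("degenerate geometry: the four LSCC landmarks are ",
                    "collinear or coincident")
  structure(m, class = c("lscc_landmark_set", "matrix"))
}

#' Build the LSCC coordinate frame from four landmarks
#'
#' Constructs the anatomical frame in five steps: (1) fit a
#' total-least-squares plane to the four landmarks; (2) project the
#' landmarks orthogonally onto it; (3) take the origin as the mean of the
#' four projections; (4) set the x axis through the midpoints of the
#' anterior--posterior segment on each side, pointing right to left, and
#' the y axis along the anterior-to-posterior direction within the plane,
#' orthogonal to x; (5) complete a right-handed basis with z = x cross y
#' (inferior to superior), then rotate the y and z axes about the x axis by
#' `tilt_degrees` to bring the frame's xy plane from the canal plane toward
#' the conventional horizontal head orientation (the canal plane sits about
#' 20 degrees from the Reid horizontal).
#'
#' The rotation sense is the right-hand rule about the +x axis; pass a
#' negative `tilt_degrees` for the opposite sense, or 0 to keep the raw
#' canal-plane frame.
#'
#' @param landmarks an [lscc_landmark_set()] (or a 4 x 3 matrix with those
#'   row names).
#' @param tilt_degrees signed rotation about the frame's x axis applied
#'   after the canal-plane frame is built; default 20.
#' @return an object of class `lscc_frame`: list with `origin` (world mm),
#'   `rotation` (3 x 3; columns are the frame's x, y, z axes in world
#'   coordinates), `plane` (the fitted `lscc_plane`), `projections` (4 x 3
#'   projected landmarks), `tilt_degrees`.
#' @export
build_lscc_frame <- function(landmarks, tilt_degrees = 20) {
  landmarks <- as_landmark_set(landmarks)
  if (!is.finite(tilt_degrees)) stop_input("tilt_degrees must be finite")

  plane <- fit_plane(landmarks)
  proj <- project_onto_plane(unclass(landmarks), plane)
  rownames(proj) <- rownames(landmarks)
  origin <- colMeans(proj)

  left_mid  <- colMeans(proj[c("left_anterior", "left_posterior"), ])
  right_mid <- colMeans(proj[c("right_anterior", "right_posterior"), ])
  xv <- left_mid - right_mid
  if (sqrt(sum(xv^2)) < .tol$collinear)
    stop_degenerate("degenerate geometry: left and right landmark midpoints ",
                    "coincide; no x axis is defined")
  xhat <- xv / sqrt(sum(xv^2))

  ant_mid  <- colMeans(proj[c("left_anterior", "right_anterior"), ])
  post_mid <- colMeans(proj[c("left_posterior", "right_posterior"), ])
  yv <- post_mid - ant_mid               # anterior -> posterior
  yv <- yv - sum(yv * xhat) * xhat       # in-plane, orthogonal to x
  if (sqrt(sum(yv^2)) < .tol$collinear)
    stop_degenerate("degenerate geometry: anterior and posterior landmark ",
                    "midpoints coincide; no y axis is defined")
  yhat <- yv / sqrt(sum(yv^2))
  zhat <- cross3(xhat, yhat)             # right-handed; inferior -> superior

  R <- cbind(x = xhat, y = yhat, z = zhat)
  if (tilt_degrees != 0) {
    tilt <- rotation_about_axis(xhat, tilt_degrees)
    R <- cbind(x = xhat, y = as.numeric(tilt %*% yhat),
               z = as.numeric(tilt %*% zhat))
  }
  check_rotation(R, "frame rotation")

  structure(list(origin = as.numeric(origin), rotation = R, plane = plane,
                 projections = proj, tilt_degrees = tilt_degrees),
            class = "lscc_frame")
}

as_landmark_set <- function(landmarks) {
  if (inherits(landmarks, "lscc_landmark_set")) return(landmarks)
  m <- as_point_matrix(landmarks, "landmarks")
  need <- c("left_anterior", "left_posterior", "right_anterior",
            "right_posterior")
  if (is.null(rownames(m)) || !all(need %in% rownames(m)))
    stop_input("landmark matrix must have rows named ",
               paste(need, collapse = ", "))
  lscc_landmark_set(m["left_anterior", ], m["left_posterior", ],
                    m["right_anterior", ], m["right_posterior", ])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' World/frame coordinate maps induced by an LSCC frame
#'
#' `world_to_frame_transform()` returns the rigid map taking world
#' coordinates to frame coordinates, `p' = R^T (p - origin)`;
#' `frame_to_world_transform()` its inverse. `world_to_frame()` and
#' `frame_to_world()` apply them directly to points.
#'
#' @param frame an `lscc_frame` from [build_lscc_frame()].
#' @return a [rigid_transform()].
#' @export
world_to_frame_transform <- function(frame) {
  stopifnot(inherits(frame, "lscc_frame"))
  Rt <- t(frame$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% frame$origin))
}

#' @rdname world_to_frame_transform
#' @export
frame_to_world_transform <- function(frame) {
  stopifnot(inherits(frame, "lscc_frame"))
  rigid_transform(frame$rotation, frame$origin)
}

#' @rdname world_to_frame_transform
#' @param p a 3-D point or n x 3 matrix, mm.
#' @export
world_to_frame <- function(frame, p) {
  transform_points(world_to_frame_transform(frame), p)
}

#' @rdname world_to_frame_transform
#' @export
frame_to_world <- function(frame, p) {
  transform_points(frame_to_world_transform(frame), p)
}

#' Cross-modality co-registration transform from two frames
#'
#' Given frames built independently from CT and MR landmarks of the same
#' subject, returns the world map sending a CT-world location to the
#' MR-world location with identical frame coordinates. Transforming both
#' images into their own frames therefore co-registers them, and this
#' transform is the implied CT-to-MR rigid registration.
#'
#' @param frame_from,frame_to `lscc_frame` objects.
#' @return a [rigid_transform()] mapping `frame_from`'s world onto
#'   `frame_to`'s world.
#' @export
cross_modality_transform <- function(frame_from, frame_to) {
  compose_transforms(frame_to_world_transform(frame_to),
                     world_to_frame_transform(frame_from))
}

#' @export
print.lscc_frame <- function(x, ...) {
  cat("LSCC coordinate frame (tilt ", x$tilt_degrees, " deg)\n", sep = "")
  cat("  origin:", format(x$origin, digits = 6), "mm\n")
  cat("  axes (columns x, y, z in world coordinates):\n")
  print(round(x$rotation, 6))
  cat("  plane RMS residual:", format(x$plane$rms_residual, digits = 4), "mm\n")
  invisible(x)
}
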
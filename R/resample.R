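#' In-memory image volume with an LPS world affine
#'
#' A 3-D intensity array plus the 4 x 4 affine mapping 0-based voxel
#' indices to world millimetres in the LPS (+x left, +y posterior,
#' +z superior) convention used throughout the package.
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing, mm (ignored when `affine` is given).
#' @param origin world position of voxel (0,0,0), mm.
#' @param affine optional full 4 x 4 voxel-to-world affine (LPS).
#' @return an object of class `image_volume`: list with `data`, `affine`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop_input("image data must be a 3-D array")
  if (is.null(affine)) {
    grid <- as_voxel_grid(spacing)
    affine <- diag(4)
    diag(affine)[1:3] <- grid$spacing
    affine[1:3, 4] <- as_point3(origin, "origin")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop_input("affine must be a finite 4 x 4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop_input("affine linear part is singular")
  structure(list(data = data, affine = affine), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("Image volume", paste(dim(x$data), collapse = " x "), "voxels\n")
  cat("affine (voxel -> LPS mm):\n"); print(round(x$affine, 4))
  invisible(x)
}

vox2world <- function(vol, idx) {
  idx <- as_point_matrix(idx, "voxel indices")
  h <- cbind(idx, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

world2vox <- function(vol, p) {
  p <- as_point_matrix(p, "world points")
  h <- cbind(p, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE]
}

#' Read/write NIfTI-1 volumes as LPS image volumes
#'
#' NIfTI stores a RAS voxel-to-world affine; on read it is converted to
#' the package's LPS convention by negating the x and y world axes, and
#' the conversion is reversed on write.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_nifti_volume`: an [image_volume()].
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop_input("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_input("cannot read NIfTI '", path,
                                                 "': ", conditionMessage(e)))
  ras <- structure(RNifti::xform(img), class = NULL)
  lps <- diag(c(-1, -1, 1, 1)) %*% ras
  if (length(dim(img)) != 3L)
    stop_input("expected a 3-D NIfTI volume, got ",
               length(dim(img)), " dimensions")
  arr <- array(as.numeric(img), dim = dim(img))   # plain array, no nifti attrs
  image_volume(arr, affine = lps)
}

#' @rdname read_nifti_volume
#' @param vol an [image_volume()].
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  ras <- diag(c(-1, -1, 1, 1)) %*% vol$affine
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(ras, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Vectorized trilinear / nearest-neighbour sampling of a 3-D array at
# continuous 0-based voxel coordinates. Out-of-volume samples get `fill`.
sample_volume <- function(data, u, interpolation = "trilinear", fill = 0) {
  dims <- dim(data)
  n <- nrow(u)
  out <- rep(as.numeric(fill), n)
  if (interpolation == "nearest") {
    i <- round(u)
    ok <- i[, 1] >= 0 & i[, 1] <= dims[1] - 1 &
      i[, 2] >= 0 & i[, 2] <= dims[2] - 1 &
      i[, 3] >= 0 & i[, 3] <= dims[3] - 1
    ii <- i[ok, , drop = FALSE]
    out[ok] <- data[ii[, 1] + dims[1] * (ii[, 2] + dims[2] * ii[, 3]) + 1]
    return(out)
  }
  i0 <- floor(u)
  ok <- i0[, 1] >= 0 & i0[, 1] <= dims[1] - 2 &
    i0[, 2] >= 0 & i0[, 2] <= dims[2] - 2 &
    i0[, 3] >= 0 & i0[, 3] <= dims[3] - 2
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- u[ok, , drop = FALSE] - i0
  base <- i0[, 1] + dims[1] * (i0[, 2] + dims[2] * i0[, 3]) + 1
  sx <- 1; sy <- dims[1]; sz <- dims[1] * dims[2]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + w * data[base + dx * sx + dy * sy + dz * sz]
  }
  out[ok] <- acc
  out
}

#' Resample a volume into an LSCC frame on an isotropic grid
#'
#' Produces the volume expressed in the anatomical frame: the output grid
#' is isotropic at `out_spacing` (0.2604 mm by default, the common grid
#' both modalities are rescaled to), the frame origin maps to the
#' geometric centre of the output volume (index `(dims - 1)/2`), and each
#' output voxel is interpolated from the input at the corresponding world
#' position. The returned volume's affine maps output voxels to *frame*
#' coordinates.
#'
#' @param vol an [image_volume()].
#' @param frame an [build_lscc_frame()] result (in the same world as
#'   `vol`).
#' @param out_spacing isotropic output spacing, mm.
#' @param out_dims output dimensions; default covers the rotated input
#'   field of view.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill intensity for voxels outside the input field of view.
#' @return an [image_volume()] on the frame grid.
#' @export
resample_to_frame <- function(vol, frame, out_spacing = 0.2604,
                              out_dims = NULL,
                              interpolation = c("trilinear", "nearest"),
                              fill = 0) {
  stopifnot(inherits(vol, "image_volume"), inherits(frame, "lscc_frame"))
  interpolation <- match.arg(interpolation)
  if (!is.finite(out_spacing) || out_spacing <= 0)
    stop_input("out_spacing must be positive")
  if (is.null(out_dims)) out_dims <- default_frame_dims(vol, frame,
                                                        out_spacing)
  out_dims <- as.integer(out_dims)
  if (length(out_dims) != 3L || any(out_dims < 1L))
    stop_input("out_dims must be 3 integers >= 1")

  centre <- (out_dims - 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(out_dims[1]) - 1L,
                               j = seq_len(out_dims[2]) - 1L,
                               k = seq_len(out_dims[3]) - 1L))
  fpts <- sweep(idx, 2L, centre) * out_spacing        # frame coordinates
  wpts <- frame_to_world(frame, fpts)                 # input world
  u <- world2vox(vol, wpts)                           # continuous voxels
  vals <- sample_volume(vol$data, u, interpolation, fill)

  out_affine <- diag(4)
  diag(out_affine)[1:3] <- out_spacing
  out_affine[1:3, 4] <- -centre * out_spacing         # frame origin at centre
  image_volume(array(vals, dim = out_dims), affine = out_affine)
}

# Output FOV: the input corner box expressed in frame coordinates.
default_frame_dims <- function(vol, frame, out_spacing) {
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(i = c(0, d[1] - 1), j = c(0, d[2] - 1),
                                   k = c(0, d[3] - 1)))
  f <- world_to_frame(frame, vox2world(vol, corners))
  half <- apply(abs(f), 2L, max)
  2L * as.integer(ceiling(half / out_spacing)) + 1L
}

#' Co-register a CT/MR pair via their LSCC frames
#'
#' Builds each modality's LSCC frame from its own landmark set and
#' resamples both volumes onto the identical frame grid; since both are
#' expressed in the same anatomical frame, the outputs are co-registered.
#' Also returns the implied CT-to-MR rigid world transform (see
#' [cross_modality_transform()]). Either volume may be `NULL` for a
#' landmark-only co-registration (the transform and frames are still
#' returned).
#'
#' @param ct_vol,mr_vol [image_volume()]s (or `NULL`).
#' @param ct_landmarks,mr_landmarks [lscc_landmark_set()]s in the
#'   respective volume's world.
#' @param tilt_degrees frame tilt, degrees.
#' @param out_spacing,out_dims,interpolation,fill as
#'   [resample_to_frame()]; the default `out_dims` covers both inputs.
#' @return list with `ct`, `mr` (resampled volumes or `NULL`),
#'   `transform` (CT world to MR world [rigid_transform()]), and
#'   `frames` (list of the two `lscc_frame`s).
#' @export
coregister_pair <- function(ct_vol = NULL, ct_landmarks,
                            mr_vol = NULL, mr_landmarks,
                            tilt_degrees = 20, out_spacing = 0.2604,
                            out_dims = NULL,
                            interpolation = c("trilinear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  frame_ct <- build_lscc_frame(ct_landmarks, tilt_degrees = tilt_degrees)
  frame_mr <- build_lscc_frame(mr_landmarks, tilt_degrees = tilt_degrees)

  if (is.null(out_dims) && (!is.null(ct_vol) || !is.null(mr_vol))) {
    dims_list <- list()
    if (!is.null(ct_vol))
      dims_list$ct <- default_frame_dims(ct_vol, frame_ct, out_spacing)
    if (!is.null(mr_vol))
      dims_list$mr <- default_frame_dims(mr_vol, frame_mr, out_spacing)
    out_dims <- do.call(pmax, dims_list)
  }
  res <- function(vol, frame) {
    if (is.null(vol)) NULL
    else resample_to_frame(vol, frame, out_spacing, out_dims,
                           interpolation, fill)
  }
  list(ct = res(ct_vol, frame_ct),
       mr = res(mr_vol, frame_mr),
       transform = cross_modality_transform(frame_ct, frame_mr),
       frames = list(ct = frame_ct, mr = frame_mr))
}

#' Fused mid-slice overlays of two co-registered volumes
#'
#' Writes the mid-axial, mid-coronal and mid-sagittal slices of two
#' volumes on the same grid as fused PNG images. In `"blend"` mode the
#' first volume is shown in magenta and the second in green (grey where
#' they agree); `"checker"` mode alternates blocks of the two images.
#' Each volume is normalised by its own intensity range, so the fusion is
#' deterministic.
#'
#' @param a,b [image_volume()]s on identical grids.
#' @param prefix output path prefix; `_axial.png`, `_coronal.png`,
#'   `_sagittal.png` are appended.
#' @param mode `"blend"` or `"checker"`.
#' @param checker_size checker block size in voxels.
#' @return (invisibly) list with the written `paths` and the fused RGB
#'   `slices`.
#' @export
overlay_slices <- function(a, b, prefix, mode = c("blend", "checker"),
                           checker_size = 16L) {
  stopifnot(inherits(a, "image_volume"), inherits(b, "image_volume"))
  mode <- match.arg(mode)
  # NIfTI sforms are stored in single precision, so allow that much slack
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-4)
    stop_input("overlay requires two volumes on the identical grid")
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) array(0, dim = dim(x)) else (x - r[1]) / diff(r)
  }
  an <- norm01(a$data); bn <- norm01(b$data)
  d <- dim(an)
  mid <- pmax(1L, as.integer(round((d + 1) / 2)))
  slices <- list(axial = list(an[, , mid[3]], bn[, , mid[3]]),
                 coronal = list(an[, mid[2], ], bn[, mid[2], ]),
                 sagittal = list(an[mid[1], , ], bn[mid[1], , ]))
  paths <- character(0)
  fused <- list()
  for (nm in names(slices)) {
    sa <- slices[[nm]][[1]]; sb <- slices[[nm]][[2]]
    if (mode == "blend") {
      rgb <- array(0, dim = c(dim(sa), 3L))
      rgb[, , 1] <- sa; rgb[, , 2] <- sb; rgb[, , 3] <- sa
    } else {
      blocks <- (floor(row(sa) / checker_size) +
                   floor(col(sa) / checker_size)) %% 2
      mixed <- ifelse(blocks == 0, sa, sb)
      rgb <- array(rep(mixed, 3L), dim = c(dim(sa), 3L))
    }
    # PNG rows run top-to-bottom; transpose so image x runs along width
    rgb <- aperm(rgb, c(2L, 1L, 3L))[dim(rgb)[2]:1, , , drop = FALSE]
    path <- paste0(prefix, "_", nm, ".png")
    png::writePNG(rgb, path)
    paths <- c(paths, path)
    fused[[nm]] <- rgb
  }
  invisible(list(paths = paths, slices = fused))
}
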
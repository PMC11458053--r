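# Small deterministic volume with a smooth ramp plus a bright blob, useful
# for interpolation checks.
ramp_volume <- function(dims = c(24, 20, 16), spacing = 1) {
  idx <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                     k = 0:(dims[3] - 1))
  vals <- idx$i + 2 * idx$j + 3 * idx$k
  image_volume(array(vals, dim = dims), spacing = rep(spacing, 3),
               origin = -spacing * (dims - 1) / 2)
}

# A frame whose axes equal the world axes, centred at `origin`.
identity_frame <- function(origin = c(0, 0, 0), tilt = 0) {
  m <- rbind(left_anterior = origin + c(10, -5, 0),
             left_posterior = origin + c(10, 5, 0),
             right_anterior = origin + c(-10, -5, 0),
             right_posterior = origin + c(-10, 5, 0))
  build_lscc_frame(m, tilt_degrees = tilt)
}

test_that("identity resample on the matching grid is lossless", {
  vol <- ramp_volume()
  out <- resample_to_frame(vol, identity_frame(), out_spacing = 1,
                           out_dims = dim(vol$data))
  inner <- out$data[2:23, 2:19, 2:15]
  expect_equal(inner, vol$data[2:23, 2:19, 2:15], tolerance = 1e-10)
})

test_that("a pure translation moves a delta spike by the integer offset", {
  dims <- c(21, 21, 21)
  arr <- array(0, dims); arr[11, 11, 11] <- 1
  vol <- image_volume(arr, spacing = c(1, 1, 1), origin = -c(10, 10, 10))
  # frame centred 3 voxels along +x: the spike should land 3 voxels lower
  out <- resample_to_frame(vol, identity_frame(origin = c(3, 0, 0)),
                           out_spacing = 1, out_dims = dims)
  expect_equal(which(out$data == max(out$data), arr.ind = TRUE)[1, ],
               c(8, 11, 11), ignore_attr = TRUE)
  expect_equal(max(out$data), 1, tolerance = 1e-10)
})

test_that("rotate + inverse resample round-trip stays within the NN-oracle bound", {
  spec <- tiny_scene_spec()
  vol <- rasterize_phantom(spec, "MR", margin = 2)
  truth <- generate_landmark_truth(spec)
  frame <- build_lscc_frame(truth$MR$lscc, tilt_degrees = 20)

  fwd <- resample_to_frame(vol, frame, out_spacing = 0.3,
                           interpolation = "trilinear")
  # resample back: the forward output's world *is* frame space, so a frame
  # with the inverse pose brings it home
  inv <- invert_transform(frame_to_world_transform(frame))
  back_frame <- build_lscc_frame(
    structure(transform_points(inv, unclass(truth$MR$lscc)),
              dimnames = dimnames(unclass(truth$MR$lscc))),
    tilt_degrees = 20)
  back <- resample_to_frame(fwd, back_frame, out_spacing = 0.3,
                            out_dims = dim(vol$data))
  # compare on an interior core (the round trip fills the border)
  d <- dim(vol$data); core <- lapply(d, function(n) 8:(n - 8))
  got <- back$data[core[[1]], core[[2]], core[[3]]]
  ref <- vol$data[core[[1]], core[[2]], core[[3]]]
  mae_tri <- mean(abs(got - ref))

  # nearest-neighbour oracle on the same phantom bounds the interpolation
  # error scale: trilinear should do no worse than twice the NN error
  fwd_nn <- resample_to_frame(vol, frame, out_spacing = 0.3,
                              interpolation = "nearest")
  back_nn <- resample_to_frame(fwd_nn, back_frame, out_spacing = 0.3,
                               out_dims = dim(vol$data),
                               interpolation = "nearest")
  got_nn <- back_nn$data[core[[1]], core[[2]], core[[3]]]
  mae_nn <- mean(abs(got_nn - ref))
  expect_gt(mae_nn, 0)
  expect_lt(mae_tri, 2 * mae_nn)
  # and the output range never exceeds the input range under trilinear
  expect_gte(min(fwd$data), min(vol$data) * 0)
  expect_lte(max(fwd$data), max(vol$data) + 1e-9)
})

test_that("co-registration of an exact rigid copy recovers the motion", {
  m <- random_landmark_matrix(jitter = 0.2, motion = rigid_transform())
  set <- as_set <- lscc_landmark_set(m["left_anterior", ],
                                     m["left_posterior", ],
                                     m["right_anterior", ],
                                     m["right_posterior", ])
  # identical landmarks: identity cross transform
  res0 <- coregister_pair(NULL, set, NULL, set)
  expect_lt(max(abs(as_homogeneous(res0$transform) - diag(4))), 1e-10)

  set.seed(61)
  motion <- random_rigid()
  m2 <- transform_points(motion, m); rownames(m2) <- rownames(m)
  res <- coregister_pair(NULL, m, NULL, m2)
  expect_lt(max(abs(as_homogeneous(res$transform) -
                      as_homogeneous(motion))), 1e-8)
  # symmetry: swapping the modalities inverts the transform
  res_sw <- coregister_pair(NULL, m2, NULL, m)
  expect_lt(max(abs(as_homogeneous(res_sw$transform) -
                      as_homogeneous(invert_transform(res$transform)))),
            1e-10)
})

test_that("landmark jitter propagates to probe TRE like a Monte-Carlo oracle", {
  set.seed(65)
  sigma <- 0.1
  m <- random_landmark_matrix(jitter = 0, motion = rigid_transform())
  probes <- rbind(c(33, 0, 8), c(-33, 0, 8))
  jitter_tre <- function(builder) {
    replicate(300, {
      mj1 <- m + matrix(rnorm(12, 0, sigma), 4, 3)
      mj2 <- m + matrix(rnorm(12, 0, sigma), 4, 3)
      rownames(mj1) <- rownames(mj2) <- rownames(m)
      builder(mj1, mj2)
    })
  }
  # implementation path: coregister_pair's cross transform
  impl <- jitter_tre(function(a, b) {
    tr <- coregister_pair(NULL, a, NULL, b)$transform
    mean(sqrt(rowSums((transform_points(tr, probes) - probes)^2)))
  })
  # oracle path: step-by-step frames and homogeneous matrices only
  orac <- jitter_tre(function(a, b) {
    fa <- oracle_frame(a); fb <- oracle_frame(b)
    ha <- diag(4); ha[1:3, 1:3] <- fa$rotation; ha[1:3, 4] <- fa$origin
    hb <- diag(4); hb[1:3, 1:3] <- fb$rotation; hb[1:3, 4] <- fb$origin
    moved <- homogeneous_apply(hb %*% solve(ha), probes)
    mean(sqrt(rowSums((moved - probes)^2)))
  })
  expect_gt(mean(impl), 0)
  expect_equal(mean(impl), mean(orac), tolerance = 0.1)
  # TRE grows with sigma
  sigma <- 0.3
  impl_big <- jitter_tre(function(a, b) {
    tr <- coregister_pair(NULL, a, NULL, b)$transform
    mean(sqrt(rowSums((transform_points(tr, probes) - probes)^2)))
  })
  expect_gt(mean(impl_big), mean(impl))
})

test_that("overlays are written with the slice geometry", {
  vol <- ramp_volume(c(16, 14, 12))
  prefix <- withr::local_tempfile()
  ov <- overlay_slices(vol, vol, prefix)
  expect_true(all(file.exists(ov$paths)))
  # a = b: fused magenta/green equals grey of the common image
  ax <- ov$slices$axial
  expect_equal(ax[, , 1], ax[, , 2], tolerance = 1e-12)
  expect_equal(dim(ax)[1:2], c(14, 16))  # rows = y, cols = x for axial

  # checker fusion of inverted images alternates blocks
  inv <- image_volume(max(vol$data) - vol$data, affine = vol$affine)
  ov2 <- overlay_slices(vol, inv, withr::local_tempfile(), mode = "checker",
                        checker_size = 4L)
  ch <- ov2$slices$axial[, , 1]
  expect_gt(stats::sd(ch), 0)

  other <- ramp_volume(c(16, 14, 10))
  expect_error(overlay_slices(vol, other, prefix), "identical grid")
})

test_that("NIfTI volumes round-trip through RAS with the LPS affine preserved", {
  vol <- ramp_volume(c(10, 9, 8), spacing = 0.5)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, path)
  back <- read_nifti_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-4)
  expect_error(read_nifti_volume(withr::local_tempfile(fileext = ".nii")),
               "not found")
})
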
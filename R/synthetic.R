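# Evaluate code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so simulation helpers do not disturb the
# session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of the synthetic temporal-bone study
#'
#' Describes a bilateral inner-ear geometry and the observation process of
#' a landmark-selection study: `n_patients` subjects, each imaged in CT
#' and MR with a modality-specific rigid pose, landmarks selected by
#' `n_raters` raters twice each with Gaussian selection jitter, and every
#' selection quantized to the modality's voxel grid.
#'
#' Defaults emulate the acquisition the coordinate system targets: 20
#' patients, cone-beam CT at 0.15 mm isotropic and T2 MR at
#' 0.2604 x 0.2604 x 0.3 mm, three raters with two attempts, a canal
#' plane tilted 20 degrees from the horizontal, a lateral-canal arc radius
#' of 3.2 mm and an inter-ear separation of 66 mm. Selection jitter is
#' anisotropic with larger spread along x, mirroring the observed
#' along-canal uncertainty of the junction landmarks.
#'
#' @param n_patients number of subjects.
#' @param canal_arc_radius radius of the lateral-canal arc, mm; the
#'   anterior and posterior junction landmarks sit at the ends of its
#'   diameter along y.
#' @param inter_ear_separation distance between left and right canal
#'   centres, mm.
#' @param plane_tilt_deg tilt of the canal plane relative to the world
#'   horizontal, degrees. The standard +20 degree frame rotation restores
#'   the upright orientation for a subject in canonical pose.
#' @param sscc_arc_radius radius of the superior-canal arc, mm; its apex
#'   provides the held-out probe landmark on each side.
#' @param canal_tube_radius lumen tube radius used by the phantom
#'   rasterizer, mm.
#' @param jitter_sd per-rater selection jitter: a named list of per-axis
#'   standard deviations (mm); names are the rater ids.
#' @param patient_translation_sd,patient_rotation_sd head-positioning
#'   variability across patients: per-axis translation SD (mm) and
#'   per-axis rotation SD (degrees).
#' @param anatomy_sd per-patient anatomical variability (SDs, mm) of the
#'   canal arc radius, inter-ear separation, superior-canal arc radius
#'   and superior-canal apex anterior-posterior position. Without
#'   between-subject anatomical variance, agreement statistics computed
#'   across patients in *frame* coordinates (where the head pose is
#'   normalised away) would be meaningless.
#' @param modality_pose named list of [rigid_transform()]s giving each
#'   modality's scanner pose relative to the canonical anatomy.
#' @param spacing named list of per-modality voxel spacings, mm.
#' @param n_attempts selections per rater per landmark.
#' @param seed integer seed governing all draws.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 20,
                         canal_arc_radius = 3.2,
                         inter_ear_separation = 66,
                         plane_tilt_deg = 20,
                         sscc_arc_radius = 3.4,
                         canal_tube_radius = 0.7,
                         jitter_sd = list(A = c(0.12, 0.08, 0.08),
                                          B = c(0.08, 0.06, 0.06),
                                          C = c(0.12, 0.09, 0.08)),
                         patient_translation_sd = 2,
                         patient_rotation_sd = 2,
                         anatomy_sd = list(canal_arc_radius = 0.2,
                                           inter_ear_separation = 2.5,
                                           sscc_arc_radius = 0.25,
                                           sscc_apex_y = 0.5),
                         modality_pose = list(
                           CT = rigid_transform(),
                           MR = rigid_transform(
                             rotation_about_axis(c(0, 0, 1), 3) %*%
                               rotation_about_axis(c(1, 0, 0), -4) %*%
                               rotation_about_axis(c(0, 1, 0), 2),
                             c(1.5, -2.5, 1.0))),
                         spacing = list(CT = c(0.15, 0.15, 0.15),
                                        MR = c(0.2604, 0.2604, 0.3)),
                         n_attempts = 2,
                         seed = 1) {
  if (canal_arc_radius <= 0 || inter_ear_separation <= 0 ||
      sscc_arc_radius <= 0 || canal_tube_radius <= 0)
    stop_input("phantom radii and separations must be positive")
  if (!is.finite(plane_tilt_deg)) stop_input("plane_tilt_deg must be finite")
  if (any(unlist(jitter_sd) < 0)) stop_input("jitter sd must be >= 0")
  if (patient_translation_sd < 0 || patient_rotation_sd < 0)
    stop_input("patient pose sd must be >= 0")
  if (any(unlist(anatomy_sd) < 0)) stop_input("anatomy sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 canal_arc_radius = canal_arc_radius,
                 inter_ear_separation = inter_ear_separation,
                 plane_tilt_deg = plane_tilt_deg,
                 sscc_arc_radius = sscc_arc_radius,
                 canal_tube_radius = canal_tube_radius,
                 jitter_sd = jitter_sd,
                 patient_translation_sd = patient_translation_sd,
                 patient_rotation_sd = patient_rotation_sd,
                 anatomy_sd = anatomy_sd,
                 modality_pose = modality_pose,
                 spacing = spacing,
                 n_attempts = as.integer(n_attempts),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Canonical (pre-tilt, pre-pose) landmark geometry: the canal plane is
# horizontal, ears mirror-symmetric about x = 0.
canonical_truth_points <- function(spec) {
  a <- spec$canal_arc_radius
  s <- spec$inter_ear_separation / 2
  lscc <- rbind(left_anterior  = c(s, -a, 0),
                left_posterior = c(s,  a, 0),
                right_anterior = c(-s, -a, 0),
                right_posterior = c(-s,  a, 0))
  apex_z <- 0.5 + spec$sscc_arc_radius   # superior-canal apex, off-plane
  apex_y <- if (is.null(spec$sscc_apex_y)) 0 else spec$sscc_apex_y
  sscc <- rbind(left_superior_sscc  = c(s, apex_y, apex_z),
                right_superior_sscc = c(-s, apex_y, apex_z))
  colnames(lscc) <- colnames(sscc) <- c("x", "y", "z")
  list(lscc = lscc, sscc = sscc)
}

# The canal plane is tilted by -plane_tilt_deg about +x so that the
# standard +tilt frame rotation brings the frame's z axis back to the
# world vertical for a subject in canonical pose.
tilt_transform <- function(spec) {
  rigid_transform(rotation_about_axis(c(1, 0, 0), -spec$plane_tilt_deg))
}

#' Ground-truth landmark positions per modality
#'
#' Generates the exact landmark geometry of one subject: four LSCC
#' landmarks lying exactly on the tilted canal plane, mirror-symmetric
#' about the mid-sagittal plane, plus the two superior-canal (SSCC) apex
#' probes off the plane; each modality's copy is the canonical anatomy
#' moved by that modality's pose (optionally composed with a per-patient
#' pose).
#'
#' @param spec a [phantom_spec()].
#' @param patient_pose optional extra [rigid_transform()] applied before
#'   the modality pose (head positioning of one subject).
#' @return named list per modality, each with `lscc` (an
#'   [lscc_landmark_set()]) and `sscc` (2 x 3 matrix with SSCC labels).
#' @export
generate_landmark_truth <- function(spec, patient_pose = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- canonical_truth_points(spec)
  tiltT <- tilt_transform(spec)
  out <- list()
  for (mod in names(spec$modality_pose)) {
    pose <- spec$modality_pose[[mod]]
    if (!is.null(patient_pose)) pose <- compose_transforms(pose, patient_pose)
    total <- compose_transforms(pose, tiltT)
    lscc <- transform_points(total, pts$lscc)
    sscc <- transform_points(total, pts$sscc)
    rownames(sscc) <- rownames(pts$sscc)
    out[[mod]] <- list(
      lscc = lscc_landmark_set(lscc["left_anterior", ],
                               lscc["left_posterior", ],
                               lscc["right_anterior", ],
                               lscc["right_posterior", ]),
      sscc = sscc,
      pose = total)
  }
  out
}

# Draw one patient's anatomy: the base spec with sizes perturbed by the
# anatomical SDs (clamped away from degenerate values).
random_patient_anatomy <- function(spec) {
  sdev <- function(nm) {
    v <- spec$anatomy_sd[[nm]]
    if (is.null(v)) 0 else v
  }
  spec$canal_arc_radius <- max(0.5, spec$canal_arc_radius +
                                 stats::rnorm(1, 0, sdev("canal_arc_radius")))
  spec$inter_ear_separation <-
    max(4 * spec$canal_arc_radius, spec$inter_ear_separation +
          stats::rnorm(1, 0, sdev("inter_ear_separation")))
  spec$sscc_arc_radius <- max(0.5, spec$sscc_arc_radius +
                                stats::rnorm(1, 0, sdev("sscc_arc_radius")))
  spec$sscc_apex_y <- stats::rnorm(1, 0, sdev("sscc_apex_y"))
  spec
}

# Draw a small random rigid motion for one patient's head positioning.
random_patient_pose <- function(spec) {
  ang <- stats::rnorm(3, 0, spec$patient_rotation_sd)
  R <- rotation_about_axis(c(0, 0, 1), ang[3]) %*%
    rotation_about_axis(c(0, 1, 0), ang[2]) %*%
    rotation_about_axis(c(1, 0, 0), ang[1])
  rigid_transform(R, stats::rnorm(3, 0, spec$patient_translation_sd))
}

quantize_to_grid <- function(p, spacing) {
  round(sweep(p, 2L, spacing, "/")) * rep(spacing, each = nrow(p))
}

#' Simulate a full landmark-selection study
#'
#' Draws the complete observation table of the synthetic study: for each
#' patient a random head pose, then for every modality, rater and attempt
#' each landmark position is the ground truth plus zero-mean Gaussian
#' selection jitter (per-rater, per-axis SD), quantized to the modality's
#' voxel grid (nearest voxel), so repeat-selection differences are
#' multiples of the voxel size. Deterministic given the seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed` when given.
#' @param quantize set `FALSE` to skip voxel quantization (exact
#'   continuous selections).
#' @param include_sscc include the SSCC probe landmarks (default `TRUE`).
#' @param return_truth attach the per-patient ground-truth geometry (a
#'   list of [generate_landmark_truth()] results, named by patient) as
#'   `attr(, "truth")`.
#' @return a landmark data.frame (columns as [read_landmark_table()]),
#'   with the seed recorded in `attr(, "seed")`.
#' @export
simulate_observations <- function(spec, seed = spec$seed, quantize = TRUE,
                                  include_sscc = TRUE,
                                  return_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  raters <- names(spec$jitter_sd)
  labels <- if (include_sscc) ALL_LABELS else LSCC_LABELS
  modalities <- names(spec$modality_pose)
  nlab <- length(labels)
  n_rows <- spec$n_patients * length(modalities) * length(raters) *
    spec$n_attempts * nlab
  coords <- matrix(NA_real_, n_rows, 3L)
  meta <- vector("list", n_rows / nlab)
  truths <- vector("list", spec$n_patients)
  names(truths) <- sprintf("P%02d", seq_len(spec$n_patients))
  with_seed(seed, {
    at <- 0L; blk <- 0L
    for (ip in seq_len(spec$n_patients)) {
      pat <- sprintf("P%02d", ip)
      anat <- random_patient_anatomy(spec)
      pose <- random_patient_pose(spec)
      truth <- generate_landmark_truth(anat, patient_pose = pose)
      truths[[ip]] <- truth
      for (mod in modalities) {
        true_pts <- rbind(unclass(truth[[mod]]$lscc), truth[[mod]]$sscc)
        true_pts <- true_pts[labels, , drop = FALSE]
        sp <- spec$spacing[[mod]]
        for (rater in raters) {
          sd3 <- rep(as.numeric(spec$jitter_sd[[rater]]), length.out = 3L)
          for (att in seq_len(spec$n_attempts)) {
            jit <- matrix(stats::rnorm(3L * nlab, 0,
                                       rep(sd3, each = nlab)), ncol = 3L)
            obs <- true_pts + jit
            if (quantize) obs <- quantize_to_grid(obs, sp)
            coords[at + seq_len(nlab), ] <- obs
            at <- at + nlab
            blk <- blk + 1L
            meta[[blk]] <- c(pat, mod, rater, att)
          }
        }
      }
    }
  })
  meta <- do.call(rbind, meta)
  out <- data.frame(
    patient_id = rep(meta[, 1L], each = nlab),
    modality = rep(meta[, 2L], each = nlab),
    rater_id = rep(meta[, 3L], each = nlab),
    attempt = rep(as.integer(meta[, 4L]), each = nlab),
    label = rep(labels, times = nrow(meta)),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  if (return_truth) attr(out, "truth") <- truths
  out
}

#' Rasterize the synthetic inner-ear phantom into a modality grid
#'
#' Renders both ears into a voxel volume: each lateral canal is a
#' half-torus arc ending exactly at the anterior/posterior junction
#' landmarks, the vestibule is an ellipsoid whose surface passes through
#' those junctions, and each superior canal is a vertical arc whose apex
#' is the SSCC probe landmark. CT-like volumes show dark fluid within
#' bright bone; MR-like volumes show bright fluid on a dark background
#' (inverted contrast ordering).
#'
#' @param spec a [phantom_spec()].
#' @param modality `"CT"` or `"MR"` (selects spacing, pose and contrast).
#' @param dims optional output dimensions (voxels); the default fits the
#'   whole geometry plus `margin`.
#' @param margin padding around the geometry, mm.
#' @param patient_pose optional extra rigid pose, as in
#'   [generate_landmark_truth()].
#' @return an [image_volume()] whose affine places the phantom at its
#'   world (posed) coordinates.
#' @export
rasterize_phantom <- function(spec, modality = "CT", dims = NULL,
                              margin = 4, patient_pose = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  mod <- toupper(modality)
  if (!mod %in% names(spec$spacing))
    stop_input("no spacing defined for modality '", modality, "'")
  sp <- spec$spacing[[mod]]
  truth <- generate_landmark_truth(spec, patient_pose = patient_pose)[[mod]]
  total <- truth$pose

  a <- spec$canal_arc_radius
  s <- spec$inter_ear_separation / 2
  as_ <- spec$sscc_arc_radius
  tube <- spec$canal_tube_radius
  extent <- c(s + a + tube, a + as_ + tube, as_ + 0.5 + tube)

  scene <- rbind(unclass(truth$lscc), truth$sscc)
  corners <- as.matrix(expand.grid(x = c(-1, 1) * extent[1],
                                   y = c(-1, 1) * extent[2],
                                   z = c(-extent[3], extent[3])))
  corners <- transform_points(total, corners)
  lo <- apply(corners, 2L, min) - margin
  hi <- apply(corners, 2L, max) + margin
  if (is.null(dims)) {
    dims <- ceiling((hi - lo) / sp) + 1L
  } else {
    dims <- as.integer(dims)
    need <- ceiling((hi - lo) / sp) + 1L
    if (any(dims < need))
      stop_input("volume of dims [", paste(dims, collapse = ", "),
                 "] too small to contain the phantom geometry (needs [",
                 paste(need, collapse = ", "), "])")
  }
  origin <- lo

  # voxel centre world coordinates, then back to canonical coordinates
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  world <- sweep(sweep(idx, 2L, sp, "*"), 2L, origin, "+")
  p0 <- transform_points(invert_transform(total), world)

  fluid <- rep(FALSE, nrow(p0))
  for (side in c(1, -1)) {
    cc <- c(side * s, 0, 0)
    q <- sweep(p0, 2L, cc)
    # lateral canal: arc of the ring of radius a in the canal plane,
    # spanning the lateral half (|angle from lateral direction| <= 90 deg)
    rho <- sqrt(q[, 1]^2 + q[, 2]^2)
    lateral_half <- side * q[, 1] >= 0
    d_arc <- sqrt((rho - a)^2 + q[, 3]^2)
    d_end <- pmin(sqrt(q[, 1]^2 + (q[, 2] - a)^2 + q[, 3]^2),
                  sqrt(q[, 1]^2 + (q[, 2] + a)^2 + q[, 3]^2))
    d_lat <- ifelse(lateral_half, d_arc, d_end)
    # vestibule: ellipsoid through the two junction landmarks
    inside_vest <- (q[, 1] / 1.6)^2 + (q[, 2] / a)^2 + (q[, 3] / 1.4)^2 <= 1
    # superior canal: arc in the sagittal plane of this ear, apex up
    qs <- q; qs[, 3] <- qs[, 3] - 0.5
    rho_s <- sqrt(qs[, 2]^2 + qs[, 3]^2)
    upper <- qs[, 3] >= 0
    d_sup_arc <- sqrt((rho_s - as_)^2 + qs[, 1]^2)
    d_sup_end <- pmin(sqrt(qs[, 1]^2 + (qs[, 2] - as_)^2 + qs[, 3]^2),
                      sqrt(qs[, 1]^2 + (qs[, 2] + as_)^2 + qs[, 3]^2))
    d_sup <- ifelse(upper, d_sup_arc, d_sup_end)
    fluid <- fluid | d_lat <= tube | inside_vest | d_sup <= tube
  }

  vals <- if (mod == "CT") ifelse(fluid, 100, 800) else ifelse(fluid, 900, 50)
  vol <- array(vals, dim = dims)
  image_volume(vol, spacing = sp, origin = origin)
}
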
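# Independent oracles, each coded from first principles so they share no
# code path with the implementation they check.

# --- random geometry -------------------------------------------------------

# Random rigid motion within the head-pose range: rotations up to
# `max_deg` per axis (scans are acquired roughly upright, so the
# right/left ordering of the landmarks is preserved) and translations up
# to `max_mm`.
random_rigid <- function(max_deg = 30, max_mm = 40) {
  ang <- runif(3, -max_deg, max_deg)
  R <- rotation_about_axis(c(1, 0, 0), ang[1]) %*%
    rotation_about_axis(c(0, 1, 0), ang[2]) %*%
    rotation_about_axis(c(0, 0, 1), ang[3])
  rigid_transform(R, runif(3, -max_mm, max_mm))
}

# Random LSCC-like landmark set: a bilateral configuration with jitter,
# moved by a random rigid motion.
random_landmark_matrix <- function(jitter = 0.3, motion = random_rigid()) {
  base <- rbind(left_anterior  = c(33, -3.2, 0),
                left_posterior = c(33, 3.2, 0),
                right_anterior = c(-33, -3.2, 0),
                right_posterior = c(-33, 3.2, 0))
  pts <- base + matrix(rnorm(12, 0, jitter), 4, 3)
  out <- transform_points(motion, pts)
  rownames(out) <- rownames(base)
  out
}

random_landmark_set <- function(...) {
  m <- random_landmark_matrix(...)
  lscc_landmark_set(m["left_anterior", ], m["left_posterior", ],
                    m["right_anterior", ], m["right_posterior", ])
}

# --- step-by-step frame oracle --------------------------------------------

# Plane via eigen-decomposition of the covariance matrix (not SVD),
# explicit projection, explicit Gram-Schmidt, and the tilt applied with
# the closed-form 2-D rotation in the (y0, z0) plane rather than a
# Rodrigues matrix.
oracle_frame <- function(m, tilt_degrees = 20) {
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  ev <- eigen(t(cm) %*% cm, symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0 || (nrm[3] == 0 && nrm[2] < 0)) nrm <- -nrm
  proj <- m - (cm %*% nrm) %*% t(nrm)
  origin <- colMeans(proj)
  lmid <- (proj["left_anterior", ] + proj["left_posterior", ]) / 2
  rmid <- (proj["right_anterior", ] + proj["right_posterior", ]) / 2
  xh <- (lmid - rmid) / sqrt(sum((lmid - rmid)^2))
  amid <- (proj["left_anterior", ] + proj["right_anterior", ]) / 2
  pmid <- (proj["left_posterior", ] + proj["right_posterior", ]) / 2
  y0 <- (pmid - amid) - sum((pmid - amid) * xh) * xh
  y0 <- y0 / sqrt(sum(y0^2))
  z0 <- c(xh[2] * y0[3] - xh[3] * y0[2],
          xh[3] * y0[1] - xh[1] * y0[3],
          xh[1] * y0[2] - xh[2] * y0[1])
  th <- tilt_degrees * pi / 180
  yh <- cos(th) * y0 + sin(th) * z0
  zh <- cos(th) * z0 - sin(th) * y0
  list(origin = origin, rotation = cbind(x = xh, y = yh, z = zh))
}

# Angle via the chord, which stays accurate for tiny angles (acos of the
# dot product bottoms out around sqrt(machine eps)).
angle_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  2 * asin(min(1, sqrt(sum((u - v)^2)) / 2))
}

# Largest axis angle (rad) and origin distance between two frames.
frame_discrepancy <- function(f1, f2) {
  ang <- max(sapply(1:3, function(i)
    angle_between(f1$rotation[, i], f2$rotation[, i])))
  c(angle = ang, origin = sqrt(sum((f1$origin - f2$origin)^2)))
}

# --- homogeneous-matrix transform oracle -----------------------------------

homogeneous_apply <- function(m4, p) {
  h <- cbind(p, 1) %*% t(m4)
  h[, 1:3, drop = FALSE]
}

# --- brute-force ICC oracle -------------------------------------------------

# Two-way ANOVA mean squares from explicit double loops over the layout,
# then the absolute-agreement ICC formulas typed directly.
oracle_icc <- function(m, form = "single") {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  r <- if (form == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
  p <- pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(r = r, p = p, msr = msr, msc = msc, mse = mse)
}

# --- small simulated studies ------------------------------------------------

small_spec <- function(n_patients = 4, seed = 1, ...) {
  phantom_spec(n_patients = n_patients, seed = seed, ...)
}

# Phantom spec with a reduced scene so rasterized volumes stay small.
tiny_scene_spec <- function(seed = 1, ...) {
  phantom_spec(inter_ear_separation = 14, seed = seed, ...)
}
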
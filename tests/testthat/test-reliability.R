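# A deterministic toy study: 5 patients, 2 modalities, 3 raters, 2
# attempts, built directly so every expected value can be reasoned out.
toy_study <- function(jitter = 0, seed = 1, raters = c("A", "B", "C")) {
  set.seed(seed)
  rows <- list()
  for (p in 1:5) {
    truth <- random_landmark_matrix(jitter = 0, motion = rigid_transform(
      translation = c(0, 0, 2 * p)))
    for (mod in c("CT", "MR")) for (r in raters) for (att in 1:2) {
      obs <- truth + matrix(rnorm(12, 0, jitter), 4, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", p), modality = mod, rater_id = r,
        attempt = att, label = rownames(truth),
        x = obs[, 1], y = obs[, 2], z = obs[, 3])
    }
  }
  do.call(rbind, rows)
}

test_that("identical attempts give zero differences and r = 1", {
  tab <- toy_study(jitter = 0)
  rep <- intra_rater_report(tab)
  expect_true(all(rep$mean == 0))
  expect_true(all(rep$max == 0))
  expect_true(all(rep$r == 1))
  expect_true(all(rep$degenerate[rep$coordinate %in% c("x", "y")] |
                    rep$r[rep$coordinate %in% c("x", "y")] == 1))
})

test_that("a single one-voxel CT discrepancy shows up as max = 0.15 mm", {
  tab <- toy_study(jitter = 0)
  i <- which(tab$modality == "CT" & tab$rater_id == "A" &
               tab$attempt == 2 & tab$label == "left_anterior" &
               tab$patient_id == "P03")
  tab$x[i] <- tab$x[i] + 0.15
  rep <- intra_rater_report(tab)
  row <- rep[rep$modality == "CT" & rep$rater_id == "A" &
               rep$label == "left_anterior" & rep$coordinate == "x", ]
  expect_equal(row$max, 0.15)
  expect_equal(row$mean, 0.15 / 5)   # one of five patients differs
  untouched <- rep[rep$modality == "MR" & rep$rater_id == "A" &
                     rep$coordinate == "x", ]
  expect_true(all(untouched$max == 0))
})

test_that("missing attempts are reported with the patient", {
  tab <- toy_study(jitter = 0)
  tab <- tab[!(tab$patient_id == "P02" & tab$rater_id == "B" &
                 tab$attempt == 2 & tab$label == "left_anterior"), ]
  expect_error(intra_rater_report(tab), "P02")
})

test_that("intra-rater mean |difference| matches the folded-normal law", {
  # difference of two attempts ~ N(0, 2 sigma^2); E|d| = 2 sigma / sqrt(pi)
  sigma <- 0.1
  spec <- phantom_spec(n_patients = 20, seed = 5,
                       jitter_sd = list(A = rep(sigma, 3),
                                        B = rep(sigma, 3),
                                        C = rep(sigma, 3)))
  means <- replicate(30, {
    tab <- simulate_observations(spec, seed = sample.int(1e6, 1),
                                 quantize = FALSE, include_sscc = FALSE)
    rep <- intra_rater_report(tab)
    mean(rep$mean)
  })
  expect_equal(mean(means), 2 * sigma / sqrt(pi), tolerance = 0.05)
})

test_that("worst rater pair equals exhaustive enumeration over all pairs", {
  set.seed(33)
  tab <- toy_study(jitter = 0.1, seed = 7)
  rep <- inter_rater_report(tab)
  # oracle: enumerate the three pairs by hand for a few cells
  med <- stats::aggregate(cbind(x, y, z) ~ patient_id + modality +
                            rater_id + label, data = tab, FUN = mean)
  for (row_i in sample(nrow(rep), 6)) {
    row <- rep[row_i, ]
    pats <- sort(unique(med$patient_id))
    vals <- sapply(c("A", "B", "C"), function(r) {
      g <- med[med$modality == row$modality & med$label == row$label &
                 med$rater_id == r, ]
      g[match(pats, g$patient_id), row$coordinate]
    })
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    rs <- sapply(pairs, function(pr)
      oracle_icc(cbind(vals[, pr[1]], vals[, pr[2]]))$r)
    expect_equal(row$r, min(rs), tolerance = 1e-10)
    expect_equal(row$pair,
                 paste(pairs[[which.min(rs)]], collapse = "|"))
  }
})

test_that("an offset rater is the worst pair with the constructed mean difference", {
  tab <- toy_study(jitter = 0)
  shift <- tab$rater_id == "C" & tab$modality == "CT"
  tab$x[shift] <- tab$x[shift] + 0.3
  rep <- inter_rater_report(tab)
  xrows <- rep[rep$modality == "CT" & rep$coordinate == "x", ]
  expect_true(all(grepl("C", xrows$pair)))
  expect_true(all(abs(xrows$mean - 0.3) < 1e-12))
  # raters identical -> r = 1, zero differences (MR untouched)
  mr <- rep[rep$modality == "MR", ]
  expect_true(all(mr$mean == 0) && all(mr$r == 1))
})

test_that("TRE computes Euclidean distances and refuses frame landmarks", {
  a <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(target_registration_error(a, a)$distances, c(0, 0))
  tre <- target_registration_error(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
  expect_equal(tre$mean, 5)
  expect_equal(tre$max, 5)
  expect_error(target_registration_error(a, a, labels = c(
    "left_anterior", "left_superior_sscc")),
    "independent of the frame")
  expect_error(target_registration_error(a, rbind(c(0, 0, 0))), "length")

  # invariance under a common rigid motion
  set.seed(39)
  b <- a + matrix(rnorm(6, sd = 0.3), 2, 3)
  t0 <- target_registration_error(a, b)
  motion <- random_rigid(180, 50)
  t1 <- target_registration_error(transform_points(motion, a),
                                  transform_points(motion, b))
  expect_equal(t1$distances, t0$distances, tolerance = 1e-10)
})

test_that("TRE against ground truth matches the known misalignment", {
  set.seed(43)
  m <- random_landmark_matrix(jitter = 0.2)
  f_ct <- build_lscc_frame(m)
  motion <- random_rigid()
  m2 <- transform_points(motion, m); rownames(m2) <- rownames(m)
  # MR landmarks get extra jitter: the frames now disagree slightly
  m2j <- m2 + matrix(rnorm(12, 0, 0.1), 4, 3); rownames(m2j) <- rownames(m)
  f_mr <- build_lscc_frame(m2j)
  probes <- rbind(c(33, 0, 8), c(-33, 0, 8))
  probes_mr <- transform_points(motion, probes)
  got <- target_registration_error(world_to_frame(f_ct, probes),
                                   world_to_frame(f_mr, probes_mr))
  # oracle: map the MR probe back through the ground-truth motion and the
  # CT frame, against the MR frame coordinates
  oracle_d <- sqrt(rowSums((world_to_frame(f_ct, probes) -
                              world_to_frame(f_mr, probes_mr))^2))
  expect_equal(got$distances, oracle_d, tolerance = 1e-12)
  expect_gt(got$mean, 0)
})

test_that("Bland-Altman limits behave and cover ~95% of Gaussian pairs", {
  a <- c(1, 2, 3, 4)
  same <- bland_altman(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(c(same$lower, same$upper), c(0, 0))

  off <- bland_altman(a + 2, a)
  expect_equal(off$mean_difference, 2)
  expect_equal(off$sd, 0)

  set.seed(47)
  x <- rnorm(1e4); y <- x + rnorm(1e4, sd = 0.5)
  ba <- bland_altman(x, y)
  inside <- mean(ba$differences >= ba$lower & ba$differences <= ba$upper)
  expect_equal(inside, 0.95, tolerance = 0.01)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("planarity report is zero for coplanar medians and tracks a lifted landmark", {
  tab <- toy_study(jitter = 0)   # landmarks exactly coplanar
  rep <- planarity_report(tab)
  expect_true(all(rep$mean < 1e-9))
  expect_true(all(rep$max < 1e-9))
  expect_true(all(rep$r == 1))

  # lift one landmark off the plane: the plane fit spreads the offset over
  # all four projections, mostly in z for a near-horizontal plane
  tab2 <- toy_study(jitter = 0)
  lift <- tab2$modality == "CT" & tab2$label == "left_anterior" &
    tab2$patient_id == "P01"
  tab2$z[lift] <- tab2$z[lift] + 0.2
  rep2 <- planarity_report(tab2)
  z_ct <- rep2[rep2$modality == "CT" & rep2$coordinate == "z", ]
  xy_ct <- rep2[rep2$modality == "CT" & rep2$coordinate != "z", ]
  expect_gt(z_ct$mean, 0)
  expect_gt(z_ct$mean, 5 * max(xy_ct$mean))
  mr <- rep2[rep2$modality == "MR", ]
  expect_true(all(mr$mean < 1e-9))
})

test_that("planarity differences equal an explicit normal-equations oracle", {
  set.seed(51)
  tab <- toy_study(jitter = 0.15, seed = 13)
  rep <- planarity_report(tab)
  med <- median_landmarks(tab)
  for (mod in c("CT", "MR")) {
    diffs <- c()
    for (p in sprintf("P%02d", 1:5)) {
      pts <- as.matrix(med[med$modality == mod & med$patient_id == p,
                           c("x", "y", "z")])
      # oracle: plane z-direction via explicit 3x3 normal-equation solve of
      # the homogeneous system (smallest eigenvector of the scatter matrix
      # by inverse iteration)
      ctr <- colMeans(pts); cm <- sweep(pts, 2, ctr)
      S <- t(cm) %*% cm
      v <- c(0, 0, 1)
      for (it in 1:200) {
        v <- solve(S + 1e-12 * diag(3), v); v <- v / sqrt(sum(v^2))
      }
      proj <- pts - (cm %*% v) %*% t(v)
      diffs <- rbind(diffs, abs(pts - proj))
    }
    for (coord in c("x", "y", "z")) {
      ci <- match(coord, c("x", "y", "z"))
      row <- rep[rep$modality == mod & rep$coordinate == coord, ]
      expect_equal(row$mean, mean(diffs[, ci]), tolerance = 1e-8)
      expect_equal(row$max, max(diffs[, ci]), tolerance = 1e-8)
    }
  }
})

test_that("accuracy report recovers zero TRE for perfectly consistent modalities", {
  # MR is an exact rigid copy of CT: frames agree, SSCC coordinates match
  set.seed(55)
  rows <- list()
  motion <- random_rigid()
  for (p in 1:4) {
    m <- random_landmark_matrix(jitter = 0.2,
                                motion = rigid_transform(
                                  translation = c(0, 0, 3 * p)))
    sscc <- rbind(left_superior_sscc = c(33, 0, 8 + 3 * p),
                  right_superior_sscc = c(-33, 0, 8 + 3 * p))
    for (mod in c("CT", "MR")) {
      pts <- rbind(m, sscc)
      if (mod == "MR") pts <- transform_points(motion, pts)
      rownames(pts) <- c(rownames(m), rownames(sscc))
      for (r in c("A", "B", "C")) for (att in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%02d", p), modality = mod, rater_id = r,
          attempt = att, label = rownames(pts),
          x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }
  }
  tab <- do.call(rbind, rows)
  acc <- accuracy_report(tab)
  expect_lt(acc$tre$max, 1e-8)
  expect_true(all(abs(acc$table$mean) < 1e-8))
  expect_true(all(abs(sapply(acc$bland_altman, `[[`,
                             "mean_difference")) < 1e-8))
})
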
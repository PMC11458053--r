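#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Computes ICC(A,1) (single measures) or ICC(A,k) (average measures) from
#' an n subjects x k measurements matrix, following the two-way
#' random-effects, absolute-agreement model of McGraw & Wong. With
#' between-subject mean square `MSR`, between-measurement mean square
#' `MSC` and error mean square `MSE`:
#'
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + \frac{MSC - MSE}{n}}}
#'
#' The p-value tests the null of zero intraclass correlation with
#' `F = MSR / MSE` on (n-1, (n-1)(k-1)) degrees of freedom (for a non-zero
#' null the denominator is the McGraw-Wong linear combination of `MSC` and
#' `MSE` with Satterthwaite degrees of freedom).
#'
#' A matrix with zero total variance (all cells identical) is perfect
#' agreement by construction: the estimate is returned as r = 1 with a
#' `degenerate` flag and p reported as the machine epsilon, rather than
#' the 0/0 `NaN` the formulas would produce.
#'
#' @param ratings numeric n x k matrix, one coordinate of one landmark:
#'   rows are subjects (patients), columns are measurements (raters or
#'   attempts). No missing cells; n >= 2, k >= 2.
#' @param form `"single"` for ICC(A,1) or `"average"` for ICC(A,k).
#' @param null_icc the null hypothesis value for the significance test
#'   (default 0).
#' @return a list of class `icc_result`: `r`, `p`, `form`, `model`,
#'   `F`, `df1`, `df2`, the mean squares, `n`, `k`, and `degenerate`.
#' @references McGraw, K.O. & Wong, S.P. (1996) Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods 1(1).
#' @export
icc_agreement <- function(ratings, form = c("single", "average"),
                          null_icc = 0) {
  form <- match.arg(form)
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop_input("ratings matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop_input("ratings matrix needs >= 2 subjects and >= 2 measurements")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)     # between subjects
  ssc <- n * sum((col_means - grand)^2)     # between measurements
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)            # interaction + error; the
  # subtraction can go fractionally negative in floating point when the
  # residual is exactly zero (e.g. a constant offset between columns)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- sst < n * k * (grand^2 + 1) * 1e-24
  if (degenerate) {
    r <- 1
    Fstat <- Inf; df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    p <- .Machine$double.eps
  } else {
    r <- switch(form,
      single  = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
      average = (msr - mse) / (msr + (msc - mse) / n))
    # F test of H0: ICC = null_icc (absolute agreement)
    if (null_icc == 0) {
      Fstat <- msr / mse
      df1 <- n - 1
      df2 <- (n - 1) * (k - 1)
    } else {
      a <- k * null_icc / (n * (1 - null_icc))
      b <- 1 + k * null_icc * (n - 1) / (n * (1 - null_icc))
      denom <- a * msc + b * mse
      Fstat <- msr / denom
      df1 <- n - 1
      df2 <- denom^2 / ((a * msc)^2 / (k - 1) +
                          (b * mse)^2 / ((n - 1) * (k - 1)))
    }
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }

  structure(list(r = r, p = p, form = form,
                 model = "two-way random effects, absolute agreement",
                 F = Fstat, df1 = df1, df2 = df2,
                 MSR = msr, MSC = msc, MSE = mse, n = n, k = k,
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  label <- if (x$form == "single") "ICC(A,1)" else sprintf("ICC(A,%d)", x$k)
  cat(sprintf("%s = %.4f (p = %.3g; F(%g, %.4g) = %.4g; n = %d, k = %d)%s\n",
              label, x$r, x$p, x$df1, x$df2, x$F, x$n, x$k,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Summary of absolute differences
#'
#' @param differences numeric vector of paired differences (mm); absolute
#'   values are taken.
#' @return list with `mean`, `sd`, `max` of the absolute differences and
#'   `n`.
#' @export
difference_summary <- function(differences) {
  d <- abs(as.numeric(differences))
  if (!length(d) || any(!is.finite(d)))
    stop_input("differences must be a non-empty finite numeric vector")
  list(mean = mean(d), sd = stats::sd(d), max = max(d), n = length(d))
}

# Both ICC forms + difference summary for one ratings matrix built from two
# paired measurement vectors; returns a one-row data.frame chunk.
icc_diff_row <- function(a, b) {
  m <- cbind(a, b)
  single <- icc_agreement(m, "single")
  average <- icc_agreement(m, "average")
  ds <- difference_summary(a - b)
  data.frame(r = single$r, p = single$p,
             r_average = average$r, p_average = average$p,
             mean = ds$mean, sd = ds$sd, max = ds$max, n = ds$n,
             degenerate = single$degenerate)
}

check_complete <- function(observations, n_raters = NULL, n_attempts = 2L,
                           labels = LSCC_LABELS) {
  obs <- observations[observations$label %in% labels, ]
  if (nrow(obs) == 0L) stop_input("no observations for labels ",
                                  paste(labels, collapse = ", "))
  obs
}

#' Intra-rater reliability report
#'
#' For each rater, modality, landmark and coordinate: the ICC over the
#' n-patients x 2-attempts matrix (the two attempts play the role of the
#' k = 2 measurements in the absolute-agreement model) and the mean, SD
#' and maximum of the absolute attempt-to-attempt differences.
#'
#' @param observations a landmark data.frame with exactly 2 attempts per
#'   (patient, modality, rater, landmark).
#' @param labels landmark labels to report (default the four LSCC
#'   landmarks).
#' @return a data.frame with columns `modality`, `rater_id`, `label`,
#'   `coordinate`, `r`, `p` (single-measures ICC, the reported form),
#'   `r_average`, `p_average`, `mean`, `sd`, `max`, `n`.
#' @export
intra_rater_report <- function(observations, labels = LSCC_LABELS) {
  obs <- check_complete(observations, labels = labels)
  out <- list()
  for (mod in sort(unique(obs$modality)))
    for (rater in sort(unique(obs$rater_id)))
      for (lab in intersect(labels, unique(obs$label))) {
        sub <- obs[obs$modality == mod & obs$rater_id == rater &
                     obs$label == lab, ]
        if (nrow(sub) == 0L) next
        wide <- attempt_matrix(sub, rater, lab)
        for (coord in c("x", "y", "z")) {
          row <- icc_diff_row(wide[[coord]][, 1L], wide[[coord]][, 2L])
          out[[length(out) + 1L]] <-
            cbind(data.frame(modality = mod, rater_id = rater, label = lab,
                             coordinate = coord), row)
        }
      }
  do.call(rbind, out)
}

# n_patients x 2 matrices of one rater's two attempts, per coordinate.
attempt_matrix <- function(sub, rater, lab) {
  patients <- sort(unique(sub$patient_id))
  get <- function(attempt) {
    a <- sub[sub$attempt == attempt, ]
    missing_pat <- setdiff(patients, a$patient_id)
    if (length(missing_pat))
      stop_input("rater '", rater, "', landmark '", lab, "': missing ",
                 "attempt ", attempt, " for patient(s) ",
                 paste(missing_pat, collapse = ", "))
    a[match(patients, a$patient_id), c("x", "y", "z")]
  }
  a1 <- get(1L); a2 <- get(2L)
  list(x = cbind(a1$x, a2$x), y = cbind(a1$y, a2$y), z = cbind(a1$z, a2$z))
}

#' Inter-rater reliability report (worst rater pair)
#'
#' Each rater's two attempts are first averaged per patient and landmark.
#' For every pair of raters the ICC and absolute-difference summary are
#' computed per landmark and coordinate, and the worst of the three pairs
#' is reported. "Worst" defaults to the pair with the lowest
#' single-measures ICC; the pair with the largest mean absolute difference
#' is also identified (`worst_by_diff_pair`) since the two criteria can
#' disagree.
#'
#' @inheritParams intra_rater_report
#' @return a data.frame with one row per modality x landmark x coordinate:
#'   the worst pair's statistics plus `pair` (rater ids, `"A|B"`) and
#'   `worst_by_diff_pair`.
#' @export
inter_rater_report <- function(observations, labels = LSCC_LABELS) {
  obs <- check_complete(observations, labels = labels)
  out <- list()
  for (mod in sort(unique(obs$modality)))
    for (lab in intersect(labels, unique(obs$label))) {
      sub <- obs[obs$modality == mod & obs$label == lab, ]
      if (nrow(sub) == 0L) next
      raters <- sort(unique(sub$rater_id))
      if (length(raters) < 2L)
        stop_input("inter-rater report needs >= 2 raters, found ",
                   length(raters))
      patients <- sort(unique(sub$patient_id))
      means <- lapply(raters, function(r) {
        wide <- attempt_matrix(sub[sub$rater_id == r, ], r, lab)
        sapply(wide, rowMeans)   # n_patients x 3 (x, y, z)
      })
      names(means) <- raters
      pairs <- utils::combn(raters, 2L, simplify = FALSE)
      for (coord in c("x", "y", "z")) {
        ci <- match(coord, c("x", "y", "z"))
        rows <- lapply(pairs, function(pr) {
          cbind(data.frame(pair = paste(pr, collapse = "|")),
                icc_diff_row(means[[pr[1L]]][, ci], means[[pr[2L]]][, ci]))
        })
        tab <- do.call(rbind, rows)
        worst <- which.min(tab$r)
        worst_diff <- which.max(tab$mean)
        out[[length(out) + 1L]] <-
          cbind(data.frame(modality = mod, label = lab, coordinate = coord),
                tab[worst, , drop = FALSE],
                data.frame(worst_by_diff_pair = tab$pair[worst_diff]))
      }
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Target registration error between matched point lists
#'
#' Euclidean distances between corresponding points of two co-registered
#' point sets, summarised by mean, SD and maximum. TRE is only meaningful
#' on landmarks that did not define the registration, so LSCC labels are
#' rejected when labels are supplied.
#'
#' @param points_a,points_b matched n x 3 matrices (mm) in a common frame.
#' @param labels optional character vector of landmark labels for the
#'   points; any frame-defining LSCC label is an error.
#' @return list of class `tre_summary`: `distances`, `mean`, `sd`, `max`,
#'   `n`, and `per_coordinate` (a [difference_summary()] per axis).
#' @export
target_registration_error <- function(points_a, points_b, labels = NULL) {
  a <- as_point_matrix(points_a, "points_a")
  b <- as_point_matrix(points_b, "points_b")
  if (nrow(a) != nrow(b))
    stop_input("point lists have different lengths (", nrow(a), " vs ",
               nrow(b), ")")
  if (nrow(a) < 1L) stop_input("need at least one point pair")
  if (!is.null(labels)) {
    bad <- intersect(canonical_label(labels), LSCC_LABELS)
    if (length(bad))
      stop_input("TRE landmarks must be independent of the frame; ",
                 "remove frame-defining label(s): ",
                 paste(bad, collapse = ", "))
  }
  d <- sqrt(rowSums((a - b)^2))
  per_coord <- lapply(seq_len(3L), function(i) difference_summary(
    if (all((a[, i] - b[, i]) == 0)) rep(0, nrow(a)) else a[, i] - b[, i]))
  names(per_coord) <- c("x", "y", "z")
  structure(list(distances = d, mean = mean(d),
                 sd = if (length(d) > 1L) stats::sd(d) else 0,
                 max = max(d), n = length(d), per_coordinate = per_coord),
            class = "tre_summary")
}

#' @export
print.tre_summary <- function(x, ...) {
  cat(sprintf("TRE over %d landmark pairs: mean %.4f, sd %.4f, max %.4f mm\n",
              x$n, x$mean, x$sd, x$max))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements computes the differences `a - b`, the pair
#' averages `(a + b)/2`, the mean difference, and the 95% limits of
#' agreement `mean +/- 1.96 sd` of the differences. Ideal agreement is
#' zero difference.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return list of class `bland_altman`: `averages`, `differences`,
#'   `mean_difference`, `lower`, `upper`, `sd`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_input("paired vectors differ in length")
  if (length(a) < 2L) stop_input("Bland-Altman needs >= 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_input("non-finite values in paired measurements")
  d <- a - b
  s <- stats::sd(d)
  structure(list(averages = (a + b) / 2, differences = d,
                 mean_difference = mean(d), sd = s,
                 lower = mean(d) - 1.96 * s, upper = mean(d) + 1.96 * s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4f, 95%% limits [%.4f, %.4f]\n",
              x$mean_difference, x$lower, x$upper))
  invisible(x)
}

#' Planarity check of the LSCC landmarks
#'
#' For each patient and modality the componentwise median of the repeated
#' selections of each LSCC landmark is computed, a total-least-squares
#' plane is fitted to the four medians, and each median is compared with
#' its orthogonal projection on that plane. Differences are pooled over
#' landmarks and patients within each modality (4 landmarks x n patients
#' pairs per coordinate), and per-coordinate agreement between the median
#' and projected coordinates is summarised with the absolute-agreement ICC.
#' Near-zero differences and r close to 1 support approximating the two
#' lateral canals as coplanar.
#'
#' @param observations a landmark data.frame containing the LSCC labels.
#' @return a data.frame with one row per modality x coordinate: `r`, `p`,
#'   `r_average`, `p_average`, `mean`, `sd`, `max`, `n`.
#' @export
planarity_report <- function(observations) {
  med <- median_landmarks(
    observations[observations$label %in% LSCC_LABELS, ])
  out <- list()
  for (mod in sort(unique(med$modality))) {
    orig <- NULL; proj <- NULL
    for (pat in sort(unique(med$patient_id[med$modality == mod]))) {
      sub <- med[med$modality == mod & med$patient_id == pat, ]
      missing_labels <- setdiff(LSCC_LABELS, sub$label)
      if (length(missing_labels))
        stop_input("patient '", pat, "', modality '", mod, "': incomplete ",
                   "LSCC selections (missing ",
                   paste(missing_labels, collapse = ", "), ")")
      pts <- as.matrix(sub[match(LSCC_LABELS, sub$label), c("x", "y", "z")])
      plane <- fit_plane(pts)
      orig <- rbind(orig, pts)
      proj <- rbind(proj, project_onto_plane(pts, plane))
    }
    for (coord in c("x", "y", "z")) {
      ci <- match(coord, c("x", "y", "z"))
      out[[length(out) + 1L]] <-
        cbind(data.frame(modality = mod, coordinate = coord),
              icc_diff_row(orig[, ci], proj[, ci]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-modality accuracy report on held-out SSCC landmarks
#'
#' Builds the LSCC frame per patient and modality from the componentwise
#' medians of the repeated LSCC selections, maps each modality's SSCC
#' probe landmarks into its own frame (which co-registers the modalities),
#' and compares the CT and MR frame coordinates: per-landmark,
#' per-coordinate ICC and absolute-difference summaries, plus the
#' Euclidean target registration error and Bland-Altman statistics per
#' coordinate.
#'
#' @param observations a landmark data.frame with the four LSCC labels and
#'   the `left_superior_sscc` / `right_superior_sscc` probe labels for
#'   both modalities.
#' @param tilt_degrees frame tilt passed to [build_lscc_frame()].
#' @return list with `table` (data.frame: label x coordinate rows with
#'   `r`, `p`, `mean`, `sd`, `max`), `tre` (a `tre_summary` pooled over
#'   both SSCC landmarks), `bland_altman` (per-coordinate
#'   [bland_altman()] results over all SSCC points), and `frame_points`
#'   (per patient/label CT and MR frame coordinates).
#' @export
accuracy_report <- function(observations, tilt_degrees = 20) {
  sscc <- observations[observations$label %in% SSCC_LABELS, ]
  if (nrow(sscc) == 0L)
    stop_input("no SSCC probe landmarks in the table")
  med_sscc <- median_landmarks(sscc)
  patients <- sort(unique(med_sscc$patient_id))

  rows <- list()
  for (pat in patients) {
    for (mod in c("CT", "MR")) {
      set <- landmark_set_from_table(observations, pat, mod)
      frame <- build_lscc_frame(set, tilt_degrees = tilt_degrees)
      for (lab in SSCC_LABELS) {
        sel <- med_sscc[med_sscc$patient_id == pat &
                          med_sscc$modality == mod &
                          med_sscc$label == lab, ]
        if (nrow(sel) != 1L)
          stop_input("patient '", pat, "': missing ", lab, " in ", mod)
        f <- world_to_frame(frame, as.numeric(sel[, c("x", "y", "z")]))
        rows[[length(rows) + 1L]] <-
          data.frame(patient_id = pat, modality = mod, label = lab,
                     x = f[1], y = f[2], z = f[3])
      }
    }
  }
  fp <- do.call(rbind, rows)

  tab <- list()
  ct_all <- NULL; mr_all <- NULL
  for (lab in SSCC_LABELS) {
    ct <- fp[fp$modality == "CT" & fp$label == lab, ]
    mr <- fp[fp$modality == "MR" & fp$label == lab, ]
    ct <- ct[match(patients, ct$patient_id), ]
    mr <- mr[match(patients, mr$patient_id), ]
    ct_all <- rbind(ct_all, as.matrix(ct[, c("x", "y", "z")]))
    mr_all <- rbind(mr_all, as.matrix(mr[, c("x", "y", "z")]))
    for (coord in c("x", "y", "z"))
      tab[[length(tab) + 1L]] <-
        cbind(data.frame(label = lab, coordinate = coord),
              icc_diff_row(ct[[coord]], mr[[coord]]))
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL

  ba <- lapply(c(x = 1L, y = 2L, z = 3L), function(i)
    bland_altman(ct_all[, i], mr_all[, i]))

  list(table = tab,
       tre = target_registration_error(ct_all, mr_all),
       bland_altman = ba,
       frame_points = fp)
}
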
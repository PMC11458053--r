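LSCC_LABELS <- c("left_anterior", "left_posterior",
                 "right_anterior", "right_posterior")
SSCC_LABELS <- c("left_superior_sscc", "right_superior_sscc")
ALL_LABELS <- c(LSCC_LABELS, SSCC_LABELS)

# Map the spellings found in clinical spreadsheets ("Left Anterior LSCC",
# "right superior SSCC", ...) onto canonical labels.
canonical_label <- function(label) {
  x <- tolower(trimws(as.character(label)))
  x <- gsub("[^a-z]+", " ", x)
  x <- trimws(gsub("\\b(lscc|sscc|scc)\\b", "", x))
  x <- gsub(" +", "_", x)
  x[x == "left_superior"] <- "left_superior_sscc"
  x[x == "right_superior"] <- "right_superior_sscc"
  bad <- !(x %in% ALL_LABELS)
  if (any(bad))
    stop_input("unrecognised landmark label(s): ",
               paste(unique(label[bad]), collapse = ", "))
  x
}

#' Voxel grid description
#'
#' @param spacing 3-vector, mm per voxel, strictly positive.
#' @param dims 3-vector of voxel counts (optional, defaults to `NA`).
#' @return an object of class `voxel_grid`. Indices are 0-based.
#' @export
voxel_grid <- function(spacing, dims = c(NA, NA, NA)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop_input("voxel spacing must be 3 positive finite values (mm)")
  dims <- as.numeric(dims)
  if (length(dims) != 3L || any(!is.na(dims) & dims < 1))
    stop_input("grid dimensions must be >= 1 per axis")
  structure(list(spacing = spacing, dims = dims), class = "voxel_grid")
}

#' Convert between voxel indices and world millimetres
#'
#' Indices are 0-based and map to world coordinates as
#' `world = index * spacing` (voxel-corner origin, no half-voxel offset),
#' so coordinate differences between selections are exact multiples of the
#' voxel size. Set `offset = "center"` for the half-voxel-centre convention
#' used by some tools.
#'
#' @param index integer voxel triple (or n x 3 matrix), 0-based,
#'   non-negative.
#' @param grid a [voxel_grid()] (or a 3-vector of spacings).
#' @param offset `"corner"` (default) or `"center"`.
#' @return `voxel_to_world`: world mm; `world_to_voxel`: continuous voxel
#'   coordinates (not rounded).
#' @export
voxel_to_world <- function(index, grid, offset = c("corner", "center")) {
  offset <- match.arg(offset)
  grid <- as_voxel_grid(grid)
  single <- is.numeric(index) && is.null(dim(index))
  idx <- as_point_matrix(index, "voxel index")
  if (any(idx < 0)) stop_input("voxel indices must be non-negative")
  shift <- if (offset == "center") 0.5 else 0
  w <- sweep(idx + shift, 2L, grid$spacing, "*")
  if (single) as.numeric(w) else w
}

#' @rdname voxel_to_world
#' @param p world point(s), mm.
#' @export
world_to_voxel <- function(p, grid, offset = c("corner", "center")) {
  offset <- match.arg(offset)
  grid <- as_voxel_grid(grid)
  single <- is.numeric(p) && is.null(dim(p))
  pts <- as_point_matrix(p, "world points")
  shift <- if (offset == "center") 0.5 else 0
  v <- sweep(pts, 2L, grid$spacing, "/") - shift
  if (single) as.numeric(v) else v
}

as_voxel_grid <- function(grid) {
  if (inherits(grid, "voxel_grid")) grid else voxel_grid(grid)
}

#' Canonical modality voxel spacings
#'
#' Acquisition spacings of the cone-beam CT (0.15 mm isotropic) and
#' high-resolution T2 MR (0.2604 x 0.2604 x 0.3 mm) protocols the
#' coordinate system was designed for.
#' @param modality `"CT"` or `"MR"`.
#' @return 3-vector of spacings, mm.
#' @export
modality_spacing <- function(modality) {
  switch(toupper(modality),
         CT = c(0.15, 0.15, 0.15),
         MR = c(0.2604, 0.2604, 0.3),
         stop_input("unknown modality '", modality, "' (use CT or MR)"))
}

LANDMARK_COLUMNS <- c("patient_id", "modality", "rater_id", "attempt",
                      "label", "x", "y", "z")

#' Read a landmark observation table
#'
#' Reads a table of expert landmark selections: one row per
#' (patient, modality, rater, attempt, label) with x/y/z coordinates.
#' Accepted dialects are comma- or tab-delimited text and XLSX (first
#' sheet), each with a header row; column names are matched
#' case-insensitively and may use `patient`/`rater` for
#' `patient_id`/`rater_id`.
#'
#' Coordinates may be world millimetres or voxel indices. If every
#' coordinate in a modality is a non-negative integer and a spacing is
#' known for that modality (from `spacing` or [modality_spacing()]), the
#' values are interpreted as 0-based voxel indices and converted to mm;
#' the choice is reported with a message.
#'
#' @param path file path (`.csv`, `.tsv`/`.txt`, or `.xlsx`).
#' @param spacing `NULL` (auto: CT/MR protocol spacings for integer-valued
#'   tables), `"mm"` to force millimetre interpretation, or a named list
#'   of per-modality spacing 3-vectors to force voxel interpretation.
#' @return a data.frame with columns `patient_id`, `modality`, `rater_id`,
#'   `attempt`, `label`, `x`, `y`, `z` (mm, LPS world).
#' @export
read_landmark_table <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop_input("landmark table not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    tsv = ,
    txt = utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE),
    xlsx = as.data.frame(readxl::read_excel(path, sheet = 1L)),
    stop_input("unsupported landmark table format '.", ext,
               "' (use .csv, .tsv, .txt or .xlsx)"))
  parse_landmark_frame(raw, spacing = spacing, where = path)
}

parse_landmark_frame <- function(raw, spacing = NULL, where = "table") {
  nm <- tolower(trimws(names(raw)))
  nm[nm == "patient"] <- "patient_id"
  nm[nm == "rater"] <- "rater_id"
  nm[nm == "expert"] <- "rater_id"
  names(raw) <- nm
  missing_cols <- setdiff(LANDMARK_COLUMNS, nm)
  if (length(missing_cols))
    stop_input(where, ": missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  df <- raw[LANDMARK_COLUMNS]

  for (col in c("x", "y", "z", "attempt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_input(where, ": non-numeric ", col, " at row ",
                 paste(utils::head(bad, 5L) + 1L, collapse = ", "),
                 " (1 = header)")
    df[[col]] <- v
  }
  if (any(df$attempt != round(df$attempt) | df$attempt < 1))
    stop_input(where, ": attempt must be a positive integer")
  df$attempt <- as.integer(df$attempt)
  df$patient_id <- as.character(df$patient_id)
  df$rater_id <- as.character(df$rater_id)
  df$modality <- toupper(trimws(as.character(df$modality)))
  if (!all(df$modality %in% c("CT", "MR")))
    stop_input(where, ": modality must be CT or MR")
  df$label <- canonical_label(df$label)

  key <- paste(df$patient_id, df$modality, df$rater_id, df$attempt, df$label,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_input(where, ": duplicate (patient, modality, rater, attempt, ",
               "label) at row ", dup[1L] + 1L, " (1 = header): ",
               gsub("\r", "/", key[dup[1L]]))

  df <- convert_voxel_columns(df, spacing)
  rownames(df) <- NULL
  df
}

# Auto-detection: an all-integer, non-negative coordinate block for a
# modality with known spacing is taken to be voxel indices.
convert_voxel_columns <- function(df, spacing) {
  if (identical(spacing, "mm")) return(df)
  for (mod in unique(df$modality)) {
    rows <- df$modality == mod
    xyz <- as.matrix(df[rows, c("x", "y", "z")])
    sp <- if (is.list(spacing) && !is.null(spacing[[mod]]))
      as.numeric(spacing[[mod]]) else modality_spacing(mod)
    forced <- is.list(spacing) && !is.null(spacing[[mod]])
    looks_integer <- all(xyz >= 0) && max(abs(xyz - round(xyz))) < 1e-9
    if (forced || (is.null(spacing) && looks_integer)) {
      if (!looks_integer)
        stop_input("spacing given for ", mod, " but coordinates are not ",
                   "non-negative integers; cannot be voxel indices")
      df[rows, c("x", "y", "z")] <- voxel_to_world(xyz, voxel_grid(sp))
      message("read_landmark_table: ", mod, " coordinates interpreted as ",
              "0-based voxel indices at spacing [",
              paste(sp, collapse = ", "), "] mm")
    }
  }
  df
}

#' Write a landmark observation table
#'
#' Writes CSV or TSV depending on the file extension; coordinates are
#' world millimetres.
#' @param observations a landmark data.frame as returned by
#'   [read_landmark_table()] or [simulate_observations()].
#' @param path output path (`.csv` or `.tsv`).
#' @export
write_landmark_table <- function(observations, path) {
  stopifnot(is.data.frame(observations))
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(observations))
  if (length(missing_cols))
    stop_input("observations lack column(s): ",
               paste(missing_cols, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  sep <- switch(ext, csv = ",", tsv = "\t",
                stop_input("unsupported output format '.", ext, "'"))
  utils::write.table(observations[LANDMARK_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export landmarks in ITK-SNAP label-point text format
#'
#' One point per line: `x y z label`, world mm, with a comment header.
#' @param points n x 3 matrix of world points (mm) with row names as
#'   labels, or a landmark data.frame.
#' @param path output path.
#' @export
write_itksnap_points <- function(points, path) {
  if (is.data.frame(points)) {
    labels <- points$label
    pts <- as.matrix(points[, c("x", "y", "z")])
  } else {
    pts <- as_point_matrix(points)
    labels <- rownames(pts)
    if (is.null(labels)) labels <- seq_len(nrow(pts))
  }
  lines <- c("# ITK-SNAP landmark points (world mm, LPS)",
             sprintf("%.6f %.6f %.6f %s", pts[, 1], pts[, 2], pts[, 3],
                     labels))
  writeLines(lines, path)
  invisible(path)
}

#' Componentwise median of repeated landmark selections
#'
#' The median of each coordinate over all observations of one landmark
#' (for an even count, the mean of the two middle order statistics). Using
#' medians of the six expert selections (3 raters x 2 attempts) rather
#' than any single selection reduces bias when building the frame.
#'
#' @param observations a landmark data.frame, all rows sharing one
#'   (patient, modality, label); or an n x 3 matrix of repeated positions.
#' @return a 3-vector, mm.
#' @export
median_landmark <- function(observations) {
  if (is.data.frame(observations)) {
    if (nrow(observations) == 0L) stop_input("no observations to median")
    for (col in c("patient_id", "modality", "label"))
      if (length(unique(observations[[col]])) != 1L)
        stop_input("median_landmark needs observations of a single ",
                   "(patient, modality, label); ", col, " varies")
    pts <- as.matrix(observations[, c("x", "y", "z")])
  } else {
    pts <- as_point_matrix(observations, "observations")
    if (nrow(pts) == 0L) stop_input("no observations to median")
  }
  apply(pts, 2L, stats::median)
}

#' Per-landmark medians for a whole table
#'
#' @param observations a landmark data.frame.
#' @return a data.frame with one row per (patient, modality, label) and the
#'   componentwise median coordinates.
#' @export
median_landmarks <- function(observations) {
  stopifnot(is.data.frame(observations))
  key <- paste(observations$patient_id, observations$modality,
               observations$label, sep = "\r")
  idx <- split(seq_len(nrow(observations)), key)
  first <- vapply(idx, `[[`, integer(1L), 1L)
  med <- t(vapply(idx, function(i)
    c(stats::median(observations$x[i]), stats::median(observations$y[i]),
      stats::median(observations$z[i])), numeric(3L)))
  res <- data.frame(patient_id = observations$patient_id[first],
                    modality = observations$modality[first],
                    label = observations$label[first],
                    x = med[, 1L], y = med[, 2L], z = med[, 3L],
                    stringsAsFactors = FALSE)
  res <- res[order(res$patient_id, res$modality, res$label), ]
  rownames(res) <- NULL
  res
}

#' Extract an LSCC landmark set for one patient and modality
#'
#' @param observations a landmark data.frame (typically per-landmark
#'   medians from [median_landmarks()]).
#' @param patient_id,modality the key to extract.
#' @return an [lscc_landmark_set()].
#' @export
landmark_set_from_table <- function(observations, patient_id, modality) {
  rows <- observations$patient_id == patient_id &
    observations$modality == toupper(modality) &
    observations$label %in% LSCC_LABELS
  sub <- observations[rows, ]
  if (nrow(sub) == 0L)
    stop_input("no LSCC landmarks for patient '", patient_id,
               "', modality '", modality, "'")
  med <- median_landmarks(sub)
  missing_labels <- setdiff(LSCC_LABELS, med$label)
  if (length(missing_labels))
    stop_input("patient '", patient_id, "', modality '", modality,
               "': missing LSCC landmark(s): ",
               paste(missing_labels, collapse = ", "))
  pos <- function(lab) as.numeric(med[med$label == lab, c("x", "y", "z")])
  lscc_landmark_set(pos("left_anterior"), pos("left_posterior"),
                    pos("right_anterior"), pos("right_posterior"))
}
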
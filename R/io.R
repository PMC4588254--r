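# CSV and YAML interfaces. Landmark coordinates are stored in pixels with
# the femoral-head calibration kept in a separate file, matching the
# digitise-then-calibrate workflow; all writers emit deterministic bytes
# (fixed column order, fixed formatting, LF line endings).

read_csv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop_pelvimetrix(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop_pelvimetrix(sprintf("%s: missing column(s): %s", path,
      paste(missing_cols, collapse = ", ")))
  }
  df
}

parse_numeric_col <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (anyNA(x)) {
    bad <- which(is.na(x))
    stop_pelvimetrix(sprintf(
      "%s: malformed numeric value in column '%s' at data line(s): %s",
      path, col, paste(bad + 1L, collapse = ", "))) # +1 for header line
  }
  x
}

#' Read landmark sheets and calibration records from CSV
#'
#' The sheets file has one row per digitised landmark with columns
#' `subject_id, view, landmark, side, u_px, v_px`; the calibration file has
#' one row per subject and view with columns
#' `subject_id, view, fh_true_mm, fh_px`. Validation of landmark
#' completeness is deferred to measurement time, so partially digitised
#' sheets load cleanly.
#'
#' @param sheets_path Path to the landmark CSV.
#' @param calibration_path Path to the calibration CSV.
#' @return Named list of `landmark_sheet` objects, one per subject.
#' @export
read_landmark_csv <- function(sheets_path, calibration_path) {
  sheets <- read_csv_strict(sheets_path,
    c("subject_id", "view", "landmark", "side", "u_px", "v_px"))
  sheets$u_px <- parse_numeric_col(sheets, "u_px", sheets_path)
  sheets$v_px <- parse_numeric_col(sheets, "v_px", sheets_path)
  key <- paste(sheets$subject_id, sheets$view, sheets$landmark, sheets$side)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop_pelvimetrix(sprintf(
      "%s: duplicate (subject, view, landmark, side) row(s) at data line(s): %s",
      sheets_path, paste(dup + 1L, collapse = ", ")))
  }
  cal <- read_csv_strict(calibration_path,
    c("subject_id", "view", "fh_true_mm", "fh_px"))
  cal$fh_true_mm <- parse_numeric_col(cal, "fh_true_mm", calibration_path)
  cal$fh_px <- parse_numeric_col(cal, "fh_px", calibration_path)
  ids <- unique(sheets$subject_id)
  out <- lapply(ids, function(id) {
    d <- sheets[sheets$subject_id == id, ]
    cc <- cal[cal$subject_id == id, c("view", "fh_px", "fh_true_mm")]
    if (!nrow(cc)) {
      stop_pelvimetrix(sprintf("%s: no calibration rows for subject '%s'",
        calibration_path, id))
    }
    landmark_sheet(id,
      data.frame(view = d$view, landmark = d$landmark, side = d$side,
                 u = d$u_px, v = d$v_px, stringsAsFactors = FALSE),
      calibration = cc, unit = "px")
  })
  stats::setNames(out, ids)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

csv_line <- function(...) paste(..., sep = ",")

#' Write landmark sheets (and calibration) to CSV
#'
#' Coordinates are written with full `%.17g` precision so a write-read
#' round trip is lossless.
#'
#' @param sheets A `landmark_sheet` or list of them (pixel units).
#' @param sheets_path,calibration_path Output paths.
#' @return Invisibly, `sheets_path`.
#' @export
write_landmark_csv <- function(sheets, sheets_path, calibration_path) {
  if (inherits(sheets, "landmark_sheet")) sheets <- list(sheets)
  lines <- "subject_id,view,landmark,side,u_px,v_px"
  cal_lines <- "subject_id,view,fh_true_mm,fh_px"
  for (sh in sheets) {
    if (sh$unit != "px") {
      stop_pelvimetrix("landmark CSVs store pixel coordinates; sheet is in mm")
    }
    d <- sh$data
    lines <- c(lines, csv_line(sh$subject_id, d$view, d$landmark, d$side,
      sprintf("%.17g", d$u), sprintf("%.17g", d$v)))
    cc <- sh$calibration
    cal_lines <- c(cal_lines, csv_line(sh$subject_id, cc$view,
      sprintf("%.17g", cc$fh_true_mm), sprintf("%.17g", cc$fh_px)))
  }
  write_lines_lf(lines, sheets_path)
  write_lines_lf(cal_lines, calibration_path)
  invisible(sheets_path)
}

REPORT_COLUMNS <- c("subject_id",
  "vertical_mm", "vertical_dir", "ap_mm", "ap_dir",
  "transverse_mm", "transverse_dir",
  "sagittal_mm", "sagittal_class", "inlet_mm", "inlet_class",
  "outlet_mm", "outlet_class")

#' Write displacement reports to CSV
#'
#' One row per subject, numeric values in mm to 3 decimals, deterministic
#' column order and line endings. An empty report list yields a
#' header-only file.
#'
#' @param reports A `displacement_report`, a list of them, or a data frame
#'   in report-column layout.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "displacement_report")) reports <- list(reports)
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    df <- do.call(rbind, lapply(reports, as.data.frame))
  }
  lines <- paste(REPORT_COLUMNS, collapse = ",")
  if (!is.null(df) && nrow(df)) {
    missing_cols <- setdiff(REPORT_COLUMNS, names(df))
    if (length(missing_cols)) {
      stop_pelvimetrix(sprintf("report is missing column(s): %s",
        paste(missing_cols, collapse = ", ")))
    }
    num <- grepl("_mm$", REPORT_COLUMNS)
    body <- vapply(seq_len(nrow(df)), function(i) {
      vals <- vapply(seq_along(REPORT_COLUMNS), function(j) {
        v <- df[i, REPORT_COLUMNS[j]]
        if (num[j]) fmt_num(as.numeric(v)) else as.character(v)
      }, character(1))
      paste(vals, collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  write_lines_lf(lines, path)
  invisible(path)
}

#' Read displacement reports back from CSV
#'
#' @param path Report CSV written by [write_report_csv()].
#' @return Data frame in report-column layout.
#' @export
read_report_csv <- function(path) {
  df <- read_csv_strict(path, REPORT_COLUMNS)
  for (col in REPORT_COLUMNS[grepl("_mm$", REPORT_COLUMNS)]) {
    df[[col]] <- parse_numeric_col(df, col, path)
  }
  df
}

#' Write a reliability report to CSV
#'
#' Layout mirrors a per-parameter agreement table: parameter, statistic,
#' estimate, CI bounds (ICC) or p-value (kappa), Landis-Koch label and a
#' degenerate flag; numbers to 3 decimals.
#'
#' @param report A `reliability_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reliability_csv <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  lines <- "parameter,statistic,estimate,ci_low,ci_high,p_value,label,degenerate"
  body <- vapply(seq_len(nrow(report)), function(i) {
    csv_line(report$parameter[i], report$statistic[i],
      fmt_num(report$estimate[i]), fmt_num(report$ci_low[i]),
      fmt_num(report$ci_high[i]),
      ifelse(is.na(report$p_value[i]), "NA",
             formatC(report$p_value[i], format = "e", digits = 3)),
      ifelse(is.na(report$label[i]), "NA", report$label[i]),
      tolower(report$degenerate[i]))
  }, character(1))
  write_lines_lf(c(lines, body), path)
  invisible(path)
}

TRUTH_COLUMNS <- c("subject_id", "injured_side", "tx_mm", "ty_mm", "tz_mm",
                   "rot_x_deg", "rot_y_deg", "rot_z_deg", "pivot")

#' Write / read ground-truth displacement tables
#'
#' @param truth Data frame as in `simulated_study$truth`.
#' @param path CSV path.
#' @return Invisibly `path`; for the reader, the truth data frame.
#' @export
write_truth_csv <- function(truth, path) {
  missing_cols <- setdiff(TRUTH_COLUMNS, names(truth))
  if (length(missing_cols)) {
    stop_pelvimetrix(sprintf("truth is missing column(s): %s",
      paste(missing_cols, collapse = ", ")))
  }
  num <- grepl("_mm$|_deg$", TRUTH_COLUMNS)
  lines <- paste(TRUTH_COLUMNS, collapse = ",")
  body <- vapply(seq_len(nrow(truth)), function(i) {
    vals <- vapply(seq_along(TRUTH_COLUMNS), function(j) {
      v <- truth[i, TRUTH_COLUMNS[j]]
      if (num[j]) sprintf("%.17g", as.numeric(v)) else as.character(v)
    }, character(1))
    paste(vals, collapse = ",")
  }, character(1))
  write_lines_lf(c(lines, body), path)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- read_csv_strict(path, TRUTH_COLUMNS)
  for (col in TRUTH_COLUMNS[grepl("_mm$|_deg$", TRUTH_COLUMNS)]) {
    df[[col]] <- parse_numeric_col(df, col, path)
  }
  df
}

#' Write a recovery table to CSV
#'
#' Long layout: one row per metric (translation bias/RMSE per parameter,
#' classification accuracy per plane).
#'
#' @param recovery A `recovery_table` from [evaluate_recovery()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recovery_csv <- function(recovery, path) {
  stopifnot(inherits(recovery, "recovery_table"))
  lines <- "metric,parameter,value,n"
  tr <- recovery$translation
  for (i in seq_len(nrow(tr))) {
    lines <- c(lines,
      csv_line("bias_mm", tr$parameter[i], fmt_num(tr$bias_mm[i]), tr$n[i]),
      csv_line("rmse_mm", tr$parameter[i], fmt_num(tr$rmse_mm[i]), tr$n[i]))
  }
  ra <- recovery$rotation_accuracy
  for (i in seq_len(nrow(ra))) {
    lines <- c(lines, csv_line("class_accuracy", ra$plane[i],
      fmt_num(ra$accuracy[i]), ra$n[i]))
  }
  write_lines_lf(lines, path)
  invisible(path)
}

STUDY_CONFIG_DEFAULTS <- list(
  n_subjects = 25L, n_raters = 5L, noise_sd_mm = 1, mm_per_px = 0.5,
  ap_tilt_deg = 45, obliquity_deg = 45, fh_diameter_mm = 48, seed = 1L,
  threshold_mm = 2, label_convention = "table2", pivot = "centroid",
  icc_type = "single", kappa_mode = "fleiss",
  displacement = list(
    p_translation_dominant = 0.5, translation_sd_mm = 10,
    translation_cap_mm = 30, rotation_sd_deg = 8, rotation_cap_deg = 20,
    minor_rotation_sd_deg = 2))

#' Read and validate a study configuration (YAML)
#'
#' Unknown keys are rejected; omitted keys take the documented defaults.
#'
#' @param path YAML file path.
#' @return A validated config list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    stop_pelvimetrix(sprintf("config file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(STUDY_CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop_pelvimetrix(sprintf("unknown config key(s): %s (allowed: %s)",
      paste(unknown, collapse = ", "),
      paste(names(STUDY_CONFIG_DEFAULTS), collapse = ", ")))
  }
  if (!is.null(cfg$displacement)) {
    unknown_d <- setdiff(names(cfg$displacement),
                         names(STUDY_CONFIG_DEFAULTS$displacement))
    if (length(unknown_d)) {
      stop_pelvimetrix(sprintf("unknown displacement config key(s): %s",
        paste(unknown_d, collapse = ", ")))
    }
    cfg$displacement <- utils::modifyList(STUDY_CONFIG_DEFAULTS$displacement,
                                          cfg$displacement)
  }
  cfg <- utils::modifyList(STUDY_CONFIG_DEFAULTS, cfg)
  if (!cfg$label_convention %in% c("table2", "text")) {
    stop_pelvimetrix("label_convention must be 'table2' or 'text'")
  }
  if (!cfg$icc_type %in% c("single", "average")) {
    stop_pelvimetrix("icc_type must be 'single' or 'average'")
  }
  if (!cfg$kappa_mode %in% c("fleiss", "pairwise_cohen_mean")) {
    stop_pelvimetrix("kappa_mode must be 'fleiss' or 'pairwise_cohen_mean'")
  }
  check_finite(c(cfg$n_subjects, cfg$n_raters, cfg$noise_sd_mm,
                 cfg$mm_per_px, cfg$ap_tilt_deg, cfg$seed, cfg$threshold_mm),
               "config values")
  do.call(displacement_distribution, cfg$displacement) # validates
  structure(cfg, class = "study_config")
}
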
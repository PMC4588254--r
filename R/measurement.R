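# Displacement measurement from calibrated 2D landmark coordinates.
#
# All quantities are differences of absolute coordinate differences between
# the injured side, the intact side and the sacral endplate centre S, so
# they are invariant to where the image origin sits and to reflecting the
# whole image. Translational values are signed millimetres with a direction
# label; rotational values are millimetre indicators classified against a
# symmetric neutral band (default +/- 2 mm, the anatomic-reduction
# threshold of the Majeed convention).

VIEWS <- c("ap", "inlet", "outlet")
SIDES <- c("intact", "injured", "midline")
LANDMARK_VOCAB <- c(
  "ASIS", "ischial_tuberosity", "iliac_wing_superior", "anterior_SI_joint",
  "sacral_endplate_centre", "femoral_head_d1", "femoral_head_d2"
)

# Landmarks each formula needs: view, landmark, side
FORMULA_LANDMARKS <- list(
  vertical = data.frame(
    view = "outlet",
    landmark = c("iliac_wing_superior", "iliac_wing_superior",
                 "sacral_endplate_centre"),
    side = c("injured", "intact", "midline")),
  ap = data.frame(
    view = "inlet",
    landmark = c("anterior_SI_joint", "anterior_SI_joint",
                 "sacral_endplate_centre"),
    side = c("injured", "intact", "midline")),
  transverse = data.frame(
    view = "inlet",
    landmark = c("anterior_SI_joint", "anterior_SI_joint",
                 "sacral_endplate_centre"),
    side = c("injured", "intact", "midline")),
  sagittal = data.frame(
    view = "ap",
    landmark = rep(c("ASIS", "ischial_tuberosity"), 2),
    side = rep(c("intact", "injured"), each = 2)),
  inlet = data.frame(
    view = "inlet",
    landmark = rep(c("ASIS", "anterior_SI_joint"), 2),
    side = rep(c("intact", "injured"), each = 2)),
  outlet = data.frame(
    view = "outlet",
    landmark = rep(c("ASIS", "ischial_tuberosity"), 2),
    side = rep(c("intact", "injured"), each = 2))
)

#' Per-subject landmark sheet
#'
#' The sole input of the measurement system: 2D landmark coordinates across
#' the three standardized views, in pixels (with a per-view femoral-head
#' calibration record) or directly in millimetres.
#'
#' @param subject_id Subject identifier (scalar).
#' @param data Data frame with columns `view` (`ap`/`inlet`/`outlet`),
#'   `landmark` (see `LANDMARK_VOCAB`), `side`
#'   (`intact`/`injured`/`midline`), `u`, `v` (numeric coordinates).
#'   Image `v` increases superiorly (for the inlet view, anteriorly along
#'   the outlet axis); `u` increases toward the patient's left.
#' @param calibration Data frame with columns `view`, `fh_px` (measured
#'   femoral head pixel diameter in that view) and `fh_true_mm` (true
#'   diameter). Required when `unit = "px"`.
#' @param unit `"px"` or `"mm"`.
#' @return An object of class `landmark_sheet`.
#' @export
landmark_sheet <- function(subject_id, data, calibration = NULL,
                           unit = c("px", "mm")) {
  unit <- match.arg(unit)
  req <- c("view", "landmark", "side", "u", "v")
  if (!all(req %in% names(data))) {
    stop_pelvimetrix(sprintf("landmark data must have columns: %s",
      paste(req, collapse = ", ")))
  }
  data <- as.data.frame(data)[req]
  bad_view <- setdiff(unique(data$view), VIEWS)
  if (length(bad_view)) {
    stop_pelvimetrix(sprintf("unknown view(s): %s (allowed: %s)",
      paste(bad_view, collapse = ", "), paste(VIEWS, collapse = ", ")))
  }
  bad_lm <- setdiff(unique(data$landmark), LANDMARK_VOCAB)
  if (length(bad_lm)) {
    stop_pelvimetrix(sprintf("unknown landmark(s): %s (vocabulary: %s)",
      paste(bad_lm, collapse = ", "), paste(LANDMARK_VOCAB, collapse = ", ")))
  }
  bad_side <- setdiff(unique(data$side), SIDES)
  if (length(bad_side)) {
    stop_pelvimetrix(sprintf("unknown side(s): %s (allowed: %s)",
      paste(bad_side, collapse = ", "), paste(SIDES, collapse = ", ")))
  }
  check_finite(data$u, "u coordinates")
  check_finite(data$v, "v coordinates")
  key <- paste(data$view, data$landmark, data$side)
  if (anyDuplicated(key)) {
    stop_pelvimetrix(sprintf("duplicate landmark row(s): %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (unit == "px") {
    if (is.null(calibration)) {
      stop_pelvimetrix("pixel-unit sheets require a calibration record")
    }
    creq <- c("view", "fh_px", "fh_true_mm")
    if (!all(creq %in% names(calibration))) {
      stop_pelvimetrix(sprintf("calibration must have columns: %s",
        paste(creq, collapse = ", ")))
    }
    calibration <- as.data.frame(calibration)[creq]
    mm_per_pixel(calibration$fh_true_mm, calibration$fh_px) # validates
  }
  structure(
    list(subject_id = subject_id, data = data, calibration = calibration,
         unit = unit),
    class = "landmark_sheet")
}

#' Calibrate a pixel landmark sheet to millimetres
#'
#' Each view's coordinates are multiplied by that view's femoral-head scale
#' `fh_true_mm / fh_px`, so magnification may differ per projection. A sheet
#' already in mm is returned unchanged.
#'
#' @param sheet A `landmark_sheet`.
#' @return A `landmark_sheet` with `unit = "mm"` and an added
#'   `scales` element (named mm-per-pixel scale per view).
#' @export
calibrate_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "landmark_sheet"))
  if (sheet$unit == "mm") {
    if (is.null(sheet$scales)) sheet$scales <- c(ap = 1, inlet = 1, outlet = 1)
    return(sheet)
  }
  cal <- sheet$calibration
  need <- unique(sheet$data$view)
  missing_cal <- setdiff(need, cal$view)
  if (length(missing_cal)) {
    stop_pelvimetrix(sprintf("no calibration record for view(s): %s",
      paste(missing_cal, collapse = ", ")))
  }
  scales <- stats::setNames(mm_per_pixel(cal$fh_true_mm, cal$fh_px), cal$view)
  s <- scales[sheet$data$view]
  sheet$data$u <- sheet$data$u * s
  sheet$data$v <- sheet$data$v * s
  sheet$unit <- "mm"
  sheet$scales <- scales
  sheet
}

# Fetch one landmark's (u, v); NULL if absent.
sheet_coord <- function(sheet, view, landmark, side) {
  d <- sheet$data
  i <- which(d$view == view & d$landmark == landmark & d$side == side)
  if (!length(i)) return(NULL)
  c(u = d$u[i], v = d$v[i])
}

missing_landmarks <- function(sheet, formula) {
  need <- FORMULA_LANDMARKS[[formula]]
  miss <- vapply(seq_len(nrow(need)), function(i) {
    is.null(sheet_coord(sheet, need$view[i], need$landmark[i], need$side[i]))
  }, logical(1))
  need[miss, , drop = FALSE]
}

require_landmarks <- function(sheet, formula) {
  miss <- missing_landmarks(sheet, formula)
  if (nrow(miss)) {
    stop_pelvimetrix(
      sprintf("missing landmark(s) for %s measurement: %s", formula,
        paste(sprintf("%s [%s, %s]", miss$landmark, miss$view, miss$side),
              collapse = "; ")),
      class = "pelvimetrix_missing_landmark",
      landmarks = miss)
  }
  invisible(TRUE)
}

signed_direction <- function(value, pos, neg) {
  value <- unname(value)
  list(value_mm = value,
       direction = if (value > 0) pos else if (value < 0) neg else "none")
}

#' Vertical (cephalad/caudad) displacement from the outlet view
#'
#' `|v(C') - v(S)| - |v(C) - v(S)|` where C/C' are the intact/injured
#' superior iliac wing points and S the sacral endplate centre, all in the
#' outlet view, in mm. Positive values mean cephalad displacement of the
#' injured hemipelvis, negative caudad.
#'
#' @param sheet A `landmark_sheet` (calibrated automatically if in pixels).
#' @return List with `value_mm` and `direction`
#'   (`cephalad`/`caudad`/`none`).
#' @export
vertical_displacement <- function(sheet) {
  sheet <- calibrate_sheet(sheet)
  require_landmarks(sheet, "vertical")
  ci <- sheet_coord(sheet, "outlet", "iliac_wing_superior", "injured")
  cc <- sheet_coord(sheet, "outlet", "iliac_wing_superior", "intact")
  s <- sheet_coord(sheet, "outlet", "sacral_endplate_centre", "midline")
  signed_direction(abs(ci["v"] - s["v"]) - abs(cc["v"] - s["v"]),
                   "cephalad", "caudad")
}

#' Anterior-posterior displacement from the inlet view
#'
#' `|v(H') - v(S)| - |v(H) - v(S)|` with H/H' the intact/injured anterior
#' SI joint (iliac side) in the inlet view; the inlet image vertical is the
#' outlet-plane normal (Z). Positive = anterior, negative = posterior.
#'
#' @inheritParams vertical_displacement
#' @return List with `value_mm` and `direction`
#'   (`anterior`/`posterior`/`none`).
#' @export
ap_displacement <- function(sheet) {
  sheet <- calibrate_sheet(sheet)
  require_landmarks(sheet, "ap")
  hi <- sheet_coord(sheet, "inlet", "anterior_SI_joint", "injured")
  hc <- sheet_coord(sheet, "inlet", "anterior_SI_joint", "intact")
  s <- sheet_coord(sheet, "inlet", "sacral_endplate_centre", "midline")
  signed_direction(abs(hi["v"] - s["v"]) - abs(hc["v"] - s["v"]),
                   "anterior", "posterior")
}

#' Transverse (lateral/medial) displacement from the inlet view
#'
#' `|u(H') - u(S)| - |u(H) - u(S)|` in the inlet view. Positive = lateral
#' (away from the midline), negative = medial.
#'
#' @inheritParams vertical_displacement
#' @return List with `value_mm` and `direction` (`lateral`/`medial`/`none`).
#' @export
transverse_displacement <- function(sheet) {
  sheet <- calibrate_sheet(sheet)
  require_landmarks(sheet, "transverse")
  hi <- sheet_coord(sheet, "inlet", "anterior_SI_joint", "injured")
  hc <- sheet_coord(sheet, "inlet", "anterior_SI_joint", "intact")
  s <- sheet_coord(sheet, "inlet", "sacral_endplate_centre", "midline")
  signed_direction(abs(hi["u"] - s["u"]) - abs(hc["u"] - s["u"]),
                   "lateral", "medial")
}

#' Rotational displacement indicator for one plane
#'
#' Intact-side landmark distance minus injured-side landmark distance, in
#' mm, per plane:
#' \describe{
#'   \item{sagittal}{AP view, vertical ASIS-to-ischial-tuberosity distances:
#'     `|v(A) - v(B)| - |v(A') - v(B')|`.}
#'   \item{inlet}{inlet view, transverse ASIS-to-anterior-SI-joint
#'     distances: `|u(G) - u(H)| - |u(G') - u(H')|`.}
#'   \item{outlet}{outlet view, transverse ASIS-to-ischial-tuberosity
#'     distances: `|u(E) - u(D)| - |u(E') - u(D')|`.}
#' }
#'
#' @inheritParams vertical_displacement
#' @param plane One of `"sagittal"`, `"inlet"`, `"outlet"`.
#' @return Indicator in mm (positive when the injured-side distance is
#'   smaller than the intact-side distance).
#' @export
rotation_indicator <- function(sheet, plane = c("sagittal", "inlet", "outlet")) {
  plane <- match.arg(plane)
  sheet <- calibrate_sheet(sheet)
  require_landmarks(sheet, plane)
  cfg <- switch(plane,
    sagittal = list(view = "ap", a = "ASIS", b = "ischial_tuberosity",
                    coord = "v"),
    inlet = list(view = "inlet", a = "ASIS", b = "anterior_SI_joint",
                 coord = "u"),
    outlet = list(view = "outlet", a = "ASIS", b = "ischial_tuberosity",
                  coord = "u"))
  dist_side <- function(side) {
    a <- sheet_coord(sheet, cfg$view, cfg$a, side)
    b <- sheet_coord(sheet, cfg$view, cfg$b, side)
    abs(a[cfg$coord] - b[cfg$coord])
  }
  unname(dist_side("intact") - dist_side("injured"))
}

ROTATION_LABELS <- list(
  table2 = list(
    sagittal = c(neg = "flexion", pos = "extension"),
    inlet = c(neg = "external_rotation", pos = "internal_rotation"),
    outlet = c(neg = "valgus", pos = "varus")),
  # Alternative reading of the descriptive prose, which inverts the
  # sagittal and outlet label pairs relative to the canonical table.
  text = list(
    sagittal = c(neg = "extension", pos = "flexion"),
    inlet = c(neg = "external_rotation", pos = "internal_rotation"),
    outlet = c(neg = "varus", pos = "valgus"))
)

#' Classify a rotational indicator against the neutral band
#'
#' Indicators strictly below `-threshold_mm` or strictly above
#' `+threshold_mm` are classified in the plane's two directions; the band
#' `[-threshold_mm, +threshold_mm]` is neutral, inclusive at both ends.
#'
#' @param indicator_mm Rotational indicator (mm), as returned by
#'   [rotation_indicator()].
#' @param plane `"sagittal"`, `"inlet"` or `"outlet"`.
#' @param threshold_mm Half-width of the neutral band in mm (> 0);
#'   default 2, the anatomic-reduction threshold.
#' @param label_convention `"table2"` (canonical) or `"text"` (inverts the
#'   sagittal and outlet label pairs).
#' @return Class label: `neutral`, or one of `flexion`/`extension`,
#'   `internal_rotation`/`external_rotation`, `varus`/`valgus`.
#' @export
#' @examples
#' classify_rotation(-3, "sagittal") # "flexion"
#' classify_rotation(2, "inlet")     # "neutral" (band inclusive)
classify_rotation <- function(indicator_mm,
                              plane = c("sagittal", "inlet", "outlet"),
                              threshold_mm = 2,
                              label_convention = c("table2", "text")) {
  plane <- match.arg(plane)
  label_convention <- match.arg(label_convention)
  check_finite(indicator_mm, "indicator_mm")
  if (!is.numeric(threshold_mm) || length(threshold_mm) != 1L ||
      threshold_mm <= 0) {
    stop_pelvimetrix("threshold_mm must be a single positive number")
  }
  labs <- ROTATION_LABELS[[label_convention]][[plane]]
  ifelse(indicator_mm < -threshold_mm, labs[["neg"]],
    ifelse(indicator_mm > threshold_mm, labs[["pos"]], "neutral"))
}

#' Full displacement report for one subject
#'
#' Aggregates the three translational displacements and the three
#' rotational indicators with their classes from one calibrated landmark
#' sheet. Deterministic: the same sheet always yields the identical report.
#'
#' @inheritParams vertical_displacement
#' @param threshold_mm Neutral band half-width (mm).
#' @param label_convention `"table2"` or `"text"`.
#' @param allow_partial If `TRUE`, formulas with missing landmarks yield
#'   `NA` instead of failing; default `FALSE` fails loudly, listing every
#'   absent landmark at once.
#' @return An object of class `displacement_report`.
#' @export
measure_displacement <- function(sheet, threshold_mm = 2,
                                 label_convention = c("table2", "text"),
                                 allow_partial = FALSE) {
  label_convention <- match.arg(label_convention)
  sheet <- calibrate_sheet(sheet)
  all_missing <- do.call(rbind, lapply(names(FORMULA_LANDMARKS),
    function(f) missing_landmarks(sheet, f)))
  all_missing <- unique(all_missing)
  if (nrow(all_missing) && !allow_partial) {
    stop_pelvimetrix(
      sprintf("missing landmark(s): %s",
        paste(sprintf("%s [%s, %s]", all_missing$landmark, all_missing$view,
                      all_missing$side), collapse = "; ")),
      class = "pelvimetrix_missing_landmark",
      landmarks = all_missing)
  }
  try_val <- function(fun, ...) {
    tryCatch(fun(sheet, ...), pelvimetrix_missing_landmark = function(e) NULL)
  }
  na_sd <- list(value_mm = NA_real_, direction = NA_character_)
  tr <- list(
    vertical = try_val(vertical_displacement),
    ap = try_val(ap_displacement),
    transverse = try_val(transverse_displacement))
  tr <- lapply(tr, function(x) if (is.null(x)) na_sd else x)
  rot <- lapply(c(sagittal = "sagittal", inlet = "inlet", outlet = "outlet"),
    function(p) {
      ind <- tryCatch(rotation_indicator(sheet, p),
        pelvimetrix_missing_landmark = function(e) NA_real_)
      list(indicator_mm = ind,
           class = if (is.na(ind)) NA_character_ else
             classify_rotation(ind, p, threshold_mm, label_convention))
    })
  structure(
    list(subject_id = sheet$subject_id, translation = tr, rotation = rot,
         threshold_mm = threshold_mm, label_convention = label_convention,
         scales = sheet$scales),
    class = "displacement_report")
}

#' @export
as.data.frame.displacement_report <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    vertical_mm = unname(x$translation$vertical$value_mm),
    vertical_dir = x$translation$vertical$direction,
    ap_mm = unname(x$translation$ap$value_mm),
    ap_dir = x$translation$ap$direction,
    transverse_mm = unname(x$translation$transverse$value_mm),
    transverse_dir = x$translation$transverse$direction,
    sagittal_mm = unname(x$rotation$sagittal$indicator_mm),
    sagittal_class = x$rotation$sagittal$class,
    inlet_mm = unname(x$rotation$inlet$indicator_mm),
    inlet_class = x$rotation$inlet$class,
    outlet_mm = unname(x$rotation$outlet$indicator_mm),
    outlet_class = x$rotation$outlet$class,
    stringsAsFactors = FALSE)
}

#' @export
print.displacement_report <- function(x, ...) {
  cat(sprintf("Displacement report for subject '%s'\n", x$subject_id))
  cat(sprintf("  vertical:   %8.3f mm (%s)\n",
    x$translation$vertical$value_mm, x$translation$vertical$direction))
  cat(sprintf("  AP:         %8.3f mm (%s)\n",
    x$translation$ap$value_mm, x$translation$ap$direction))
  cat(sprintf("  transverse: %8.3f mm (%s)\n",
    x$translation$transverse$value_mm, x$translation$transverse$direction))
  for (p in names(x$rotation)) {
    cat(sprintf("  %-10s %8.3f mm -> %s\n", paste0(p, ":"),
      x$rotation[[p]]$indicator_mm, x$rotation[[p]]$class))
  }
  cat(sprintf("  neutral band: +/- %g mm; labels: %s\n",
    x$threshold_mm, x$label_convention))
  invisible(x)
}

#' @export
print.landmark_sheet <- function(x, ...) {
  cat(sprintf("<landmark_sheet> subject '%s', %d landmarks, unit = %s\n",
    x$subject_id, nrow(x$data), x$unit))
  invisible(x)
}
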
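# Forward model and in-silico study generator: a parametric bilateral
# hemipelvis landmark template with exact mirror symmetry, rigid
# displacement of the injured side with a documented sign convention,
# orthographic rendering to pixel landmark sheets, observer marking noise,
# and recovery evaluation against the known ground truth.

TEMPLATE_LANDMARKS <- c("ASIS", "ischial_tuberosity", "iliac_wing_superior",
                        "anterior_SI_joint", "PSIS")

# Left-side landmark coordinates in a body-aligned frame (mm): columns are
# lateral offset from the midline, height above the S1 endplate centre, and
# anterior offset from it. Engineering fixture with plausible adult
# magnitudes; not measured anatomy.
TEMPLATE_BODY_FRAME <- rbind(
  ASIS                = c(120,  -60,  85),
  ischial_tuberosity  = c( 55, -200,   5),
  iliac_wing_superior = c( 95,   55,  15),
  anterior_SI_joint   = c( 45,  -30,  20),
  PSIS                = c( 35,  -10, -55),
  femoral_head        = c( 90,  -75,  75)
)

#' Default bilateral hemipelvis landmark template
#'
#' Ground-truth anatomy for the simulator: the five bony landmarks per side
#' plus the femoral head centre, expressed in the pelvis-specific frame
#' (origin at the sacral endplate centre S; +X patient-left, +Y
#' perpendicular to the inlet plane, +Z perpendicular to the outlet plane).
#' The template is authored in a body-aligned frame and rotated into the
#' pelvis frame by the pelvic obliquity, so that its projections look like
#' standard radiographs; the two sides are exactly mirror-symmetric about
#' the X = 0 midplane.
#'
#' @param obliquity_deg Pelvic obliquity (degrees) used to convert the
#'   body-frame authoring coordinates into the pelvis frame; default 45.
#' @param fh_diameter_mm True femoral head diameter (mm), the calibration
#'   fiducial; default 48.
#' @return An object of class `pelvis_template`: list with `landmarks`
#'   (data frame `landmark`, `side`, `x`, `y`, `z`), `fh_centre`,
#'   `fh_diameter_mm` and `obliquity_deg`.
#' @export
default_template <- function(obliquity_deg = 45, fh_diameter_mm = 48) {
  check_finite(obliquity_deg, "obliquity_deg")
  if (fh_diameter_mm <= 0) {
    stop_pelvimetrix("fh_diameter_mm must be positive")
  }
  t <- obliquity_deg * pi / 180
  bf <- TEMPLATE_BODY_FRAME
  # body (lateral, superior, anterior) -> pelvis frame (x, y, z)
  pelvis <- cbind(
    x = bf[, 1],
    y = bf[, 2] * sin(t) + bf[, 3] * cos(t),
    z = bf[, 3] * sin(t) - bf[, 2] * cos(t))
  mk_side <- function(side, sgn) {
    data.frame(landmark = rownames(bf)[1:5], side = side,
      x = sgn * pelvis[1:5, "x"], y = pelvis[1:5, "y"], z = pelvis[1:5, "z"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  fh <- data.frame(side = c("left", "right"),
    x = c(pelvis["femoral_head", "x"], -pelvis["femoral_head", "x"]),
    y = pelvis["femoral_head", "y"], z = pelvis["femoral_head", "z"],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(landmarks = rbind(mk_side("left", 1), mk_side("right", -1)),
         fh_centre = fh, fh_diameter_mm = fh_diameter_mm,
         obliquity_deg = obliquity_deg, injured_side = NA_character_),
    class = "pelvis_template")
}

template_side_matrix <- function(template, side) {
  d <- template$landmarks[template$landmarks$side == side, ]
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$landmark
  m
}

#' Ground-truth rigid displacement of the injured hemipelvis
#'
#' Sign conventions (positive value -> named direction, mirrored
#' consistently between sides):
#' \describe{
#'   \item{rot_x}{extension (+) / flexion (-), about the transverse axis.}
#'   \item{rot_y}{internal (+) / external (-) rotation, about the
#'     inlet-plane normal.}
#'   \item{rot_z}{varus (+) / valgus (-), about the outlet-plane normal.}
#'   \item{tx, ty, tz}{translation along +X (patient-left), +Y, +Z (mm).}
#' }
#'
#' @param tx,ty,tz Translation components (mm).
#' @param rot_x,rot_y,rot_z Rotation angles (degrees) with the directional
#'   meaning above.
#' @param pivot `"centroid"` (of the injured side's five landmarks,
#'   default), `"si_joint"`, `"acetabulum"`, or a length-3 point (mm).
#' @param injured_side `"left"` or `"right"`.
#' @return An object of class `displacement_spec`.
#' @export
displacement_spec <- function(tx = 0, ty = 0, tz = 0,
                              rot_x = 0, rot_y = 0, rot_z = 0,
                              pivot = "centroid", injured_side = "right") {
  check_finite(c(tx, ty, tz, rot_x, rot_y, rot_z), "displacement parameters")
  if (!injured_side %in% c("left", "right")) {
    stop_pelvimetrix("injured_side must be 'left' or 'right'")
  }
  if (is.character(pivot)) {
    if (!pivot %in% c("centroid", "si_joint", "acetabulum")) {
      stop_pelvimetrix(
        "pivot must be 'centroid', 'si_joint', 'acetabulum' or a 3D point")
    }
  } else {
    check_finite(pivot, "pivot")
    if (length(pivot) != 3L) stop_pelvimetrix("numeric pivot must be length 3")
  }
  structure(
    list(translation = c(tx = tx, ty = ty, tz = tz),
         rotation = c(rot_x = rot_x, rot_y = rot_y, rot_z = rot_z),
         pivot = pivot, injured_side = injured_side),
    class = "displacement_spec")
}

resolve_pivot <- function(template, spec) {
  if (is.numeric(spec$pivot)) return(as.numeric(spec$pivot))
  m <- template_side_matrix(template, spec$injured_side)
  switch(spec$pivot,
    centroid = colMeans(m),
    si_joint = m["anterior_SI_joint", ],
    acetabulum = {
      fh <- template$fh_centre
      as.numeric(fh[fh$side == spec$injured_side, c("x", "y", "z")])
    })
}

# Map the anatomical rotation convention to world angles about +X/+Y/+Z.
# Flexion/extension is mirror-symmetric in X, so the world angle equals
# rot_x for both sides; internal/external and varus/valgus are mirror
# antisymmetric, so the world angle flips sign between sides.
world_rotation <- function(rotation, injured_side) {
  c(rotation[["rot_x"]],
    if (injured_side == "right") rotation[["rot_y"]] else -rotation[["rot_y"]],
    if (injured_side == "left") rotation[["rot_z"]] else -rotation[["rot_z"]])
}

#' Apply a ground-truth displacement to the injured hemipelvis
#'
#' Rigidly transforms the injured side's landmarks and femoral head centre;
#' the intact side and the sacral endplate centre stay fixed.
#'
#' @param template A `pelvis_template`.
#' @param spec A `displacement_spec`.
#' @return A displaced `pelvis_template` with `injured_side` recorded.
#' @export
displace <- function(template, spec) {
  stopifnot(inherits(template, "pelvis_template"),
            inherits(spec, "displacement_spec"))
  w <- world_rotation(spec$rotation, spec$injured_side)
  tf <- rigid_transform(rot_x = w[1], rot_y = w[2], rot_z = w[3],
    pivot = resolve_pivot(template, spec),
    translation = spec$translation)
  side <- spec$injured_side
  idx <- template$landmarks$side == side
  template$landmarks[idx, c("x", "y", "z")] <-
    apply_rigid(as.matrix(template$landmarks[idx, c("x", "y", "z")]), tf)
  fidx <- template$fh_centre$side == side
  template$fh_centre[fidx, c("x", "y", "z")] <-
    apply_rigid(as.matrix(template$fh_centre[fidx, c("x", "y", "z")]), tf)
  template$injured_side <- side
  template
}

# Which landmarks are digitised in which view (the per-view scheme of the
# measurement system; S is the shared midline reference in inlet/outlet).
VIEW_LANDMARKS <- list(
  ap = c("ASIS", "ischial_tuberosity"),
  outlet = c("iliac_wing_superior", "ischial_tuberosity", "ASIS"),
  inlet = c("ASIS", "anterior_SI_joint")
)

#' Render a displaced template into a pixel landmark sheet
#'
#' Projects each view's landmark set orthographically, converts mm to
#' pixels at the given rendering scale, and attaches the femoral-head
#' calibration record (pixel diameter = true diameter / mm-per-pixel,
#' per view).
#'
#' @param template A `pelvis_template` (displaced or not).
#' @param subject_id Subject identifier for the sheet.
#' @param injured_side `"left"` or `"right"`; defaults to the side recorded
#'   by [displace()].
#' @param views Named list of the three views (see [default_views()]).
#' @param mm_per_px Rendering scale, a scalar or a named per-view vector.
#' @return A pixel-unit `landmark_sheet`.
#' @export
render_sheets <- function(template, subject_id = "subject",
                          injured_side = template$injured_side,
                          views = default_views(), mm_per_px = 0.5) {
  stopifnot(inherits(template, "pelvis_template"))
  if (is.na(injured_side) || !injured_side %in% c("left", "right")) {
    stop_pelvimetrix("injured_side must be 'left' or 'right'")
  }
  if (!all(c("ap", "inlet", "outlet") %in% names(views))) {
    stop_pelvimetrix("views must contain 'ap', 'inlet' and 'outlet'")
  }
  if (length(mm_per_px) == 1L) {
    mm_per_px <- c(ap = mm_per_px, inlet = mm_per_px, outlet = mm_per_px)
  }
  check_finite(mm_per_px, "mm_per_px")
  if (any(mm_per_px <= 0)) stop_pelvimetrix("mm_per_px must be positive")
  side_label <- function(s) ifelse(s == injured_side, "injured", "intact")
  rows <- list()
  for (vn in c("ap", "inlet", "outlet")) {
    pts <- template$landmarks[
      template$landmarks$landmark %in% VIEW_LANDMARKS[[vn]], ]
    uv <- project_points(as.matrix(pts[, c("x", "y", "z")]), views[[vn]])
    rows[[vn]] <- data.frame(view = vn, landmark = pts$landmark,
      side = side_label(pts$side),
      u = uv[, "u"] / mm_per_px[[vn]], v = uv[, "v"] / mm_per_px[[vn]],
      stringsAsFactors = FALSE, row.names = NULL)
    if (vn %in% c("inlet", "outlet")) {
      suv <- project_points(rbind(c(0, 0, 0)), views[[vn]])
      rows[[paste0(vn, "_s")]] <- data.frame(view = vn,
        landmark = "sacral_endplate_centre", side = "midline",
        u = suv[, "u"] / mm_per_px[[vn]], v = suv[, "v"] / mm_per_px[[vn]],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  calibration <- data.frame(
    view = c("ap", "inlet", "outlet"),
    fh_px = template$fh_diameter_mm / mm_per_px[c("ap", "inlet", "outlet")],
    fh_true_mm = template$fh_diameter_mm,
    stringsAsFactors = FALSE, row.names = NULL)
  landmark_sheet(subject_id, do.call(rbind, rows), calibration, unit = "px")
}

#' Add observer marking noise to a landmark sheet
#'
#' Perturbs every landmark coordinate independently with isotropic Gaussian
#' noise of the given standard deviation in image millimetres (converted to
#' pixels through each view's calibration scale). The calibration record
#' itself is left untouched. Seed-deterministic and side-effect free on the
#' caller's RNG stream.
#'
#' @param sheet A `landmark_sheet`.
#' @param sd_mm Noise standard deviation in mm, `>= 0`.
#' @param seed Optional integer seed.
#' @return A `landmark_sheet` of the same unit.
#' @export
add_marking_noise <- function(sheet, sd_mm, seed = NULL) {
  stopifnot(inherits(sheet, "landmark_sheet"))
  check_finite(sd_mm, "sd_mm")
  if (sd_mm < 0) stop_pelvimetrix("sd_mm must be non-negative")
  if (sd_mm == 0) return(sheet)
  if (sheet$unit == "px") {
    cal <- sheet$calibration
    scales <- stats::setNames(mm_per_pixel(cal$fh_true_mm, cal$fh_px),
                              cal$view)
    sd_units <- sd_mm / scales[sheet$data$view]
  } else {
    sd_units <- rep(sd_mm, nrow(sheet$data))
  }
  n <- nrow(sheet$data)
  noise <- with_seed(seed, matrix(stats::rnorm(2 * n), n, 2))
  sheet$data$u <- sheet$data$u + noise[, 1] * sd_units
  sheet$data$v <- sheet$data$v + noise[, 2] * sd_units
  sheet
}

#' Displacement distribution for simulated study subjects
#'
#' A two-component mixture spanning the unstable pelvic ring injury
#' spectrum. Every subject is displaced: the three translation components
#' are drawn from a zero-mean truncated Gaussian with SD
#' `translation_sd_mm` (capped at `translation_cap_mm`), mirroring a
#' cohort of uniformly dislocated hemipelves. The rotational pattern
#' differs by component: translation-dominant subjects (type C-like
#' vertical-shear patterns) carry only small residual rotations
#' (`minor_rotation_sd_deg`), while rotation-dominant subjects (type
#' B-like open/closed-book and compression patterns) draw rotations at the
#' full `rotation_sd_deg` scale (capped at `rotation_cap_deg`).
#'
#' @param p_translation_dominant Mixture weight of the type C-like
#'   component.
#' @param translation_sd_mm,translation_cap_mm Translation scale and
#'   truncation bound (mm), applied to every subject.
#' @param rotation_sd_deg,rotation_cap_deg Rotation scale and truncation
#'   bound (degrees) for rotation-dominant subjects.
#' @param minor_rotation_sd_deg Residual rotation scale (degrees) for
#'   translation-dominant subjects.
#' @return An object of class `displacement_distribution`.
#' @export
displacement_distribution <- function(p_translation_dominant = 0.5,
                                      translation_sd_mm = 10,
                                      translation_cap_mm = 30,
                                      rotation_sd_deg = 8,
                                      rotation_cap_deg = 20,
                                      minor_rotation_sd_deg = 2) {
  vals <- c(p_translation_dominant, translation_sd_mm, translation_cap_mm,
            rotation_sd_deg, rotation_cap_deg, minor_rotation_sd_deg)
  check_finite(vals, "distribution parameters")
  if (p_translation_dominant < 0 || p_translation_dominant > 1) {
    stop_pelvimetrix("p_translation_dominant must lie in [0, 1]")
  }
  if (any(vals[-1] < 0)) {
    stop_pelvimetrix("distribution scales and caps must be non-negative")
  }
  structure(as.list(environment())[c(
    "p_translation_dominant", "translation_sd_mm", "translation_cap_mm",
    "rotation_sd_deg", "rotation_cap_deg", "minor_rotation_sd_deg")],
    class = "displacement_distribution")
}

rnorm_trunc <- function(n, sd, cap) {
  if (sd == 0 || cap == 0) return(rep(0, n))
  out <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(out) > cap)) {
    out[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  out
}

draw_spec <- function(dist, pivot) {
  dominant_translation <- stats::runif(1) < dist$p_translation_dominant
  rsd <- if (dominant_translation) dist$minor_rotation_sd_deg else
    dist$rotation_sd_deg
  tr <- rnorm_trunc(3, dist$translation_sd_mm, dist$translation_cap_mm)
  ro <- rnorm_trunc(3, rsd, dist$rotation_cap_deg)
  displacement_spec(tx = tr[1], ty = tr[2], tz = tr[3],
    rot_x = ro[1], rot_y = ro[2], rot_z = ro[3], pivot = pivot,
    injured_side = sample(c("left", "right"), 1))
}

#' Simulate a multi-rater reliability study
#'
#' Draws per-subject ground-truth displacements, renders the noiseless
#' landmark sheets, and derives one independently perturbed sheet per
#' rater. The whole study is a deterministic function of `seed`.
#'
#' @param n_subjects Number of simulated subjects (`>= 2`); 25 mirrors the
#'   reference study design.
#' @param n_raters Number of simulated observers (`>= 2`); default 5.
#' @param sd_mm Observer marking noise SD in image mm; default 1.
#' @param seed Integer seed driving every random draw.
#' @param distribution A [displacement_distribution()].
#' @param template A `pelvis_template`.
#' @param pivot Rotation pivot passed to [displacement_spec()].
#' @param views Views used for rendering.
#' @param mm_per_px Rendering scale.
#' @return An object of class `simulated_study`: list with `truth` (data
#'   frame of ground-truth parameters), `specs`, `noiseless_sheets`,
#'   `rater_sheets` (list indexed `[[rater]][[subject]]`), and the
#'   generating configuration.
#' @export
simulate_study <- function(n_subjects = 25, n_raters = 5, sd_mm = 1,
                           seed = 1,
                           distribution = displacement_distribution(),
                           template = default_template(),
                           pivot = "centroid",
                           views = default_views(), mm_per_px = 0.5) {
  if (n_subjects < 2 || n_raters < 2) {
    stop_pelvimetrix("need n_subjects >= 2 and n_raters >= 2")
  }
  stopifnot(inherits(distribution, "displacement_distribution"))
  all_zero <- distribution$translation_sd_mm == 0 &&
    distribution$rotation_sd_deg == 0 &&
    distribution$minor_rotation_sd_deg == 0
  if (all_zero) {
    warn_degenerate(paste(
      "all-zero displacement distribution: simulated subjects are",
      "undisplaced and reliability statistics will be degenerate"))
  }
  ids <- sprintf("S%03d", seq_len(n_subjects))
  specs <- with_seed(derive_seed(seed, 0L),
    lapply(seq_len(n_subjects), function(i) draw_spec(distribution, pivot)))
  names(specs) <- ids
  noiseless <- lapply(seq_len(n_subjects), function(i) {
    render_sheets(displace(template, specs[[i]]), subject_id = ids[i],
      views = views, mm_per_px = mm_per_px)
  })
  names(noiseless) <- ids
  rater_sheets <- lapply(seq_len(n_raters), function(k) {
    sheets <- lapply(seq_len(n_subjects), function(i) {
      add_marking_noise(noiseless[[i]], sd_mm,
        seed = derive_seed(seed, k, i))
    })
    names(sheets) <- ids
    sheets
  })
  names(rater_sheets) <- sprintf("rater%d", seq_len(n_raters))
  truth <- do.call(rbind, lapply(ids, function(id) {
    s <- specs[[id]]
    data.frame(subject_id = id, injured_side = s$injured_side,
      tx_mm = s$translation[["tx"]], ty_mm = s$translation[["ty"]],
      tz_mm = s$translation[["tz"]], rot_x_deg = s$rotation[["rot_x"]],
      rot_y_deg = s$rotation[["rot_y"]], rot_z_deg = s$rotation[["rot_z"]],
      pivot = if (is.character(s$pivot)) s$pivot else
        paste(s$pivot, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  structure(
    list(truth = truth, specs = specs, noiseless_sheets = noiseless,
         rater_sheets = rater_sheets, n_subjects = n_subjects,
         n_raters = n_raters, sd_mm = sd_mm, seed = seed,
         distribution = distribution, template = template, pivot = pivot,
         views = views, mm_per_px = mm_per_px),
    class = "simulated_study")
}

#' Measure every rater's sheets of a simulated study
#'
#' @param study A `simulated_study`.
#' @param threshold_mm,label_convention Passed to [measure_displacement()].
#' @return Long data frame: one row per rater x subject with the six
#'   numeric parameters and three class labels, ready for
#'   [reliability_report()] and [evaluate_recovery()].
#' @export
measure_study <- function(study, threshold_mm = 2,
                          label_convention = c("table2", "text")) {
  stopifnot(inherits(study, "simulated_study"))
  label_convention <- match.arg(label_convention)
  out <- lapply(names(study$rater_sheets), function(rt) {
    dfs <- lapply(study$rater_sheets[[rt]], function(sh) {
      as.data.frame(measure_displacement(sh, threshold_mm = threshold_mm,
        label_convention = label_convention))
    })
    cbind(rater = rt, do.call(rbind, dfs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

truth_direction <- function(angle, plane) {
  stopifnot(angle != 0)
  labs <- ROTATION_LABELS$table2[[plane]]
  if (angle > 0) labs[["pos"]] else labs[["neg"]]
}

#' Evaluate measurement recovery against ground truth
#'
#' Compares per-rater measurements with the simulator's known rigid
#' displacements: signed bias and RMSE for the three translations
#' (ground-truth transverse displacement is expressed lateral-positive for
#' the injured side) and a confusion matrix plus accuracy for each
#' rotational class. The ground-truth class of a plane is the direction of
#' its nonzero true angle; when the true angle is exactly zero it is the
#' classification of the noiselessly rendered indicator (which can be
#' non-neutral through projection cross-talk from other-axis rotations).
#'
#' @param truth Ground-truth data frame as in `simulated_study$truth`, or a
#'   `simulated_study` (its `truth` is used).
#' @param measurements Long measurement data frame from [measure_study()]
#'   (or CSV reports read back with a `rater` column).
#' @param threshold_mm Neutral band half-width used for truth classes.
#' @param label_convention Label convention used for truth classes.
#' @param template,views,mm_per_px,pivot Forward-model settings used to
#'   re-render noiseless indicators; default to the study's own settings
#'   when `truth` is a `simulated_study`.
#' @return An object of class `recovery_table`: list with `translation`
#'   (parameter, bias_mm, rmse_mm, n), `rotation_accuracy` (plane,
#'   accuracy, n) and `confusion` (per-plane tables truth x measured).
#' @export
evaluate_recovery <- function(truth, measurements, threshold_mm = 2,
                              label_convention = c("table2", "text"),
                              template = default_template(),
                              views = default_views(), mm_per_px = 0.5,
                              pivot = "centroid") {
  label_convention <- match.arg(label_convention)
  if (inherits(truth, "simulated_study")) {
    study <- truth
    truth <- study$truth
    template <- study$template
    views <- study$views
    mm_per_px <- study$mm_per_px
    pivot <- study$pivot
  }
  if (!setequal(unique(measurements$subject_id), truth$subject_id)) {
    stop_pelvimetrix(sprintf(
      "subject sets differ between truth and measurements: %s",
      paste(c(setdiff(truth$subject_id, measurements$subject_id),
              setdiff(measurements$subject_id, truth$subject_id)),
            collapse = ", ")))
  }
  i <- match(as.character(measurements$subject_id),
             as.character(truth$subject_id))
  true_vertical <- truth$ty_mm[i]
  true_ap <- truth$tz_mm[i]
  true_transverse <- ifelse(truth$injured_side[i] == "left",
                            truth$tx_mm[i], -truth$tx_mm[i])
  translation <- data.frame(
    parameter = c("vertical_mm", "ap_mm", "transverse_mm"),
    bias_mm = c(mean(measurements$vertical_mm - true_vertical),
                mean(measurements$ap_mm - true_ap),
                mean(measurements$transverse_mm - true_transverse)),
    rmse_mm = c(sqrt(mean((measurements$vertical_mm - true_vertical)^2)),
                sqrt(mean((measurements$ap_mm - true_ap)^2)),
                sqrt(mean((measurements$transverse_mm - true_transverse)^2))),
    n = nrow(measurements), stringsAsFactors = FALSE)
  # truth classes, re-rendering noiseless indicators where the angle is 0
  angle_cols <- c(sagittal = "rot_x_deg", inlet = "rot_y_deg",
                  outlet = "rot_z_deg")
  truth_classes <- matrix(NA_character_, nrow(truth), 3,
    dimnames = list(truth$subject_id, names(angle_cols)))
  needs_render <- truth[rowSums(truth[, angle_cols] == 0) > 0, , drop = FALSE]
  rendered <- list()
  for (j in seq_len(nrow(needs_render))) {
    r <- needs_render[j, ]
    spec <- displacement_spec(tx = r$tx_mm, ty = r$ty_mm, tz = r$tz_mm,
      rot_x = r$rot_x_deg, rot_y = r$rot_y_deg, rot_z = r$rot_z_deg,
      pivot = pivot, injured_side = r$injured_side)
    rendered[[as.character(r$subject_id)]] <- render_sheets(
      displace(template, spec), subject_id = r$subject_id,
      views = views, mm_per_px = mm_per_px)
  }
  for (j in seq_len(nrow(truth))) {
    for (p in names(angle_cols)) {
      ang <- truth[j, angle_cols[[p]]]
      truth_classes[j, p] <- if (ang != 0) {
        lab <- ROTATION_LABELS[[label_convention]][[p]]
        if (ang > 0) lab[["pos"]] else lab[["neg"]]
      } else {
        ind <- rotation_indicator(rendered[[as.character(truth$subject_id[j])]],
                                  p)
        classify_rotation(ind, p, threshold_mm, label_convention)
      }
    }
  }
  class_cols <- c(sagittal = "sagittal_class", inlet = "inlet_class",
                  outlet = "outlet_class")
  confusion <- list()
  acc <- data.frame(plane = names(class_cols), accuracy = NA_real_,
                    n = nrow(measurements), stringsAsFactors = FALSE)
  for (p in names(class_cols)) {
    tr <- truth_classes[as.character(measurements$subject_id), p]
    me <- measurements[[class_cols[[p]]]]
    lv <- sort(unique(c(tr, me)))
    confusion[[p]] <- table(truth = factor(tr, lv), measured = factor(me, lv))
    acc$accuracy[acc$plane == p] <- mean(tr == me)
  }
  structure(list(translation = translation, rotation_accuracy = acc,
                 confusion = confusion),
            class = "recovery_table")
}

#' @export
print.pelvis_template <- function(x, ...) {
  cat(sprintf(
    "<pelvis_template> %d landmarks/side, fh diameter %.1f mm, obliquity %g deg%s\n",
    length(TEMPLATE_LANDMARKS), x$fh_diameter_mm, x$obliquity_deg,
    if (!is.na(x$injured_side)) paste0(", injured side: ", x$injured_side)
    else ""))
  invisible(x)
}

#' @export
print.displacement_spec <- function(x, ...) {
  cat(sprintf(
    "<displacement_spec> %s side; t = (%s) mm; rot = (%s) deg; pivot = %s\n",
    x$injured_side,
    paste(formatC(x$translation, format = "g", digits = 4), collapse = ", "),
    paste(formatC(x$rotation, format = "g", digits = 4), collapse = ", "),
    if (is.character(x$pivot)) x$pivot else
      paste(formatC(x$pivot, format = "g"), collapse = ", ")))
  invisible(x)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d subjects x %d raters, marking noise %g mm, seed %d\n",
    x$n_subjects, x$n_raters, x$sd_mm, x$seed))
  invisible(x)
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("Translational recovery (measured - truth):\n")
  print(x$translation, row.names = FALSE, digits = 4)
  cat("Rotational class accuracy:\n")
  print(x$rotation_accuracy, row.names = FALSE, digits = 4)
  invisible(x)
}
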
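test_that("default template is exactly mirror-symmetric and anatomically plausible", {
  tpl <- default_template()
  left <- tpl$landmarks[tpl$landmarks$side == "left", ]
  right <- tpl$landmarks[tpl$landmarks$side == "right", ]
  expect_identical(left$landmark, right$landmark)
  expect_identical(left$x, -right$x)
  expect_identical(left$y, right$y)
  expect_identical(left$z, right$z)
  expect_gt(tpl$fh_diameter_mm, 0)
  # inter-landmark distances within plausible adult bounds (mm)
  lm3 <- function(side, name) {
    r <- tpl$landmarks[tpl$landmarks$side == side &
                       tpl$landmarks$landmark == name, ]
    c(r$x, r$y, r$z)
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_true(d(lm3("left", "ASIS"), lm3("right", "ASIS")) > 200 &&
              d(lm3("left", "ASIS"), lm3("right", "ASIS")) < 300)
  expect_true(d(lm3("left", "ASIS"), lm3("left", "ischial_tuberosity")) > 120 &&
              d(lm3("left", "ASIS"), lm3("left", "ischial_tuberosity")) < 230)
  expect_true(d(lm3("left", "anterior_SI_joint"), c(0, 0, 0)) < 80)
})

test_that("zero displacement measures as zero everywhere", {
  sheet <- render_sheets(default_template(), injured_side = "left")
  rep <- as.data.frame(measure_displacement(sheet))
  for (col in c("vertical_mm", "ap_mm", "transverse_mm", "sagittal_mm",
                "inlet_mm", "outlet_mm")) {
    expect_equal(rep[[col]], 0, tolerance = 1e-9)
  }
  expect_identical(unique(unlist(
    rep[c("sagittal_class", "inlet_class", "outlet_class")])), "neutral")
})

test_that("displace moves only the injured side, rigidly", {
  tpl <- default_template()
  # pure translation shifts y only
  d1 <- displace(tpl, displacement_spec(ty = 10, injured_side = "right"))
  moved <- d1$landmarks[d1$landmarks$side == "right", ]
  orig <- tpl$landmarks[tpl$landmarks$side == "right", ]
  expect_equal(moved$y, orig$y + 10)
  expect_equal(moved$x, orig$x)
  expect_equal(moved$z, orig$z)
  expect_identical(d1$landmarks[d1$landmarks$side == "left", ],
                   tpl$landmarks[tpl$landmarks$side == "left", ])
  # rotation about any pivot preserves injured-side intra-landmark distances
  for (pivot in c("centroid", "si_joint", "acetabulum")) {
    d2 <- displace(tpl, displacement_spec(rot_x = 8, rot_y = -5, rot_z = 12,
      pivot = pivot, injured_side = "left"))
    m0 <- as.matrix(tpl$landmarks[tpl$landmarks$side == "left",
                                  c("x", "y", "z")])
    m1 <- as.matrix(d2$landmarks[d2$landmarks$side == "left",
                                 c("x", "y", "z")])
    expect_lt(max(abs(dist(m0) - dist(m1))), 1e-9)
  }
  expect_error(displacement_spec(injured_side = "both"),
    class = "pelvimetrix_validation")
})

test_that("rendering follows the per-view landmark scheme and calibration", {
  sheet <- render_sheets(default_template(), injured_side = "right",
                         mm_per_px = 0.5)
  d <- sheet$data
  # S shares its u coordinate between inlet and outlet (common X axis)
  s_u <- d$u[d$landmark == "sacral_endplate_centre"]
  expect_equal(s_u[1], s_u[2])
  # view-specific landmark sets
  expect_setequal(d$landmark[d$view == "ap"], c("ASIS", "ischial_tuberosity"))
  expect_setequal(d$landmark[d$view == "inlet"],
    c("ASIS", "anterior_SI_joint", "sacral_endplate_centre"))
  expect_setequal(d$landmark[d$view == "outlet"],
    c("iliac_wing_superior", "ischial_tuberosity", "ASIS",
      "sacral_endplate_centre"))
  # femoral head pixel diameter = true diameter / mm_per_px
  expect_equal(sheet$calibration$fh_px, rep(48 / 0.5, 3))
  expect_equal(sheet$calibration$fh_true_mm, rep(48, 3))
})

test_that("marking noise is seed-deterministic with the stated SD", {
  sheet <- render_sheets(default_template(), injured_side = "left")
  expect_identical(add_marking_noise(sheet, 0, seed = 1), sheet)
  n1 <- add_marking_noise(sheet, 1.5, seed = 99)
  n2 <- add_marking_noise(sheet, 1.5, seed = 99)
  expect_identical(n1, n2)
  expect_false(identical(n1$data$u, sheet$data$u))
  expect_error(add_marking_noise(sheet, -1), class = "pelvimetrix_validation")
  # empirical SD of repeated perturbations of one landmark ~ sd_mm (in mm)
  scale <- sheet$calibration$fh_true_mm[1] / sheet$calibration$fh_px[1]
  devs <- vapply(1:5000, function(i) {
    ns <- add_marking_noise(sheet, 2, seed = i)
    (ns$data$u[1] - sheet$data$u[1]) * scale
  }, numeric(1))
  devs_v <- vapply(1:5000, function(i) {
    ns <- add_marking_noise(sheet, 2, seed = i)
    (ns$data$v[1] - sheet$data$v[1]) * scale
  }, numeric(1))
  expect_equal(sd(c(devs, devs_v)), 2, tolerance = 0.02)
})

test_that("rotation sign table holds for all directions, pivots and sides", {
  # the core scientific assertion: a single-axis rotation in each named
  # direction classifies as that direction, for every shipped pivot
  cases <- expand.grid(side = c("left", "right"),
    pivot = c("centroid", "si_joint", "acetabulum"),
    angle = c(5, 10, 20), stringsAsFactors = FALSE)
  dirs <- list(
    list(axis = "rot_x", sign = 1, plane = "sagittal", class = "extension"),
    list(axis = "rot_x", sign = -1, plane = "sagittal", class = "flexion"),
    list(axis = "rot_y", sign = 1, plane = "inlet",
         class = "internal_rotation"),
    list(axis = "rot_y", sign = -1, plane = "inlet",
         class = "external_rotation"),
    list(axis = "rot_z", sign = 1, plane = "outlet", class = "varus"),
    list(axis = "rot_z", sign = -1, plane = "outlet", class = "valgus"))
  for (i in seq_len(nrow(cases))) {
    for (dd in dirs) {
      args <- list(pivot = cases$pivot[i], injured_side = cases$side[i])
      args[[dd$axis]] <- dd$sign * cases$angle[i]
      sheet <- do.call(displaced_sheet, args)
      got <- classify_rotation(rotation_indicator(sheet, dd$plane), dd$plane)
      expect_identical(got, dd$class,
        label = sprintf("%s %+g deg, %s pivot, %s side -> %s",
          dd$axis, dd$sign * cases$angle[i], cases$pivot[i], cases$side[i],
          got))
    }
  }
})

test_that("simulated studies are reproducible bit-for-bit from the seed", {
  s1 <- simulate_study(n_subjects = 4, n_raters = 2, sd_mm = 1, seed = 31)
  s2 <- simulate_study(n_subjects = 4, n_raters = 2, sd_mm = 1, seed = 31)
  expect_identical(s1, s2)
  s3 <- simulate_study(n_subjects = 4, n_raters = 2, sd_mm = 1, seed = 32)
  expect_false(identical(s1$truth, s3$truth))
  # study shape mirrors the reference protocol
  expect_identical(dim(s1$truth), c(4L, 9L))
  expect_length(s1$rater_sheets, 2L)
  expect_length(s1$rater_sheets[[1]], 4L)
  # raters get independent noise streams
  expect_false(identical(s1$rater_sheets[[1]][[1]]$data$u,
                         s1$rater_sheets[[2]][[1]]$data$u))
  # an all-zero distribution is allowed but flagged
  expect_warning(
    simulate_study(n_subjects = 2, n_raters = 2, sd_mm = 0, seed = 1,
      distribution = displacement_distribution(translation_sd_mm = 0,
        rotation_sd_deg = 0, minor_rotation_sd_deg = 0)),
    class = "pelvimetrix_degenerate")
})

test_that("recovery evaluation is exact at zero noise and flags mismatches", {
  # pure translations: rotations perturb the translational formulas through
  # projection cross-talk, so exact recovery is a pure-translation property
  study <- simulate_study(n_subjects = 5, n_raters = 2, sd_mm = 0, seed = 17,
    distribution = displacement_distribution(rotation_sd_deg = 0,
      minor_rotation_sd_deg = 0))
  m <- measure_study(study)
  rec <- evaluate_recovery(study, m)
  expect_equal(rec$translation$rmse_mm, rep(0, 3), tolerance = 1e-9)
  expect_equal(rec$translation$bias_mm, rep(0, 3), tolerance = 1e-9)
  # explicit single-axis 10-degree rotations classify perfectly at zero noise
  truth <- data.frame(
    subject_id = sprintf("R%02d", 1:6),
    injured_side = rep(c("left", "right"), 3),
    tx_mm = 0, ty_mm = 0, tz_mm = 0,
    rot_x_deg = c(10, -10, 0, 0, 0, 0),
    rot_y_deg = c(0, 0, 10, -10, 0, 0),
    rot_z_deg = c(0, 0, 0, 0, 10, -10),
    pivot = "centroid", stringsAsFactors = FALSE)
  meas <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    sheet <- displaced_sheet(rot_x = r$rot_x_deg, rot_y = r$rot_y_deg,
      rot_z = r$rot_z_deg, injured_side = r$injured_side,
      subject_id = r$subject_id)
    cbind(rater = "rater1", as.data.frame(measure_displacement(sheet)),
          stringsAsFactors = FALSE)
  }))
  rec2 <- evaluate_recovery(truth, meas)
  expect_equal(rec2$rotation_accuracy$accuracy, rep(1, 3))
  bad <- m
  bad$subject_id[bad$subject_id == "S001"] <- "S999"
  expect_error(evaluate_recovery(study, bad),
    class = "pelvimetrix_validation")
})

test_that("unbiased vertical recovery under noisy pure translations", {
  # difference-of-absolutes stays unbiased when landmarks sit well away
  # from the reference: check via simulation at 1 mm marking noise
  sheet0 <- displaced_sheet(ty = 8, injured_side = "right")
  vals <- vapply(1:400, function(i) {
    measure_displacement(
      add_marking_noise(sheet0, 1, seed = i))$translation$vertical$value_mm
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 8), 4 * se)
})
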
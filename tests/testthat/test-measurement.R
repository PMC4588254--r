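# Arithmetic fixture: a minimal mm-unit sheet built from explicit
# coordinates, used to pin the printed formulas down to their arithmetic.
mm_sheet <- function(rows) {
  landmark_sheet("fix", rows, unit = "mm")
}

row_lm <- function(view, landmark, side, u, v) {
  data.frame(view = view, landmark = landmark, side = side, u = u, v = v,
    stringsAsFactors = FALSE)
}

test_that("translational formulas reproduce the printed arithmetic", {
  # outlet vertical: v(C)=100, v(C')=110, v(S)=50 -> +10 cephalad
  sheet <- mm_sheet(rbind(
    row_lm("outlet", "iliac_wing_superior", "intact", -60, 100),
    row_lm("outlet", "iliac_wing_superior", "injured", 60, 110),
    row_lm("outlet", "sacral_endplate_centre", "midline", 0, 50)))
  res <- vertical_displacement(sheet)
  expect_equal(res$value_mm, 10)
  expect_identical(res$direction, "cephalad")

  # inlet AP: v(H')-v(S)=30, v(H)-v(S)=22 -> +8 anterior
  sheet <- mm_sheet(rbind(
    row_lm("inlet", "anterior_SI_joint", "intact", -40, 22),
    row_lm("inlet", "anterior_SI_joint", "injured", 40, 30),
    row_lm("inlet", "sacral_endplate_centre", "midline", 0, 0)))
  res <- ap_displacement(sheet)
  expect_equal(res$value_mm, 8)
  expect_identical(res$direction, "anterior")
  # same sheet transversally: |40-0| - |-40-0| = 0 -> none
  res <- transverse_displacement(sheet)
  expect_equal(res$value_mm, 0)
  expect_identical(res$direction, "none")

  # inlet transverse: |u(H')-u(S)|=60, |u(H)-u(S)|=55 -> +5 lateral
  sheet <- mm_sheet(rbind(
    row_lm("inlet", "anterior_SI_joint", "intact", -55, 20),
    row_lm("inlet", "anterior_SI_joint", "injured", 60, 20),
    row_lm("inlet", "sacral_endplate_centre", "midline", 0, 20)))
  res <- transverse_displacement(sheet)
  expect_equal(res$value_mm, 5)
  expect_identical(res$direction, "lateral")

  # mirror-symmetric landmarks at equal height -> 0, none
  sheet <- mm_sheet(rbind(
    row_lm("outlet", "iliac_wing_superior", "intact", -80, 95),
    row_lm("outlet", "iliac_wing_superior", "injured", 80, 95),
    row_lm("outlet", "sacral_endplate_centre", "midline", 0, 40)))
  res <- vertical_displacement(sheet)
  expect_equal(res$value_mm, 0)
  expect_identical(res$direction, "none")
})

test_that("rotation indicators reproduce the printed arithmetic", {
  # sagittal: |v(A)-v(B)| = 120, |v(A')-v(B')| = 112 -> +8
  sheet <- mm_sheet(rbind(
    row_lm("ap", "ASIS", "intact", -100, 60),
    row_lm("ap", "ischial_tuberosity", "intact", -50, -60),
    row_lm("ap", "ASIS", "injured", 100, 55),
    row_lm("ap", "ischial_tuberosity", "injured", 50, -57)))
  expect_equal(rotation_indicator(sheet, "sagittal"), 8)
  # symmetric anatomy, no displacement -> 0 in all three planes
  zero <- render_sheets(default_template(), injured_side = "right")
  for (p in c("sagittal", "inlet", "outlet")) {
    expect_equal(rotation_indicator(zero, p), 0, tolerance = 1e-9)
  }
})

test_that("rotation classification honours the inclusive neutral band", {
  expect_identical(classify_rotation(-3, "sagittal"), "flexion")
  expect_identical(classify_rotation(3, "sagittal"), "extension")
  expect_identical(classify_rotation(2, "sagittal"), "neutral")
  expect_identical(classify_rotation(-2, "sagittal"), "neutral")
  expect_identical(classify_rotation(2 + 1e-9, "sagittal"), "extension")
  expect_identical(classify_rotation(-2 - 1e-9, "sagittal"), "flexion")
  expect_identical(classify_rotation(-3, "inlet"), "external_rotation")
  expect_identical(classify_rotation(3, "inlet"), "internal_rotation")
  expect_identical(classify_rotation(-3, "outlet"), "valgus")
  expect_identical(classify_rotation(3, "outlet"), "varus")
  # custom threshold
  expect_identical(classify_rotation(3, "outlet", threshold_mm = 4), "neutral")
  expect_error(classify_rotation(1, "outlet", threshold_mm = 0),
    class = "pelvimetrix_validation")
})

test_that("text label convention inverts the sagittal and outlet pairs only", {
  expect_identical(classify_rotation(3, "sagittal", label_convention = "text"),
    "flexion")
  expect_identical(classify_rotation(-3, "sagittal", label_convention = "text"),
    "extension")
  expect_identical(classify_rotation(3, "outlet", label_convention = "text"),
    "valgus")
  expect_identical(classify_rotation(3, "inlet", label_convention = "text"),
    "internal_rotation")
})

test_that("pure translations are recovered exactly through the forward model", {
  for (side in c("left", "right")) {
    r <- measure_displacement(displaced_sheet(ty = 12, injured_side = side))
    expect_equal(r$translation$vertical$value_mm, 12, tolerance = 1e-9)
    expect_identical(r$translation$vertical$direction, "cephalad")
    expect_equal(r$translation$ap$value_mm, 0, tolerance = 1e-9)
    expect_equal(r$translation$transverse$value_mm, 0, tolerance = 1e-9)
    expect_identical(r$rotation$sagittal$class, "neutral")
    expect_identical(r$rotation$inlet$class, "neutral")
    expect_identical(r$rotation$outlet$class, "neutral")
  }
  r <- measure_displacement(displaced_sheet(tz = -9.5, injured_side = "left"))
  expect_equal(r$translation$ap$value_mm, -9.5, tolerance = 1e-9)
  expect_identical(r$translation$ap$direction, "posterior")
  # lateral is +x for a left, -x for a right hemipelvis
  r <- measure_displacement(displaced_sheet(tx = 6, injured_side = "left"))
  expect_equal(r$translation$transverse$value_mm, 6, tolerance = 1e-9)
  expect_identical(r$translation$transverse$direction, "lateral")
  r <- measure_displacement(displaced_sheet(tx = 6, injured_side = "right"))
  expect_equal(r$translation$transverse$value_mm, -6, tolerance = 1e-9)
  expect_identical(r$translation$transverse$direction, "medial")
})

test_that("simulated internal rotation drives the inlet indicator positive", {
  for (side in c("left", "right")) {
    sheet <- displaced_sheet(rot_y = 10, injured_side = side)
    expect_gt(rotation_indicator(sheet, "inlet"), 2)
    expect_identical(
      measure_displacement(sheet)$rotation$inlet$class, "internal_rotation")
  }
})

test_that("all quantities are invariant to image-frame shifts and mirroring", {
  sheet <- displaced_sheet(tx = 4, ty = -8, tz = 3, rot_x = 6, rot_y = -4,
    rot_z = 9, injured_side = "right")
  ref <- as.data.frame(measure_displacement(sheet))
  # translate every image frame by an arbitrary offset
  shifted <- sheet
  shifted$data$u <- shifted$data$u + 321.5
  shifted$data$v <- shifted$data$v - 77.25
  expect_equal(as.data.frame(measure_displacement(shifted)), ref,
    tolerance = 1e-12)
  # mirror through the sagittal midplane (u -> -u): magnitudes unchanged
  mirrored <- sheet
  mirrored$data$u <- -mirrored$data$u
  expect_equal(as.data.frame(measure_displacement(mirrored)), ref,
    tolerance = 1e-12)
})

test_that("missing landmarks fail loudly, naming every absent landmark", {
  sheet <- displaced_sheet(ty = 5, injured_side = "left")
  sheet$data <- sheet$data[!(sheet$data$landmark == "sacral_endplate_centre" &
                             sheet$data$view == "inlet"), ]
  err <- expect_error(ap_displacement(sheet),
    class = "pelvimetrix_missing_landmark")
  expect_match(conditionMessage(err), "sacral_endplate_centre")
  expect_match(conditionMessage(err), "inlet")
  # aggregate report lists the absence too, once, and allows partial mode
  err <- expect_error(measure_displacement(sheet),
    class = "pelvimetrix_missing_landmark")
  expect_match(conditionMessage(err), "sacral_endplate_centre")
  partial <- measure_displacement(sheet, allow_partial = TRUE)
  expect_true(is.na(partial$translation$ap$value_mm))
  expect_true(is.na(partial$translation$transverse$value_mm))
  expect_equal(partial$translation$vertical$value_mm, 5, tolerance = 1e-9)
})

test_that("sheet validation rejects bad vocabulary and duplicates", {
  expect_error(mm_sheet(row_lm("ap", "femur", "intact", 0, 0)),
    class = "pelvimetrix_validation")
  expect_error(mm_sheet(row_lm("lateral", "ASIS", "intact", 0, 0)),
    class = "pelvimetrix_validation")
  expect_error(mm_sheet(row_lm("ap", "ASIS", "left", 0, 0)),
    class = "pelvimetrix_validation")
  expect_error(
    mm_sheet(rbind(row_lm("ap", "ASIS", "intact", 0, 0),
                   row_lm("ap", "ASIS", "intact", 1, 1))),
    class = "pelvimetrix_validation")
  # pixel sheets require calibration
  expect_error(
    landmark_sheet("s", row_lm("ap", "ASIS", "intact", 0, 0), unit = "px"),
    class = "pelvimetrix_validation")
})
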
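---
title: "Measuring hemipelvis displacement on standardized radiographs: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemipelvis displacement on standardized radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvimetrix)
```

## The measurement model

An unstable pelvic ring injury leaves one hemipelvis rigidly displaced
relative to the sacrum while the contralateral side stays (approximately)
in place. The measurement system quantifies that displacement from three
standardized projections using only 2D landmark coordinates, on the
premise that the injured hemipelvis itself is intact (a rigid body) and
the contralateral hemipelvis provides the patient's own symmetric
reference.

The pelvis-specific frame puts the origin at the centre of the superior
S1 endplate (S), X along the transverse axis (+X toward the patient's
left), Y perpendicular to the inlet plane and Z perpendicular to the
outlet plane. The inlet radiograph is then the X/Z coordinate plane and
the outlet radiograph the X/Y plane; both are modelled as orthographic
(parallel-beam) projections, because the frame's defining property is
precisely that these views *are* coordinate planes. Perspective
divergence of a real beam is deliberately out of scope: it introduces a
view-dependent magnification that the femoral-head calibration absorbs to
first order anyway.

Translational displacement compares each side's distance to the midline
reference S, per view, and signs the result: vertical (outlet view,
cephalad positive), antero-posterior (inlet view, anterior positive) and
transverse (inlet view, lateral positive). Rotational displacement is not
measured as an angle at all — radiographs cannot give one robustly —
but as the change in a projected inter-landmark distance: the intact-side
distance minus the injured-side distance for a landmark pair chosen, per
plane, to be maximally sensitive to that plane's rotation (ASIS–ischial
tuberosity vertically in the AP view for sagittal rotation;
ASIS–anterior-SI-joint transversally in the inlet view for
internal/external rotation; ASIS–ischial tuberosity transversally in the
outlet view for varus/valgus). A shrinking injured-side distance maps to
extension / internal rotation / varus respectively; the indicator is
reported in millimetres.

All six quantities are differences of absolute coordinate differences, so
they are invariant to shifting the image origin, and mirroring the whole
image together with swapping the side labels leaves every magnitude
unchanged.

### The neutral band

Rotational indicators within ±2 mm (inclusive at both ends) classify as
neutral. The 2 mm half-width adopts the anatomic-reduction threshold of
the Majeed convention (0–2 mm residual displacement) and is interpreted
in millimetres *after* calibration, not in pixels: the threshold is a
clinical quantity, and pixel units would make it depend on detector
resolution. It is configurable (`threshold_mm`).

### Label conventions

The canonical direction table maps a positive sagittal indicator (injured
vertical ASIS–ischial distance smaller) to extension and a positive
outlet indicator to varus. Descriptive accounts of the same system
disagree internally about these two pairs (one passage has flexion rather
than extension shrinking the injured distance, another has valgus rather
than varus). The package follows the canonical table by default and
exposes `label_convention = "text"`, which swaps exactly the sagittal and
outlet label pairs; the inlet pair is uncontested. Note the forward model
settles the physics: with the shipped template, a rotation that tips the
iliac wing posteriorly shortens the projected AP-view ASIS–ischial
distance, which the default convention labels extension.

## The coordinate and projection machinery

Rigid transforms rotate about a pivot (intrinsic X→Y→Z composition,
right-handed, degrees) then translate; pairwise distances are preserved
to better than 1e-9 mm, which the tests assert on random point sets.
Composition order only matters for combined multi-axis rotations — the
default simulations use single-axis displacements — and is documented
rather than configurable per call.

The AP view is constructed by tilting the inlet beam axis about X by the
patient's pelvic obliquity, which varies between roughly 40° and 60°
across adults; the default is the midpoint 45°. Its image vertical is the
in-plane direction with a positive superior component, so cephalad is up;
at a tilt of 90° the AP construction coincides with the outlet view.

Calibration is per view: each view carries its own measured femoral-head
pixel diameter, since magnification can differ per projection, and the
mm-per-pixel scale is simply the true diameter over the pixel diameter.
Because rendering divides by the scale and calibration multiplies by it,
any rendering scale cancels exactly — the tests check that 0.5 and
2.0 mm/px produce identical reports.

## The synthetic-data generator

There is no public cohort with both standardized radiographs and 3D
reconstruction ground truth, so validation is in silico and the simulator
is a first-class part of the package: the 3D reconstruction "gold
standard" becomes the simulator's exactly known displacement.

**Template.** `default_template()` ships a bilateral landmark set (ASIS,
ischial tuberosity, superior iliac wing point, anterior SI joint, PSIS,
plus the femoral head centre and a 48 mm head diameter) that is exactly
mirror-symmetric about X = 0. The coordinates are authored in a
body-aligned frame (lateral / superior / anterior offsets from S with
plausible adult magnitudes, e.g. ASIS ±120 mm lateral) and rotated into
the pelvis frame by the obliquity, so projections look like real
radiographs. They are engineering fixtures, not measured anatomy; the
tests only constrain them to anatomically plausible distance ranges. PSIS
is carried for completeness but used by no radiographic formula.

**Displacement.** `displacement_spec()` uses anatomical sign conventions:
`rot_x` positive = extension, `rot_y` positive = internal rotation,
`rot_z` positive = varus, mirrored consistently between sides (flexion /
extension is mirror-symmetric about the midplane, the other two pairs are
mirror-antisymmetric, so their world-frame angle flips sign with the
injured side). The rotation pivot is not anatomically determined, so
three options ship: the injured side's landmark centroid (default), the
anterior SI joint, and the femoral head centre (acetabulum). The
direction-classification sign table must and does hold for all three —
rotational indicators are differences of projected coordinates, which
makes them independent of where along the rotation axis the pivot sits.

**Study distribution.** Simulated cohorts mirror an all-displaced series
of unstable injuries: every subject draws all three translation
components from a zero-mean truncated Gaussian with SD 10 mm (capped at
30 mm). The rotational pattern is a mixture: translation-dominant
subjects (type C-like vertical shear) carry only residual rotations
(SD 2°), rotation-dominant subjects (type B-like open/closed-book and
compression patterns) draw rotations with SD 8°, capped at 20° to keep
the projected landmarks in a realistic field of view. The weights default
to 0.5/0.5 and are configurable. These scales reproduce the
between-subject spread under which the measurement system's published
reliability was observed, and the caps respect the template geometry (the
absolute-value formulas are only sign-faithful while a landmark stays on
its own side of the reference, which holds up to ≥30 mm translations for
the shipped template).

**Noise.** Observer digitisation error is modelled as independent
isotropic Gaussian perturbation of each landmark's image position, with a
default SD of 1 mm — about 2 px at typical detector resolution. The
femoral-head diameter measurement is left noise-free: no observer error
model for the fiducial is available, and perturbing it would convert
additive marking noise into multiplicative calibration noise of a made-up
magnitude. Consequently the simulation isolates landmark-placement
variability, which is the dominant error source the reliability protocol
was designed around.

**Seeds.** Every random draw in `simulate_study()` derives from the
single `seed` argument through fixed integer offsets (subject specs and
each rater × subject noise stream get their own derived seed), so a study
regenerates bit-for-bit, and perturbing a single rater never shifts
another rater's stream.

### What passing simulations do and do not show

The simulator demonstrates internal validity: the formulas invert their
own forward model (exact translational recovery at zero noise, correct
rotation directions for ≥5° single-axis rotations), and they remain
reliable under realistic marking noise. It does not demonstrate clinical
validity: real radiographs add perspective magnification, patient
malpositioning (the true obliquity is unknown per patient), landmark
ambiguity from overlapping bowel gas and comminution, and deviations from
the mirror-symmetry assumption — none of which the generator emulates.
Cross-talk, however, is faithfully reproduced: a single-plane rotation
perturbs other planes' quantities (for example a 10° internal rotation
shifts the measured AP translation by several millimetres), a property of
the measurement system itself that the recovery tables quantify.

## Reliability statistics

The ICC uses the two-way random-effects model computed from the two-way
ANOVA mean squares. The published description does not fix
single-vs-average measures or consistency-vs-agreement; the package
defaults to ICC(2,1) — single measures, absolute agreement — because the
clinical question is the reliability of one surgeon's measurement, with
ICC(2,k) available via `type = "average"`. Confidence intervals use the
F-based interval with a Satterthwaite approximation to the denominator
degrees of freedom; for the average-measures form the single-measures
interval is Spearman–Brown-stepped. A matrix with zero between-subject
variance makes the ICC undefined: the package signals a classed
degenerate-statistics condition (CLI exit code 3) rather than propagating
NaN.

The kappa flavour for five raters is likewise unstated; the default is
Fleiss' multi-rater kappa with the classic large-sample z test under the
no-agreement null (an assumption worth noting: the reported p-values'
test was never specified). `mode = "pairwise_cohen_mean"` averages
Cohen's kappa over rater pairs instead. For two raters Fleiss' kappa
coincides with Cohen's exactly when the raters share marginal
distributions (in general it is Scott's pi); the equivalence test
therefore uses matched-marginal matrices.

Landis–Koch labels are a total monotone step function on (−∞, 1]. The
printed scale lists closed decade bands with one-hundredth gaps (…0.20,
then 0.21…); the implementation uses half-open bands with breakpoints
midway inside each gap (0.205, 0.405, 0.605, 0.805), so every printed
bound lands in the band whose printed range contains it and values inside
a gap get the nearer label. Negative values are "poor"; values above 1
are rejected.

## Numerical and testing choices

Problem sizes were chosen so the whole suite runs in seconds: rigidity
and oracle checks use 10–50 random instances, the Monte-Carlo noise-SD
check uses 10,000 perturbation samples (2% tolerance, ~4 SE), the
direction sign table is exhaustive over 6 directions × 3 pivots × 2 sides
× 4 angles, and reliability simulations use the reference 25 × 5 design.
Statistical estimators are verified against independently coded oracles
(ANOVA mean squares via `lm`/`anova`, kappa via direct count loops) to
1e-10. Exactness claims (translation recovery, calibration cancellation)
are asserted at 1e-9–1e-12, reflecting double-precision rotation and
projection arithmetic.

Degenerate inputs fail loudly and specifically: missing landmarks name
the landmark, view and side (with an explicit `allow_partial` opt-in for
partial reports); unbalanced rater grids list the missing cells; all-zero
displacement distributions are allowed but flagged. Ties at the neutral
boundary are neutral by construction; a zero translational value gets the
direction label "none" (the convention is silent on ties).

## Known limitations

- Orthographic projection ignores beam divergence and source–detector
  geometry; per-view calibration absorbs uniform magnification only.
- Rotation magnitudes are reported in millimetres of indicator, not
  degrees; only the 3D ground truth has angles.
- The intact-side-as-reference premise excludes bilateral injuries.
- The absolute-value formulas lose sign fidelity for displacements large
  enough to carry a landmark across the midline reference (≳30–45 mm
  with the default template).
- Simulated reliability reflects the generator's noise model, not human
  observers; the class kappas in particular depend strongly on how much
  of the rotation distribution sits near the ±2 mm band.
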
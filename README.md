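# pelvimetrix

Landmark-based measurement of hemipelvis displacement on standardized
pelvic radiographs, with an in-silico validation framework.

## The problem

Unstable pelvic ring fractures (AO/OTA type B and C) displace one
hemipelvis relative to the sacrum and the intact side, both by translation
and by rotation in three orthogonal planes. Preoperative assessment still
relies on three plain projections — inlet, outlet and anterior–posterior
(AP) — but classical radiographic measures are poorly standardized and
cover mostly translation. `pelvimetrix` implements a coordinate-based
measurement system for surgeons, radiologists and methods researchers: a
handful of bony landmarks are digitised per view, a femoral-head fiducial
converts pixels to millimetres, and closed-form coordinate differences
yield three signed translational displacements plus three rotational
direction classes.

## The method

A pelvis-specific Cartesian frame is anchored at the centre of the
superior S1 endplate (S): X transverse (toward the patient's left), Y
perpendicular to the inlet plane, Z perpendicular to the outlet plane, so
the inlet and outlet radiographs are orthographic images of the X/Z and
X/Y planes. With primed symbols on the injured side, per-view image
coordinates `u` (horizontal) and `v` (vertical), and C = superior iliac
wing point, H = anterior SI joint (iliac side), A/B = ASIS and ischial
tuberosity in the AP view, G/E = ASIS in the inlet/outlet views, D =
ischial tuberosity in the outlet view:

| Quantity | Formula (mm) | Positive means |
|---|---|---|
| vertical (outlet) | `\|v_C' − v_S\| − \|v_C − v_S\|` | cephalad |
| antero-posterior (inlet) | `\|v_H' − v_S\| − \|v_H − v_S\|` | anterior |
| transverse (inlet) | `\|u_H' − u_S\| − \|u_H − u_S\|` | lateral |
| sagittal rotation (AP) | `\|v_A − v_B\| − \|v_A' − v_B'\|` | extension if > 2 |
| inlet rotation | `\|u_G − u_H\| − \|u_G' − u_H'\|` | internal rotation if > 2 |
| outlet rotation | `\|u_E − u_D\| − \|u_E' − u_D'\|` | varus if > 2 |

Rotational indicators within ±2 mm (inclusive; the anatomic-reduction
threshold) classify as neutral. Because no reference 3D reconstructions
can ship with a package, validation is in silico: a mirror-symmetric 3D
landmark template is rigidly displaced with known ground truth, projected
into the three views (AP beam tilted by a configurable pelvic obliquity,
default 45°), perturbed with Gaussian observer marking noise, measured,
and compared back. Inter-rater agreement uses the two-way random-effects
ICC (single measures, absolute agreement) with F-based 95% confidence
intervals, Fleiss/Cohen kappa with large-sample tests, and the
Landis–Koch scale.

## Worked example

Displace the right hemipelvis of the built-in template by 12 mm cephalad
plus 10° internal rotation, render noiseless sheets, and measure:

```r
library(pelvimetrix)
tpl   <- default_template()
spec  <- displacement_spec(ty = 12, rot_y = 10, injured_side = "right")
sheet <- render_sheets(displace(tpl, spec), subject_id = "case01")
measure_displacement(sheet)
#> Displacement report for subject 'case01'
#>   vertical:     12.000 mm (cephalad)
#>   AP:           -4.202 mm (posterior)
#>   transverse:    1.976 mm (lateral)
#>   sagittal:     8.437 mm -> extension
#>   inlet:       12.804 mm -> internal_rotation
#>   outlet:      -6.380 mm -> valgus
#>   neutral band: +/- 2 mm; labels: table2
```

The 12 mm vertical translation is recovered exactly and the internal
rotation is classified correctly (indicator 12.8 mm > 2). The non-zero
AP/sagittal/outlet entries show genuine projection cross-talk: a rotation
about one axis moves landmarks in the other views too — a property of the
measurement system itself, quantifiable here because the ground truth is
known.

A full reliability study in the reference design (25 subjects, 5 raters,
1 mm marking noise):

```r
study <- simulate_study(n_subjects = 25, n_raters = 5, sd_mm = 1, seed = 1)
reliability_report(measure_study(study))
#> Reliability report: 25 subjects, 5 raters (ICC single, kappa fleiss)
#>       parameter statistic estimate ci_low ci_high   p_value          label
#>     vertical_mm       icc   0.9783 0.9616  0.9892        NA almost perfect
#>           ap_mm       icc   0.9746 0.9553  0.9874        NA almost perfect
#>   transverse_mm       icc   0.9323 0.8837  0.9657        NA almost perfect
#>     sagittal_mm       icc   0.9350 0.8885  0.9670        NA almost perfect
#>        inlet_mm       icc   0.9404 0.8974  0.9698        NA almost perfect
#>       outlet_mm       icc   0.9796 0.9640  0.9898        NA almost perfect
#>  sagittal_class     kappa   0.6424     NA      NA 1.064e-43    substantial
#>     inlet_class     kappa   0.6023     NA      NA 3.449e-41       moderate
#>    outlet_class     kappa   0.7704     NA      NA 1.030e-53    substantial
```

All six continuous parameters land above 0.9 ("almost perfect"): at 1 mm
digitisation noise the formulas are highly reliable. The class kappas are
lower because many simulated rotations fall near the ±2 mm band, where a
millimetre of noise flips the label — the discretisation, not the
indicator, is the fragile part.

## Command line

A thin wrapper is installed at `inst/cli/pelvimetrix`:

```sh
Rscript inst/cli/pelvimetrix simulate --config study.yaml --out-dir study/
Rscript inst/cli/pelvimetrix measure --sheets study/sheets_rater1.csv \
    --calibration study/calibration_rater1.csv --out report1.csv
Rscript inst/cli/pelvimetrix reliability --reports report*.csv --out reliability.csv
Rscript inst/cli/pelvimetrix evaluate --truth study/truth.csv \
    --reports report*.csv --out recovery.csv
```

Exit codes: 0 success, 2 validation error, 3 degenerate statistics.

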
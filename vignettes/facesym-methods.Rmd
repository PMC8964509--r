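---
title: "Measuring facial reanimation: models and methods in facesym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial reanimation: models and methods in facesym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The measurement problem

After a facial nerve injury the affected hemiface loses tone: the oral
commissure droops, the philtrum is dragged toward the healthy side by the
unopposed contralateral musculature, the palpebral fissure widens because the
orbicularis oculi can no longer close the lid, and the commissure barely moves
on an attempted smile. Reanimation surgery (for example a masseteric-to-facial
nerve transfer) aims to undo these deficits, and its evaluation combines three
kinds of evidence: clinician-graded instruments, patient-reported outcomes,
and quantitative photogrammetry. `facesym` implements all three plus the
prognostic models that relate preoperative characteristics to outcome, and a
synthetic-cohort generator that makes the entire pipeline testable without any
patient data.

## Photogrammetric model

All measurements start from 2-D pixel landmarks digitized on standardized
clinical photographs taken under five task conditions (rest, eyebrow raising,
eye closure, snarl, wide smile).

**Calibration.** Absolute size cannot be read off a photograph, but the
horizontal corneal white-to-white diameter is nearly constant across adults.
The limbus-to-limbus pixel distance is therefore identified with 11.576 mm,
giving `mm_per_pixel = 11.576 / wtw_pixels` exactly. By default the healthy
eye anchors the scale: paralysis distorts the lid aperture but not the limbus,
and using the unaffected side is the conservative choice; a `mean`-of-both-eyes
and a paralytic-eye option exist. One calibration is shared by all photographs
of a session (they share scale); per-condition recalibration is available by
flag.

**Face frame.** The central line of the face is the perpendicular bisector of
the segment joining the iris centers. Its intersection with the vermilion
margin of the lower lip defines the *reference point*; when a wavy vermilion
polyline yields several intersections, the one nearest the inter-commissure
midpoint is used. The frame's x axis runs along the inter-iris direction
toward the healthy side, and the y axis is perpendicular with the superior
direction positive. Image coordinates are y-down raster pixels, so the frame
flips the vertical sign — stated explicitly to keep every "superior positive"
quantity honest. Because the frame is built from the measured geometry itself,
every millimetre-valued output is invariant to rotation, translation and
uniform scaling of the pixel coordinates (tested to 1e-6 mm).

**Indices.** With `f` (horizontal distance of a commissure from the central
line, mm) and `g` (vertical offset from the reference point, superior
positive):

* Facial Asymmetry Index (FAI): absolute difference between the two sides'
  medial-canthus-to-commissure distances; 0 = perfect symmetry.
* Palpebral fissure width: lid-to-lid distance on the vertical through the
  iris center; 0 = full closure.
* Philtrum deviation: signed perpendicular distance from the philtrum to the
  central line, positive toward the healthy side.
* Commissure angle: `atan(g / f)` in degrees. The horizontal leg of this
  angle is taken to be `f` — a deliberate package reading, since `f` is the
  only horizontal quantity defined at the commissure.
* Bilateral slope angle: `atan((g - g') / (f + f'))`, healthy side unprimed.
* Smile excursion: change from rest to smile in the reference-point-to-
  commissure distance, with `dh`/`dv` component changes. "Static excursion"
  (the `f`, `g`, overall distances at rest) and "dynamic excursion" (the same
  at smile) are kept as separate operations because the literature overloads
  the word excursion.
* Philtrum-adjusted horizontal distance: the commissure's horizontal distance
  measured from the philtrum's vertical instead of the central line, so a
  philtrum displaced toward the healthy side shrinks the healthy-side value
  and inflates the paralytic one. The alternative reading (subtracting the
  deviation from the FAI) was rejected because the adjustment is described
  per side.
* Reanimation class: a postoperative overall smile excursion of the paralytic
  commissure below 3.0 mm is `poor`; 3.0 mm is the minimal excursion for a
  `good` result (boundary included as good).

Pre/post differences are oriented so improvement is positive: asymmetry-type
indices as pre − post, excursion-type indices as post − pre. A difference
whose operand is missing is `NA`, never silently zero.

## Instrument scorers

* **FNGS2.0**: four regions (brow, eye, nasolabial fold, oral commissure)
  each 1-6 plus synkinesis 0-3; total movement = region sum (4-24); final
  grade mapping 4→I, 5-9→II, 10-14→III, 15-19→IV, 20-23→V, 24→VI. The grade
  is mapped from the movement total excluding synkinesis — the reading
  consistent with a total of 20 co-occurring with grade V — and a
  synkinesis-inclusive mapping is selectable by flag.
* **Sunnybrook FGS**: resting symmetry raw sum × 5 (0-20), voluntary movement
  raw sum × 4 (20-100), synkinesis raw sum (0-15); composite = voluntary −
  resting − synkinesis ∈ [−35, 100].
* **FaCE Scale**: 15 items each 1-5; reverse-keyed items recoded as
  `6 − item`; each domain and the total rescaled linearly to 0-100
  (`total = (sum − 15)/60 × 100`). The item-to-domain map and the
  reverse-keyed list ship as an editable configuration
  (`face_scale_config()`) so a translated instrument with different structure
  can be swapped in; the default treats the three movement items as directly
  keyed and the twelve symptom-worded items as reverse-keyed. No imputation:
  a missing item is an error.

Scorers are exact integer/rational arithmetic; half-integer medians can arise
only from cohort aggregation, never from a scorer.

## Prognostic models

**Preprocessing.** Each continuous predictor is standardized (mean/SD), then
passed through a shifted Box-Cox power transform. Plain Box-Cox after
centring is ill-posed (z-scores are not positive), so an offset of
`1 − min(z)` maps the training values onto a strictly positive domain, the
power `lambda` is chosen by maximum likelihood, and the transform is anchored
so the training mean maps to exactly 0 (with `lambda = 1` a column comes back
as its plain z-scores). Binary indicators pass through. The fitted
specification is stored and re-applied to new patients; out-of-domain values
are clipped with a warning.

**Effect models.** For each evaluation index, a logistic model with
elastic-net regularization (mixing `alpha = 0.5` by default) is fitted to a
dichotomized outcome, with the penalty chosen by 5-fold cross-validated
deviance on a seed-deterministic fold assignment — a fixed seed gives
bit-identical coefficients. How the continuous indices were dichotomized in
the source analyses is not stated; the package default is a median split per
index, with a fixed-threshold option so the 3.0 mm reanimation rule can drive
the overall-effect outcome. Variable importance is
`100 · |beta| / max|beta|` per index, so the most influential predictor in a
row always scores 100 and an all-zero row scores all zeros. Below 30
observations the package warns that cross-validated penalty selection is
unstable; refitted coefficients on a 20-patient series carry no claim of
clinical validity, and recovery tests run on synthetic cohorts instead.

**Time to first contraction.** Cox proportional-hazards regression (Efron tie
handling) of months from surgery to the first visible facial contraction with
biting, with per-predictor hazard ratios, 95% CIs, Wald p-values and the
concordance. Rank-deficient designs and all-censored inputs are rejected.

**Cohort comparisons.** Instrument scores (ranked) are compared pre/post by
the Wilcoxon matched-pairs signed rank test and summarized as median (IQR);
photogrammetric metrics by the two-tailed paired t test, summarized as
mean ± SD. The assignment is overridable per variable. No multiple-testing
correction is applied by default, mirroring common practice in this
literature; a Holm option is available in downstream code if needed.

## The synthetic cohort generator

The generator deforms a symmetric millimetre template face (inter-iris
distance 62 mm, palpebral fissure 8.23 mm, commissures 23 mm lateral and
12.7 mm above the lower-lip reference point) by a severity-scaled paralysis:
vertical commissure droop, medial commissure pull, philtrum shift toward the
healthy side, fissure widening, residual eye-closure gap, and loss of smile
excursion. Postoperative faces attenuate the deformation by a recovery
fraction. The smile displaces each commissure radially away from the
reference point, so the configured gain *is* the measured overall excursion
in closed form; at severity 0 the paralytic gain equals the healthy gain and
the face is exactly symmetric. Gaussian digitization jitter (default SD
0.2 mm, about one pixel of annotation error) is added per landmark
coordinate in mm space, and the face is emitted in pixels under a random
similarity transform.

Two modelling choices deserve emphasis:

* **One transform per session.** The similarity transform (rotation ±10°,
  scale 3-6 px/mm, translation) is shared by all task conditions of a
  patient-timepoint, consistent with a photo session sharing scale and with
  the shared calibration and REST-derived frame. Metrics are invariant to it.
* **Full closure is one landmark.** When the lids meet, a rater sees a single
  lid line and digitizes one point; the generator therefore emits coincident
  upper/lower lid landmarks sharing one jitter draw, and a fully closed eye
  measures exactly 0 mm. Without this, folded measurement noise would make a
  0 mm eye read ~0.2 mm on average and bias every closure summary upward.

**Study presets.** `study_preset("pre")` / `study_preset("post")` encode the
published cohort summaries as target distributions. A single latent severity
quantile `u ~ U(0,1)` per patient drives comonotone, moment-matched gamma
draws (a worse patient is worse on every index) for: static FAI
(4.87 ± 2.39 mm pre, 1.46 ± 1.30 post), philtrum deviation at rest
(3.61 ± 2.17 pre, 1.46 post) and smiling (7.74 ± 2.72 pre, 2.32 post; the
unpublished postoperative spreads are scaled by the preoperative coefficient
of variation), and the forced-closure gap. Eye closure is a mixture matched
in closed form: preoperatively the best 15% of patients (3/20 in the study)
close fully and the rest share the gap that restores the printed 3.88 mm
mean; postoperatively 85% (17/20) close fully and residual gaps follow a
gamma whose mean 0.933 and SD 0.616 reproduce the printed 0.14 ± 0.41 mm
cohort mean and SD exactly. The commissure droop per patient is solved by
monotone root-finding so the noise-free FAI equals the drawn target — a
deterministic inversion of the package's own geometry, not a fit to any
patient data. Paralytic smile gains target 0.19 mm pre and 5.05 mm post,
anticomonotone in `u`. Dynamic asymmetry summaries (smile FAI, slope angles)
are emergent, not matched.

Cohort covariates echo the study demographics: age ~ N(40.5, 12²) truncated
to 18-62, causes tumor/Bell/trauma/infection at 50/25/20/5%, log-normal
duration with median 16.5 months, log-normal follow-up with median 11.8
months. Instrument items derive from `u` through documented monotone
staircase maps (no joint model of photographs and clinician scores exists to
emulate). Binary surgical-effect outcomes are drawn from a logistic model at
configurable true coefficients on the five standardized predictors; first
contraction times are exponential with baseline mean 2.32 months scaled by a
true proportional-hazards linear predictor and censored at follow-up. The
ground-truth object stores every parameter and latent, so expected values of
any metric are recomputable analytically or by brute force.

**What passing tests show — and what they do not.** The generator produces
faces whose *measured summary statistics* match the published ones, with
realistic digitization noise and pose variation. It does not model synkinesis
dynamics, rater disagreement, non-Gaussian annotation blunders, correlation
between instrument scores and photograph noise, or photo-realistic texture;
recovering the printed means from these cohorts validates the measurement
arithmetic and calibration chain, not any clinical claim.

## Numerical choices

* Geometric equality tolerance 1e-6 mm; frame round-trips hold to 1e-9.
* `atan` angles are returned in degrees in (−90, 90]; a commissure exactly on
  the central line returns ±90° with a warning, and a zero `f + f'`
  denominator in the slope angle is a degenerate-geometry error.
* Importance scaling divides before multiplying so the largest coefficient
  maps to exactly 100 in floating point.
* A requested zero elastic-net penalty is floored at 1e-8 with a warning
  (exactly unpenalized logistic fits can be separated); single-predictor
  designs are padded with an all-zero dummy column required by the solver and
  the dummy coefficient is dropped.
* Writers emit byte-stable output (coordinates rounded to 1e-6 px, full-
  precision JSON numbers elsewhere); reports are pure functions of inputs.

## Problem sizes

The shipped test suite and the acceptance script use cohorts of up to 2000
synthetic patients for distribution-recovery checks (standard error of the
preoperative FAI mean ≈ 0.05 mm), 500 faces per level for monotonicity
properties, 10⁴ random inputs for scorer range/monotonicity properties,
n = 800 for the Cox hazard-ratio recovery and 200 replicates for CI coverage
— sizes at which Monte-Carlo error is well below every asserted tolerance.

## Known limitations

* The package measures digitized landmarks; it does not detect landmarks in
  photographs or decode images/video.
* The FaCE item-to-domain default follows the original English instrument;
  translated versions may need a different `face_scale_config()`.
* Whether the published static indices used the rest photograph only or an
  average over tasks is unstated; `facesym` computes per-condition values and
  leaves aggregation to the caller.
* Elastic-net coefficient values refitted on small clinical series are not
  clinically validated outputs; only structure, signs on synthetic analogues
  and the scaling rule are testable.
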
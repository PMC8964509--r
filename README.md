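# facesym

Quantitative evaluation of facial reanimation surgery from calibrated
landmark photogrammetry, clinician-graded and patient-reported instruments,
and prognostic models.

Facial nerve palsy droops the oral commissure, drags the philtrum toward the
healthy side, widens the palpebral fissure and abolishes smile excursion.
Surgeons who reanimate such faces (e.g. by masseteric-to-facial nerve
transfer) need to quantify the deficit and its recovery. `facesym` provides
the full measurement chain for clinicians and methodologists working on 2-D
clinical photographs:

* **Photogrammetry** — reads per-patient landmark files (JSON or long CSV),
  converts pixels to millimetres via the standardized white-to-white corneal
  diameter (11.576 mm), builds a face-centric frame from the perpendicular
  bisector of the inter-iris segment and its intersection with the lower-lip
  vermilion, and computes the symmetry indices: the Facial Asymmetry Index
  `FAI = |d(canthus, commissure)_paralytic − d(canthus, commissure)_healthy|`,
  palpebral fissure width, signed philtrum deviation, commissure components
  `f` (lateral) and `g` (vertical), smile excursion, philtrum-adjusted
  horizontal excursion, the commissure angle `atan(g/f)` and the bilateral
  slope angle `atan((g − g′)/(f + f′))`, plus the 3.0 mm good/poor
  reanimation rule.
* **Instrument scorers** — FNGS2.0 (regional 1-6 scores, grade I-VI),
  Sunnybrook FGS (composite = 4·voluntary − 5·resting − synkinesis raw sums)
  and the 15-item FaCE Scale rescaled to 0-100 per domain.
* **Prognosis** — per-index elastic-net logistic models on standardized,
  Box-Cox-transformed preoperative predictors (age, gender, duration, cause,
  preoperative grade) with 0-100 coefficient-magnitude importance, and Cox
  regression for time to first facial contraction.
* **Synthetic cohorts** — a generator that deforms a symmetric template face
  by configurable droop/pull/widening with digitization noise and random
  photo-session pose, with presets moment-matched to published cohort
  summaries, so the entire pipeline is testable end to end without any
  patient data.

## Worked example

```r
library(facesym)

# instrument arithmetic
score_fngs(brow = 6, eye = 4, nasolabial_fold = 5, oral_commissure = 5)
#> $total_movement: 20      $final_grade: 5
score_sunnybrook(resting = c(1, 2, 1), voluntary = c(1, 3, 2, 2, 2),
                 synkinesis = c(0, 0, 0, 0, 0))
#> $resting_total: 20   $voluntary_total: 40   $composite: 20

# a synthetic cohort of 200 patients, measured by the pipeline
cohort <- generate_cohort(cohort_generator_config(n = 200, seed = 42))
cohort$faces$SYN0001$pre
#> <annotated_face> patient SYN0001, pre-op, paralyzed side right
#>   conditions: REST, EYE_CLOSURE, SMILE
#>   calibration: 0.28414 mm/px (wtw 40.74 px, healthy eye)

symmetry_metrics(cohort$faces$SYN0001$post)$reanimation_class
#> [1] "good"

paired_compare(
  vapply(cohort$faces, function(f) facial_asymmetry_index(f$pre),  numeric(1)),
  vapply(cohort$faces, function(f) facial_asymmetry_index(f$post), numeric(1)),
  method = "paired_t", variable = "static FAI (mm)")
#> static FAI (mm) [paired_t, n=200]: pre 4.81 +/- 2.47 -> post 1.45 +/- 1.39, p = 2.686e-90
```

The cohort's mean preoperative static FAI (4.81 mm here) sits within sampling
error of the 4.87 mm generator target; the paired comparison shows the
reanimation restoring near-symmetry (FAI below the ~3 mm threshold casual
observers can detect), exactly the pattern the presets encode.

A thin command-line wrapper over the same functions ships in
`inst/cli/facesym.R` with subcommands `measure`, `score`, `simulate`,
`compare`, `report` and `predict`.

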
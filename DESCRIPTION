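Package: facesym
Title: Photogrammetric Facial Symmetry Measurement, Facial-Function Grading,
    and Prognostic Modelling for Facial Reanimation Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative evaluation of facial reanimation
    surgery (e.g. masseteric-to-facial nerve transfer). Reads calibrated 2-D
    facial landmark files, converts pixels to millimetres via the standardized
    white-to-white corneal diameter, builds a face-centric coordinate frame,
    and computes facial symmetry indices: the Facial Asymmetry Index, palpebral
    fissure width, philtrum deviation, oral commissure excursions and angles.
    Provides deterministic scorers for three facial-function instruments
    (FNGS2.0, Sunnybrook Facial Grading System, FaCE Scale), prognostic models
    (cross-validated elastic-net logistic regression with 0-100 variable
    importance, Cox regression for time to first facial contraction), paired
    pre/post cohort comparisons, and a synthetic-cohort generator that emulates
    paralyzed and reanimated face geometry for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
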
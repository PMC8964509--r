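# Deterministic scorers for the three facial-function instruments:
# FNGS2.0 (clinician-graded regions + synkinesis), the Sunnybrook Facial
# Grading System (resting symmetry, voluntary movement, synkinesis), and the
# patient-reported FaCE Scale (15 items, six domains, 0-100).

.check_range <- function(x, name, lo, hi) {
  if (length(x) != 1 || !is.finite(x) || x < lo || x > hi || x != round(x))
    stop(sprintf("item '%s' must be an integer in %d..%d (got %s)",
                 name, lo, hi, paste(x, collapse = ",")), call. = FALSE)
  as.integer(x)
}

#' Score the Facial Nerve Grading Scale 2.0
#'
#' Four facial regions (brow, eye, nasolabial fold, oral commissure) are each
#' graded 1 (normal) to 6 (no movement); synkinesis is graded 0-3. The total
#' movement score is the sum of the four regions (4-24) and maps to the final
#' grade I-VI: 4 -> 1, 5-9 -> 2, 10-14 -> 3, 15-19 -> 4, 20-23 -> 5, 24 -> 6.
#'
#' @param brow,eye,nasolabial_fold,oral_commissure Region scores, integers 1-6.
#' @param synkinesis Synkinesis score, integer 0-3.
#' @param grade_includes_synkinesis If `TRUE`, the grade mapping is applied to
#'   the synkinesis-inclusive total instead of the movement total (an
#'   alternative reading of the instrument; off by default).
#' @return A list with `total_movement` (4-24), `total_with_synkinesis`
#'   (4-27), and `final_grade` (1-6).
#' @export
score_fngs <- function(brow, eye, nasolabial_fold, oral_commissure,
                       synkinesis = 0, grade_includes_synkinesis = FALSE) {
  brow <- .check_range(brow, "brow", 1, 6)
  eye <- .check_range(eye, "eye", 1, 6)
  nasolabial_fold <- .check_range(nasolabial_fold, "nasolabial_fold", 1, 6)
  oral_commissure <- .check_range(oral_commissure, "oral_commissure", 1, 6)
  synkinesis <- .check_range(synkinesis, "synkinesis", 0, 3)
  total <- brow + eye + nasolabial_fold + oral_commissure
  basis <- if (grade_includes_synkinesis) total + synkinesis else total
  grade <- if (basis <= 4) 1L else if (basis <= 9) 2L else if (basis <= 14) 3L
           else if (basis <= 19) 4L else if (basis <= 23) 5L else 6L
  list(total_movement = total, total_with_synkinesis = total + synkinesis,
       final_grade = grade)
}

#' Score the Sunnybrook Facial Grading System
#'
#' Resting symmetry items (eye 0-1, cheek/nasolabial fold 0-2, mouth 0-1) sum
#' and are multiplied by 5 (total 0-20, higher = more resting asymmetry).
#' Five voluntary-movement items (brow lift, gentle eye closure, open mouth
#' smile, snarl, lip pucker), each 1-5, sum and are multiplied by 4 (total
#' 20-100, higher = better movement). Five synkinesis items, each 0-3, sum
#' unweighted (0-15). Composite = voluntary - resting - synkinesis.
#'
#' @param resting Length-3 integer vector `(eye, cheek_nlf, mouth)`.
#' @param voluntary Length-5 integer vector, items 1-5 each.
#' @param synkinesis Length-5 integer vector, items 0-3 each.
#' @return A list with `resting_total`, `voluntary_total`, `synkinesis_total`,
#'   `composite`.
#' @export
score_sunnybrook <- function(resting, voluntary, synkinesis) {
  if (length(resting) != 3) stop("resting must have 3 items", call. = FALSE)
  if (length(voluntary) != 5) stop("voluntary must have 5 items", call. = FALSE)
  if (length(synkinesis) != 5) stop("synkinesis must have 5 items", call. = FALSE)
  resting[1] <- .check_range(resting[1], "resting eye", 0, 1)
  resting[2] <- .check_range(resting[2], "resting cheek_nlf", 0, 2)
  resting[3] <- .check_range(resting[3], "resting mouth", 0, 1)
  vol_names <- c("brow lift", "gentle eye closure", "open mouth smile",
                 "snarl", "lip pucker")
  for (i in 1:5) {
    voluntary[i] <- .check_range(voluntary[i], paste("voluntary", vol_names[i]), 1, 5)
    synkinesis[i] <- .check_range(synkinesis[i], paste("synkinesis", vol_names[i]), 0, 3)
  }
  resting_total <- 5L * sum(resting)
  voluntary_total <- 4L * sum(voluntary)
  synkinesis_total <- sum(synkinesis)
  list(resting_total = as.integer(resting_total),
       voluntary_total = as.integer(voluntary_total),
       synkinesis_total = as.integer(synkinesis_total),
       composite = as.integer(voluntary_total - resting_total - synkinesis_total))
}

#' Default FaCE Scale configuration
#'
#' Item-to-domain assignment and reverse-keyed item list for the 15-item FaCE
#' Scale. The mapping follows the original instrument's six domains: Facial
#' Movement (items 1-3), Facial Comfort (4, 5, 8), Oral Function (6, 7), Eye
#' Comfort (9, 10), Lacrimal Control (12, 13), Social Function (11, 14, 15).
#' Items 4-15 are symptom-worded (higher raw agreement = worse function) and
#' are reverse-keyed before rescaling. The configuration is a plain list so a
#' translated instrument with a different structure can be swapped in.
#'
#' @return A list with `domains` (named list of item indices) and
#'   `reverse_keyed` (integer vector).
#' @export
face_scale_config <- function() {
  list(
    domains = list(
      facial_movement = c(1L, 2L, 3L),
      facial_comfort = c(4L, 5L, 8L),
      oral_function = c(6L, 7L),
      eye_comfort = c(9L, 10L),
      lacrimal_control = c(12L, 13L),
      social_function = c(11L, 14L, 15L)),
    reverse_keyed = 4:15)
}

#' Score the FaCE Scale
#'
#' 15 items, each answered 1-5. Reverse-keyed items are recoded as
#' `6 - item`; each domain and the total are then linearly rescaled to 0-100:
#' `((sum - n_items) / (4 * n_items)) * 100`, so the total is
#' `((item sum) - 15) / 60 * 100` after recoding. No imputation is performed:
#' a missing item is an error.
#'
#' @param items Numeric vector of 15 item responses, each in 1..5.
#' @param config Instrument structure, see [face_scale_config()].
#' @return A list with one 0-100 score per domain and `total`.
#' @export
score_face_scale <- function(items, config = face_scale_config()) {
  if (length(items) != 15 || any(is.na(items)))
    stop("FaCE scoring requires all 15 items (no imputation)", call. = FALSE)
  for (i in seq_along(items))
    items[i] <- .check_range(items[i], sprintf("face item %d", i), 1, 5)
  recoded <- items
  recoded[config$reverse_keyed] <- 6 - recoded[config$reverse_keyed]
  rescale <- function(idx) {
    n <- length(idx)
    (sum(recoded[idx]) - n) / (4 * n) * 100
  }
  out <- lapply(config$domains, rescale)
  out$total <- rescale(seq_len(15))
  out
}

#' Score an instrument item table
#'
#' Applies one of the three scorers row-wise to a data.frame of item scores.
#' Expected columns: FNGS2.0 `brow, eye, nasolabial_fold, oral_commissure,
#' synkinesis`; Sunnybrook `rest_eye, rest_cheek_nlf, rest_mouth, vol_1..5,
#' syn_1..5`; FaCE `item_1..15`. Any identifier columns (e.g. `patient_id`,
#' `timepoint`) are carried through.
#'
#' @param items A data.frame, one row per assessment.
#' @param instrument `"fngs2"`, `"sunnybrook"` or `"face"`.
#' @return The input identifier columns with the score columns appended.
#' @export
score_instrument_table <- function(items, instrument = c("fngs2", "sunnybrook", "face")) {
  instrument <- match.arg(instrument)
  id_cols <- intersect(c("patient_id", "timepoint"), names(items))
  rows <- lapply(seq_len(nrow(items)), function(i) {
    r <- items[i, , drop = FALSE]
    sc <- switch(instrument,
      fngs2 = score_fngs(r$brow, r$eye, r$nasolabial_fold, r$oral_commissure,
                         if ("synkinesis" %in% names(r)) r$synkinesis else 0),
      sunnybrook = score_sunnybrook(
        c(r$rest_eye, r$rest_cheek_nlf, r$rest_mouth),
        unlist(r[paste0("vol_", 1:5)]),
        unlist(r[paste0("syn_", 1:5)])),
      face = score_face_scale(unlist(r[paste0("item_", 1:15)])))
    cbind(r[, id_cols, drop = FALSE],
          as.data.frame(sc, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
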
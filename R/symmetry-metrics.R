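# Quantitative facial-symmetry indices measured on a calibrated annotated
# face: Facial Asymmetry Index, palpebral fissure width, philtrum deviation,
# oral commissure components/excursions/angles, and pre/post differences.

#' Minimal postoperative smile excursion for good reanimation (mm)
#' @format Length-one numeric, millimetres.
#' @export
REANIMATION_THRESHOLD_MM <- 3.0

# face-frame mm coordinates (u lateral toward healthy, v superior) of a landmark
.face_uv <- function(face, condition, landmark) {
  set <- .set_for(face, condition)
  to_face_mm(.get_point(set, landmark), face$frame, .calib_for(face, condition))
}

.side_landmark <- function(base, side, face) {
  paste(base, .side_label(side, face$paralyzed_side), sep = "_")
}

#' Facial Asymmetry Index (FAI)
#'
#' Absolute difference between the two sides in the distance from the medial
#' canthus to the ipsilateral oral commissure. Lower values mean a more
#' symmetric face; 0 is perfect symmetry.
#'
#' @param face An [annotated_face].
#' @param condition Task condition, usually `"REST"` (static) or `"SMILE"`
#'   (dynamic).
#' @return FAI in millimetres (>= 0).
#' @export
facial_asymmetry_index <- function(face, condition = "REST") {
  set <- .set_for(face, condition)
  mm <- .calib_for(face, condition)$mm_per_pixel
  d_side <- function(side) {
    mm * .dist2d(.side_point(set, "medial_canthus", side, face$paralyzed_side),
                 .side_point(set, "oral_commissure", side, face$paralyzed_side))
  }
  abs(d_side("paralytic") - d_side("healthy"))
}

#' Palpebral fissure width
#'
#' Distance between the upper and lower eyelid margins measured on the
#' vertical line through the iris center. 0 mm means full eyelid closure.
#'
#' @inheritParams facial_asymmetry_index
#' @param side `"healthy"` or `"paralytic"`.
#' @return Width in millimetres (>= 0).
#' @export
palpebral_fissure_width <- function(face, side, condition = "REST") {
  set <- .set_for(face, condition)
  mm <- .calib_for(face, condition)$mm_per_pixel
  mm * .dist2d(.side_point(set, "eyelid_upper", side, face$paralyzed_side),
               .side_point(set, "eyelid_lower", side, face$paralyzed_side))
}

#' Philtrum deviation from the facial midline
#'
#' Perpendicular distance from the philtrum landmark to the central line of
#' the face, signed positive toward the healthy side (paralysis typically
#' drags the philtrum toward the healthy side, so untreated faces score
#' positive).
#'
#' @inheritParams facial_asymmetry_index
#' @return Signed deviation in millimetres.
#' @export
philtrum_deviation <- function(face, condition = "REST") {
  unname(.face_uv(face, condition, "philtrum")["u"])
}

#' Oral commissure components in the face frame
#'
#' Decomposes the position of one oral commissure relative to the reference
#' point into `f`, the horizontal distance from the central line (mm, >= 0),
#' and `g`, the vertical offset from the reference point (mm, superior
#' positive). These are the quantities entering the commissure angle and the
#' bilateral slope angle.
#'
#' @inheritParams palpebral_fissure_width
#' @return A `commissure_components` list with fields `f`, `g`, `side`,
#'   `condition`.
#' @export
commissure_components <- function(face, side, condition = "REST") {
  side <- match.arg(side, c("healthy", "paralytic"))
  uv <- .face_uv(face, condition,
                 .side_landmark("oral_commissure", side, face))
  structure(list(f = abs(unname(uv["u"])), g = unname(uv["v"]),
                 side = side, condition = condition),
            class = "commissure_components")
}

#' Commissure excursion relative to the reference point
#'
#' Horizontal (`f`), vertical (`g`) and overall (Euclidean) distance of the
#' oral commissure from the reference point within one condition; the "static
#' excursion" at `REST` and the "dynamic excursion" at `SMILE`.
#'
#' @inheritParams palpebral_fissure_width
#' @return Named numeric `c(horizontal, vertical, overall)` in millimetres.
#' @export
commissure_excursion <- function(face, side, condition = "REST") {
  cc <- commissure_components(face, side, condition)
  c(horizontal = cc$f, vertical = cc$g, overall = sqrt(cc$f^2 + cc$g^2))
}

#' Smile excursion of the oral commissure
#'
#' Change, from repose to smile, in the distance from the reference point to
#' the oral commissure, plus the corresponding changes in the horizontal and
#' vertical components. Positive values mean the commissure moved away from
#' the reference point when smiling.
#'
#' @inheritParams palpebral_fissure_width
#' @return Named numeric `c(dh, dv, overall)` in millimetres (signed).
#' @export
smile_excursion <- function(face, side) {
  rest <- commissure_excursion(face, side, "REST")
  smile <- commissure_excursion(face, side, "SMILE")
  c(dh = unname(smile["horizontal"] - rest["horizontal"]),
    dv = unname(smile["vertical"] - rest["vertical"]),
    overall = unname(smile["overall"] - rest["overall"]))
}

#' Philtrum-adjusted horizontal commissure distance
#'
#' Horizontal distance of the oral commissure measured from the vertical
#' through the philtrum landmark rather than from the central line. A philtrum
#' displaced toward the healthy side therefore reduces the healthy-side value
#' and increases the paralytic-side value, exposing asymmetry that the
#' midline-referenced distance hides.
#'
#' @inheritParams palpebral_fissure_width
#' @return Adjusted horizontal distance in millimetres (>= 0).
#' @export
adjusted_horizontal <- function(face, side, condition = "REST") {
  side <- match.arg(side, c("healthy", "paralytic"))
  u_comm <- .face_uv(face, condition,
                     .side_landmark("oral_commissure", side, face))["u"]
  u_phil <- .face_uv(face, condition, "philtrum")["u"]
  unname(abs(u_comm - u_phil))
}

#' Angle of the oral commissure above the horizontal
#'
#' `atan(g / f)` in degrees, where `f` and `g` are the commissure components;
#' positive when the commissure sits above the horizontal through the
#' reference point.
#'
#' @inheritParams palpebral_fissure_width
#' @return Angle in degrees, in (-90, 90]; if `f = 0` the +/-90 degree limit
#'   is returned with a warning.
#' @export
commissure_angle <- function(face, side, condition = "REST") {
  cc <- commissure_components(face, side, condition)
  if (cc$f == 0) {
    warning("commissure lies on the central line (f = 0); returning +/-90 degrees",
            call. = FALSE)
    return(90 * sign(cc$g))
  }
  atan(cc$g / cc$f) * 180 / pi
}

#' Slope angle of the bilateral oral commissures
#'
#' `atan((g - g') / (f + f'))` in degrees, with unprimed components from the
#' healthy side and primed from the paralytic side. 0 degrees means level
#' commissures; a drooped paralytic commissure gives a positive slope.
#'
#' @inheritParams facial_asymmetry_index
#' @return Angle in degrees.
#' @export
bilateral_slope_angle <- function(face, condition = "REST") {
  h <- commissure_components(face, "healthy", condition)
  p <- commissure_components(face, "paralytic", condition)
  denom <- h$f + p$f
  if (denom == 0)
    stop("degenerate geometry: both commissures on the central line", call. = FALSE)
  atan((h$g - p$g) / denom) * 180 / pi
}

#' Classify reanimation quality from postoperative smile excursion
#'
#' A postoperative overall smile excursion of the paralytic oral commissure
#' below 3.0 mm is classified as poor reanimation; 3.0 mm is the minimal
#' excursion for a good result.
#'
#' @param excursion_mm Numeric vector of overall smile excursions (mm).
#' @return Character vector, `"good"` or `"poor"`.
#' @export
classify_reanimation <- function(excursion_mm) {
  ifelse(excursion_mm < REANIMATION_THRESHOLD_MM, "poor", "good")
}

.try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

#' Compute the full symmetry-metric vector for one annotated face
#'
#' Evaluates every symmetry index available from the face's captured
#' conditions; indices whose condition or landmarks are missing come back
#' `NA`. The paralytic-side postoperative smile excursion additionally yields
#' the good/poor reanimation class.
#'
#' @param face An [annotated_face].
#' @return A one-row data.frame of metrics (documented, stable column order).
#' @export
symmetry_metrics <- function(face) {
  out <- data.frame(
    patient_id = face$patient_id, timepoint = face$timepoint,
    fai_rest = .try_na(facial_asymmetry_index(face, "REST")),
    fai_smile = .try_na(facial_asymmetry_index(face, "SMILE")),
    palpebral_healthy_rest = .try_na(palpebral_fissure_width(face, "healthy", "REST")),
    palpebral_paralytic_rest = .try_na(palpebral_fissure_width(face, "paralytic", "REST")),
    palpebral_healthy_closure = .try_na(palpebral_fissure_width(face, "healthy", "EYE_CLOSURE")),
    palpebral_paralytic_closure = .try_na(palpebral_fissure_width(face, "paralytic", "EYE_CLOSURE")),
    philtrum_dev_rest = .try_na(philtrum_deviation(face, "REST")),
    philtrum_dev_smile = .try_na(philtrum_deviation(face, "SMILE")),
    stringsAsFactors = FALSE)
  for (side in c("healthy", "paralytic")) {
    for (cond in c("REST", "SMILE")) {
      exc <- .try_na(commissure_excursion(face, side, cond))
      tag <- paste0(side, "_", tolower(cond))
      out[[paste0("exc_horizontal_", tag)]] <- unname(exc["horizontal"])
      out[[paste0("exc_vertical_", tag)]] <- unname(exc["vertical"])
      out[[paste0("exc_overall_", tag)]] <- unname(exc["overall"])
      out[[paste0("adjusted_horizontal_", tag)]] <-
        .try_na(adjusted_horizontal(face, side, cond))
      out[[paste0("commissure_angle_", tag)]] <-
        .try_na(suppressWarnings(commissure_angle(face, side, cond)))
    }
    sm <- .try_na(smile_excursion(face, side))
    out[[paste0("smile_dh_", side)]] <- unname(sm["dh"])
    out[[paste0("smile_dv_", side)]] <- unname(sm["dv"])
    out[[paste0("smile_overall_", side)]] <- unname(sm["overall"])
  }
  out$slope_angle_rest <- .try_na(bilateral_slope_angle(face, "REST"))
  out$slope_angle_smile <- .try_na(bilateral_slope_angle(face, "SMILE"))
  out$reanimation_class <-
    if (face$timepoint == "post" && is.finite(out$smile_overall_paralytic)) {
      classify_reanimation(out$smile_overall_paralytic)
    } else NA_character_
  out
}

#' Pre/post differences of the evaluation indices
#'
#' Computes the evaluation indices used by the prognostic models as signed
#' pre-to-post changes, oriented so that improvement is positive:
#' asymmetry-type indices (FAI, philtrum deviation magnitude, slope-angle
#' magnitude) as pre - post, excursion-type indices as post - pre. An index
#' whose operand is missing at either timepoint comes back `NA` (flagged
#' missing, never silently zero).
#'
#' @param pre,post One-row data.frames from [symmetry_metrics()] for the same
#'   patient at the two timepoints.
#' @return A one-row data.frame of differences.
#' @export
metric_differences <- function(pre, post) {
  stopifnot(identical(pre$patient_id, post$patient_id))
  d <- function(x) ifelse(is.finite(x), x, NA_real_)
  data.frame(
    patient_id = pre$patient_id,
    diff_static_fai = d(pre$fai_rest) - d(post$fai_rest),
    diff_dynamic_fai = d(pre$fai_smile) - d(post$fai_smile),
    diff_static_overall_excursion_paralytic =
      d(post$exc_overall_paralytic_rest) - d(pre$exc_overall_paralytic_rest),
    diff_dynamic_overall_excursion_paralytic =
      d(post$exc_overall_paralytic_smile) - d(pre$exc_overall_paralytic_smile),
    diff_static_philtrum_dev =
      abs(d(pre$philtrum_dev_rest)) - abs(d(post$philtrum_dev_rest)),
    diff_dynamic_philtrum_dev =
      abs(d(pre$philtrum_dev_smile)) - abs(d(post$philtrum_dev_smile)),
    restoration_dynamic_slope_angle =
      abs(d(pre$slope_angle_smile)) - abs(d(post$slope_angle_smile)),
    stringsAsFactors = FALSE)
}

#' Measure a set of landmark files into a metrics table
#'
#' Convenience wrapper over [read_landmarks()] + [symmetry_metrics()]: one row
#' per patient-timepoint, stable column order.
#'
#' @param paths Character vector of landmark file paths.
#' @param meta Optional list of [patient_meta] keyed by patient id.
#' @return A data.frame of symmetry metrics.
#' @export
measure_landmark_files <- function(paths, meta = NULL) {
  rows <- lapply(paths, function(p) {
    face <- read_landmarks(p)
    if (!is.null(meta) && face$patient_id %in% names(meta))
      face$meta <- meta[[face$patient_id]]
    symmetry_metrics(face)
  })
  do.call(rbind, rows)
}
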
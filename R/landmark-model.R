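# Landmark domain model: task conditions, calibrated landmark sets, the
# white-to-white pixel->mm calibration and the face-centric coordinate frame.

#' Standardized horizontal white-to-white corneal diameter (mm)
#'
#' The horizontal corneal diameter is nearly invariant across adults, which
#' makes it a usable intrinsic ruler on clinical photographs: the distance in
#' pixels between the medial and lateral corneal limbus is assumed to span
#' 11.576 mm, and every other measurement is scaled accordingly.
#'
#' @format A length-one numeric (millimetres).
#' @export
WTW_MM <- 11.576

#' Task conditions captured in a photographic session
#'
#' @format Character vector of the five standard task conditions.
#' @export
FACE_CONDITIONS <- c("REST", "BROW_RAISE", "EYE_CLOSURE", "SNARL", "SMILE")

# point landmarks a set may carry ("left"/"right" are anatomical, i.e. the
# subject's own left and right, independent of which side is paralyzed)
.POINT_LANDMARKS <- c(
  "iris_center_left", "iris_center_right",
  "limbus_medial_left", "limbus_lateral_left",
  "limbus_medial_right", "limbus_lateral_right",
  "medial_canthus_left", "medial_canthus_right",
  "oral_commissure_left", "oral_commissure_right",
  "philtrum",
  "eyelid_upper_left", "eyelid_lower_left",
  "eyelid_upper_right", "eyelid_lower_right"
)

# landmarks every condition must carry (calibration must be computable)
.REQUIRED_ALWAYS <- c(
  "iris_center_left", "iris_center_right",
  "limbus_medial_left", "limbus_lateral_left",
  "limbus_medial_right", "limbus_lateral_right"
)

.dist2d <- function(a, b) sqrt(sum((a - b)^2))

.assert_point <- function(p, name, condition = NULL) {
  where <- if (is.null(condition)) "" else sprintf(" in condition %s", condition)
  if (!is.numeric(p) || length(p) != 2 || any(!is.finite(p))) {
    stop(sprintf("landmark '%s'%s must be a finite (x, y) pair", name, where),
         call. = FALSE)
  }
  invisible(p)
}

#' Construct a landmark set for one task condition
#'
#' @param condition One of [FACE_CONDITIONS].
#' @param points Named list of length-2 numeric vectors, pixel coordinates in
#'   image convention (x rightward, y downward). Names must be landmark names;
#'   unknown names are dropped with a warning.
#' @param vermilion Two-column numeric matrix: ordered polyline of points along
#'   the vermilion margin of the lower lip, spanning horizontally across both
#'   oral commissures. Required for `REST` (the face frame is anchored there).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(condition, points, vermilion = NULL) {
  condition <- match.arg(condition, FACE_CONDITIONS)
  stopifnot(is.list(points))
  unknown <- setdiff(names(points), .POINT_LANDMARKS)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown landmark(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    points <- points[setdiff(names(points), unknown)]
  }
  for (nm in names(points)) .assert_point(points[[nm]], nm, condition)
  missing <- setdiff(.REQUIRED_ALWAYS, names(points))
  if (length(missing) > 0) {
    stop(sprintf("missing landmark %s in condition %s",
                 paste(missing, collapse = ", "), condition), call. = FALSE)
  }
  if (!is.null(vermilion)) {
    vermilion <- as.matrix(vermilion)
    if (ncol(vermilion) != 2 || nrow(vermilion) < 2 || any(!is.finite(vermilion)))
      stop("vermilion must be a finite polyline with >= 2 points", call. = FALSE)
    dimnames(vermilion) <- list(NULL, c("x", "y"))
  }
  structure(list(condition = condition, points = points, vermilion = vermilion),
            class = "landmark_set")
}

# fetch a landmark or fail with a named error
.get_point <- function(set, name) {
  p <- set$points[[name]]
  if (is.null(p)) {
    stop(sprintf("missing landmark %s in condition %s", name, set$condition),
         call. = FALSE)
  }
  p
}

# map healthy/paralytic to anatomical left/right for a given paralyzed side
.side_label <- function(side, paralyzed_side) {
  side <- match.arg(side, c("healthy", "paralytic"))
  if (side == "paralytic") paralyzed_side else setdiff(c("left", "right"), paralyzed_side)
}

.side_point <- function(set, base, side, paralyzed_side) {
  .get_point(set, paste(base, .side_label(side, paralyzed_side), sep = "_"))
}

#' Patient metadata record
#'
#' @param id Patient identifier.
#' @param age Age in years.
#' @param gender `"female"` or `"male"`.
#' @param cause Cause of paralysis: `"tumor"`, `"bell_palsy"`, `"trauma"`,
#'   `"infection"` or `"other"`.
#' @param paralysis_duration Months from onset to surgery; must be positive.
#' @param paralyzed_side `"left"` or `"right"`.
#' @param preop_fngs_grade Integer facial nerve grade 1-6 before surgery.
#' @param time_to_first_contraction Months to first visible facial contraction
#'   with biting after surgery, or `NA` if not (yet) observed.
#' @param followup Postoperative follow-up in months.
#' @return A `patient_meta` object (named list).
#' @export
patient_meta <- function(id, age, gender, cause, paralysis_duration,
                         paralyzed_side, preop_fngs_grade,
                         time_to_first_contraction = NA_real_,
                         followup = NA_real_) {
  gender <- match.arg(gender, c("female", "male"))
  cause <- match.arg(cause, c("tumor", "bell_palsy", "trauma", "infection", "other"))
  paralyzed_side <- match.arg(paralyzed_side, c("left", "right"))
  if (!is.finite(paralysis_duration) || paralysis_duration <= 0)
    stop("paralysis_duration must be > 0", call. = FALSE)
  if (!preop_fngs_grade %in% 1:6)
    stop("preop_fngs_grade must be an integer in 1..6", call. = FALSE)
  structure(list(
    id = as.character(id), age = as.numeric(age), gender = gender, cause = cause,
    paralysis_duration = as.numeric(paralysis_duration),
    paralyzed_side = paralyzed_side,
    preop_fngs_grade = as.integer(preop_fngs_grade),
    time_to_first_contraction = as.numeric(time_to_first_contraction),
    followup = as.numeric(followup)
  ), class = "patient_meta")
}

#' Compute the pixel-to-millimetre calibration from the corneal limbus
#'
#' The distance in pixels between the medial and lateral limbus of the chosen
#' eye is identified with the standardized white-to-white corneal diameter
#' ([WTW_MM], 11.576 mm), so `mm_per_pixel = 11.576 / wtw_pixels`.
#'
#' @param set A [landmark_set] containing limbus landmarks.
#' @param paralyzed_side `"left"` or `"right"` (to resolve `source_eye`).
#' @param source_eye Which eye anchors the scale: `"healthy"` (default;
#'   paralysis can distort the lid aperture but not the limbus, and the healthy
#'   side is the conservative choice), `"paralytic"`, or `"mean"` of both eyes.
#' @return A `calibration_info` object with fields `mm_per_pixel`,
#'   `source_eye`, `wtw_pixels`.
#' @export
compute_calibration <- function(set, paralyzed_side,
                                source_eye = c("healthy", "paralytic", "mean")) {
  source_eye <- match.arg(source_eye)
  wtw_for <- function(side_lab) {
    .dist2d(.get_point(set, paste0("limbus_medial_", side_lab)),
            .get_point(set, paste0("limbus_lateral_", side_lab)))
  }
  wtw <- if (source_eye == "mean") {
    mean(c(wtw_for("left"), wtw_for("right")))
  } else {
    wtw_for(.side_label(source_eye, paralyzed_side))
  }
  if (!is.finite(wtw) || wtw <= 0)
    stop("degenerate geometry: white-to-white pixel distance must be > 0",
         call. = FALSE)
  structure(list(mm_per_pixel = WTW_MM / wtw, source_eye = source_eye,
                 wtw_pixels = wtw),
            class = "calibration_info")
}

# intersections of the line {p0 + t*dir} with a polyline; returns matrix of points
.line_polyline_intersections <- function(p0, dir, poly) {
  # line normal form: n . (x - p0) = 0 with n perpendicular to dir
  n <- c(-dir[2], dir[1])
  out <- NULL
  f <- as.vector((poly[, 1] - p0[1]) * n[1] + (poly[, 2] - p0[2]) * n[2])
  for (i in seq_len(nrow(poly) - 1)) {
    f1 <- f[i]; f2 <- f[i + 1]
    if (f1 == 0) out <- rbind(out, poly[i, ])
    if ((f1 < 0 && f2 > 0) || (f1 > 0 && f2 < 0)) {
      t <- f1 / (f1 - f2)
      out <- rbind(out, poly[i, ] + t * (poly[i + 1, ] - poly[i, ]))
    }
  }
  if (!is.null(out) && f[length(f)] == 0) out <- rbind(out, poly[nrow(poly), ])
  out
}

#' Build the face-centric coordinate frame
#'
#' The central line of the face is the perpendicular bisector of the segment
#' joining the two iris centers. Its intersection with the vermilion margin of
#' the lower lip is the reference point (frame origin); all symmetry
#' measurements refer to it. The frame's x axis runs along the inter-iris
#' direction toward the healthy side and its y axis is perpendicular with the
#' superior direction positive (image y points down, so the frame flips it).
#'
#' @param set The `REST` [landmark_set] (iris centers and vermilion required).
#' @param paralyzed_side `"left"` or `"right"`.
#' @return A `face_frame` object with `origin`, `x_axis`, `y_axis` (pixel
#'   space; axes are orthonormal).
#' @export
build_face_frame <- function(set, paralyzed_side) {
  iris_l <- .get_point(set, "iris_center_left")
  iris_r <- .get_point(set, "iris_center_right")
  if (.dist2d(iris_l, iris_r) < .Machine$double.eps^0.5)
    stop("degenerate geometry: iris centers coincide", call. = FALSE)
  if (is.null(set$vermilion))
    stop(sprintf("missing landmark lower_lip_vermilion in condition %s",
                 set$condition), call. = FALSE)
  mid <- (iris_l + iris_r) / 2
  inter <- (iris_r - iris_l) / .dist2d(iris_l, iris_r)
  bisector_dir <- c(-inter[2], inter[1])
  hits <- .line_polyline_intersections(mid, bisector_dir, set$vermilion)
  if (is.null(hits) || nrow(hits) == 0)
    stop("central line does not intersect the lower-lip vermilion polyline",
         call. = FALSE)
  if (nrow(hits) > 1) {
    cm <- (.get_point(set, "oral_commissure_left") +
           .get_point(set, "oral_commissure_right")) / 2
    d <- sqrt((hits[, 1] - cm[1])^2 + (hits[, 2] - cm[2])^2)
    origin <- hits[which.min(d), ]
  } else {
    origin <- hits[1, ]
  }
  origin <- as.numeric(origin)
  healthy <- .side_label("healthy", paralyzed_side)
  iris_healthy <- if (healthy == "left") iris_l else iris_r
  iris_paral <- if (healthy == "left") iris_r else iris_l
  x_axis <- (iris_healthy - iris_paral) / .dist2d(iris_healthy, iris_paral)
  y_axis <- c(-x_axis[2], x_axis[1])
  # orient y superiorly: iris centers must sit above (positive v of) the mouth
  if (sum((mid - origin) * y_axis) < 0) y_axis <- -y_axis
  structure(list(origin = origin, x_axis = x_axis, y_axis = y_axis),
            class = "face_frame")
}

#' Convert a pixel point into face-frame millimetres
#'
#' @param p Length-2 numeric, pixel coordinates.
#' @param frame A [build_face_frame()] result.
#' @param calib A [compute_calibration()] result.
#' @return Named numeric `c(u, v)`: `u` mm lateral (positive toward the healthy
#'   side), `v` mm vertical (positive superiorly).
#' @export
to_face_mm <- function(p, frame, calib) {
  .assert_point(p, "point")
  d <- p - frame$origin
  c(u = calib$mm_per_pixel * sum(d * frame$x_axis),
    v = calib$mm_per_pixel * sum(d * frame$y_axis))
}

#' Invert [to_face_mm()]: face-frame millimetres back to pixel coordinates
#'
#' @param uv Named or unnamed length-2 numeric `(u, v)` in mm.
#' @inheritParams to_face_mm
#' @return Length-2 numeric pixel coordinates.
#' @export
from_face_mm <- function(uv, frame, calib) {
  px <- as.numeric(uv) / calib$mm_per_pixel
  frame$origin + px[1] * frame$x_axis + px[2] * frame$y_axis
}

#' Assemble an annotated face for one patient-timepoint
#'
#' Bundles the landmark sets of a photographic session with a shared
#' calibration (photos in one session share scale) and the face frame derived
#' from the `REST` set.
#'
#' @param sets List of [landmark_set] objects; a `REST` set is mandatory.
#' @param patient_id Patient identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param paralyzed_side `"left"` or `"right"`.
#' @param meta Optional [patient_meta] (its `paralyzed_side` must agree).
#' @param source_eye Calibration eye, see [compute_calibration()].
#' @param per_condition_calibration If `TRUE`, each condition is recalibrated
#'   from its own limbus landmarks instead of sharing the `REST` calibration.
#' @return An `annotated_face` object.
#' @export
annotated_face <- function(sets, patient_id, timepoint, paralyzed_side,
                           meta = NULL,
                           source_eye = c("healthy", "paralytic", "mean"),
                           per_condition_calibration = FALSE) {
  source_eye <- match.arg(source_eye)
  timepoint <- match.arg(timepoint, c("pre", "post"))
  paralyzed_side <- match.arg(paralyzed_side, c("left", "right"))
  if (!is.null(meta) && !identical(meta$paralyzed_side, paralyzed_side))
    stop("meta$paralyzed_side disagrees with paralyzed_side", call. = FALSE)
  stopifnot(is.list(sets), length(sets) >= 1)
  names(sets) <- vapply(sets, function(s) s$condition, character(1))
  if (!"REST" %in% names(sets))
    stop("a REST landmark set is required", call. = FALSE)
  calib <- compute_calibration(sets$REST, paralyzed_side, source_eye)
  per_cond <- NULL
  if (per_condition_calibration) {
    per_cond <- lapply(sets, compute_calibration,
                       paralyzed_side = paralyzed_side, source_eye = source_eye)
  }
  frame <- build_face_frame(sets$REST, paralyzed_side)
  structure(list(
    patient_id = as.character(patient_id), timepoint = timepoint,
    paralyzed_side = paralyzed_side, meta = meta, sets = sets,
    calibration = calib, per_condition_calibration = per_cond, frame = frame
  ), class = "annotated_face")
}

# calibration applicable to a given condition of a face
.calib_for <- function(face, condition) {
  if (!is.null(face$per_condition_calibration) &&
      condition %in% names(face$per_condition_calibration)) {
    face$per_condition_calibration[[condition]]
  } else {
    face$calibration
  }
}

.set_for <- function(face, condition) {
  s <- face$sets[[condition]]
  if (is.null(s))
    stop(sprintf("condition %s not captured for patient %s (%s)",
                 condition, face$patient_id, face$timepoint), call. = FALSE)
  s
}

#' @method print annotated_face
#' @export
print.annotated_face <- function(x, ...) {
  cat(sprintf("<annotated_face> patient %s, %s-op, paralyzed side %s\n",
              x$patient_id, x$timepoint, x$paralyzed_side))
  cat(sprintf("  conditions: %s\n", paste(names(x$sets), collapse = ", ")))
  cat(sprintf("  calibration: %.5f mm/px (wtw %.2f px, %s eye)\n",
              x$calibration$mm_per_pixel, x$calibration$wtw_pixels,
              x$calibration$source_eye))
  invisible(x)
}
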
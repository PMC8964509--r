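# Landmark and metadata file I/O.
#
# Two dialects carry the same content:
#   * JSON: one document per patient-timepoint; keys named exactly as the
#     landmark fields, plus schema_version / patient_id / timepoint /
#     paralyzed_side; per-condition objects under "conditions".
#   * CSV (long): columns patient_id, timepoint, paralyzed_side, condition,
#     landmark, x, y; the vermilion polyline is repeated "lower_lip_vermilion"
#     rows in polyline order.
# Coordinates are 0-based pixel floats. Writers emit byte-stable output.

.SCHEMA_VERSION <- 1L
.KNOWN_JSON_KEYS <- c("schema_version", "patient_id", "timepoint",
                      "paralyzed_side", "conditions")

#' Write an annotated face to the JSON landmark schema
#'
#' @param face An [annotated_face].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(face, path) {
  conds <- lapply(face$sets, function(s) {
    out <- lapply(s$points, function(p) round(unname(p), 6))
    if (!is.null(s$vermilion))
      out$lower_lip_vermilion <- unname(round(s$vermilion, 6))
    out
  })
  doc <- list(schema_version = .SCHEMA_VERSION,
              patient_id = face$patient_id,
              timepoint = face$timepoint,
              paralyzed_side = face$paralyzed_side,
              conditions = conds)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Write an annotated face to the long CSV landmark schema
#'
#' @inheritParams write_landmarks_json
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(face, path) {
  rows <- list()
  for (cond in names(face$sets)) {
    s <- face$sets[[cond]]
    for (nm in names(s$points)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = face$patient_id, timepoint = face$timepoint,
        paralyzed_side = face$paralyzed_side, condition = cond,
        landmark = nm, x = round(s$points[[nm]][1], 6),
        y = round(s$points[[nm]][2], 6), stringsAsFactors = FALSE)
    }
    if (!is.null(s$vermilion)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = face$patient_id, timepoint = face$timepoint,
        paralyzed_side = face$paralyzed_side, condition = cond,
        landmark = "lower_lip_vermilion",
        x = round(s$vermilion[, 1], 6), y = round(s$vermilion[, 2], 6),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_point <- function(v, name, condition, where) {
  x <- suppressWarnings(as.numeric(unlist(v)))
  if (length(x) != 2 || any(!is.finite(x)))
    stop(sprintf("malformed coordinates for landmark '%s' (condition %s) in %s",
                 name, condition, where), call. = FALSE)
  x
}

.sets_from_condition_list <- function(conds, where) {
  lapply(names(conds), function(cond) {
    entries <- conds[[cond]]
    verm <- NULL
    if (!is.null(entries$lower_lip_vermilion)) {
      verm <- entries$lower_lip_vermilion
      if (is.list(verm)) verm <- do.call(rbind, lapply(verm, unlist))
      verm <- matrix(suppressWarnings(as.numeric(verm)), ncol = 2)
      if (any(!is.finite(verm)))
        stop(sprintf("malformed lower_lip_vermilion coordinates (condition %s) in %s",
                     cond, where), call. = FALSE)
      entries$lower_lip_vermilion <- NULL
    }
    pts <- lapply(names(entries), function(nm)
      .parse_point(entries[[nm]], nm, cond, where))
    names(pts) <- names(entries)
    landmark_set(cond, pts, vermilion = verm)
  })
}

#' Read a landmark file into an annotated face
#'
#' Accepts both supported dialects; `format = "auto"` dispatches on the file
#' extension. Unknown fields are ignored with a warning; a missing required
#' landmark raises an error naming the landmark and condition.
#'
#' @param path Landmark file (`.json` or `.csv`).
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @param meta Optional [patient_meta]; if supplied its `paralyzed_side`
#'   overrides/validates the one stored in the file.
#' @inheritParams annotated_face
#' @return An [annotated_face].
#' @export
read_landmarks <- function(path, format = c("auto", "json", "csv"), meta = NULL,
                           source_eye = c("healthy", "paralytic", "mean"),
                           per_condition_calibration = FALSE) {
  format <- match.arg(format)
  source_eye <- match.arg(source_eye)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    unknown <- setdiff(names(doc), .KNOWN_JSON_KEYS)
    if (length(unknown) > 0)
      warning(sprintf("ignoring unknown field(s) in %s: %s", path,
                      paste(unknown, collapse = ", ")), call. = FALSE)
    for (k in c("patient_id", "timepoint", "paralyzed_side", "conditions"))
      if (is.null(doc[[k]]))
        stop(sprintf("landmark JSON %s lacks required field '%s'", path, k),
             call. = FALSE)
    sets <- .sets_from_condition_list(doc$conditions, path)
    pid <- doc$patient_id; tp <- doc$timepoint; side <- doc$paralyzed_side
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "timepoint", "paralyzed_side", "condition",
              "landmark", "x", "y")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop(sprintf("landmark CSV %s lacks column(s): %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    extra <- setdiff(names(df), need)
    if (length(extra) > 0)
      warning(sprintf("ignoring unknown column(s) in %s: %s", path,
                      paste(extra, collapse = ", ")), call. = FALSE)
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
                 !is.finite(suppressWarnings(as.numeric(df$y))))
    if (length(bad) > 0)
      stop(sprintf("malformed coordinates in %s at data row(s) %s", path,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    if (length(unique(df$patient_id)) != 1 || length(unique(df$timepoint)) != 1)
      stop("landmark CSV must contain exactly one patient-timepoint", call. = FALSE)
    conds <- list()
    for (cond in unique(df$condition)) {
      sub <- df[df$condition == cond, , drop = FALSE]
      entry <- list()
      for (nm in unique(sub$landmark)) {
        rows <- sub[sub$landmark == nm, , drop = FALSE]
        if (nm == "lower_lip_vermilion") {
          entry[[nm]] <- cbind(rows$x, rows$y)
        } else {
          entry[[nm]] <- c(rows$x[1], rows$y[1])
        }
      }
      conds[[cond]] <- entry
    }
    sets <- .sets_from_condition_list(conds, path)
    pid <- df$patient_id[1]; tp <- df$timepoint[1]; side <- df$paralyzed_side[1]
  }
  if (!is.null(meta)) side <- meta$paralyzed_side
  annotated_face(sets, patient_id = pid, timepoint = tp, paralyzed_side = side,
                 meta = meta, source_eye = source_eye,
                 per_condition_calibration = per_condition_calibration)
}

#' Write a patient metadata table to CSV
#'
#' @param meta_list List of [patient_meta] objects, or a data.frame already in
#'   the metadata column layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_meta <- function(meta_list, path) {
  df <- if (is.data.frame(meta_list)) meta_list else
    do.call(rbind, lapply(meta_list, function(m)
      as.data.frame(unclass(m), stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a patient metadata CSV
#'
#' @param path Metadata CSV path.
#' @return A list of [patient_meta] objects, named by patient id.
#' @export
read_patient_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "gender", "cause", "paralysis_duration",
            "paralyzed_side", "preop_fngs_grade")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("metadata CSV lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    patient_meta(
      id = df$id[i], age = df$age[i], gender = df$gender[i], cause = df$cause[i],
      paralysis_duration = df$paralysis_duration[i],
      paralyzed_side = df$paralyzed_side[i],
      preop_fngs_grade = df$preop_fngs_grade[i],
      time_to_first_contraction =
        if ("time_to_first_contraction" %in% names(df))
          df$time_to_first_contraction[i] else NA_real_,
      followup = if ("followup" %in% names(df)) df$followup[i] else NA_real_)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}
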
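# Shared fixtures: all built in code, no stored data.

# identity mm->pixel transform (y flip only), for hand-checkable geometry
identity_transform <- function() list(scale = 1, theta = 0, shift = c(0, 0))

# noise-free generator config for deterministic geometry fixtures
quiet_config <- function(...) face_generator_config(landmark_noise_sd = 0, ...)

# a symmetric pixel-space landmark scaffold (y down): iris on y = 0,
# white-to-white 57.88 px (0.2 mm/px), mouth area around y = 400.
# Returns a named list of points plus a horizontal vermilion polyline.
scaffold_points <- function() {
  list(
    iris_center_left = c(-50, 0), iris_center_right = c(50, 0),
    limbus_medial_left = c(-50 + 28.94, 0), limbus_lateral_left = c(-50 - 28.94, 0),
    limbus_medial_right = c(50 - 28.94, 0), limbus_lateral_right = c(50 + 28.94, 0),
    medial_canthus_left = c(-25, 10), medial_canthus_right = c(25, 10),
    eyelid_upper_left = c(-50, -20), eyelid_lower_left = c(-50, 20),
    eyelid_upper_right = c(-50 + 100, -20), eyelid_lower_right = c(50, 20),
    philtrum = c(0, 330),
    oral_commissure_left = c(-120, 340), oral_commissure_right = c(120, 340)
  )
}

scaffold_vermilion <- function() cbind(seq(-150, 150, by = 25), 400)

# build an annotated face from (optionally modified) scaffold coordinates
scaffold_face <- function(points = scaffold_points(),
                          vermilion = scaffold_vermilion(),
                          paralyzed_side = "left", timepoint = "pre",
                          condition_sets = NULL) {
  sets <- list(landmark_set("REST", points, vermilion = vermilion))
  if (!is.null(condition_sets)) sets <- c(sets, condition_sets)
  annotated_face(sets, patient_id = "FIX", timepoint = timepoint,
                 paralyzed_side = paralyzed_side)
}

# apply a similarity transform (rotation deg, uniform scale, translation) to
# every pixel coordinate of an annotated face and rebuild it
transform_face <- function(face, theta_deg = 0, scale = 1, shift = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tf <- function(p) as.numeric(scale * R %*% p + shift)
  sets <- lapply(face$sets, function(s) {
    pts <- lapply(s$points, tf)
    verm <- if (is.null(s$vermilion)) NULL else t(apply(s$vermilion, 1, tf))
    landmark_set(s$condition, pts, vermilion = verm)
  })
  annotated_face(sets, patient_id = face$patient_id, timepoint = face$timepoint,
                 paralyzed_side = face$paralyzed_side)
}

# geometric mirror: reflect every pixel coordinate about a vertical axis and
# flip the paralyzed-side flag (landmark labels keep their names)
mirror_face <- function(face, axis_x = 0) {
  refl <- function(p) c(2 * axis_x - p[1], p[2])
  sets <- lapply(face$sets, function(s) {
    pts <- lapply(s$points, refl)
    verm <- t(apply(s$vermilion %||% matrix(numeric(0), 0, 2), 1, refl))
    if (nrow(verm) == 0) verm <- NULL
    landmark_set(s$condition, pts, vermilion = verm)
  })
  annotated_face(sets, patient_id = face$patient_id, timepoint = face$timepoint,
                 paralyzed_side = setdiff(c("left", "right"), face$paralyzed_side))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# exact two-sided signed-rank p-value by enumeration over all sign patterns
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  # two-sided: double the smaller tail (the null distribution is symmetric)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# the full mm-valued metric vector used by invariance properties
metric_vector <- function(face) {
  m <- symmetry_metrics(face)
  unlist(m[vapply(m, is.numeric, logical(1))])
}
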
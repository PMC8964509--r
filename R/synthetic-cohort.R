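# Synthetic faces and patient cohorts with the geometric and statistical
# structure the measurement pipeline assumes: a symmetric template face in
# millimetres is deformed by paralysis (commissure droop, philtrum/commissure
# pull toward the healthy side, widened palpebral fissure, lost smile
# excursion), optionally attenuated by recovery, jittered, and emitted in
# pixel coordinates under a random similarity transform per photo session.

#' Symmetric template face in millimetres
#'
#' Canonical healthy geometry (y up, midline at x = 0, units mm): iris centers
#' 62 mm apart, corneal limbus consistent with the 11.576 mm white-to-white
#' diameter, palpebral fissures 8.23 mm, oral commissures 23 mm lateral and
#' 12.7 mm above the lower-lip reference point, philtrum on the midline.
#'
#' @param wtw_mm White-to-white corneal diameter (mm).
#' @return A list with per-side point coordinates and the vermilion polyline.
#' @export
face_template <- function(wtw_mm = WTW_MM) {
  half_wtw <- wtw_mm / 2
  pts <- list(
    iris_center_right = c(31, 0), iris_center_left = c(-31, 0),
    limbus_medial_right = c(31 - half_wtw, 0),
    limbus_lateral_right = c(31 + half_wtw, 0),
    limbus_medial_left = c(-31 + half_wtw, 0),
    limbus_lateral_left = c(-31 - half_wtw, 0),
    medial_canthus_right = c(15.5, -2), medial_canthus_left = c(-15.5, -2),
    eyelid_upper_right = c(31, 4.115), eyelid_lower_right = c(31, -4.115),
    eyelid_upper_left = c(-31, 4.115), eyelid_lower_left = c(-31, -4.115),
    philtrum = c(0, -63),
    oral_commissure_right = c(23, -63.3), oral_commissure_left = c(-23, -63.3)
  )
  vx <- seq(-30, 30, length.out = 13)
  verm <- cbind(vx, -76 + 0.0015 * vx^2)
  list(points = pts, vermilion = verm, reference = c(0, -76))
}

#' Face generator configuration
#'
#' Deformation magnitudes are the values applied at severity 1 (fully
#' paralyzed); `generate_face()` scales them linearly by severity and, for
#' postoperative faces, by `1 - recovery_fraction`.
#'
#' @param droop Vertical drop of the paralytic oral commissure (mm).
#' @param commissure_pull Medial pull of the paralytic commissure toward the
#'   healthy side (mm).
#' @param lateral_pull Philtrum shift toward the healthy side at rest (mm).
#' @param philtrum_smile_extra Additional philtrum shift when smiling (mm).
#' @param fissure_widening Widening of the paralytic palpebral fissure at rest
#'   (mm, split between the two lids).
#' @param closure_gap Residual paralytic fissure width during forced eye
#'   closure (mm); 0 means full closure (the lids meet and are digitized as
#'   one margin).
#' @param smile_gain_healthy Overall smile excursion of the healthy commissure
#'   (mm), applied radially away from the reference point.
#' @param smile_gain_paralytic Paralytic-side excursion at severity 1; the
#'   effective gain interpolates from `smile_gain_healthy` (severity 0) to
#'   this value (severity 1), so a severity-0 face smiles symmetrically.
#' @param recovery_fraction Fraction of the deformation undone
#'   postoperatively, in `[0, 1]`.
#' @param landmark_noise_sd Gaussian digitization jitter per landmark
#'   coordinate (mm).
#' @param wtw_mm White-to-white corneal diameter (mm).
#' @param seed Optional integer; when set, [generate_face()] is deterministic.
#' @param template Template geometry, see [face_template()].
#' @return A `face_generator_config` list.
#' @export
face_generator_config <- function(droop = 8, commissure_pull = 2.8,
                                  lateral_pull = 4, philtrum_smile_extra = 4,
                                  fissure_widening = 2, closure_gap = 4,
                                  smile_gain_healthy = 5.8,
                                  smile_gain_paralytic = 0.2,
                                  recovery_fraction = 0,
                                  landmark_noise_sd = 0.2,
                                  wtw_mm = WTW_MM, seed = NULL,
                                  template = NULL) {
  stopifnot(landmark_noise_sd >= 0, recovery_fraction >= 0, recovery_fraction <= 1,
            droop >= 0, closure_gap >= 0)
  if (is.null(template)) template <- face_template(wtw_mm)
  structure(list(
    droop = droop, commissure_pull = commissure_pull,
    lateral_pull = lateral_pull, philtrum_smile_extra = philtrum_smile_extra,
    fissure_widening = fissure_widening, closure_gap = closure_gap,
    smile_gain_healthy = smile_gain_healthy,
    smile_gain_paralytic = smile_gain_paralytic,
    recovery_fraction = recovery_fraction,
    landmark_noise_sd = landmark_noise_sd, wtw_mm = wtw_mm, seed = seed,
    template = template), class = "face_generator_config")
}

# mirror template so that the paralytic side is the requested anatomical side;
# the template's "right" is treated as paralytic before mirroring
.oriented_template <- function(template, paralyzed_side) {
  if (paralyzed_side == "right") return(template)
  swap <- function(nm) {
    out <- nm
    out <- sub("_right$", "_TMP", out)
    out <- sub("_left$", "_right", out)
    sub("_TMP$", "_left", out)
  }
  pts <- lapply(template$points, function(p) c(-p[1], p[2]))
  names(pts) <- swap(names(template$points))
  verm <- template$vermilion
  verm[, 1] <- -verm[, 1]
  list(points = pts, vermilion = verm[nrow(verm):1, ], reference = template$reference)
}

# deform the mm template at effective severity s (paralytic side = "right"
# pre-mirroring is handled by .oriented_template: here sides are anatomical)
.deform_condition <- function(tmpl, config, s, condition, paralyzed_side) {
  healthy_side <- setdiff(c("left", "right"), paralyzed_side)
  sgn_healthy <- if (healthy_side == "right") 1 else -1  # +x toward healthy?
  pts <- tmpl$points
  P <- function(base) paste(base, paralyzed_side, sep = "_")
  H <- function(base) paste(base, healthy_side, sep = "_")
  # rest deformation (applies in every condition)
  pts[[P("oral_commissure")]] <- pts[[P("oral_commissure")]] +
    c(sgn_healthy * config$commissure_pull * s, -config$droop * s)
  pts$philtrum <- pts$philtrum + c(sgn_healthy * config$lateral_pull * s, 0)
  pts[[P("eyelid_upper")]][2] <- pts[[P("eyelid_upper")]][2] +
    config$fissure_widening * s / 2
  pts[[P("eyelid_lower")]][2] <- pts[[P("eyelid_lower")]][2] -
    config$fissure_widening * s / 2
  if (condition == "EYE_CLOSURE") {
    iris_h <- pts[[H("iris_center")]]; iris_p <- pts[[P("iris_center")]]
    pts[[H("eyelid_upper")]] <- iris_h
    pts[[H("eyelid_lower")]] <- iris_h
    gap <- config$closure_gap * s
    pts[[P("eyelid_upper")]] <- iris_p + c(0, gap / 2)
    pts[[P("eyelid_lower")]] <- iris_p - c(0, gap / 2)
  }
  if (condition == "SMILE") {
    ref <- tmpl$reference
    radial <- function(p) (p - ref) / sqrt(sum((p - ref)^2))
    ch <- pts[[H("oral_commissure")]]
    pts[[H("oral_commissure")]] <- ch + config$smile_gain_healthy * radial(ch)
    gain_p <- (1 - s) * config$smile_gain_healthy + s * config$smile_gain_paralytic
    cp <- pts[[P("oral_commissure")]]
    pts[[P("oral_commissure")]] <- cp + gain_p * radial(cp)
    pts$philtrum <- pts$philtrum + c(sgn_healthy * config$philtrum_smile_extra * s, 0)
  }
  list(points = pts, vermilion = tmpl$vermilion)
}

# random similarity transform mm (y up) -> pixels (y down)
.random_session_transform <- function() {
  theta <- stats::runif(1, -10, 10) * pi / 180
  list(scale = stats::runif(1, 3, 6), theta = theta,
       shift = stats::runif(2, 200, 800))
}

.apply_transform <- function(xy_mm, tr) {
  # flip to image convention (y down), then rotate/scale/translate
  x <- xy_mm[1]; y <- -xy_mm[2]
  c(tr$scale * (cos(tr$theta) * x - sin(tr$theta) * y) + tr$shift[1],
    tr$scale * (sin(tr$theta) * x + cos(tr$theta) * y) + tr$shift[2])
}

#' Generate one synthetic annotated face
#'
#' Deforms the symmetric template by severity-scaled paralysis (postoperative
#' faces attenuate the deformation by `recovery_fraction`), adds Gaussian
#' digitization jitter in mm, and emits pixel coordinates under a random
#' similarity transform shared by all task conditions of the session (photos
#' of one session share scale and pose). Fully closed eyelids are emitted as
#' one coincident point for both lids (a single visible lid margin), sharing
#' one jitter draw.
#'
#' @param config A [face_generator_config()].
#' @param severity Paralysis severity in `[0, 1]`; 0 is a healthy face.
#' @param stage `"pre"` or `"post"` (post applies `recovery_fraction`).
#' @param paralyzed_side Anatomical side of the paralysis.
#' @param conditions Task conditions to emit (`REST` always included).
#' @param patient_id Identifier stored on the face.
#' @param transform Optional fixed similarity transform (list with `scale`,
#'   `theta`, `shift`); default random.
#' @return An [annotated_face].
#' @export
generate_face <- function(config, severity = 1, stage = c("pre", "post"),
                          paralyzed_side = c("left", "right"),
                          conditions = c("REST", "EYE_CLOSURE", "SMILE"),
                          patient_id = "SYN", transform = NULL) {
  stage <- match.arg(stage)
  paralyzed_side <- match.arg(paralyzed_side)
  stopifnot(severity >= 0, severity <= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  conditions <- union("REST", conditions)
  s <- severity * if (stage == "post") 1 - config$recovery_fraction else 1
  tmpl <- .oriented_template(config$template, paralyzed_side)
  if (is.null(transform)) transform <- .random_session_transform()
  sd_mm <- config$landmark_noise_sd
  sets <- lapply(conditions, function(cond) {
    geo <- .deform_condition(tmpl, config, s, cond, paralyzed_side)
    pts <- geo$points
    # jitter in mm; coincident lid pairs share one draw (one visible margin)
    jit <- lapply(pts, function(p) p + stats::rnorm(2, 0, sd_mm))
    for (side in c("left", "right")) {
      up <- paste0("eyelid_upper_", side); lo <- paste0("eyelid_lower_", side)
      if (isTRUE(all.equal(pts[[up]], pts[[lo]], tolerance = 1e-12)))
        jit[[lo]] <- jit[[up]]
    }
    verm <- geo$vermilion + matrix(stats::rnorm(length(geo$vermilion), 0, sd_mm),
                                   ncol = 2)
    px <- lapply(jit, .apply_transform, tr = transform)
    verm_px <- t(apply(verm, 1, .apply_transform, tr = transform))
    landmark_set(cond, px, vermilion = verm_px)
  })
  annotated_face(sets, patient_id = patient_id, timepoint = stage,
                 paralyzed_side = paralyzed_side)
}

# noise-free FAI implied by a droop/pull of the paralytic commissure
.fai_for_droop <- function(template, droop, pull) {
  canthus <- template$points$medial_canthus_right
  comm <- template$points$oral_commissure_right
  d_h <- .dist2d(canthus, comm)
  d_p <- .dist2d(canthus, comm + c(-pull, -droop))
  abs(d_p - d_h)
}

# droop achieving a target noise-free FAI (monotone; commissure pull follows
# droop at a fixed ratio)
.droop_for_fai <- function(template, fai, pull_ratio = 0.35) {
  if (fai <= 0) return(0)
  f <- function(d) .fai_for_droop(template, d, pull_ratio * d) - fai
  stats::uniroot(f, c(0, 80), tol = 1e-10)$root
}

# moment-matched gamma draws via a common severity quantile (comonotone)
.qgamma_ms <- function(u, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(u, shape = shape, rate = shape / mean)
}

#' Generator presets matched to the printed study summaries
#'
#' Per-patient geometry targets are drawn comonotonically from a shared latent
#' severity quantile `u` (a worse patient is worse on every index) using
#' moment-matched gamma distributions for the preoperative static FAI
#' (4.87 +/- 2.39 mm), philtrum deviation at rest (3.61 +/- 2.17 mm) and when
#' smiling (7.74 +/- 2.72 mm), and the forced-closure residual fissure. Eye
#' closure is a mixture: preoperatively the best 15% of patients close fully
#' (3/20 in the study) and the rest share the gap that restores the printed
#' 3.88 mm mean; postoperatively 85% close fully (17/20) and the residual gaps
#' follow a gamma matched so the cohort mean and SD are the printed
#' 0.14 +/- 0.41 mm. Postoperative FAI (1.46 +/- 1.30 mm) and philtrum
#' deviations (1.46 / 2.32 mm, spread scaled by the preoperative coefficient
#' of variation) are matched the same way; the paralytic smile excursion
#' targets 0.19 mm pre and 5.05 mm post.
#'
#' @param stage `"pre"` or `"post"`.
#' @return A list of target-distribution parameters.
#' @export
study_preset <- function(stage = c("pre", "post")) {
  stage <- match.arg(stage)
  if (stage == "pre") {
    list(stage = "pre",
         fai = c(mean = 4.87, sd = 2.39),
         philtrum_rest = c(mean = 3.61, sd = 2.17),
         philtrum_smile = c(mean = 7.74, sd = 2.72),
         full_closure_prob = 0.15,
         closure_gap = c(mean = 3.88 / 0.85, sd = 0),
         smile_paralytic = c(mean = 0.19, sd = 0.10),
         smile_healthy = c(mean = 5.8, sd = 1.2))
  } else {
    # post closure: mean 0.15*E[gap]=0.14 and total SD 0.41 give
    # E[gap]=0.9333, sd(gap)=0.616 in closed form
    list(stage = "post",
         fai = c(mean = 1.46, sd = 1.30),
         philtrum_rest = c(mean = 1.46, sd = 2.17 * 1.46 / 3.61),
         philtrum_smile = c(mean = 2.32, sd = 2.72 * 2.32 / 7.74),
         full_closure_prob = 0.85,
         closure_gap = c(mean = 0.14 / 0.15, sd = 0.616),
         smile_paralytic = c(mean = 5.05, sd = 1.50),
         smile_healthy = c(mean = 5.8, sd = 1.2))
  }
}

# per-patient face config realizing the preset targets for latent quantile u
.preset_face_config <- function(preset, u, base = face_generator_config()) {
  tmpl <- base$template
  draw <- function(par, q) {
    if (par[["sd"]] <= 0) return(unname(par[["mean"]]))
    .qgamma_ms(q, par[["mean"]], par[["sd"]])
  }
  fai <- draw(preset$fai, u)
  philtrum <- draw(preset$philtrum_rest, u)
  philtrum_smile <- draw(preset$philtrum_smile, u)
  # comonotone closure: the best patients (lowest u) close fully
  closes <- u < preset$full_closure_prob
  gap <- if (closes) 0 else draw(preset$closure_gap,
                                 stats::runif(1))  # residual spread independent
  droop <- .droop_for_fai(tmpl, fai)
  face_generator_config(
    droop = droop, commissure_pull = 0.35 * droop,
    lateral_pull = philtrum,
    philtrum_smile_extra = max(0, philtrum_smile - philtrum),
    fissure_widening = if (preset$stage == "pre") 9.07 - 8.23 else 0,
    closure_gap = gap,
    smile_gain_healthy = draw(preset$smile_healthy, stats::runif(1)),
    smile_gain_paralytic = draw(preset$smile_paralytic, 1 - u),
    recovery_fraction = 0, landmark_noise_sd = base$landmark_noise_sd,
    wtw_mm = base$wtw_mm, template = tmpl)
}

#' Cohort generator configuration
#'
#' @param n Number of patients.
#' @param age_mean,age_sd Age distribution (years), truncated to 18-62.
#' @param p_female Probability of female gender.
#' @param cause_probs Named probabilities over the cause categories.
#' @param duration_meanlog,duration_sdlog Log-normal paralysis duration
#'   (months), truncated to 2-192.
#' @param effect_coefficients True coefficients of the binary-outcome logistic
#'   model on the five standardized predictors.
#' @param effect_intercept True logistic intercept.
#' @param cox_coefficients True log-hazard coefficients on the standardized
#'   predictors.
#' @param baseline_contraction_mean Mean months to first facial contraction at
#'   the baseline covariate profile (exponential baseline).
#' @param followup_meanlog,followup_sdlog Log-normal follow-up (months);
#'   contraction times beyond follow-up are censored.
#' @param seed Integer seed.
#' @return A `cohort_generator_config` list.
#' @export
cohort_generator_config <- function(
    n = 100, age_mean = 40.5, age_sd = 12, p_female = 0.5,
    cause_probs = c(tumor = 0.5, bell_palsy = 0.25, trauma = 0.2,
                    infection = 0.05, other = 0),
    duration_meanlog = log(16.5), duration_sdlog = 0.9,
    effect_coefficients = c(age = -0.5, female = 0, duration = -0.3,
                            cause_trauma = 0.3, preop_fngs_grade = 0.4),
    effect_intercept = 0.5,
    cox_coefficients = c(age = -0.2, female = 0, duration = -0.4,
                         cause_trauma = 0.3, preop_fngs_grade = 0),
    baseline_contraction_mean = 2.32,
    followup_meanlog = log(11.8), followup_sdlog = 0.35,
    seed = 1) {
  stopifnot(n >= 1, abs(sum(cause_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_generator_config")
}

# documented monotone staircases: latent severity quantile u -> item scores
# (worse u -> worse function); thresholds roughly echo the study's medians
.instrument_items <- function(u, stage) {
  if (stage == "pre") {
    fngs <- c(brow = 5 + (u > 0.25), eye = 3 + (u > 0.1),
              nasolabial_fold = 4 + (u > 0.3) + (u > 0.85),
              oral_commissure = 4 + (u > 0.3) + (u > 0.85),
              synkinesis = 0 + (u > 0.92))
    sb_rest <- c(rest_eye = 0 + (u > 0.05), rest_cheek_nlf = 1 + (u > 0.15),
                 rest_mouth = 0 + (u > 0.2))
    sb_vol <- c(1, 3 - (u > 0.8), 2 - (u > 0.85) + (u < 0.2),
                2 - (u > 0.85) + (u < 0.2), 2 - (u > 0.85) + (u < 0.2))
    sb_syn <- c(0, 0, 0 + (u > 0.6), 0 + (u > 0.6), 0 + (u > 0.9))
    face_base <- 2 + 2 * (1 - u)
  } else {
    fngs <- c(brow = 5 + (u > 0.25), eye = 3, nasolabial_fold = 2 + (u > 0.3),
              oral_commissure = 2 + (u > 0.3), synkinesis = 0 + (u > 0.45))
    sb_rest <- c(rest_eye = 0 + (u > 0.4), rest_cheek_nlf = 0 + (u > 0.2),
                 rest_mouth = 0 + (u > 0.55))
    sb_vol <- c(1, 4 - (u > 0.7), 3 - (u > 0.75) + (u < 0.15),
                3 - (u > 0.75), 4 - (u > 0.7) - (u > 0.9))
    sb_syn <- c(0, 0, 1 - (u < 0.2), 1 - (u < 0.25), 0 + (u > 0.8))
    face_base <- 3.2 + 1.5 * (1 - u)
  }
  item_shift <- c(-1, 0, 0, 1, 0, 1, 1, 0, 0, 1, -1, 0, 1, -1, 0) * 0.5
  face_items <- pmin(5, pmax(1, round(face_base + item_shift)))
  list(fngs = as.list(fngs), sb_rest = unname(sb_rest), sb_vol = sb_vol,
       sb_syn = sb_syn, face = face_items)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a synthetic patient cohort
#'
#' Draws patient covariates, per-patient latent severity, pre- and
#' postoperative annotated faces realizing the [study_preset()] geometry
#' targets, instrument item scores via documented monotone severity
#' staircases, binary surgical-effect outcomes from the true logistic model,
#' and first-contraction times from the true proportional-hazards model.
#'
#' @param config A [cohort_generator_config()].
#' @param face_config Base [face_generator_config()] (noise level, template).
#' @param out_dir Optional directory; when given, landmark JSON files, a
#'   metadata CSV and instrument item CSVs are written there.
#' @return A `synthetic_cohort` list: `meta` (list of [patient_meta]),
#'   `faces` (per patient: `pre`, `post` [annotated_face]s), `items`
#'   (instrument tables), `outcome` (binary effect outcome), `truth`
#'   (a `cohort_truth` with every generator parameter and per-patient latent).
#' @export
generate_cohort <- function(config, face_config = face_generator_config(),
                            out_dir = NULL) {
  set.seed(config$seed)
  n <- config$n
  age <- round(.rtrunc_norm(n, config$age_mean, config$age_sd, 18, 62))
  female <- stats::rbinom(n, 1, config$p_female)
  cause <- sample(names(config$cause_probs), n, replace = TRUE,
                  prob = config$cause_probs)
  duration <- pmin(192, pmax(2, stats::rlnorm(n, config$duration_meanlog,
                                              config$duration_sdlog)))
  side <- sample(c("left", "right"), n, replace = TRUE)
  u <- stats::runif(n)

  pre_preset <- study_preset("pre")
  post_preset <- study_preset("post")
  faces <- vector("list", n)
  items_fngs <- items_sb <- items_face <- list()
  meta_list <- vector("list", n)
  grades <- integer(n)
  ids <- sprintf("SYN%04d", seq_len(n))

  for (i in seq_len(n)) {
    it_pre <- .instrument_items(u[i], "pre")
    it_post <- .instrument_items(u[i], "post")
    grades[i] <- score_fngs(it_pre$fngs$brow, it_pre$fngs$eye,
                            it_pre$fngs$nasolabial_fold,
                            it_pre$fngs$oral_commissure,
                            it_pre$fngs$synkinesis)$final_grade
    cfg_pre <- .preset_face_config(pre_preset, u[i], face_config)
    cfg_post <- .preset_face_config(post_preset, u[i], face_config)
    faces[[i]] <- list(
      pre = generate_face(cfg_pre, severity = 1, stage = "pre",
                          paralyzed_side = side[i], patient_id = ids[i]),
      post = generate_face(cfg_post, severity = 1, stage = "post",
                           paralyzed_side = side[i], patient_id = ids[i]))
    for (tp in c("pre", "post")) {
      it <- if (tp == "pre") it_pre else it_post
      items_fngs[[length(items_fngs) + 1L]] <- data.frame(
        patient_id = ids[i], timepoint = tp, brow = it$fngs$brow,
        eye = it$fngs$eye, nasolabial_fold = it$fngs$nasolabial_fold,
        oral_commissure = it$fngs$oral_commissure,
        synkinesis = it$fngs$synkinesis, stringsAsFactors = FALSE)
      sb <- c(it$sb_rest, it$sb_vol, it$sb_syn)
      items_sb[[length(items_sb) + 1L]] <- data.frame(
        patient_id = ids[i], timepoint = tp,
        rest_eye = sb[1], rest_cheek_nlf = sb[2], rest_mouth = sb[3],
        t(stats::setNames(sb[4:8], paste0("vol_", 1:5))),
        t(stats::setNames(sb[9:13], paste0("syn_", 1:5))),
        stringsAsFactors = FALSE)
      items_face[[length(items_face) + 1L]] <- data.frame(
        patient_id = ids[i], timepoint = tp,
        t(stats::setNames(it$face, paste0("item_", 1:15))),
        stringsAsFactors = FALSE)
    }
  }

  # outcomes at the true model coefficients on standardized predictors
  pred <- data.frame(age = age, female = female, duration = duration,
                     cause_trauma = as.integer(cause == "trauma"),
                     preop_fngs_grade = grades)
  Z <- scale(as.matrix(pred))
  Z[, apply(as.matrix(pred), 2, stats::sd) == 0] <- 0
  lp_eff <- config$effect_intercept +
    as.numeric(Z %*% config$effect_coefficients[colnames(Z)])
  outcome <- stats::rbinom(n, 1, stats::plogis(lp_eff))
  lp_cox <- as.numeric(Z %*% config$cox_coefficients[colnames(Z)])
  t_contr <- stats::rexp(n, rate = exp(lp_cox) / config$baseline_contraction_mean)
  followup <- stats::rlnorm(n, config$followup_meanlog, config$followup_sdlog)
  event <- as.integer(t_contr <= followup)
  time_obs <- pmin(t_contr, followup)

  for (i in seq_len(n)) {
    meta_list[[i]] <- patient_meta(
      id = ids[i], age = age[i], gender = if (female[i]) "female" else "male",
      cause = cause[i], paralysis_duration = duration[i],
      paralyzed_side = side[i], preop_fngs_grade = grades[i],
      time_to_first_contraction = if (event[i]) time_obs[i] else NA_real_,
      followup = followup[i])
    faces[[i]]$pre$meta <- meta_list[[i]]
    faces[[i]]$post$meta <- meta_list[[i]]
  }
  names(meta_list) <- ids; names(faces) <- ids

  items <- list(fngs = do.call(rbind, items_fngs),
                sunnybrook = do.call(rbind, items_sb),
                face = do.call(rbind, items_face))
  truth <- structure(list(
    config = config, face_config = face_config,
    presets = list(pre = pre_preset, post = post_preset),
    u = u, predictors = pred, predictors_std = Z,
    lp_effect = lp_eff, p_outcome = stats::plogis(lp_eff),
    lp_cox = lp_cox, contraction_time = t_contr, followup = followup,
    event = event), class = "cohort_truth")
  cohort <- structure(list(meta = meta_list, faces = faces, items = items,
                           outcome = outcome, time = time_obs, event = event,
                           truth = truth), class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lm_dir <- file.path(out_dir, "landmarks")
  dir.create(lm_dir, showWarnings = FALSE)
  for (id in names(cohort$faces)) {
    for (tp in c("pre", "post")) {
      write_landmarks_json(cohort$faces[[id]][[tp]],
                           file.path(lm_dir, sprintf("%s_%s.json", id, tp)))
    }
  }
  write_patient_meta(cohort$meta, file.path(out_dir, "meta.csv"))
  for (nm in names(cohort$items)) {
    utils::write.csv(cohort$items[[nm]],
                     file.path(out_dir, sprintf("items_%s.csv", nm)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(patient_id = names(cohort$meta),
                              outcome = cohort$outcome, time = cohort$time,
                              event = cohort$event),
                   file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort` (or its `truth` field).
#' @return The `cohort_truth`: every generator parameter and per-patient
#'   latent needed to recompute expected metrics.
#' @export
ground_truth <- function(cohort) {
  if (inherits(cohort, "cohort_truth")) cohort else cohort$truth
}
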
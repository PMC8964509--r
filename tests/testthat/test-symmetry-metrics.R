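test_that("a perfectly symmetric face scores zero on every asymmetry index", {
  face <- generate_face(quiet_config(), severity = 0, paralyzed_side = "left",
                        transform = identity_transform())
  expect_equal(facial_asymmetry_index(face, "REST"), 0, tolerance = 1e-9)
  expect_equal(facial_asymmetry_index(face, "SMILE"), 0, tolerance = 1e-9)
  expect_equal(philtrum_deviation(face, "REST"), 0, tolerance = 1e-9)
  expect_equal(bilateral_slope_angle(face, "REST"), 0, tolerance = 1e-9)
  expect_equal(adjusted_horizontal(face, "healthy") -
                 adjusted_horizontal(face, "paralytic"), 0, tolerance = 1e-9)
  cc_h <- commissure_components(face, "healthy")
  cc_p <- commissure_components(face, "paralytic")
  expect_equal(cc_h$f, cc_p$f, tolerance = 1e-9)
  expect_equal(cc_h$g, cc_p$g, tolerance = 1e-9)
})

test_that("FAI equals the planar distance difference on a hand-built fixture", {
  # distances chosen in mm at 0.2 mm/px: healthy 60.2080, paralytic 55.0363
  pts <- scaffold_points()
  pts$medial_canthus_right <- c(80, 50)
  pts$medial_canthus_left <- c(-80, 50)
  pts$oral_commissure_right <- c(80, 50 + 60.2080 / 0.2)  # healthy (right)
  pts$oral_commissure_left <- c(-80, 50 + 55.0363 / 0.2)  # paralytic (left)
  face <- scaffold_face(points = pts)
  d_h <- 0.2 * sqrt(sum((pts$medial_canthus_right - pts$oral_commissure_right)^2))
  d_p <- 0.2 * sqrt(sum((pts$medial_canthus_left - pts$oral_commissure_left)^2))
  expect_equal(d_h, 60.2080)
  expect_equal(abs(d_p - d_h), 5.1717, tolerance = 1e-9)
  expect_equal(facial_asymmetry_index(face, "REST"), 5.1717, tolerance = 1e-9)
})

test_that("palpebral fissure width is the calibrated lid distance", {
  pts <- scaffold_points()
  pts$eyelid_upper_right <- c(50, -20)
  pts$eyelid_lower_right <- c(50, 20)   # 40 px apart at 0.2 mm/px
  face <- scaffold_face(points = pts)
  expect_equal(palpebral_fissure_width(face, "healthy", "REST"), 8.0)
  # coincident lids = full closure
  pts$eyelid_lower_right <- pts$eyelid_upper_right
  face0 <- scaffold_face(points = pts)
  expect_equal(palpebral_fissure_width(face0, "healthy", "REST"), 0)
})

test_that("philtrum deviation is signed toward the healthy side", {
  pts <- scaffold_points()
  # paralyzed left -> healthy is the right-labelled side at +x; 18.05 px
  pts$philtrum <- c(18.05, 330)
  face <- scaffold_face(points = pts)
  expect_equal(philtrum_deviation(face, "REST"), 3.61, tolerance = 1e-9)
  # mirrored labels: magnitude preserved, sign flipped
  expect_equal(philtrum_deviation(mirror_face(face), "REST"), -3.61,
               tolerance = 1e-9)
})

test_that("commissure components decompose position in the face frame", {
  pts <- scaffold_points()
  # healthy (right) commissure: 125 px lateral, 25 px above origin (0,400)
  pts$oral_commissure_right <- c(125, 375)
  face <- scaffold_face(points = pts)
  cc <- commissure_components(face, "healthy", "REST")
  expect_equal(cc$f, 25)
  expect_equal(cc$g, 5)
  # invariance under 15 degree rotation
  rot <- transform_face(face, theta_deg = 15, shift = c(11, -7))
  cc_r <- commissure_components(rot, "healthy", "REST")
  expect_equal(cc_r$f, cc$f, tolerance = 1e-6)
  expect_equal(cc_r$g, cc$g, tolerance = 1e-6)
})

test_that("smile excursion equals the brute-force distance change", {
  cfg <- quiet_config(smile_gain_healthy = 5.8, smile_gain_paralytic = 0.2)
  face <- generate_face(cfg, severity = 1, paralyzed_side = "right",
                        transform = identity_transform())
  for (side in c("healthy", "paralytic")) {
    sm <- smile_excursion(face, side)
    # brute force from raw landmark pixels via the frame
    lab <- if (side == "paralytic") face$paralyzed_side else
      setdiff(c("left", "right"), face$paralyzed_side)
    nm <- paste0("oral_commissure_", lab)
    mmpx <- face$calibration$mm_per_pixel
    d <- function(cond) {
      p <- face$sets[[cond]]$points[[nm]]
      mmpx * sqrt(sum((p - face$frame$origin)^2))
    }
    expect_equal(unname(sm["overall"]), d("SMILE") - d("REST"),
                 tolerance = 1e-9)
  }
  # no movement at all
  sets <- face$sets
  sets$SMILE <- landmark_set("SMILE", sets$REST$points,
                             vermilion = sets$REST$vermilion)
  still <- annotated_face(sets, "S", "pre", face$paralyzed_side)
  expect_equal(unname(smile_excursion(still, "healthy")), c(0, 0, 0))
})

test_that("philtrum-adjusted horizontal distances follow the sign convention", {
  pts <- scaffold_points()
  pts$oral_commissure_right <- c(125, 400)   # healthy f = 25 mm
  pts$oral_commissure_left <- c(-125, 400)   # paralytic f = 25 mm
  pts$philtrum <- c(15, 330)                 # +3 mm toward healthy
  face <- scaffold_face(points = pts)
  expect_equal(adjusted_horizontal(face, "healthy", "REST"), 22)
  expect_equal(adjusted_horizontal(face, "paralytic", "REST"), 28)
  # philtrum on the central line reduces to the unadjusted distance
  pts$philtrum <- c(0, 330)
  face0 <- scaffold_face(points = pts)
  expect_equal(adjusted_horizontal(face0, "healthy", "REST"),
               commissure_components(face0, "healthy", "REST")$f)
})

test_that("commissure and slope angles match the arctangent closed form", {
  pts <- scaffold_points()
  pts$oral_commissure_right <- c(125, 375)   # f 25, g 5
  pts$oral_commissure_left <- c(-125, 425)   # f 25, g -5
  face <- scaffold_face(points = pts)
  expect_equal(commissure_angle(face, "healthy", "REST"),
               atan(5 / 25) * 180 / pi, tolerance = 1e-9)
  expect_equal(commissure_angle(face, "healthy", "REST"), 11.3099,
               tolerance = 1e-4)
  expect_lt(commissure_angle(face, "paralytic", "REST"), 0)
  # slope angle: (g - g') / (f + f') = 10/50
  expect_equal(bilateral_slope_angle(face, "REST"), atan(10 / 50) * 180 / pi,
               tolerance = 1e-9)
  # level commissures
  pts$oral_commissure_left <- c(-125, 375)
  expect_equal(bilateral_slope_angle(scaffold_face(points = pts), "REST"), 0,
               tolerance = 1e-9)
  # mirrored labels leave the magnitude unchanged
  pts$oral_commissure_left <- c(-125, 425)
  f2 <- scaffold_face(points = pts)
  expect_equal(abs(bilateral_slope_angle(mirror_face(f2), "REST")),
               abs(bilateral_slope_angle(f2, "REST")), tolerance = 1e-9)
})

test_that("commissure on the central line returns the 90 degree limit", {
  pts <- scaffold_points()
  pts$oral_commissure_right <- c(0, 375)
  face <- scaffold_face(points = pts)
  expect_warning(a <- commissure_angle(face, "healthy", "REST"), "central line")
  expect_equal(a, 90)
})

test_that("reanimation classification implements the 3.0 mm rule", {
  expect_identical(classify_reanimation(2.9), "poor")
  expect_identical(classify_reanimation(3.0), "good")
  expect_identical(classify_reanimation(5.05), "good")
  # exhaustive agreement with a direct threshold comparison
  set.seed(1)
  x <- runif(1e4, 0, 8)
  expect_identical(classify_reanimation(x),
                   ifelse(x >= 3.0, "good", "poor"))
})

test_that("metric differences are signed so improvement is positive", {
  face_pre <- generate_face(quiet_config(), severity = 0.9, stage = "pre",
                            paralyzed_side = "left",
                            transform = identity_transform())
  cfg_post <- quiet_config(recovery_fraction = 0.8)
  face_post <- generate_face(cfg_post, severity = 0.9, stage = "post",
                             paralyzed_side = "left",
                             transform = identity_transform())
  m_pre <- symmetry_metrics(face_pre)
  m_post <- symmetry_metrics(face_post)
  d <- metric_differences(m_pre, m_post)
  expect_equal(d$diff_static_fai, m_pre$fai_rest - m_post$fai_rest)
  expect_gt(d$diff_static_fai, 0)          # recovery improved symmetry
  expect_gt(d$diff_dynamic_overall_excursion_paralytic, 0)
  # identical timepoints give all-zero differences
  d0 <- metric_differences(m_pre, m_pre)
  expect_true(all(abs(unlist(d0[-1])) < 1e-12))
  # a missing SMILE condition flags the dynamic indices as missing
  sets <- face_post$sets[c("REST", "EYE_CLOSURE")]
  m_nosmile <- symmetry_metrics(annotated_face(sets, face_post$patient_id,
                                               "post", "left"))
  dn <- metric_differences(m_pre, m_nosmile)
  expect_true(is.na(dn$diff_dynamic_fai))
  expect_true(is.na(dn$restoration_dynamic_slope_angle))
  expect_false(is.na(dn$diff_static_fai))
})

test_that("all metrics are invariant to similarity transforms of the pixels", {
  set.seed(5)
  face <- generate_face(face_generator_config(landmark_noise_sd = 0.2),
                        severity = 0.8, paralyzed_side = "left",
                        transform = identity_transform())
  v0 <- metric_vector(face)
  for (i in 1:3) {
    tr <- transform_face(face, theta_deg = runif(1, -30, 30),
                         scale = runif(1, 0.5, 4), shift = runif(2, -300, 300))
    expect_equal(metric_vector(tr), v0, tolerance = 1e-6)
  }
})

test_that("mirror relabelling preserves unsigned metrics and negates signed ones", {
  set.seed(6)
  face <- generate_face(quiet_config(), severity = 0.7, paralyzed_side = "left",
                        transform = identity_transform())
  mir <- mirror_face(face)
  expect_equal(facial_asymmetry_index(mir), facial_asymmetry_index(face),
               tolerance = 1e-9)
  expect_equal(palpebral_fissure_width(mir, "paralytic"),
               palpebral_fissure_width(face, "healthy"), tolerance = 1e-9)
  expect_equal(philtrum_deviation(mir), -philtrum_deviation(face),
               tolerance = 1e-9)
})

test_that("mean FAI and slope angle increase strictly with the droop level", {
  droops <- c(1, 3, 5, 7, 9)
  n_per <- 500
  mean_fai <- mean_slope <- numeric(length(droops))
  set.seed(77)
  for (k in seq_along(droops)) {
    cfg <- face_generator_config(droop = droops[k],
                                 commissure_pull = 0.35 * droops[k],
                                 landmark_noise_sd = 0.2)
    fai <- slope <- numeric(n_per)
    for (i in seq_len(n_per)) {
      f <- generate_face(cfg, severity = 1, paralyzed_side = "left",
                         conditions = "REST")
      fai[i] <- facial_asymmetry_index(f, "REST")
      slope[i] <- bilateral_slope_angle(f, "REST")
    }
    mean_fai[k] <- mean(fai); mean_slope[k] <- mean(slope)
  }
  expect_true(all(diff(mean_fai) > 0))
  expect_true(all(diff(mean_slope) > 0))
})
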
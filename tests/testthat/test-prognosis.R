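make_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 40, 12), female = rbinom(n, 1, 0.5),
             duration = rlnorm(n, log(16), 0.8),
             cause_trauma = rbinom(n, 1, 0.2),
             preop_fngs_grade = sample(3:6, n, replace = TRUE))
}

test_that("preprocessing standardizes, anchors, and round-trips", {
  d <- make_design(200)
  pp <- preprocess_predictors(d)
  # binary indicators pass through untouched
  expect_identical(pp$transformed$female, d$female)
  expect_identical(pp$transformed$cause_trauma, d$cause_trauma)
  # lambda = 1 reduces to plain z-scores
  pp1 <- preprocess_predictors(d["age"], lambda = 1)
  expect_equal(pp1$transformed$age, as.numeric(scale(d$age)), tolerance = 1e-12)
  # transform then inverse recovers the original to 1e-9
  back <- invert_preprocess(pp$spec, pp$transformed)
  for (nm in names(d)) expect_equal(back[[nm]], d[[nm]], tolerance = 1e-9)
  # new data uses the stored spec, identically on the training rows
  expect_equal(apply_preprocess(pp$spec, d), pp$transformed, tolerance = 1e-12)
  # constant columns are rejected by name
  d$flat <- 5
  expect_error(preprocess_predictors(d), "'flat'")
})

test_that("out-of-domain transform inputs are clipped with a warning", {
  d <- data.frame(x = c(1, 2, 3, 4, 5))
  pp <- preprocess_predictors(d, lambda = 0.5)
  expect_warning(apply_preprocess(pp$spec, data.frame(x = -100)), "clipping")
})

test_that("near-zero penalty recovers the closed-form log odds ratio ln(6)", {
  # 2x2 table: x=1 -> (8 events, 2 non), x=0 -> (4 events, 6 non)
  x <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  fit <- suppressWarnings(fit_effect_model(x, y, lambda = 1e-7))
  expect_equal(unname(fit$coefficients["x"]), log(6), tolerance = 1e-3)
  # and matches an unpenalized glm oracle
  oracle <- glm(y ~ x, family = binomial)
  expect_equal(unname(fit$coefficients["x"]), unname(coef(oracle)["x"]),
               tolerance = 1e-3)
})

test_that("a huge penalty shrinks every coefficient to zero", {
  d <- make_design(100)
  y <- rbinom(100, 1, 0.5)
  fit <- suppressWarnings(fit_effect_model(as.matrix(d), y, lambda = 100))
  expect_true(all(fit$coefficients[-1] == 0))
})

test_that("elastic net recovers signs and sparsity structure at n = 500", {
  set.seed(21)
  n <- 500
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  beta <- c(1, 0, -0.5, 0, 0.8)
  y <- rbinom(n, 1, plogis(X %*% beta))
  fit <- fit_effect_model(X, y, seed = 3)
  est <- fit$coefficients[paste0("x", 1:5)]
  expect_gt(est["x1"], 0); expect_lt(est["x3"], 0); expect_gt(est["x5"], 0)
  expect_true(max(abs(est[c("x2", "x4")])) < min(abs(est[c("x1", "x3", "x5")])))
})

test_that("importance scaling is linear, permutation-equivariant and scale-free", {
  co <- c(a = 0.2, b = -0.4, c = 0.1)
  expect_equal(importance_scale(co), c(a = 50, b = 100, c = 25))
  expect_equal(importance_scale(c(a = 0, b = 0)), c(a = 0, b = 0))
  expect_equal(importance_scale(co * 17), importance_scale(co))
  perm <- c("c", "a", "b")
  expect_equal(importance_scale(co[perm]), importance_scale(co)[perm])
  # max importance is 100 whenever any coefficient is nonzero
  set.seed(30)
  for (i in 1:20) {
    v <- rnorm(5) * rbinom(5, 1, 0.7)
    names(v) <- paste0("v", 1:5)
    imp <- importance_scale(v)
    expect_true(all(imp >= 0 & imp <= 100))
    if (any(v != 0)) expect_equal(max(imp), 100)
  }
})

test_that("fixed seed gives bit-identical cross-validated coefficients", {
  set.seed(40)
  X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rbinom(100, 1, plogis(X[, 1]))
  f1 <- fit_effect_model(X, y, seed = 7)
  f2 <- fit_effect_model(X, y, seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("effect model rejects degenerate inputs", {
  set.seed(41)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_effect_model(X, rep(1, 40)), "constant")
  expect_warning(fit_effect_model(X, rbinom(40, 1, 0.5), lambda = 0),
                 "floored")
  suppressWarnings(
    expect_warning(fit_effect_model(X[1:20, ], rbinom(20, 1, 0.5), seed = 1),
                   "fewer than 30"))
})

test_that("Cox regression recovers a true hazard ratio of 2 at n = 800", {
  set.seed(50)
  n <- 800
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.3 * exp(log(2) * x))
  cens <- runif(n, 0, 15)
  res <- fit_time_to_contraction(data.frame(group = x),
                                 times = pmin(t, cens),
                                 events = as.integer(t <= cens))
  hr <- res$table$hr[res$table$predictor == "group"]
  expect_gt(hr, 1.7); expect_lt(hr, 2.3)
  expect_equal(res$table$hr, exp(res$table$log_hr))
  expect_true(all(res$table$ci_lower <= res$table$ci_upper))
})

test_that("Cox confidence intervals cover a null covariate at nominal rate", {
  set.seed(51)
  covered <- logical(200)
  for (r in 1:200) {
    n <- 120
    x <- rnorm(n)
    t <- rexp(n, 0.4)
    cens <- runif(n, 0, 8)
    res <- fit_time_to_contraction(data.frame(x = x), pmin(t, cens),
                                   as.integer(t <= cens))
    covered[r] <- res$table$ci_lower[1] <= 1 && res$table$ci_upper[1] >= 1
  }
  expect_gte(mean(covered), 0.93)
})

test_that("log hazard ratio bias shrinks with sample size", {
  true_lhr <- log(2)
  bias_at <- function(n, reps = 40) {
    est <- numeric(reps)
    for (r in 1:reps) {
      x <- rbinom(n, 1, 0.5)
      t <- rexp(n, 0.5 * exp(true_lhr * x))
      res <- fit_time_to_contraction(data.frame(x = x), t, rep(1L, n))
      est[r] <- res$table$log_hr[1]
    }
    abs(mean(est) - true_lhr)
  }
  set.seed(52)
  b <- c(bias_at(100), bias_at(400), bias_at(1600))
  expect_true(all(diff(b) < 0))
})

test_that("Cox fit rejects degenerate designs", {
  x <- rnorm(50); t <- rexp(50, 1)
  expect_error(fit_time_to_contraction(data.frame(a = x, b = x), t,
                                       rep(1L, 50)), "rank-deficient")
  expect_error(fit_time_to_contraction(data.frame(a = x), t, rep(0L, 50)),
               "censored")
  expect_error(fit_time_to_contraction(data.frame(a = x), -t, rep(1L, 50)),
               "negative")
})

test_that("prognosis prediction applies the stored spec and fitted models", {
  set.seed(60)
  d <- make_design(300)
  pp <- preprocess_predictors(d[, PREDICTOR_NAMES])
  X <- as.matrix(pp$transformed)
  y <- rbinom(300, 1, plogis(0.3 + X[, "age"]))
  fit <- fit_effect_model(X, y, seed = 2)
  # a patient at the training mean of the continuous predictors with zero
  # indicators has linear predictor = intercept
  mean_patient <- data.frame(age = mean(d$age), female = 0,
                             duration = mean(d$duration), cause_trauma = 0,
                             preop_fngs_grade = mean(d$preop_fngs_grade))
  pr <- predict_prognosis(mean_patient, list(out = fit), pp$spec)
  expect_equal(pr$probabilities$out,
               plogis(unname(fit$coefficients["(Intercept)"])),
               tolerance = 1e-9)
  expect_error(predict_prognosis(mean_patient[, -1], list(out = fit), pp$spec),
               "missing predictor")
})

test_that("importance tables have the per-index structure and 0-100 scale", {
  set.seed(61)
  d <- make_design(150)
  idx <- data.frame(
    effect_a = rnorm(150, sd = 2) + 0.8 * scale(d$age)[, 1],
    effect_b = rnorm(150, sd = 2))
  tab <- fit_importance_table(d, idx, seed = 4)
  expect_identical(rownames(tab$importance), c("effect_a", "effect_b"))
  expect_identical(colnames(tab$importance), PREDICTOR_NAMES)
  imp <- as.matrix(tab$importance)
  expect_true(all(imp >= 0 & imp <= 100))
  for (r in 1:2) {
    if (any(abs(tab$coefficients[r, ]) > 0)) expect_equal(max(imp[r, ]), 100)
  }
})
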
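# Prognostic modelling: predictor preprocessing (z-score + shifted Box-Cox),
# cross-validated elastic-net logistic models per evaluation index with
# 0-100 variable importance, and Cox regression for time to first facial
# contraction.

#' Names of the five preoperative predictors
#' @format Character vector.
#' @export
PREDICTOR_NAMES <- c("age", "female", "duration", "cause_trauma",
                     "preop_fngs_grade")

#' Build a predictor table from patient metadata
#'
#' @param meta_list List of [patient_meta] objects.
#' @return A data.frame with the five predictor columns (and `id`).
#' @export
predictor_table <- function(meta_list) {
  do.call(rbind, lapply(meta_list, function(m) data.frame(
    id = m$id, age = m$age, female = as.integer(m$gender == "female"),
    duration = m$paralysis_duration,
    cause_trauma = as.integer(m$cause == "trauma"),
    preop_fngs_grade = as.numeric(m$preop_fngs_grade),
    stringsAsFactors = FALSE)))
}

.is_binary <- function(x) all(x %in% c(0, 1))

# shifted Box-Cox power transform of a z-scored column; offset makes the
# z-scores strictly positive (Box-Cox needs a positive domain) and the
# transform is re-anchored so the training mean (z = 0) maps to exactly 0
.bc_raw <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

.bc_apply <- function(z, lambda, offset) {
  y <- z + offset
  if (any(y <= 0)) {
    warning("values below the training domain of the power transform; clipping",
            call. = FALSE)
    y <- pmax(y, .Machine$double.eps)
  }
  .bc_raw(y, lambda) - .bc_raw(offset, lambda)
}

.bc_invert <- function(t, lambda, offset) {
  t <- t + .bc_raw(offset, lambda)
  y <- if (abs(lambda) < 1e-8) exp(t) else (lambda * t + 1)^(1 / lambda)
  y - offset
}

#' Preprocess a predictor table for modelling
#'
#' Continuous columns are standardized (subtract mean, divide by SD) and then
#' passed through a shifted Box-Cox power transform: an offset of
#' `1 - min(z)` maps the z-scores onto a strictly positive domain (plain
#' Box-Cox after centring is ill-posed), the power parameter lambda is chosen
#' by maximum likelihood, and the transform is anchored so a value at the
#' training mean maps to exactly 0 (with `lambda = 1` the column therefore
#' comes back as its plain z-scores). Binary indicator columns pass through
#' untouched. The fitted specification can be re-applied to new patients with
#' [apply_preprocess()] and inverted with [invert_preprocess()].
#'
#' @param design A data.frame of predictors (non-numeric columns such as `id`
#'   are carried through untransformed).
#' @param lambda Optional fixed power parameter; default `NULL` estimates it
#'   per column by maximum likelihood (via [car::powerTransform()]).
#' @return A list with `transformed` (data.frame) and `spec` (a
#'   `preprocess_spec`: per-column mean, sd, lambda, offset).
#' @export
preprocess_predictors <- function(design, lambda = NULL) {
  spec <- list()
  out <- design
  for (nm in names(design)) {
    x <- design[[nm]]
    if (!is.numeric(x)) next
    if (.is_binary(x)) {
      spec[[nm]] <- list(type = "binary")
      next
    }
    if (length(unique(x)) < 2)
      stop(sprintf("constant column '%s' cannot be standardized", nm),
           call. = FALSE)
    m <- mean(x); s <- stats::sd(x)
    z <- (x - m) / s
    offset <- 1 - min(z)
    lam <- if (is.null(lambda)) {
      unname(car::powerTransform(z + offset, family = "bcPower")$lambda)
    } else lambda
    out[[nm]] <- .bc_apply(z, lam, offset)
    spec[[nm]] <- list(type = "continuous", mean = m, sd = s,
                       lambda = lam, offset = offset)
  }
  structure(list(transformed = out, spec = structure(spec, class = "preprocess_spec")),
            class = "preprocess_result")
}

#' Apply a stored preprocessing specification to new data
#'
#' @param spec A `preprocess_spec` from [preprocess_predictors()].
#' @param newdata Data.frame containing the columns the spec was fitted on.
#' @return The transformed data.frame. Values outside the training domain of
#'   the power transform are clipped with a warning.
#' @export
apply_preprocess <- function(spec, newdata) {
  miss <- setdiff(names(spec), names(newdata))
  if (length(miss) > 0)
    stop(sprintf("missing predictor column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  out <- newdata
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$type == "binary") next
    z <- (newdata[[nm]] - s$mean) / s$sd
    out[[nm]] <- .bc_apply(z, s$lambda, s$offset)
  }
  out
}

#' Invert a preprocessing specification
#'
#' @inheritParams apply_preprocess
#' @param transformed Data.frame of transformed values.
#' @return Data.frame on the original scale.
#' @export
invert_preprocess <- function(spec, transformed) {
  out <- transformed
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$type == "binary") next
    z <- .bc_invert(transformed[[nm]], s$lambda, s$offset)
    out[[nm]] <- z * s$sd + s$mean
  }
  out
}

#' Dichotomize a continuous evaluation index
#'
#' @param y Numeric vector.
#' @param rule `"median"` (split at the sample median, above = 1) or
#'   `"threshold"` with `threshold` given (>= threshold = 1; e.g. the 3.0 mm
#'   good-reanimation rule for postoperative smile excursion).
#' @param threshold Numeric cut point when `rule = "threshold"`.
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(y, rule = c("median", "threshold"), threshold = NULL) {
  rule <- match.arg(rule)
  cut <- if (rule == "median") stats::median(y) else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  as.integer(if (rule == "median") y > cut else y >= cut)
}

#' Fit an elastic-net-regularized logistic model for one evaluation index
#'
#' Penalized logistic regression (mixing parameter `alpha`, default 0.5)
#' with the penalty chosen by k-fold cross-validated deviance on a
#' deterministic fold assignment, so a fixed seed yields bit-identical
#' coefficients.
#'
#' @param X Numeric matrix or data.frame of (preprocessed) predictors.
#' @param y Binary outcome vector (0/1).
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation. A value of 0
#'   is floored at 1e-8 with a warning (an exactly unpenalized fit can be
#'   separated).
#' @return An `effect_model` list: `coefficients` (named, incl. intercept),
#'   `lambda`, `alpha`.
#' @export
fit_effect_model <- function(X, y, alpha = 0.5, nfolds = 5, seed = 1,
                             lambda = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(unique(y)) < 2) stop("outcome y is constant", call. = FALSE)
  n <- nrow(X)
  if (n < nfolds) stop("need at least as many observations as folds", call. = FALSE)
  if (n < 30)
    warning("fewer than 30 observations: cross-validated penalty selection is unstable",
            call. = FALSE)
  # the solver needs >= 2 columns; pad single-predictor designs with an
  # all-zero dummy whose coefficient is necessarily zero, dropped afterwards
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, .dummy = 0)
  if (!is.null(lambda)) {
    if (lambda <= 0) {
      warning("penalty floored at 1e-8 (zero penalty risks separation)",
              call. = FALSE)
      lambda <- 1e-8
    }
    # descending path ending at the requested penalty stabilizes convergence
    path <- sort(unique(c(lambda * c(1000, 100, 10, 1))), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                          lambda = path, thresh = 1e-12, maxit = 1e6)
    beta <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y))
    sel <- lambda
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            foldid = foldid, type.measure = "deviance")
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
    sel <- cv$lambda.min
  }
  names(beta) <- c("(Intercept)", colnames(X))
  if (padded) beta <- beta[names(beta) != ".dummy"]
  structure(list(coefficients = beta, lambda = sel, alpha = alpha,
                 predictors = setdiff(names(beta), "(Intercept)")),
            class = "effect_model")
}

#' Scale coefficient magnitudes to 0-100 importance
#'
#' `importance_i = 100 * |beta_i| / max_j |beta_j|`; an all-zero coefficient
#' vector yields all-zero importances. The intercept is excluded.
#'
#' @param model An `effect_model`, or a named numeric coefficient vector.
#' @return Named numeric vector of importances in `[0, 100]`.
#' @export
importance_scale <- function(model) {
  coefs <- if (inherits(model, "effect_model")) model$coefficients else model
  coefs <- coefs[setdiff(names(coefs), "(Intercept)")]
  m <- max(abs(coefs))
  if (m == 0) return(stats::setNames(rep(0, length(coefs)), names(coefs)))
  # divide first so the largest coefficient maps to exactly 100
  (abs(coefs) / m) * 100
}

#' Fit effect models for several evaluation indices and tabulate importance
#'
#' For each evaluation-index column, the index is dichotomized (median split
#' by default; pass a named `thresholds` entry to use a fixed cut such as the
#' 3.0 mm reanimation rule) and an elastic-net logistic model on the
#' preprocessed predictors is fitted; coefficient magnitudes are rescaled to
#' 0-100 importance per index.
#'
#' @param predictors Data.frame with the columns of [PREDICTOR_NAMES].
#' @param indices Data.frame of continuous evaluation indices (one column per
#'   index, rows aligned with `predictors`).
#' @param thresholds Optional named numeric vector: fixed dichotomization
#'   thresholds for specific index columns.
#' @inheritParams fit_effect_model
#' @return A list with `importance` (data.frame, indices x predictors),
#'   `coefficients` (signed, same shape), `models`, and `preprocess` spec.
#' @export
fit_importance_table <- function(predictors, indices, thresholds = NULL,
                                 alpha = 0.5, nfolds = 5, seed = 1) {
  pp <- preprocess_predictors(predictors[, PREDICTOR_NAMES, drop = FALSE])
  X <- as.matrix(pp$transformed)
  models <- list(); imp <- list(); coefs <- list()
  for (nm in names(indices)) {
    y <- indices[[nm]]
    ok <- is.finite(y)
    if (!is.null(thresholds) && nm %in% names(thresholds)) {
      yb <- dichotomize(y[ok], "threshold", threshold = thresholds[[nm]])
    } else {
      yb <- dichotomize(y[ok], "median")
    }
    fit <- fit_effect_model(X[ok, , drop = FALSE], yb, alpha = alpha,
                            nfolds = nfolds, seed = seed)
    models[[nm]] <- fit
    coefs[[nm]] <- fit$coefficients[PREDICTOR_NAMES]
    imp[[nm]] <- importance_scale(fit)
  }
  list(importance = as.data.frame(do.call(rbind, imp)),
       coefficients = as.data.frame(do.call(rbind, coefs)),
       models = models, preprocess = pp$spec)
}

#' Cox regression for time to first facial contraction
#'
#' Proportional-hazards regression of the months from surgery to the first
#' visible facial contraction with biting on the preoperative predictors.
#' Ties are handled by the Efron approximation.
#'
#' @param X Data.frame or matrix of predictors.
#' @param times Non-negative event/censoring times (months).
#' @param events 0/1 event indicators (1 = contraction observed).
#' @return A `cox_result` list: `table` (per-predictor log HR, HR, 95% CI,
#'   Wald p), `concordance`, and the underlying `survival::coxph` fit.
#' @export
fit_time_to_contraction <- function(X, times, events) {
  X <- as.data.frame(X)
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  if (sum(events) < 1) stop("all observations censored: no events to model",
                            call. = FALSE)
  mm <- cbind(1, as.matrix(X))
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient design (collinear or duplicated predictor columns)",
         call. = FALSE)
  dat <- cbind(X, .time = times, .event = events)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = "efron")
  s <- summary(fit)
  tab <- data.frame(
    predictor = rownames(s$coefficients),
    log_hr = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, concordance = unname(s$concordance["C"]),
                 fit = fit),
            class = "cox_result")
}

#' Predict prognosis for new patients from fitted models
#'
#' Applies the stored preprocessing specification and the fitted models to new
#' patients: per-index predicted probability (and class at 0.5) from each
#' elastic-net logistic model, and the Cox linear predictor as an expected
#' time-to-contraction ranking (higher linear predictor = faster expected
#' contraction).
#'
#' @param newdata Data.frame with the [PREDICTOR_NAMES] columns (e.g. from
#'   [predictor_table()]).
#' @param effect_models Named list of `effect_model` fits (e.g.
#'   `fit_importance_table()$models`).
#' @param preprocess A `preprocess_spec`.
#' @param cox A `cox_result`, or `NULL` to skip the ranking.
#' @return A list with `probabilities` (data.frame patients x indices),
#'   `classes`, and `cox_linear_predictor`.
#' @export
predict_prognosis <- function(newdata, effect_models, preprocess, cox = NULL) {
  miss <- setdiff(PREDICTOR_NAMES, names(newdata))
  if (length(miss) > 0)
    stop(sprintf("missing predictor(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  Xt <- as.matrix(apply_preprocess(preprocess,
                                   newdata[, PREDICTOR_NAMES, drop = FALSE]))
  probs <- sapply(effect_models, function(m) {
    b <- m$coefficients
    as.numeric(stats::plogis(b["(Intercept)"] + Xt[, m$predictors, drop = FALSE] %*%
                               b[m$predictors]))
  })
  probs <- as.data.frame(matrix(probs, nrow = nrow(Xt),
                                dimnames = list(NULL, names(effect_models))))
  lp <- NULL
  if (!is.null(cox)) {
    lp <- as.numeric(stats::predict(cox$fit,
                                    newdata = as.data.frame(newdata), type = "lp"))
  }
  list(probabilities = probs,
       classes = as.data.frame(lapply(probs, function(p) as.integer(p >= 0.5))),
       cox_linear_predictor = lp)
}
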
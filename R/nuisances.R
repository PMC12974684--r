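## Nuisance models on the source sample: logistic propensity, arm-specific
## Cox proportional-hazards models for the survival and censoring processes
## with Breslow baselines, plus oracle (closed-form) and random-forest
## variants satisfying the same prediction interface:
##   predict_propensity(model, X)          -> clipped probabilities
##   cumhaz_matrix(model, X, times)        -> n x length(times) matrix
##   surv_matrix(model, X, times)          -> exp(-cumhaz), in (0, 1]
##   surv_at(model, X, t_each)             -> per-subject survival at own time
##   censor_jump_grid(model, upto)         -> candidate jump times of Lambda_C

#' Feature maps
#'
#' A feature map turns the raw covariate matrix into the design matrix a
#' nuisance model is fitted on. `features_identity()` uses the covariates as
#' they are; `features_exp(cols)` uses elementwise exponentials of selected
#' columns, the canonical way to *misspecify* a working model in simulation
#' studies (the true models are linear/loglinear in X, so fitting on exp(X)
#' is structurally wrong).
#'
#' @param cols integer or character indices of columns to transform.
#' @return a function `X -> matrix`.
#' @export
features_identity <- function() function(X) as_cov_matrix(X)

#' @rdname features_identity
#' @export
features_exp <- function(cols) {
  force(cols)
  function(X) {
    X <- as_cov_matrix(X)
    Z <- exp(X[, cols, drop = FALSE])
    colnames(Z) <- paste0("exp_", colnames(X)[cols])
    Z
  }
}

#' Fit a logistic propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment on an intercept plus
#' `features(X)`. Under (quasi-)perfect separation the fit is repeated with a
#' small L2 penalty (1e-4) for determinism, with a warning.
#'
#' @param src a [source_sample()].
#' @param features feature map (default identity).
#' @param eps clip bound: predictions are truncated to `[eps, 1 - eps]`.
#' @return object of class `propensity_model` with coefficient vector
#'   `theta` (intercept first).
#' @export
fit_propensity <- function(src, features = features_identity(), eps = 0.01) {
  stopifnot(inherits(src, "source_sample"))
  if (length(unique(src$A)) < 2)
    stop("both treatment arms are required to fit a propensity model",
         call. = FALSE)
  Z <- cbind(1, features(src$X))
  fit <- suppressWarnings(stats::glm.fit(Z, src$A, family = stats::binomial()))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || any(abs(fit$coefficients) > 30)
  theta <- fit$coefficients
  if (sep || anyNA(theta)) {
    warning("possible separation in propensity fit; refitting with L2 penalty 1e-4")
    theta <- ridge_logistic(Z, src$A, lambda = 1e-4)
  }
  structure(list(theta = unname(theta), features = features, eps = eps),
            class = "propensity_model")
}

## Penalized logistic Newton iterations (penalty excludes nothing; tiny ridge
## for determinism under separation).
ridge_logistic <- function(Z, y, lambda = 1e-4, maxit = 100L) {
  theta <- rep(0, ncol(Z))
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% theta)
    p <- expit(eta)
    w <- p * (1 - p)
    g <- drop(crossprod(Z, y - p)) - lambda * theta
    H <- crossprod(Z * w, Z) + diag(lambda, ncol(Z))
    step <- solve(H, g)
    theta <- theta + step
    if (max(abs(step)) < 1e-10) break
  }
  theta
}

#' @rdname fit_propensity
#' @param model a fitted `propensity_model`.
#' @param X covariate matrix.
#' @export
predict_propensity <- function(model, X) UseMethod("predict_propensity")

#' Fit an arm-specific Cox model for the survival or censoring process
#'
#' Fits a Cox proportional-hazards model by partial likelihood (Breslow tie
#' handling) on one treatment arm of the source sample, and computes the
#' Breslow estimate of the cumulative baseline hazard: at each distinct
#' event time `t_k` of the chosen role, the increment is
#' `d_k / sum(exp(beta' z_j))` over the risk set. `role = "survival"` treats
#' `Delta = 1` as the event; `role = "censoring"` treats `Delta = 0` as the
#' event.
#'
#' @inheritParams fit_propensity
#' @param arm 0 or 1, the treatment arm to fit on.
#' @param role `"survival"` or `"censoring"`.
#' @return object of class `cox_arm_model` with `beta`, `baseline_times`,
#'   `baseline_increments`.
#' @export
fit_cox_arm <- function(src, arm, role = c("survival", "censoring"),
                        features = features_identity()) {
  stopifnot(inherits(src, "source_sample"), arm %in% c(0, 1))
  role <- match.arg(role)
  keep <- src$A == arm
  if (!any(keep)) stop("empty treatment arm", call. = FALSE)
  Z <- features(src$X)[keep, , drop = FALSE]
  u <- src$U[keep]
  status <- if (role == "survival") src$Delta[keep] else 1 - src$Delta[keep]
  K <- ncol(Z)
  if (sum(status) == 0) {
    warning(sprintf("no %s events in arm %d: cumulative hazard is identically 0",
                    role, arm))
    beta <- rep(0, K)
  } else if (K == 0) {
    beta <- numeric(0)
  } else {
    y <- survival::Surv(u, status)
    fit <- survival::coxph.fit(x = Z, y = y, strata = NULL, offset = NULL,
                               init = rep(0, K),
                               control = survival::coxph.control(),
                               weights = NULL, method = "breslow",
                               rownames = NULL)
    beta <- unname(fit$coefficients)
    if (anyNA(beta)) beta[is.na(beta)] <- 0
  }
  bl <- breslow_baseline(u, status, drop(exp(Z %*% beta)))
  structure(list(beta = beta, baseline_times = bl$times,
                 baseline_increments = bl$increments,
                 features = features, arm = arm, role = role),
            class = "cox_arm_model")
}

## Breslow cumulative-baseline increments d_k / sum_{risk} exp(beta'z);
## with unit risk weights this reduces to the Nelson-Aalen estimator.
## Risk-set sums via a reverse cumulative sum over the sorted times.
breslow_baseline <- function(u, status, risk) {
  et <- sort(unique(u[status == 1]))
  if (length(et) == 0L)
    return(list(times = numeric(0), increments = numeric(0)))
  ord <- order(u)
  us <- u[ord]
  rev_risk <- rev(cumsum(rev(risk[ord])))      # sum of risk over u >= us[i]
  pos <- findInterval(et, us, left.open = TRUE) + 1L   # first index >= t
  denom <- rev_risk[pos]
  dnum <- as.numeric(tabulate(match(u[status == 1], et), nbins = length(et)))
  list(times = et, increments = dnum / denom)
}

#' Nuisance-model predictions
#'
#' `cumhaz_matrix()` evaluates the conditional cumulative hazard
#' `Lambda(t | x)` for every subject at every requested time;
#' `surv_matrix()` returns `exp(-Lambda)`; `surv_at()` evaluates survival at
#' one (subject-specific) time per subject; `censor_jump_grid()` returns the
#' jump times of the estimated cumulative hazard up to a cap (for the
#' censoring-martingale integral). Beyond the last baseline jump the
#' cumulative hazard is extrapolated flat.
#'
#' @param model a fitted nuisance model (`cox_arm_model`, `oracle_hazard_model`
#'   or `ranger_surv_model`).
#' @param X covariate matrix.
#' @param times increasing evaluation times.
#' @return matrix `nrow(X)` x `length(times)` (or a vector for `surv_at`).
#' @export
cumhaz_matrix <- function(model, X, times) UseMethod("cumhaz_matrix")

#' @export
cumhaz_matrix.cox_arm_model <- function(model, X, times) {
  Z <- model$features(X)
  risk <- drop(exp(Z %*% model$beta))
  L0 <- step_eval(model$baseline_times, cumsum(model$baseline_increments),
                  times)
  outer(risk, L0)
}

#' @rdname cumhaz_matrix
#' @export
surv_matrix <- function(model, X, times) exp(-cumhaz_matrix(model, X, times))

#' @rdname cumhaz_matrix
#' @param t_each vector of times, one per row of `X`.
#' @export
surv_at <- function(model, X, t_each) UseMethod("surv_at")

#' @export
surv_at.default <- function(model, X, t_each) {
  X <- as_cov_matrix(X)
  ## generic fallback: one column per distinct time
  ut <- sort(unique(t_each))
  Sm <- surv_matrix(model, X, ut)
  Sm[cbind(seq_len(nrow(X)), match(t_each, ut))]
}

#' @export
surv_at.cox_arm_model <- function(model, X, t_each) {
  Z <- model$features(X)
  risk <- drop(exp(Z %*% model$beta))
  L0 <- step_eval(model$baseline_times, cumsum(model$baseline_increments),
                  t_each)
  exp(-risk * L0)
}

#' @rdname cumhaz_matrix
#' @param upto upper limit for returned jump times.
#' @export
censor_jump_grid <- function(model, upto) UseMethod("censor_jump_grid")

#' @export
censor_jump_grid.cox_arm_model <- function(model, upto)
  model$baseline_times[model$baseline_times <= upto]

#' Predict survival probability from a fitted model
#'
#' Convenience scalar/vector interface: `S(t | x) = exp(-Lambda0(t) *
#' exp(beta' f(x)))`, right-continuous and nonincreasing in `t`, equal to 1
#' at `t = 0`.
#'
#' @inheritParams cumhaz_matrix
#' @param t nonnegative time (scalar or vector).
#' @param x one covariate row.
#' @export
predict_survival <- function(model, t, x) {
  stopifnot(all(t >= 0))
  drop(surv_matrix(model, matrix(x, nrow = 1L), t))
}

#' Oracle hazard model
#'
#' Closed-form nuisance model with conditional cumulative hazard
#' `Lambda(t | x) = k(x) (e^t - 1)`, the form used by the synthetic-data
#' engine. Used as a "true model" plug-in: it satisfies the same prediction
#' interface as a fitted Cox model. For the censoring-martingale integral the
#' continuous baseline is discretized on a fine grid (`n_steps` steps up to
#' `h`).
#'
#' @param risk_fn function mapping a covariate matrix to the positive
#'   multiplier `k(x)`.
#' @param h maximal horizon used when a discrete jump grid is required.
#' @param n_steps discretization resolution for the jump grid.
#' @return object of class `oracle_hazard_model`.
#' @export
oracle_hazard_model <- function(risk_fn, h = 4, n_steps = 400L) {
  structure(list(risk_fn = risk_fn, h = h, n_steps = as.integer(n_steps)),
            class = "oracle_hazard_model")
}

#' @export
cumhaz_matrix.oracle_hazard_model <- function(model, X, times)
  outer(model$risk_fn(as_cov_matrix(X)), expm1(times))

#' @export
surv_at.oracle_hazard_model <- function(model, X, t_each)
  exp(-model$risk_fn(as_cov_matrix(X)) * expm1(t_each))

#' @export
censor_jump_grid.oracle_hazard_model <- function(model, upto)
  seq(0, min(upto, model$h), length.out = model$n_steps + 1L)[-1L]

#' Oracle propensity model
#'
#' Wraps a known treatment-assignment probability function into the
#' propensity interface.
#'
#' @param prob_fn function mapping a covariate matrix to `Pr(A = 1 | X)`.
#' @param eps clip bound.
#' @export
oracle_propensity <- function(prob_fn, eps = 0.01) {
  structure(list(prob_fn = prob_fn, eps = eps), class = "oracle_propensity")
}

#' @export
predict_propensity.oracle_propensity <- function(model, X)
  clip_prob(model$prob_fn(as_cov_matrix(X)), model$eps)

## S3 dispatch for predict_propensity
#' @export
predict_propensity.propensity_model <- function(model, X) {
  Z <- cbind(1, model$features(X))
  clip_prob(expit(drop(Z %*% model$theta)), model$eps)
}

#' Bundle nuisance models
#'
#' @param propensity propensity model.
#' @param survival,censoring lists of two arm-specific hazard models,
#'   `list(arm0, arm1)`.
#' @param sampling optional sampling-score model (see
#'   [fit_sampling_score()]); calibration weights may be used instead.
#' @return object of class `nuisance_set`.
#' @export
nuisance_set <- function(propensity, survival, censoring, sampling = NULL) {
  stopifnot(length(survival) == 2L, length(censoring) == 2L)
  structure(list(propensity = propensity, survival = survival,
                 censoring = censoring, sampling = sampling),
            class = "nuisance_set")
}

#' Fit all parametric nuisance models on the source sample
#'
#' Logistic propensity plus four Cox models (survival and censoring, one per
#' arm), each with its own feature map so that working-model
#' misspecification can be induced per component.
#'
#' @inheritParams fit_propensity
#' @param feature_maps named list with entries `propensity`, `survival`,
#'   `censoring` (each a feature map).
#' @export
fit_nuisances <- function(src,
                          feature_maps = list(propensity = features_identity(),
                                              survival = features_identity(),
                                              censoring = features_identity()),
                          eps = 0.01) {
  nuisance_set(
    propensity = fit_propensity(src, feature_maps$propensity, eps = eps),
    survival = list(fit_cox_arm(src, 0, "survival", feature_maps$survival),
                    fit_cox_arm(src, 1, "survival", feature_maps$survival)),
    censoring = list(fit_cox_arm(src, 0, "censoring", feature_maps$censoring),
                     fit_cox_arm(src, 1, "censoring", feature_maps$censoring)))
}

#' Conditional-mean functionals derived from the survival model
#'
#' For the survival-indicator transformation `y(T) = I(T >= t)`:
#' `mu(a, x) = S(t | a, x)` and `Q(u, a, x) = E[y(T) | T >= u, A = a, X = x]
#' = S(t | a, x) / S(u | a, x)` for `u <= t`, and 1 for `u > t`. RMST-type
#' values operate curve-wise, applying the same formulas at every grid time.
#'
#' @param nuisances a [nuisance_set()].
#' @param transform a [surv_prob()] transformation (horizon `t`).
#' @param eps denominator floor for the conditioning survival.
#' @return list with functions `mu(a, X)` and `Q(u, a, X)` (`u` is a vector,
#'   one entry per row of `X`).
#' @export
derive_mu_Q <- function(nuisances, transform, eps = 0.01) {
  stopifnot(inherits(transform, "transform_spec"),
            transform$kind == "survival_indicator")
  t0 <- transform$horizon
  mu <- function(a, X) {
    m <- nuisances$survival[[a + 1L]]
    drop(surv_matrix(m, X, t0))
  }
  Q <- function(u, a, X) {
    X <- as_cov_matrix(X)
    m <- nuisances$survival[[a + 1L]]
    st <- drop(surv_matrix(m, X, t0))
    su <- surv_at(m, X, pmin(u, t0))
    out <- st / pmax(su, eps)
    out[u > t0] <- 1
    out
  }
  list(mu = mu, Q = Q)
}

#' Serialize fitted nuisance models to JSON
#'
#' Coefficients and Breslow baseline step functions are written in a plain
#' JSON layout for reproducibility / external reuse.
#'
#' @param nuisances a [nuisance_set()] of parametric models.
#' @param file optional path; if `NULL` the JSON string is returned.
#' @export
nuisances_to_json <- function(nuisances, file = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("nuisances_to_json requires the 'jsonlite' package", call. = FALSE)
  as_l <- function(m) list(beta = m$beta, baseline_times = m$baseline_times,
                           baseline_increments = m$baseline_increments)
  obj <- list(propensity = list(theta = nuisances$propensity$theta),
              survival = lapply(nuisances$survival, as_l),
              censoring = lapply(nuisances$censoring, as_l))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
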
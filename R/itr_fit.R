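#' Fit an optimal individualized treatment regime by transfer learning
#'
#' The main fitting function. Given a selection-biased source sample (with
#' right-censored survival outcomes) and a design-weighted target sample
#' (covariates only), it
#' \enumerate{
#'   \item fits the nuisance models on the source sample (logistic
#'     propensity, arm-specific Cox models for survival and censoring with
#'     Breslow baselines), unless oracle nuisances are supplied;
#'   \item computes source weights: entropy-balancing calibration to the
#'     design-weighted target covariate moments (default) or an explicit
#'     logistic sampling-score model;
#'   \item maximizes the estimated value (survival probability at `t` or
#'     RMST over `[0, L]`) over linear rules `d(x) = I(eta'(1, x) >= 0)`
#'     with the last (anchor) coefficient fixed at absolute value one, by
#'     differential-evolution search on internally standardized covariates;
#'   \item returns the fitted rule, its estimated value and the estimated
#'     survival curve under the rule.
#' }
#'
#' With `method = "acw"` (default) the value estimator is the augmented
#' calibration-weighted estimator built on the efficient influence function;
#' it is doubly robust: consistent if either the survival outcome model or
#' the sampling/propensity/censoring models are correctly specified. The
#' other methods are the comparison estimators (see
#' [estimate_survival_acw()]).
#'
#' @param src a [source_sample()].
#' @param tgt a [target_sample()] (not needed for `method = "dr_source"` or
#'   `"naive"`).
#' @param transform a [rmst()] or [surv_prob()] value specification.
#' @param method value estimator to maximize.
#' @param weighting `"cw"` (entropy balancing, default) or `"ipsw"`
#'   (logistic sampling score).
#' @param calibration a [calibration_spec()].
#' @param feature_maps working-model feature maps as in [fit_nuisances()].
#' @param nuisances optional pre-fitted / oracle [nuisance_set()].
#' @param weights optional precomputed weights (calibration result,
#'   sampling-score model or numeric vector).
#' @param grid optional evaluation time grid.
#' @param eps clip band for the propensity / sampling-score probabilities.
#' @param eps_denom floor for the survival and censoring-survival
#'   denominators inside the estimators. Deliberately tiny: the
#'   augmentation's internal cancellations require near-exact denominators,
#'   and an aggressive floor re-introduces raw inverse-censoring-weight
#'   instability.
#' @param search a [search_config()].
#' @param crossfit `NULL`, or `K` (folds) for cross-fitted nuisances.
#' @param learners learner factory for cross-fitting (default
#'   [parametric_learners()] with the supplied maps).
#' @return An object of class `itr_fit` with components `eta` (the fitted
#'   [linear_itr()]), `value`, `curve`, `search`, `nuisances`, `weights`,
#'   `transform`, `method`, diagnostics, and the matched call.
#' @examples
#' \donttest{
#' cfg <- sim_config(N = 20000, m = 1000)
#' pop <- simulate_population(cfg, seed = 7)
#' s <- draw_samples(pop, seed = 7)
#' fit <- itr_fit(s$src, s$tgt, transform = rmst(4),
#'                search = search_config(seed = 1, population = 15,
#'                                       generations = 15, restarts = 1))
#' fit
#' }
#' @export
itr_fit <- function(src, tgt = NULL, transform = rmst(4),
                    method = c("acw", "naive", "ipsw", "cw_ipw", "cw_or",
                               "or_t", "dr_source"),
                    weighting = c("cw", "ipsw"),
                    calibration = calibration_spec(),
                    feature_maps = list(propensity = features_identity(),
                                        survival = features_identity(),
                                        censoring = features_identity()),
                    nuisances = NULL, weights = NULL, grid = NULL,
                    eps = 0.01, eps_denom = 1e-6,
                    search = search_config(seed = 1L),
                    crossfit = NULL, learners = NULL) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  stopifnot(inherits(src, "source_sample"),
            inherits(transform, "transform_spec"))
  needs_tgt <- method %in% c("acw", "ipsw", "cw_ipw", "cw_or", "or_t") ||
    !is.null(crossfit)
  if (needs_tgt && is.null(tgt))
    stop("method '", method, "' requires a target sample", call. = FALSE)
  if (!is.null(tgt)) check_schema_match(src, tgt)

  if (!is.null(crossfit)) {
    if (method != "acw")
      stop("cross-fitting is implemented for the ACW estimator", call. = FALSE)
    if (is.null(learners))
      learners <- parametric_learners(feature_maps, calibration, eps)
    plan <- make_folds(src$n, tgt$m, K = crossfit,
                       seed = sub_seed(search$seed, "folds"))
    value_fn_itr <- crossfit_value(src, tgt, learners, NULL, transform, plan,
                                   grid = grid, eps = eps_denom)
    sr <- run_standardized_search(value_fn_itr, src, tgt, search,
                                  batch_raw = attr(value_fn_itr, "batch_fn"))
    cf <- crossfit_value(src, tgt, learners, sr$eta_hat, transform, plan,
                         grid = grid, eps = eps_denom)
    out <- list(eta = sr$eta_hat, value = cf$value, curve = cf$curve,
                search = sr, crossfit = cf, plan = plan, method = "acw_cf",
                transform = transform, src = src, tgt = tgt, eps = eps,
                eps_denom = eps_denom, call = match.call())
    class(out) <- "itr_fit"
    return(out)
  }

  if (is.null(nuisances))
    nuisances <- fit_nuisances(src, feature_maps, eps = eps)
  if (is.null(weights) && method %in% c("acw", "ipsw", "cw_ipw", "cw_or")) {
    weights <- if (method == "ipsw" ||
                   (method == "acw" && weighting == "ipsw"))
      fit_sampling_score(src, tgt, eps = eps)
    else calibrate_weights(src, tgt, calibration)
  }
  ctx <- value_context(src, tgt, nuisances, weights, grid = grid,
                       h = transform$h, eps = eps_denom)
  value_fn_itr <- function(rule) {
    if (!inherits(rule, "linear_itr")) rule <- linear_itr(rule)
    value_at(ctx, rule, method, transform)
  }
  sr <- run_standardized_search(value_fn_itr, src, tgt, search,
                                batch_raw = value_batch_fn(ctx, method,
                                                           transform))
  vals <- eval_curve(ctx, sr$eta_hat, method)
  out <- list(eta = sr$eta_hat, value = sr$value_hat,
              curve = new_curve_estimate(ctx$grid, vals, method,
                                         ctx$n_clipped),
              search = sr, nuisances = nuisances, weights = weights,
              method = method, transform = transform, src = src, tgt = tgt,
              eps = eps, eps_denom = eps_denom, grid = ctx$grid,
              call = match.call())
  class(out) <- "itr_fit"
  out
}

## Search on standardized covariates: the free coordinates live on the scale
## of z = (x - mu) / sd (pooled source + target), and the resulting rule is
## mapped back to the raw scale before normalization.
run_standardized_search <- function(value_fn_itr, src, tgt, config,
                                    batch_raw = NULL) {
  X <- if (is.null(tgt)) src$X else rbind(src$X, tgt$X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  p <- ncol(X)
  to_raw <- function(zeta) {
    ## zeta = (zeta_0, zeta_1..zeta_p) on the standardized scale
    slopes <- zeta[-1L] / sdv
    c(zeta[1L] - sum(zeta[-1L] * mu / sdv), slopes)
  }
  vf <- function(zeta) value_fn_itr(linear_itr(to_raw(zeta)))
  vb <- if (is.null(batch_raw)) NULL else function(M) {
    slopes <- sweep(M[, -1L, drop = FALSE], 2L, sdv, "/")
    raw <- cbind(M[, 1L] - drop(M[, -1L, drop = FALSE] %*% (mu / sdv)),
                 slopes)
    batch_raw(raw)
  }
  sr <- search_optimal_itr(vf, p, config, value_fn_batch = vb)
  ## map the winning standardized rule back to the raw scale
  zeta_hat <- sr$eta_hat$eta
  sr$eta_hat <- linear_itr(to_raw(zeta_hat))
  sr$value_hat <- value_fn_itr(sr$eta_hat)
  sr$standardization <- list(center = mu, scale = sdv)
  sr
}

#' @export
print.itr_fit <- function(x, ...) {
  cat("Transfer-learned optimal individualized treatment regime\n")
  cat(sprintf("  estimator: %s;  value: %s\n", x$method,
              transform_label(x$transform)))
  cat("  fitted rule (treat iff eta'(1, x) >= 0):\n")
  eta <- x$eta$eta
  names(eta) <- c("(Intercept)", colnames(x$src$X))
  print(round(eta, 4))
  cat(sprintf("  estimated value: %.4f\n", x$value))
  invisible(x)
}

transform_label <- function(tr) {
  if (tr$kind == "rmst") sprintf("RMST over [0, %g]", tr$horizon)
  else sprintf("survival probability at t = %g", tr$horizon)
}

#' @export
coef.itr_fit <- function(object, ...) {
  eta <- object$eta$eta
  names(eta) <- c("(Intercept)", colnames(object$src$X))
  eta
}

#' @export
predict.itr_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    if (is.null(object$tgt)) object$src$X else object$tgt$X
  } else if (inherits(newdata, "target_sample") ||
             inherits(newdata, "source_sample")) newdata$X
  else as_cov_matrix(newdata)
  apply_itr(object$eta, X)
}

#' @export
summary.itr_fit <- function(object, ...) {
  treated_tgt <- if (!is.null(object$tgt))
    mean(predict(object, object$tgt)) else NA_real_
  diag <- list(
    eta = coef(object), value = object$value, method = object$method,
    transform = transform_label(object$transform),
    prop_treated_target = treated_tgt,
    prop_treated_source = mean(predict(object, object$src)),
    n = object$src$n, m = if (is.null(object$tgt)) NA_integer_ else object$tgt$m,
    n_clipped = object$curve$n_clipped,
    search_evals = object$search$n_evals,
    weights = if (inherits(object$weights, "calibration_result"))
      calibration_diagnostics(object$weights) else NULL)
  class(diag) <- "summary.itr_fit"
  diag
}

#' @export
print.summary.itr_fit <- function(x, ...) {
  cat(sprintf("ITR fit (%s), %s\n", x$method, x$transform))
  cat("  rule coefficients:\n")
  print(round(x$eta, 4))
  cat(sprintf("  estimated value      %.4f\n", x$value))
  cat(sprintf("  treated (target)     %.1f%%\n", 100 * x$prop_treated_target))
  cat(sprintf("  treated (source)     %.1f%%\n", 100 * x$prop_treated_source))
  cat(sprintf("  sample sizes         n = %d, m = %s\n", x$n,
              ifelse(is.na(x$m), "-", x$m)))
  if (x$n_clipped > 0)
    cat(sprintf("  clipped denominators %d\n", x$n_clipped))
  if (!is.null(x$weights))
    cat(sprintf("  calibration ESS      %.1f / %d (max violation %.2g)\n",
                x$weights$ess, x$weights$n,
                x$weights$max_constraint_violation))
  invisible(x)
}

#' @export
plot.itr_fit <- function(x, xlab = "time", ylab = "survival under rule",
                         main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("Estimated survival curve (%s)", x$method)
  g <- c(0, x$curve$grid)
  v <- c(1, x$curve$values)
  graphics::plot(g, v, type = "s", xlab = xlab, ylab = ylab, main = main,
                 ylim = range(0, 1, v), ...)
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}

#' Bootstrap confidence interval for a fitted ITR value
#'
#' Re-runs the whole value-estimation pipeline (nuisance fitting,
#' calibration, value evaluation) on independently resampled source and
#' target samples, holding the fitted rule fixed at `eta`-hat
#' (re-optimizing the rule per replicate is available via
#' `reoptimize = TRUE` but is computationally dominant).
#'
#' @param object an [itr_fit()].
#' @param parm ignored (single parameter: the value).
#' @param level confidence level.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param reoptimize re-run the policy search on every replicate.
#' @param ... unused.
#' @return matrix with the normal-interval bounds (as `confint` usually
#'   returns), with the full `bootstrap_result` as attribute `"bootstrap"`.
#' @export
confint.itr_fit <- function(object, parm = "value", level = 0.95, B = 200L,
                            seed = 1L, reoptimize = FALSE, ...) {
  if (object$method %in% c("acw_cf"))
    stop("bootstrap CI for the cross-fitted estimator is not implemented; ",
         "bootstrap the plain ACW fit", call. = FALSE)
  fixed_eta <- object$eta
  pipe <- function(sb, tb = NULL) {
    ns <- if (inherits(object$nuisances$survival[[1]], "cox_arm_model") ||
              inherits(object$nuisances$survival[[1]], "ranger_surv_model"))
      fit_nuisances(sb, feature_maps_of(object), eps = object$eps)
    else object$nuisances  # oracle nuisances are not refit
    w <- refit_weights(object, sb, tb)
    ctx <- value_context(sb, tb, ns, w, h = object$transform$h,
                         eps = object$eps_denom)
    if (reoptimize) {
      vfn <- function(rule) {
        if (!inherits(rule, "linear_itr")) rule <- linear_itr(rule)
        value_at(ctx, rule, object$method, object$transform)
      }
      sr <- run_standardized_search(vfn, sb, tb, object$search$config)
      sr$value_hat
    } else value_at(ctx, fixed_eta, object$method, object$transform)
  }
  bt <- bootstrap_value(object$src, object$tgt, pipe, B = B, seed = seed,
                        level = level, estimate = object$value)
  out <- matrix(c(bt$ci_low, bt$ci_high), nrow = 1,
                dimnames = list("value",
                                paste0(100 * c((1 - level) / 2,
                                               1 - (1 - level) / 2), " %")))
  attr(out, "bootstrap") <- bt
  out
}

feature_maps_of <- function(object) {
  ns <- object$nuisances
  list(propensity = if (!is.null(ns$propensity$features))
         ns$propensity$features else features_identity(),
       survival = if (!is.null(ns$survival[[1]]$features))
         ns$survival[[1]]$features else features_identity(),
       censoring = if (!is.null(ns$censoring[[1]]$features))
         ns$censoring[[1]]$features else features_identity())
}

refit_weights <- function(object, sb, tb) {
  w <- object$weights
  if (is.null(w) || is.null(tb)) return(NULL)
  if (inherits(w, "calibration_result")) {
    if (is.null(w$spec)) calibrate_weights(sb, tb)
    else calibrate_weights(sb, tb, w$spec)
  } else if (inherits(w, "sampling_score_model")) {
    fit_sampling_score(sb, tb, features = w$features, eps = w$eps)
  } else NULL
}
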
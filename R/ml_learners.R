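## Random-forest nuisances (requires the suggested 'ranger' package):
## probability forest for the propensity and survival forests for the
## outcome and censoring processes, exposed through the same prediction
## interface as the parametric models so they plug into calibration-weighted
## estimation and cross-fitting unchanged.

#' Random-forest nuisance learners
#'
#' Learner factory (see [crossfit_value()]) fitting a probability forest for
#' the propensity score and arm-specific survival forests for the outcome
#' and censoring processes, with entropy-balancing calibration on first- and
#' second-order covariate moments for the sampling weights.
#'
#' @param num_trees trees per forest.
#' @param min_node_size minimum terminal node size.
#' @param seed mandatory forest seed.
#' @param calibration a [calibration_spec()] (default first + second
#'   moments).
#' @param eps clip bound.
#' @export
forest_learners <- function(num_trees = 200L, min_node_size = 15L, seed,
                            calibration = calibration_spec(moments = 2),
                            eps = 0.01) {
  if (missing(seed)) stop("a seed is mandatory for forest learners",
                          call. = FALSE)
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("forest_learners requires the 'ranger' package", call. = FALSE)
  function(train_src, train_tgt) {
    ns <- fit_nuisances_forest(train_src, num_trees = num_trees,
                               min_node_size = min_node_size, seed = seed,
                               eps = eps)
    cal <- calibrate_weights(train_src, train_tgt, calibration)
    list(nuisances = ns,
         weight_predictor = function(X) predict_calibration(cal, X))
  }
}

#' Fit random-forest nuisance models
#'
#' @param src a [source_sample()].
#' @inheritParams forest_learners
#' @return a [nuisance_set()] of forest models.
#' @export
fit_nuisances_forest <- function(src, num_trees = 200L, min_node_size = 15L,
                                 seed, eps = 0.01) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("fit_nuisances_forest requires the 'ranger' package", call. = FALSE)
  df <- as.data.frame(src$X)
  prop <- ranger::ranger(y = factor(src$A), x = df, probability = TRUE,
                         num.trees = num_trees,
                         min.node.size = min_node_size, seed = seed,
                         num.threads = 1L)
  pm <- structure(list(forest = prop, eps = eps, levels = levels(factor(src$A))),
                  class = "ranger_prob_model")
  fit_arm <- function(a, role) {
    keep <- src$A == a
    status <- if (role == "survival") src$Delta[keep] else 1 - src$Delta[keep]
    d <- data.frame(df[keep, , drop = FALSE], .time = src$U[keep],
                    .status = status)
    fr <- ranger::ranger(survival::Surv(.time, .status) ~ ., data = d,
                         num.trees = num_trees,
                         min.node.size = min_node_size, seed = seed + a,
                         num.threads = 1L)
    structure(list(forest = fr, eps = eps), class = "ranger_surv_model")
  }
  nuisance_set(propensity = pm,
               survival = list(fit_arm(0, "survival"), fit_arm(1, "survival")),
               censoring = list(fit_arm(0, "censoring"),
                                fit_arm(1, "censoring")))
}

#' @export
predict_propensity.ranger_prob_model <- function(model, X) {
  pr <- stats::predict(model$forest, data = as.data.frame(as_cov_matrix(X)),
                       num.threads = 1L)$predictions
  clip_prob(pr[, "1"], model$eps)
}

ranger_surv_grid <- function(model, X, times) {
  pred <- stats::predict(model$forest,
                         data = as.data.frame(as_cov_matrix(X)),
                         num.threads = 1L)
  ut <- pred$unique.death.times
  S <- pred$survival                      # n x length(ut), step at ut
  idx <- findInterval(times, ut)
  out <- matrix(1, nrow(S), length(times))
  pos <- idx > 0L
  if (any(pos)) out[, pos] <- S[, idx[pos], drop = FALSE]
  out
}

#' @export
cumhaz_matrix.ranger_surv_model <- function(model, X, times)
  -log(pmax(ranger_surv_grid(model, X, times), 1e-12))

#' @export
surv_at.ranger_surv_model <- function(model, X, t_each) {
  ut <- sort(unique(t_each))
  S <- ranger_surv_grid(model, X, ut)
  S[cbind(seq_len(nrow(S)), match(t_each, ut))]
}

#' @export
censor_jump_grid.ranger_surv_model <- function(model, upto) {
  ut <- model$forest$unique.death.times
  ut[ut <= upto]
}
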
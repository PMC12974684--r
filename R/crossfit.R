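## K-fold cross-fitting: nuisances (including calibration weights) are
## trained on the complement of each fold and the value estimator is
## evaluated on the held-out fold, so flexible machine-learning nuisances
## retain valid inference. Fold estimates are aggregated as their arithmetic
## mean. Per-subject weights are predicted out-of-fold (via the calibration
## multipliers or the sampling-score model) and normalized globally, which
## makes the aggregate exactly the full-sample estimator whenever the
## learners do not depend on their training data (oracle learners), and
## therefore invariant to the fold plan in that case.

#' K-fold plan for source and target samples
#'
#' Uniformly random partition of each sample into `K` folds whose sizes
#' differ by at most one; reproducible under the seed.
#'
#' @param n,m source and target sample sizes.
#' @param K number of folds (>= 2).
#' @param seed RNG seed.
#' @return object of class `fold_plan` with `source_fold_ids`,
#'   `target_fold_ids`.
#' @export
make_folds <- function(n, m, K = 5L, seed) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (K > min(n, m))
    stop("K may not exceed the smaller sample size", call. = FALSE)
  with_seed(seed, {
    sf <- sample(rep_len(seq_len(K), n))
    tf <- sample(rep_len(seq_len(K), m))
    structure(list(K = K, source_fold_ids = sf, target_fold_ids = tf,
                   seed = as.integer(seed)),
              class = "fold_plan")
  })
}

subset_source <- function(src, idx)
  source_sample(src$X[idx, , drop = FALSE], src$A[idx], src$U[idx],
                src$Delta[idx])

subset_target <- function(tgt, idx)
  target_sample(tgt$X[idx, , drop = FALSE], tgt$e[idx])

#' Default learner factory: parametric nuisances + calibration weights
#'
#' A learner factory is a function `(train_src, train_tgt) -> list(nuisances,
#' weight_predictor)` where `weight_predictor(X)` returns unnormalized
#' sampling weights for *new* source subjects. This factory fits the
#' parametric models of [fit_nuisances()] and entropy-balancing calibration
#' (out-of-fold weights through the loglinear correspondence).
#'
#' @param feature_maps as in [fit_nuisances()].
#' @param calibration a [calibration_spec()].
#' @param eps clip bound.
#' @export
parametric_learners <- function(feature_maps = list(
                                  propensity = features_identity(),
                                  survival = features_identity(),
                                  censoring = features_identity()),
                                calibration = calibration_spec(),
                                eps = 0.01) {
  function(train_src, train_tgt) {
    ns <- fit_nuisances(train_src, feature_maps, eps = eps)
    cal <- calibrate_weights(train_src, train_tgt, calibration)
    list(nuisances = ns,
         weight_predictor = function(X) predict_calibration(cal, X))
  }
}

#' Learner factory that always returns fixed (oracle) nuisances
#'
#' Ignores the training data; used to verify fold-invariance and in
#' simulation studies with true-model nuisances.
#'
#' @param nuisances a [nuisance_set()].
#' @param weight_fn function `X -> unnormalized source sampling weights`
#'   (e.g. `1 / pi_S(x)`); default uniform.
#' @export
fixed_learners <- function(nuisances, weight_fn = NULL) {
  force(nuisances); force(weight_fn)
  function(train_src, train_tgt) {
    list(nuisances = nuisances,
         weight_predictor = if (is.null(weight_fn)) function(X) rep(1, nrow(X))
                            else weight_fn)
  }
}

#' Cross-fitted value estimation
#'
#' Implements the K-fold cross-fitting procedure: for each fold `k`,
#' nuisances and calibration are trained on the complement
#' `(O_s \\ O_{s,k}, O_t \\ O_{t,k})` and the ACW estimator is evaluated on
#' fold `k`; the cross-fitted estimate is the arithmetic mean of the `K`
#' fold estimates. When `itr` is `NULL` a reusable evaluator is returned so
#' that policy search can maximize the aggregated cross-fitted value without
#' retraining nuisances per candidate rule.
#'
#' @param src,tgt source and target samples.
#' @param learners a learner factory, e.g. [parametric_learners()].
#' @param itr a [linear_itr()], or `NULL` to obtain the evaluator.
#' @param transform a [surv_prob()] or [rmst()] specification.
#' @param plan a [make_folds()] plan.
#' @param grid evaluation grid (default: source event times up to the
#'   transformation's maximal horizon).
#' @param eps clip bound.
#' @return For `itr` supplied: a list with `value`, `fold_values`, `curve`.
#'   Otherwise a function `itr_or_eta -> value` with attribute `"contexts"`.
#' @export
crossfit_value <- function(src, tgt, learners, itr, transform, plan,
                           grid = NULL, eps = 1e-6) {
  stopifnot(inherits(plan, "fold_plan"))
  check_schema_match(src, tgt)
  if (is.null(grid)) grid <- default_grid(src, transform$h)
  K <- plan$K
  n <- src$n; m <- tgt$m

  ## train per fold; handle single-arm folds by merging with the next fold
  fold_of_src <- plan$source_fold_ids
  fold_of_tgt <- plan$target_fold_ids
  fits <- vector("list", K)
  for (k in seq_len(K)) {
    excl <- k
    tr_idx <- which(!(fold_of_src %in% excl))
    while (length(unique(src$A[tr_idx])) < 2L && length(excl) < K) {
      nb <- (max(excl) %% K) + 1L
      warning("training complement of fold ", k,
              " has a single treatment arm; also excluding fold ", nb)
      excl <- c(excl, nb)
      tr_idx <- which(!(fold_of_src %in% excl))
    }
    fits[[k]] <- learners(subset_source(src, tr_idx),
                          subset_target(tgt, which(fold_of_tgt != k)))
  }

  ## assemble per-subject quantities with out-of-fold nuisances
  CORE <- matrix(0, n, length(grid))
  S0t <- matrix(0, m, length(grid)); S1t <- S0t
  w_raw <- numeric(n)
  n_clipped <- 0L
  for (k in seq_len(K)) {
    si <- which(fold_of_src == k)
    ti <- which(fold_of_tgt == k)
    f <- fits[[k]]
    ctx_k <- value_context(subset_source(src, si), NULL, f$nuisances,
                           NULL, grid = grid, eps = eps)
    CORE[si, ] <- ctx_k$CORE
    n_clipped <- n_clipped + ctx_k$n_clipped
    w_raw[si] <- f$weight_predictor(src$X[si, , drop = FALSE])
    if (length(ti)) {
      Xt <- tgt$X[ti, , drop = FALSE]
      S0t[ti, ] <- surv_matrix(f$nuisances$survival[[1L]], Xt, grid)
      S1t[ti, ] <- surv_matrix(f$nuisances$survival[[2L]], Xt, grid)
    }
  }
  q <- w_raw / sum(w_raw)          # global normalization (see module notes)
  v <- tgt$e / sum(tgt$e)

  curve_fn <- function(rule) {
    ds <- apply_itr(rule, src$X)
    dt <- apply_itr(rule, tgt$X)
    cons <- as.numeric(ds == src$A)
    drop(crossprod(q * cons, CORE)) +
      drop(crossprod(v * dt, S1t) + crossprod(v * (1 - dt), S0t))
  }
  val_fn <- function(rule) {
    if (!inherits(rule, "linear_itr")) rule <- linear_itr(rule)
    vals <- curve_fn(rule)
    if (transform$kind == "rmst")
      rmst_from_curve(vals, transform$horizon, grid = grid)
    else vals[max(1L, findInterval(transform$horizon, grid))]
  }

  if (is.null(itr)) {
    attr(val_fn, "grid") <- grid
    attr(val_fn, "curve_fn") <- curve_fn
    ## batched evaluator over the assembled out-of-fold quantities
    ctx_like <- structure(list(grid = grid, q = q, v = v, CORE = CORE,
                               S1_tgt = S1t, S0_tgt = S0t, srcX = src$X,
                               tgtX = tgt$X, A = src$A, n = n, m = m),
                          class = "value_context")
    attr(val_fn, "batch_fn") <- value_batch_fn(ctx_like, "acw", transform)
    return(val_fn)
  }

  vals <- curve_fn(itr)
  value <- val_fn(itr)
  ## per-fold estimates: K * fold partial sums (mean of folds = total)
  ds <- apply_itr(itr, src$X); dt <- apply_itr(itr, tgt$X)
  cons <- as.numeric(ds == src$A)
  fold_values <- vapply(seq_len(K), function(k) {
    si <- fold_of_src == k; ti <- fold_of_tgt == k
    cvals <- drop(crossprod((q * cons)[si], CORE[si, , drop = FALSE])) +
      drop(crossprod((v * dt)[ti], S1t[ti, , drop = FALSE]) +
             crossprod((v * (1 - dt))[ti], S0t[ti, , drop = FALSE]))
    cvals <- K * cvals
    if (transform$kind == "rmst")
      rmst_from_curve(cvals, transform$horizon, grid = grid)
    else cvals[max(1L, findInterval(transform$horizon, grid))]
  }, 0)
  list(value = value, fold_values = fold_values,
       curve = new_curve_estimate(grid, vals, "acw_cf", n_clipped),
       plan = plan)
}
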
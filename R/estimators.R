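## Value estimators for a linear ITR d:
##   acw        augmented calibration-weighted EIF estimator (source IPW term,
##              target outcome-regression term, source OR correction and
##              censoring-martingale augmentation)
##   naive      source-only IPW, no sampling adjustment
##   ipsw       IPW reweighted by an explicit sampling-score model
##   cw_ipw     IPW reweighted by calibration weights
##   cw_or      outcome regression averaged with calibration weights
##   or_t       outcome regression averaged over the target sample
##   dr_source  the standard source-only AIPW estimator with censoring
##              augmentation (no transfer adjustment)
##
## All estimators are Hajek-normalized per block: source weights sum to one,
## target weights e_j / sum(e_j). Everything that does not depend on the rule
## is precomputed once in a "value context" so that policy search only pays
## two matrix cross products per candidate rule.

ACW_METHODS <- c("acw", "naive", "ipsw", "cw_ipw", "cw_or", "or_t",
                 "dr_source")

#' Censoring-martingale augmentation
#'
#' For each source subject computes the augmentation
#' `J_i(t) = int_0^{min(U_i, t)} S(t|A_i,X_i) dM_C(u|A_i,X_i) /
#' (S(u|A_i,X_i) S_C(u|A_i,X_i))`,
#' where the estimated censoring martingale has a unit jump at `U_i` when the
#' subject is censored and compensator increments `-dLambda_C(u|A_i,X_i)` at
#' the model's jump times while the subject is at risk. It recovers the
#' information lost to censoring; without censoring (and a zero cumulative
#' censoring hazard) it is identically zero.
#'
#' @param src a [source_sample()].
#' @param nuisances a [nuisance_set()].
#' @param times evaluation time grid.
#' @param eps floor applied to the survival and censoring-survival
#'   denominators.
#' @param hcap maximal horizon: the integral runs over `(0, min(U_i, hcap)]`
#'   (the conditional mean `Q(u, a, x)` equals 1 beyond the evaluation time
#'   `t`, and the capped-data convention stops all processes at `hcap`).
#'   Defaults to `max(times)`.
#' @return matrix `n x length(times)`; attribute `n_clipped` counts floored
#'   denominators.
#' @details The integral is *not* truncated at the evaluation time `t`: for
#'   `u <= t` the integrand carries the weight
#'   `S(t|a,x) / (S(u|a,x) S_C(u|a,x))` (i.e. `Q(u) = S(t)/S(u)`), while for
#'   `u > t` the conditional mean `Q` is 1 and the weight is
#'   `1 / S_C(u|a,x)`. The `u > t` increments have mean zero but are what
#'   cancels, path by path, the potentially enormous `1/S_C(U)` factor of
#'   the inverse-probability-of-censoring term (note
#'   `1/S_C(U) = 1 + int_0^U lambda_C/S_C du`); dropping them leaves the
#'   augmented estimator unbiased but restores the raw IPCW variance.
#' @export
martingale_augmentation <- function(src, nuisances, times, eps = 1e-6,
                                    hcap = max(times)) {
  n <- src$n
  G <- length(times)
  J <- matrix(0, n, G)
  n_clip <- 0L
  for (a in c(0L, 1L)) {
    idx <- which(src$A == a)
    if (!length(idx)) next
    surv_m <- nuisances$survival[[a + 1L]]
    cens_m <- nuisances$censoring[[a + 1L]]
    Xa <- src$X[idx, , drop = FALSE]
    Ua <- src$U[idx]
    Ucap <- pmin(Ua, hcap)
    na <- length(idx)
    jumps <- censor_jump_grid(cens_m, hcap)
    Sown <- surv_matrix(surv_m, Xa, times)          # S(t | A_i, X_i)
    B_at <- matrix(0, na, G)                        # Q = S(t)/S(u) part
    C_at <- matrix(0, na, G)                        # Q = 1 tail part
    C_end <- numeric(na)
    if (length(jumps)) {
      LC <- cumhaz_matrix(cens_m, Xa, jumps)
      dLC <- LC - cbind(0, LC[, -ncol(LC), drop = FALSE])
      Su <- surv_matrix(surv_m, Xa, jumps)
      SCu <- surv_matrix(cens_m, Xa, jumps)
      n_clip <- n_clip + sum(Su < eps) + sum(SCu < eps)
      ## every evaluation point below is min(U_i, .), so the at-risk
      ## restriction is enforced by where the cumulative sums are read
      B <- -dLC / (pmax(Su, eps) * pmax(SCu, eps))
      C <- -dLC / pmax(SCu, eps)
      for (k in seq_len(ncol(B))[-1L]) {       # row-wise cumulative sums
        B[, k] <- B[, k] + B[, k - 1L]
        C[, k] <- C[, k] + C[, k - 1L]
      }
      kU <- findInterval(Ua, jumps)
      kG <- findInterval(times, jumps)
      ## index of min(U_i, t_g) in the jump grid, all subjects x grid times
      kM <- pmin(matrix(kU, na, G), matrix(kG, na, G, byrow = TRUE))
      pos <- kM > 0L
      ii <- cbind(rep.int(seq_len(na), G)[pos], kM[pos])
      B_at[pos] <- B[ii]
      C_at[pos] <- C[ii]
      posU <- kU > 0L
      C_end[posU] <- C[cbind(which(posU), kU[posU])]
    }
    ## counting-process jump at the subject's own censoring time (only for
    ## subjects censored within the horizon)
    su_own <- surv_at(surv_m, Xa, Ucap)
    sc_own <- surv_at(cens_m, Xa, Ucap)
    n_clip <- n_clip + sum(su_own < eps) + sum(sc_own < eps)
    is_cens <- (1 - src$Delta[idx]) * (Ua < hcap)
    cntB <- is_cens / (pmax(su_own, eps) * pmax(sc_own, eps))
    cntC <- is_cens / pmax(sc_own, eps)
    before_t <- outer(Ua, times, "<=")               # own jump at u <= t
    ## J_i(t) = S(t) * B_i(min(U, t)) + [C_i(min(U, h)) - C_i(min(U, t))],
    ## each part including the subject's own censoring jump where it falls
    J[idx, ] <- Sown * (B_at + before_t * cntB) +
      (C_end + cntC) - (C_at + before_t * cntC)
  }
  attr(J, "n_clipped") <- n_clip
  J
}

## Resolve a weights argument into normalized source weights (sum to 1).
resolve_source_weights <- function(weights, src) {
  if (is.null(weights)) return(rep(1 / src$n, src$n))
  w <- if (inherits(weights, "calibration_result")) weights$q
  else if (inherits(weights, "sampling_score_model"))
    predict_sampling_weight(weights, src$X)
  else as.numeric(weights)
  if (length(w) != src$n)
    stop("weights length does not match the source sample", call. = FALSE)
  if (any(w < 0)) stop("negative source weights", call. = FALSE)
  w / sum(w)
}

#' Default evaluation time grid
#'
#' Pooled distinct source event times up to the maximal horizon `h`,
#' augmented with `h` itself (the Kaplan-Meier convention: the estimated
#' curve is a right-continuous step function that can only jump at event
#' times).
#'
#' @inheritParams martingale_augmentation
#' @param h maximal horizon.
#' @export
default_grid <- function(src, h) {
  g <- sort(unique(src$U[src$Delta == 1 & src$U <= h & src$U > 0]))
  if (!length(g) || max(g) < h) g <- c(g, h)
  g
}

#' Precompute an evaluation context for value estimation
#'
#' Builds every rule-independent ingredient of the estimators on a fixed
#' time grid: per-subject inverse-propensity IPW terms, arm-specific
#' conditional survival matrices for source and target, the
#' censoring-martingale augmentation and the normalized source/target
#' weights. [eval_curve()] then evaluates any estimator for any rule with
#' two matrix products.
#'
#' @inheritParams martingale_augmentation
#' @param tgt a [target_sample()] (may be `NULL` for source-only methods).
#' @param weights calibration result, sampling-score model, numeric vector of
#'   source weights, or `NULL` for uniform.
#' @param grid evaluation time grid (default [default_grid()] up to `h`).
#' @param h maximal horizon (required when `grid` is `NULL`).
#' @param censor_at_t use the `Y_i(t) / S_C(t|A_i,X_i)` variant of the IPW
#'   term instead of the default `Delta_i Y_i(t) / S_C(U_i|A_i,X_i)`
#'   (sensitivity flag).
#' @return object of class `value_context`.
#' @export
value_context <- function(src, tgt = NULL, nuisances, weights = NULL,
                          grid = NULL, h = NULL, eps = 1e-6,
                          censor_at_t = FALSE) {
  stopifnot(inherits(src, "source_sample"), inherits(nuisances, "nuisance_set"))
  if (is.null(grid)) {
    if (is.null(h)) stop("either grid or h must be supplied", call. = FALSE)
    grid <- default_grid(src, h)
  }
  grid <- sort(unique(grid))
  n <- src$n
  n_clip <- 0L

  piA <- predict_propensity(nuisances$propensity, src$X)
  pi_own <- ifelse(src$A == 1, piA, 1 - piA)   # pi_{A_i}(X_i), already clipped
  invprop <- 1 / pi_own

  ## arm-specific conditional survival, source and target
  S_src <- lapply(c(0L, 1L), function(a)
    surv_matrix(nuisances$survival[[a + 1L]], src$X, grid))
  S_own <- S_src[[1L]]
  i1 <- src$A == 1
  S_own[i1, ] <- S_src[[2L]][i1, , drop = FALSE]

  ## IPW term. The transformation is indifferent to survival beyond its
  ## maximal horizon h, so the observed data are capped at h: a subject
  ## still under observation at h counts as an event at h, and the
  ## censoring-survival denominator is never evaluated beyond h (where
  ## positivity of the censoring process is guaranteed).
  hcap <- if (!is.null(h)) h else max(grid)
  Ucap <- pmin(src$U, hcap)
  Dcap <- pmax(src$Delta, as.numeric(src$U >= hcap))
  Yt <- outer(src$U, grid, ">=")
  if (censor_at_t) {
    SCt <- surv_matrix(nuisances$censoring[[1L]], src$X, grid)
    SCt[i1, ] <- surv_matrix(nuisances$censoring[[2L]], src$X, grid)[i1, , drop = FALSE]
    n_clip <- n_clip + sum(SCt < eps)
    IPW <- Yt / pmax(SCt, eps)
  } else {
    scU <- numeric(n)
    for (a in c(0L, 1L)) {
      idx <- which(src$A == a)
      if (length(idx))
        scU[idx] <- surv_at(nuisances$censoring[[a + 1L]],
                            src$X[idx, , drop = FALSE], Ucap[idx])
    }
    n_clip <- n_clip + sum(scU < eps)
    IPW <- (Dcap / pmax(scU, eps)) * Yt
  }

  J <- martingale_augmentation(src, nuisances, grid, eps = eps, hcap = hcap)
  n_clip <- n_clip + attr(J, "n_clipped")

  ctx <- list(grid = grid, n = n, A = src$A,
              q = resolve_source_weights(weights, src),
              invprop = invprop,
              IPW = IPW,
              S_own = S_own, S0_src = S_src[[1L]], S1_src = S_src[[2L]],
              CORE = invprop * (IPW - S_own + J),
              IPWw = invprop * IPW,
              J = J,
              n_clipped = n_clip,
              srcX = src$X)
  if (!is.null(tgt)) {
    stopifnot(inherits(tgt, "target_sample"))
    ctx$m <- tgt$m
    ctx$v <- tgt$e / sum(tgt$e)
    ctx$S0_tgt <- surv_matrix(nuisances$survival[[1L]], tgt$X, grid)
    ctx$S1_tgt <- surv_matrix(nuisances$survival[[2L]], tgt$X, grid)
    ctx$tgtX <- tgt$X
  }
  class(ctx) <- "value_context"
  ctx
}

#' Evaluate an estimated survival curve for a treatment rule
#'
#' @param ctx a [value_context()].
#' @param itr a [linear_itr()] (or precomputed 0/1 decisions via `d_src` /
#'   `d_tgt`).
#' @param method one of `"acw"`, `"naive"`, `"ipsw"`, `"cw_ipw"`, `"cw_or"`,
#'   `"or_t"`, `"dr_source"`. For `"ipsw"`/`"cw_ipw"` the context must have
#'   been built with the corresponding weights.
#' @param d_src,d_tgt optional precomputed decision vectors.
#' @return numeric vector of curve values on `ctx$grid`.
#' @export
eval_curve <- function(ctx, itr = NULL, method = "acw",
                       d_src = NULL, d_tgt = NULL) {
  method <- match.arg(method, ACW_METHODS)
  if (is.null(d_src)) d_src <- apply_itr(itr, ctx$srcX)
  cons <- as.numeric(d_src == ctx$A)
  need_tgt <- method %in% c("acw", "or_t")
  if (need_tgt && is.null(ctx$v))
    stop(sprintf("method '%s' needs a target sample in the context", method),
         call. = FALSE)
  if (need_tgt && is.null(d_tgt)) d_tgt <- apply_itr(itr, ctx$tgtX)

  tgt_or <- function(w) drop(crossprod(w * d_tgt, ctx$S1_tgt) +
                               crossprod(w * (1 - d_tgt), ctx$S0_tgt))
  src_or <- function(w) drop(crossprod(w * d_src, ctx$S1_src) +
                               crossprod(w * (1 - d_src), ctx$S0_src))
  switch(method,
    acw = drop(crossprod(ctx$q * cons, ctx$CORE)) + tgt_or(ctx$v),
    naive = drop(crossprod(cons / ctx$n, ctx$IPWw)),
    ipsw = ,
    cw_ipw = drop(crossprod(ctx$q * cons, ctx$IPWw)),
    cw_or = src_or(ctx$q),
    or_t = tgt_or(rep(1 / ctx$m, ctx$m)),
    dr_source = drop(crossprod(cons / ctx$n, ctx$CORE)) + src_or(rep(1 / ctx$n, ctx$n))
  )
}

new_curve_estimate <- function(grid, values, method, n_clipped = 0L) {
  structure(list(grid = grid, values = values, method = method,
                 n_clipped = n_clipped),
            class = "survival_curve_estimate")
}

#' Estimate the counterfactual survival curve of a treatment rule
#'
#' `estimate_survival_acw()` implements the augmented calibration-weighted
#' (ACW) estimator built on the efficient influence function: source IPW
#' term, target outcome-regression term, source outcome-regression
#' correction, and the censoring-martingale augmentation.
#' `estimate_survival_simple()` implements the naive/IPSW/CW-IPW/CW-OR/OR-t
#' comparison estimators, and `estimate_survival_dr_source()` the standard
#' source-only doubly robust estimator without any sampling adjustment
#' (consistent for the *source* value; under covariate shift it is biased
#' for the target value even though its maximizing rule can still be
#' target-optimal).
#'
#' @inheritParams value_context
#' @param itr a [linear_itr()].
#' @param warn_few warn when fewer than this many source subjects receive
#'   their rule-consistent treatment.
#' @return a `survival_curve_estimate` (fields `grid`, `values`, `method`).
#' @export
estimate_survival_acw <- function(src, tgt, nuisances, weights, itr,
                                  grid = NULL, h = NULL, eps = 1e-6,
                                  censor_at_t = FALSE, warn_few = 5L) {
  ctx <- value_context(src, tgt, nuisances, weights, grid = grid, h = h,
                       eps = eps, censor_at_t = censor_at_t)
  d_src <- apply_itr(itr, src$X)
  if (sum(d_src == src$A) < warn_few)
    warning("fewer than ", warn_few,
            " source subjects received their rule-consistent treatment")
  new_curve_estimate(ctx$grid, eval_curve(ctx, itr, "acw", d_src = d_src),
                     "acw", ctx$n_clipped)
}

#' @rdname estimate_survival_acw
#' @param method one of `"naive"`, `"ipsw"`, `"cw_ipw"`, `"cw_or"`, `"or_t"`.
#' @export
estimate_survival_simple <- function(method, src, tgt = NULL,
                                     nuisances, weights = NULL, itr,
                                     grid = NULL, h = NULL, eps = 1e-6,
                                     censor_at_t = FALSE) {
  method <- match.arg(method, c("naive", "ipsw", "cw_ipw", "cw_or", "or_t"))
  ctx <- value_context(src, tgt, nuisances, weights, grid = grid, h = h,
                       eps = eps, censor_at_t = censor_at_t)
  new_curve_estimate(ctx$grid, eval_curve(ctx, itr, method), method,
                     ctx$n_clipped)
}

#' @rdname estimate_survival_acw
#' @export
estimate_survival_dr_source <- function(src, nuisances, itr, grid = NULL,
                                        h = NULL, eps = 1e-6,
                                        censor_at_t = FALSE) {
  ctx <- value_context(src, NULL, nuisances, NULL, grid = grid, h = h,
                       eps = eps, censor_at_t = censor_at_t)
  new_curve_estimate(ctx$grid, eval_curve(ctx, itr, "dr_source"),
                     "dr_source", ctx$n_clipped)
}

#' Restricted mean survival time from an estimated curve
#'
#' Step-function (left-rectangle) integral of the curve over `[0, L]` with
#' `S(0) = 1`: the Kaplan-Meier convention for a right-continuous step
#' curve jumping at the grid times.
#'
#' @param curve a `survival_curve_estimate`, or a numeric vector of curve
#'   values (then supply `grid`).
#' @param L integration horizon; the grid must reach `L`.
#' @param grid grid times when `curve` is a plain vector.
#' @export
rmst_from_curve <- function(curve, L, grid = NULL) {
  if (inherits(curve, "survival_curve_estimate")) {
    grid <- curve$grid
    vals <- curve$values
  } else vals <- as.numeric(curve)
  if (max(grid) < L)
    stop("time grid must cover (0, L]", call. = FALSE)
  keep <- grid <= L
  tk <- grid[keep]
  sk <- vals[keep]
  ## intervals [0,t1), [t1,t2), ..., [tK, L]
  widths <- diff(c(0, tk, L))
  sum(c(1, sk) * widths)
}

#' Scalar value of a curve under a transformation
#'
#' Survival probability at the transformation horizon (step-interpolated
#' from the grid) or the RMST integral.
#'
#' @param curve a `survival_curve_estimate`.
#' @param transform a [surv_prob()] or [rmst()] specification.
#' @export
value_from_curve <- function(curve, transform) {
  stopifnot(inherits(transform, "transform_spec"))
  if (transform$kind == "rmst")
    return(rmst_from_curve(curve, transform$horizon))
  idx <- findInterval(transform$horizon, curve$grid)
  if (idx == 0L) return(1)
  curve$values[idx]
}

## Scalar value for a candidate rule straight from a context (hot path for
## policy search and bootstrap).
value_at <- function(ctx, itr, method, transform) {
  vals <- eval_curve(ctx, itr, method)
  if (transform$kind == "rmst")
    rmst_from_curve(vals, transform$horizon, grid = ctx$grid)
  else {
    idx <- findInterval(transform$horizon, ctx$grid)
    if (idx == 0L) 1 else vals[idx]
  }
}

#' @export
print.survival_curve_estimate <- function(x, ...) {
  cat(sprintf("Estimated survival curve (%s) on %d grid times in (%g, %g]\n",
              x$method, length(x$grid), min(x$grid), max(x$grid)))
  if (x$n_clipped > 0)
    cat(sprintf("  %d inverse-weight denominators floored\n", x$n_clipped))
  invisible(x)
}

#' @export
as.data.frame.survival_curve_estimate <- function(x, ...)
  data.frame(t = x$grid, S = x$values, method = x$method)

#' Export an estimated curve to CSV
#'
#' @param curve a `survival_curve_estimate`.
#' @param file output path.
#' @export
write_curve_csv <- function(curve, file) {
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  invisible(file)
}

#' Batched value evaluation for policy search
#'
#' Returns a function mapping a matrix of candidate coefficient vectors
#' (one rule per row, length `p + 1`, anchor last) to their estimated
#' values. All candidates of a search generation are evaluated with three
#' matrix products, which is what makes global policy search cheap.
#'
#' @param ctx a [value_context()].
#' @param method estimator to evaluate (see [eval_curve()]).
#' @param transform a [surv_prob()] or [rmst()] specification.
#' @export
value_batch_fn <- function(ctx, method = "acw", transform) {
  method <- match.arg(method, ACW_METHODS)
  stopifnot(inherits(transform, "transform_spec"))
  need_tgt <- method %in% c("acw", "or_t")
  if (need_tgt && is.null(ctx$v))
    stop(sprintf("method '%s' needs a target sample in the context", method),
         call. = FALSE)
  ## linear functional of the curve: value = c0 + curve %*% wts
  if (transform$kind == "rmst") {
    L <- transform$horizon
    keep <- ctx$grid <= L
    tk <- ctx$grid[keep]
    wts <- numeric(length(ctx$grid))
    wts[keep] <- diff(c(tk, L))
    c0 <- if (length(tk)) tk[1] else L
  } else {
    idx <- findInterval(transform$horizon, ctx$grid)
    wts <- numeric(length(ctx$grid))
    c0 <- 0
    if (idx == 0L) c0 <- 1 else wts[idx] <- 1
  }
  Xs1 <- cbind(1, ctx$srcX)
  Xt1 <- if (need_tgt) cbind(1, ctx$tgtX) else NULL
  A <- ctx$A
  ## project every per-subject curve onto the value functional once; a
  ## candidate's value is then a weighted sum of n + m scalars
  pv <- function(M) if (is.null(M)) NULL else drop(M %*% wts)
  core_v <- pv(ctx$CORE); ipww_v <- pv(ctx$IPWw)
  s1s_v <- pv(ctx$S1_src); s0s_v <- pv(ctx$S0_src)
  s1t_v <- pv(ctx$S1_tgt); s0t_v <- pv(ctx$S0_tgt)
  function(etas) {
    if (is.null(dim(etas))) etas <- matrix(etas, nrow = 1L)
    Dsrc <- (Xs1 %*% t(etas)) >= 0            # n x NP decisions
    vals <- switch(method,
      acw = {
        Dtgt <- (Xt1 %*% t(etas)) >= 0
        drop(crossprod((Dsrc == A) * ctx$q, core_v)) +
          drop(crossprod(Dtgt * ctx$v, s1t_v)) +
          drop(crossprod((1 - Dtgt) * ctx$v, s0t_v))
      },
      naive = drop(crossprod((Dsrc == A) / ctx$n, ipww_v)),
      ipsw = ,
      cw_ipw = drop(crossprod((Dsrc == A) * ctx$q, ipww_v)),
      cw_or = drop(crossprod(Dsrc * ctx$q, s1s_v)) +
        drop(crossprod((1 - Dsrc) * ctx$q, s0s_v)),
      or_t = {
        Dtgt <- (Xt1 %*% t(etas)) >= 0
        (drop(crossprod(Dtgt, s1t_v)) + drop(crossprod(1 - Dtgt, s0t_v))) /
          ctx$m
      },
      dr_source = drop(crossprod((Dsrc == A) / ctx$n, core_v)) +
        (drop(crossprod(Dsrc, s1s_v)) + drop(crossprod(1 - Dsrc, s0s_v))) /
          ctx$n
    )
    c0 + vals
  }
}
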
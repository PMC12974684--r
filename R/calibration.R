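## Entropy-balancing calibration of source-sample weights to design-weighted
## target moments, solved through the strictly convex Lagrange dual
##   f(lambda) = log sum_i exp(lambda' (g_i - gbar))
## by damped Newton with line search. The primal solution is
##   q_i = exp(lambda' g_i) / sum_j exp(lambda' g_j),
## the exact correspondence with a loglinear sampling-score model.

#' Calibration specification
#'
#' The vector of covariate functions `g(X)` whose design-weighted target
#' moments the weighted source sample must match. `moments = 1` calibrates
#' first moments of every covariate, `moments = 2` adds squares; custom
#' transforms can be supplied as named functions (each mapping the covariate
#' matrix to one column), e.g. to calibrate on `exp(X1)` only.
#'
#' @param moments 1 or 2, ignored when `g_functions` is given.
#' @param g_functions optional named list of functions `X -> numeric vector`.
#' @return object of class `calibration_spec`.
#' @export
calibration_spec <- function(moments = 1, g_functions = NULL) {
  stopifnot(is.null(g_functions) || length(g_functions) >= 1)
  structure(list(moments = moments, g_functions = g_functions),
            class = "calibration_spec")
}

## Build the n x K matrix of calibration functions.
calib_matrix <- function(X, spec) {
  X <- as_cov_matrix(X)
  if (!is.null(spec$g_functions)) {
    G <- vapply(spec$g_functions, function(f) as.numeric(f(X)),
                numeric(nrow(X)))
    colnames(G) <- names(spec$g_functions)
    return(as_cov_matrix(G))
  }
  G <- X
  if (spec$moments >= 2) {
    sq <- X^2
    colnames(sq) <- paste0(colnames(X), "^2")
    G <- cbind(G, sq)
  }
  G
}

#' Design-weighted target moments
#'
#' `gbar = sum_target e_i g(X_i) / sum_target e_i`, the design-weighted
#' estimate of `E[g(X)]` in the target population.
#'
#' @param tgt a [target_sample()].
#' @param spec a [calibration_spec()].
#' @return numeric vector of length `K`.
#' @export
target_moments <- function(tgt, spec = calibration_spec()) {
  stopifnot(inherits(tgt, "target_sample"))
  G <- calib_matrix(tgt$X, spec)
  drop(crossprod(G, tgt$e)) / sum(tgt$e)
}

#' Solve the entropy-balancing problem
#'
#' Minimizes `sum q_i log q_i` subject to `q >= 0`, `sum q = 1` and
#' `sum q_i g(X_i) = gbar`, via damped Newton on the Lagrange dual starting
#' at `lambda = 0`. Columns of `src_g` are internally standardized (centered
#' and scaled by source moments) for conditioning; exactly collinear columns
#' are dropped with a warning; the reported `lambda` is on the original
#' scale.
#'
#' @param src_g numeric matrix `n x K` of calibration functions evaluated on
#'   the source sample.
#' @param gbar target moment vector of length `K`.
#' @param tol convergence tolerance on the dual gradient (maximum constraint
#'   violation of the standardized moments).
#' @param max_iter maximum Newton iterations.
#' @return object of class `calibration_result`: weights `q` (sum to 1),
#'   multipliers `lambda`, `gbar`, `converged` flag and
#'   `max_constraint_violation` on the original scale.
#' @export
solve_calibration <- function(src_g, gbar, tol = 1e-10, max_iter = 200L) {
  G <- as.matrix(src_g)
  storage.mode(G) <- "double"
  n <- nrow(G)
  gbar <- as.numeric(gbar)
  if (length(gbar) != ncol(G))
    stop("gbar length must equal ncol(src_g)", call. = FALSE)

  ## drop collinear columns (constant columns are collinear with the
  ## normalization constraint)
  keep <- seq_len(ncol(G))
  qrG <- qr(cbind(1, scale(G, scale = FALSE)))
  if (qrG$rank < ncol(G) + 1L) {
    keep <- sort((qrG$pivot[seq_len(qrG$rank)] - 1L)[qrG$pivot[seq_len(qrG$rank)] > 1L])
    warning("rank-deficient calibration matrix: dropping collinear column(s) ",
            paste(setdiff(seq_len(ncol(G)), keep), collapse = ", "))
  }
  Gk <- G[, keep, drop = FALSE]
  gb <- gbar[keep]

  ## standardize by source moments
  mu <- colMeans(Gk)
  sdv <- apply(Gk, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Zs <- sweep(sweep(Gk, 2, mu), 2, sdv, "/")
  zb <- (gb - mu) / sdv
  D <- sweep(Zs, 2, zb)           # g_i - gbar, standardized

  lam <- rep(0, ncol(D))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    s <- drop(D %*% lam)
    s <- s - max(s)               # stabilized log-sum-exp
    w <- exp(s); w <- w / sum(w)
    grad <- drop(crossprod(D, w))
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    H <- crossprod(D * w, D) - tcrossprod(grad)
    step <- tryCatch(solve(H + diag(1e-12, ncol(D)), grad),
                     error = function(e) grad)
    ## damped line search on the dual objective
    f0 <- log(sum(exp(drop(D %*% lam) - max(drop(D %*% lam))))) +
      max(drop(D %*% lam))
    alpha <- 1
    repeat {
      lam_new <- lam - alpha * step
      sn <- drop(D %*% lam_new)
      fn <- log(sum(exp(sn - max(sn)))) + max(sn)
      if (fn < f0 || alpha < 1e-12) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-12 && fn >= f0) break
    lam <- lam_new
  }
  s <- drop(D %*% lam)
  s <- s - max(s)
  q <- exp(s) / sum(exp(s))
  viol <- max(abs(drop(crossprod(Gk, q)) - gb))
  if (!conv && viol > 1e-6) {
    dir <- which.max(abs(drop(crossprod(Gk, q)) - gb))
    stop(sprintf(paste0("calibration did not converge (max violation %.3g in ",
                        "column %d): target moments likely outside the convex ",
                        "hull of the source values"), viol, keep[dir]),
         call. = FALSE)
  }
  ## map multipliers back to the original scale of the kept columns
  lambda <- rep(0, ncol(G))
  lambda[keep] <- lam / sdv
  structure(list(q = q, lambda = lambda, gbar = gbar, converged = conv,
                 max_constraint_violation = viol, keep = keep,
                 n = n),
            class = "calibration_result")
}

#' Calibrate source weights to a target sample
#'
#' Front end combining [target_moments()] and [solve_calibration()], and
#' remembering the calibration functions so that weights can be *predicted*
#' for new source subjects (out-of-fold prediction in cross-fitting) through
#' the loglinear correspondence `q(x) proportional to exp(lambda' g(x))`.
#'
#' @param src a [source_sample()].
#' @param tgt a [target_sample()].
#' @param spec a [calibration_spec()].
#' @param ... passed to [solve_calibration()].
#' @return a `calibration_result` with the spec attached.
#' @export
calibrate_weights <- function(src, tgt, spec = calibration_spec(), ...) {
  check_schema_match(src, tgt)
  G <- calib_matrix(src$X, spec)
  gbar <- target_moments(tgt, spec)
  res <- solve_calibration(G, gbar, ...)
  res$spec <- spec
  res
}

#' Predict calibration weights for new source subjects
#'
#' Unnormalized weights `exp(lambda' g(x))` from a solved calibration; used
#' for out-of-fold weighting in cross-fitting.
#'
#' @param cal a `calibration_result` from [calibrate_weights()].
#' @param X covariate matrix.
#' @export
predict_calibration <- function(cal, X) {
  if (is.null(cal$spec))
    stop("calibration was solved without a spec; cannot predict", call. = FALSE)
  G <- calib_matrix(X, cal$spec)
  w <- exp(drop(G %*% cal$lambda))
  w / sum(w) * length(w)  # mean-one scaling; callers renormalize as needed
}

#' Calibration diagnostics
#'
#' Effective sample size `1 / sum(q^2)`, maximum constraint violation and the
#' Lagrange multipliers.
#'
#' @param cal a `calibration_result`.
#' @export
calibration_diagnostics <- function(cal) {
  list(ess = 1 / sum(cal$q^2), n = cal$n,
       max_constraint_violation = cal$max_constraint_violation,
       lambda = cal$lambda, converged = cal$converged)
}

#' Export calibration weights to CSV
#'
#' @param cal a `calibration_result`.
#' @param file output path.
#' @param id optional subject identifiers.
#' @export
write_weights_csv <- function(cal, file, id = seq_along(cal$q)) {
  utils::write.csv(data.frame(id = id, q = cal$q), file, row.names = FALSE)
  invisible(file)
}

#' Fit an explicit sampling-score model (IPSW)
#'
#' Logistic regression of source membership on the stacked source/target
#' covariates, with target rows weighted by their design weights. Because the
#' target sample is only a design-weighted draw from the population, the
#' fitted odds are proportional to the sampling score `pi_S(x)` up to a
#' constant; inverse-probability-of-sampling weights are therefore taken
#' proportional to the inverse fitted odds and self-normalized downstream.
#'
#' @inheritParams calibrate_weights
#' @param features feature map applied to the covariates.
#' @param eps clip bound on fitted membership probabilities.
#' @return object of class `sampling_score_model`.
#' @export
fit_sampling_score <- function(src, tgt, features = features_identity(),
                               eps = 0.01) {
  check_schema_match(src, tgt)
  Z <- cbind(1, rbind(features(src$X), features(tgt$X)))
  y <- c(rep(1, src$n), rep(0, tgt$m))
  w <- c(rep(1, src$n), tgt$e / mean(tgt$e))
  fit <- suppressWarnings(stats::glm.fit(Z, y, weights = w,
                                         family = stats::binomial()))
  structure(list(theta = unname(fit$coefficients), features = features,
                 eps = eps),
            class = "sampling_score_model")
}

#' @rdname fit_sampling_score
#' @param model a fitted `sampling_score_model`.
#' @param X covariate matrix.
#' @return `predict_sampling_weight()`: unnormalized weights proportional to
#'   `1 / pi_S(x)`.
#' @export
predict_sampling_weight <- function(model, X) {
  Z <- cbind(1, model$features(X))
  p <- clip_prob(expit(drop(Z %*% model$theta)), model$eps)
  (1 - p) / p
}
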
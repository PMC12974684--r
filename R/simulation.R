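## Synthetic-data engine. The generated study emulates transferring a
## selection-biased trial to a design-weighted target population:
##   - covariates: 3-dimensional truncated (+-4) multivariate normal, unit
##     variances, corr(X1, X3) = 0.2, other correlations 0;
##   - source inclusion: pi_S(X) = expit(-4.5 - 0.5 X1 - 0.5 X2 - 0.4 X3)
##     (sampling rate about 1.6%);
##   - treatment in the source: pi_A(X) = expit(0.5 + 0.8 X1 - 0.5 X2);
##   - survival hazards lambda(t|a,x) = exp(t) * k_a(x) (Gompertz-type, so
##     Lambda(t|a,x) = k_a(x) (e^t - 1) inverts in closed form), with
##       log k_0 = -2.5 - 1.5 X1 - X2 - 0.7 X3
##       log k_1 = -1 - X1 - 0.9 X2 - X3 - 2 X2^2 + X1 X3
##   - censoring hazards c_C * exp(t) * k_{C,a}(x) with
##       log k_{C,0} = -1.6 + 0.8 X1 - 1.1 X2 - 0.7 X3
##       log k_{C,1} = -1.8 - 0.8 X1 - 1.7 X2 - 1.4 X3
##     and scale c_C = 0.04 (about 20% censoring) or 0.2 (about 33%);
##   - value: RMST over [0, L], L = 4.
## Named RNG substreams keep the draws for covariates, potential outcomes,
## censoring, treatment and sampling separate and reproducible.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark data-generating process above. The
#' machine-learning variant uses `N = 6e5`, `m = 24000`,
#' `censor_scale = 0.2`.
#'
#' @param N target (super)population size.
#' @param m target sample size (simple random sample, so `e = N / m`).
#' @param censor_scale multiplier `c_C` of the censoring hazard.
#' @param L RMST horizon.
#' @param corr13 correlation between X1 and X3.
#' @param trunc symmetric truncation bound for the covariates.
#' @param sampling_coef,propensity_coef logistic coefficients (intercept
#'   first) of the sampling score and propensity.
#' @param eval_N size of the oracle evaluation population.
#' @export
sim_config <- function(N = 2e5, m = 8000, censor_scale = 0.04, L = 4,
                       corr13 = 0.2, trunc = 4,
                       sampling_coef = c(-4.5, -0.5, -0.5, -0.4),
                       propensity_coef = c(0.5, 0.8, -0.5),
                       eval_N = 1e5) {
  structure(list(
    N = as.integer(N), m = as.integer(m), censor_scale = censor_scale,
    L = L, corr13 = corr13, trunc = trunc,
    sampling_coef = sampling_coef, propensity_coef = propensity_coef,
    eval_N = as.integer(eval_N), p = 3L,
    surv_risk = list(
      function(X) exp(-2.5 - 1.5 * X[, 1] - X[, 2] - 0.7 * X[, 3]),
      function(X) exp(-1 - X[, 1] - 0.9 * X[, 2] - X[, 3] -
                        2 * X[, 2]^2 + X[, 1] * X[, 3])),
    cens_risk = list(
      function(X) exp(-1.6 + 0.8 * X[, 1] - 1.1 * X[, 2] - 0.7 * X[, 3]),
      function(X) exp(-1.8 - 0.8 * X[, 1] - 1.7 * X[, 2] - 1.4 * X[, 3]))),
    class = "sim_config")
}

#' Invert the cumulative hazard `Lambda(t) = k (e^t - 1)`
#'
#' For an exponential(1) draw `E`, `t = log(1 + E / k)` has survival
#' function `exp(-k (e^t - 1))`.
#'
#' @param k positive rate multiplier.
#' @param E nonnegative exponential(1) draws.
#' @export
invert_exp_hazard <- function(k, E) {
  if (any(k <= 0)) stop("rate multiplier must be positive", call. = FALSE)
  stopifnot(all(E >= 0))
  log1p(E / k)
}

## Truncated correlated normal covariates by whole-vector rejection.
draw_covariates <- function(N, config) {
  Sig <- diag(3)
  Sig[1, 3] <- Sig[3, 1] <- config$corr13
  R <- chol(Sig)
  out <- matrix(NA_real_, N, 3)
  filled <- 0L
  while (filled < N) {
    nb <- max(1000L, ceiling((N - filled) * 1.01))
    Z <- matrix(stats::rnorm(nb * 3), nb, 3) %*% R
    ok <- rowSums(abs(Z) <= config$trunc) == 3L
    Zok <- Z[ok, , drop = FALSE]
    take <- min(nrow(Zok), N - filled)
    if (take > 0) out[filled + seq_len(take), ] <- Zok[seq_len(take), , drop = FALSE]
    filled <- filled + take
  }
  colnames(out) <- c("X1", "X2", "X3")
  out
}

#' Generate a synthetic target population
#'
#' Draws covariates, both potential survival times, arm-specific potential
#' censoring times, the realized treatment, the observed time and the event
#' indicator, plus the true sampling and propensity scores, for every
#' subject of the population.
#'
#' @param config a [sim_config()].
#' @param seed master seed (named substreams are derived from it).
#' @return list of class `sim_population` with fields `X`, `T0`, `T1`, `C0`,
#'   `C1`, `A`, `U`, `Delta`, `piS`, `piA`, `config`.
#' @export
simulate_population <- function(config = sim_config(), seed) {
  N <- config$N
  X <- with_seed(sub_seed(seed, "covariates"), draw_covariates(N, config))
  Xt <- cbind(1, X)
  piS <- expit(drop(Xt %*% config$sampling_coef))
  piA <- expit(drop(cbind(1, X[, 1:2]) %*% config$propensity_coef))
  T0 <- with_seed(sub_seed(seed, "t0"),
                  invert_exp_hazard(config$surv_risk[[1]](X), stats::rexp(N)))
  T1 <- with_seed(sub_seed(seed, "t1"),
                  invert_exp_hazard(config$surv_risk[[2]](X), stats::rexp(N)))
  C0 <- with_seed(sub_seed(seed, "c0"),
                  invert_exp_hazard(config$censor_scale * config$cens_risk[[1]](X),
                                    stats::rexp(N)))
  C1 <- with_seed(sub_seed(seed, "c1"),
                  invert_exp_hazard(config$censor_scale * config$cens_risk[[2]](X),
                                    stats::rexp(N)))
  A <- with_seed(sub_seed(seed, "treatment"),
                 as.numeric(stats::runif(N) < piA))
  Tobs <- ifelse(A == 1, T1, T0)
  Cobs <- ifelse(A == 1, C1, C0)
  U <- pmin(Tobs, Cobs)
  Delta <- as.numeric(Tobs <= Cobs)
  structure(list(X = X, T0 = T0, T1 = T1, C0 = C0, C1 = C1, A = A, U = U,
                 Delta = Delta, piS = piS, piA = piA, config = config),
            class = "sim_population")
}

#' Draw the source and target samples from a population
#'
#' Source inclusion is an independent Bernoulli draw with the subject's
#' sampling score; the target sample is a simple random sample (without
#' replacement) of size `m` keeping covariates only, with constant design
#' weight `e = N / m`. The two draws use separate RNG substreams, matching
#' the non-nested design (overlap is permitted).
#'
#' @param pop a [simulate_population()] result.
#' @param seed master seed.
#' @return list with `src` ([source_sample()]), `tgt` ([target_sample()]),
#'   `n` (realized source size) and the row indices of both samples.
#' @export
draw_samples <- function(pop, seed) {
  config <- pop$config
  N <- config$N
  is_src <- with_seed(sub_seed(seed, "sampling"),
                      stats::runif(N) < pop$piS)
  sidx <- which(is_src)
  if (length(sidx) < 50)
    warning("realized source sample has fewer than 50 subjects")
  tidx <- with_seed(sub_seed(seed, "target"), sample.int(N, config$m))
  src <- source_sample(pop$X[sidx, , drop = FALSE], pop$A[sidx],
                       pop$U[sidx], pop$Delta[sidx])
  tgt <- target_sample(pop$X[tidx, , drop = FALSE], rep(N / config$m,
                                                        config$m))
  list(src = src, tgt = tgt, n = length(sidx), source_rows = sidx,
       target_rows = tidx)
}

#' Oracle (true-model) nuisances for the synthetic DGP
#'
#' Wraps the generating propensity and the closed-form survival/censoring
#' hazards into the nuisance interface, for use as true-model plug-ins.
#'
#' @param config a [sim_config()].
#' @param eps clip bound for the propensity.
#' @param n_steps discretization resolution of the continuous censoring
#'   baseline for the martingale integral.
#' @export
oracle_nuisances <- function(config = sim_config(), eps = 0.01,
                             n_steps = 400L) {
  pc <- config$propensity_coef
  nuisance_set(
    propensity = oracle_propensity(
      function(X) expit(drop(cbind(1, X[, 1:2]) %*% pc)), eps = eps),
    survival = lapply(config$surv_risk, oracle_hazard_model,
                      h = config$L, n_steps = n_steps),
    censoring = lapply(config$cens_risk, function(rf)
      oracle_hazard_model(function(X) config$censor_scale * rf(X),
                          h = config$L, n_steps = n_steps)))
}

#' True sampling-weight function of the synthetic DGP
#'
#' Returns `1 / pi_S(x)` as a function, for oracle-weighted estimators.
#'
#' @param config a [sim_config()].
#' @export
oracle_sampling_weight <- function(config = sim_config()) {
  sc <- config$sampling_coef
  function(X) 1 / expit(drop(cbind(1, as_cov_matrix(X)) %*% sc))
}

#' True value and percentage of correct decisions of a rule
#'
#' Plug-in averages on an evaluation population carrying both potential
#' outcomes: `V(eta) = mean(min(d T1 + (1 - d) T0, L))` and
#' `PCD = 1 - mean(|d* - d|)` against the reference optimal rule.
#'
#' @param itr a [linear_itr()].
#' @param pop a [simulate_population()] result (the evaluation population).
#' @param L RMST horizon.
#' @param eta_star optional reference optimal rule (a [linear_itr()]); when
#'   omitted the PCD is `NA`.
#' @return list with `true_value`, `pcd`, `eval_size`.
#' @export
true_value_and_pcd <- function(itr, pop, L = pop$config$L, eta_star = NULL) {
  d <- apply_itr(itr, pop$X)
  v <- mean(pmin(d * pop$T1 + (1 - d) * pop$T0, L))
  pcd <- if (is.null(eta_star)) NA_real_
  else 1 - mean(abs(apply_itr(eta_star, pop$X) - d))
  list(true_value = v, pcd = pcd, eval_size = nrow(pop$X))
}

#' Oracle-optimal linear rule of the synthetic DGP
#'
#' Maximizes the true (plug-in) value over the linear-ITR class by global
#' search on an evaluation population.
#'
#' @param pop evaluation population.
#' @param L RMST horizon.
#' @param config a [search_config()]; defaults to a generous budget.
#' @export
oracle_eta_star <- function(pop, L = pop$config$L,
                            config = search_config(seed = 171, population = 40L,
                                                   generations = 60L,
                                                   restarts = 2L)) {
  Xt <- cbind(1, pop$X)
  Tm <- cbind(pmin(pop$T0, L), pmin(pop$T1, L))
  vf <- function(eta) {
    d <- (drop(Xt %*% eta) >= 0) + 1L
    mean(Tm[cbind(seq_len(nrow(Tm)), d)])
  }
  search_optimal_itr(vf, ncol(pop$X), config)
}

#' Working-model specifications for the misspecification scenarios
#'
#' Four benchmark scenarios: (1) all working models correct; (2) only the
#' survival outcome model correct; (3) only the survival outcome model
#' wrong; (4) all wrong. The misspecified versions calibrate on `exp(X1)`,
#' fit the propensity on `exp(X3)`, and fit the Cox survival/censoring
#' models on `(exp(X1), exp(X2), exp(X3))`. A *correctly specified*
#' survival model for this generating process must carry the `X2^2` and
#' `X1 X3` terms of the arm-1 log-hazard, so the correct outcome feature
#' map is `(X1, X2, X3, X2^2, X1 X3)` (the extra columns are harmless in
#' arm 0, whose true coefficients for them are zero); the true censoring
#' and propensity models are linear in `X`, so identity features are
#' correct there.
#'
#' @param scenario integer in 1..4.
#' @return list with `calibration` (a [calibration_spec()]) and
#'   `feature_maps` (propensity/survival/censoring feature maps).
#' @export
scenario_nuisances <- function(scenario) {
  stopifnot(scenario %in% 1:4)
  ## the misspecified sampling model balances the first moment of X1 only,
  ## leaving the X2/X3 shift uncorrected
  wrong_cal <- calibration_spec(
    g_functions = list(X1 = function(X) X[, 1]))
  right_cal <- calibration_spec(moments = 1)
  surv_correct <- function(X) {
    Z <- cbind(X, X[, 2]^2, X[, 1] * X[, 3])
    colnames(Z) <- c(colnames(X), "X2sq", "X1X3")
    Z
  }
  out_ok <- scenario %in% c(1, 2)        # survival outcome model correct
  oth_ok <- scenario %in% c(1, 3)        # sampling/propensity/censoring correct
  list(calibration = if (oth_ok) right_cal else wrong_cal,
       feature_maps = list(
         propensity = if (oth_ok) features_identity() else features_exp(3L),
         survival = if (out_ok) surv_correct else features_exp(1:3),
         censoring = if (oth_ok) features_identity() else features_exp(1:3)))
}

#' Write a simulated study to CSV
#'
#' Writes `source.csv`, `target.csv` and, when requested, an `oracle.json`
#' with the true value of a reference rule -- a plain-text snapshot of one
#' simulated study.
#'
#' @param samples result of [draw_samples()].
#' @param dir output directory (created if needed).
#' @export
write_simulation_csv <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- samples$src
  utils::write.csv(data.frame(s$X, A = s$A, U = s$U, Delta = s$Delta),
                   file.path(dir, "source.csv"), row.names = FALSE)
  t <- samples$tgt
  utils::write.csv(data.frame(t$X, e = t$e),
                   file.path(dir, "target.csv"), row.names = FALSE)
  invisible(dir)
}
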
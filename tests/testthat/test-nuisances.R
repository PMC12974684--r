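test_that("propensity fit recovers a null and a true logistic model", {
  ## null model: A independent of X
  with_seed_test(24, {
    n <- 5000
    X <- matrix(rnorm(n * 2), ncol = 2)
    src <- source_sample(X, A = rbinom(n, 1, 0.5), U = rexp(n),
                         Delta = rep(1, n))
    pm <- fit_propensity(src)
    se <- sqrt(diag(solve(crossprod(cbind(1, X) *
      sqrt(predict_propensity(pm, X) * (1 - predict_propensity(pm, X))),
      cbind(1, X)))))
    expect_true(all(abs(pm$theta) < 3 * se))
  })
  ## parameter recovery at the benchmark coefficients (0.5, 0.8, -0.5)
  with_seed_test(22, {
    n <- 20000
    X <- matrix(rnorm(n * 2), ncol = 2)
    pA <- plogis(0.5 + 0.8 * X[, 1] - 0.5 * X[, 2])
    src <- source_sample(X, A = rbinom(n, 1, pA), U = rexp(n),
                         Delta = rep(1, n))
    pm <- fit_propensity(src)
    W <- predict_propensity(pm, X) * (1 - predict_propensity(pm, X))
    se <- sqrt(diag(solve(crossprod(cbind(1, X) * W, cbind(1, X)))))
    expect_true(all(abs(pm$theta - c(0.5, 0.8, -0.5)) < 3 * se))
  })
  ## degenerate single-arm input
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(source_sample(X, A = rep(1, 10), U = rexp(10),
                             Delta = rep(1, 10)))
})

test_that("propensity predictions respect the clip band", {
  with_seed_test(5, {
    n <- 400
    X <- matrix(rnorm(n) * 8, ncol = 1)      # extreme scores
    pA <- plogis(3 * X[, 1])
    src <- source_sample(X, A = rbinom(n, 1, pA), U = rexp(n),
                         Delta = rep(1, n))
    pm <- suppressWarnings(fit_propensity(src, eps = 0.01))
    pr <- predict_propensity(pm, X)
    expect_true(all(pr >= 0.01 & pr <= 0.99))
  })
})

test_that("Breslow baseline equals Nelson-Aalen with no covariate effect", {
  with_seed_test(31, {
    n <- 300
    U <- round(rexp(n, 0.8), 2)              # rounding forces ties
    D <- rbinom(n, 1, 0.7)
    X <- matrix(rnorm(n), ncol = 1)
    src <- source_sample(X, A = rep_len(0:1, n), U = U, Delta = D)
    ## p = 0 via a feature map that drops all columns
    m0 <- fit_cox_arm(src, 0, "survival",
                      features = function(X) X[, 0, drop = FALSE])
    keep <- src$A == 0
    u <- src$U[keep]; d <- src$Delta[keep]
    et <- sort(unique(u[d == 1]))
    na_inc <- vapply(et, function(t) sum(u == t & d == 1) / sum(u >= t), 0)
    expect_equal(m0$baseline_times, et)
    expect_equal(m0$baseline_increments, na_inc, tolerance = 1e-12)
  })
})

test_that("administrative censoring yields a single Breslow jump", {
  with_seed_test(33, {
    n <- 40
    X <- matrix(rnorm(n), ncol = 1)
    T0 <- rexp(n, 0.2)
    cens_at <- 2.5
    U <- pmin(T0, cens_at)
    D <- as.numeric(T0 <= cens_at)
    src <- source_sample(X, A = rep_len(0:1, n), U = U, Delta = D)
    mc <- fit_cox_arm(src, 1, "censoring")
    expect_equal(length(mc$baseline_times), 1L)
    expect_equal(mc$baseline_times, cens_at)
    ## hand-computed jump: (#censored at risk-set) / sum exp(beta z)
    keep <- src$A == 1
    risk_at <- src$U[keep] >= cens_at
    z <- src$X[keep, , drop = FALSE]
    expect_equal(mc$baseline_increments,
                 sum(src$Delta[keep] == 0) /
                   sum(exp(z[risk_at, ] * mc$beta)), tolerance = 1e-12)
  })
})

test_that("Cox fit recovers the benchmark arm-0 hazard at large n", {
  ## lambda(t | A=0, x) = exp(t) exp(-2.5 - 1.5 x1 - x2 - 0.7 x3)
  with_seed_test(35, {
    n <- 20000
    X <- matrix(rnorm(n * 3), ncol = 3)
    k <- exp(-2.5 - 1.5 * X[, 1] - X[, 2] - 0.7 * X[, 3])
    T0 <- invert_exp_hazard(k, rexp(n))
    src <- source_sample(X, A = c(1, 1, rep(0, n - 2)), U = T0,
                         Delta = rep(1, n))
    m <- fit_cox_arm(src, 0, "survival")
    ## refit with coxph to obtain standard errors for the 3-SE criterion
    keep <- src$A == 0
    cf <- survival::coxph(survival::Surv(src$U[keep], src$Delta[keep]) ~
                            src$X[keep, ], ties = "breslow")
    se <- sqrt(diag(cf$var))
    expect_true(all(abs(m$beta - c(-1.5, -1, -0.7)) < 3 * se))
    expect_equal(m$beta, unname(coef(cf)), tolerance = 1e-6)
    ## Breslow baseline tracks exp(-2.5)(e^t - 1) pointwise
    for (t in c(0.3, 0.6, 1)) {
      L0 <- sum(m$baseline_increments[m$baseline_times <= t])
      expect_equal(L0, exp(-2.5) * expm1(t), tolerance = 0.05)
    }
    ## fitted survival matches the closed form at x = 0
    s_fit <- predict_survival(m, 0.5, c(0, 0, 0))
    expect_equal(s_fit, exp(-exp(-2.5) * expm1(0.5)), tolerance = 0.01)
  })
})

test_that("survival predictions are proper curves", {
  m <- hand_hazard_model(beta = c(0.3), times = c(0.4, 1, 2),
                         increments = c(0.1, 0.2, 0.5))
  x <- matrix(c(-1, 0, 2), ncol = 1)
  tt <- c(0, 0.39, 0.4, 1.5, 2, 10)
  S <- surv_matrix(m, x, tt)
  expect_true(all(S > 0 & S <= 1))
  expect_equal(S[, 1], rep(1, 3))                    # S(0) = 1
  expect_true(all(diff(t(S)) <= 1e-14))              # nonincreasing in t
  ## beyond the last baseline time the cumulative value is carried forward
  expect_equal(S[, 6], S[, 5])
  ## beta = 0, Lambda0(t) = t gives exp(-t)
  m2 <- hand_hazard_model(beta = 0, times = c(0.5, 1), increments = c(0.5, 0.5))
  expect_equal(unname(predict_survival(m2, 1, 0)), exp(-1))
})

test_that("mu and Q reduce correctly at the boundaries", {
  ## S(t|a,x) = exp(-t): hand model with a dense unit-rate baseline
  steps <- seq(0.01, 3, by = 0.01)
  m <- hand_hazard_model(0, steps, rep(0.01, length(steps)))
  ns <- nuisance_set(oracle_propensity(function(X) rep(0.5, nrow(X))),
                     survival = list(m, m), censoring = no_censoring_models(1))
  mq <- derive_mu_Q(ns, surv_prob(1))
  x <- matrix(0, 1, 1)
  ## u = 0: Q(0) = mu = S(t)
  expect_equal(mq$Q(0, 1, x), mq$mu(1, x))
  ## u > t: Q = 1
  expect_equal(mq$Q(2.5, 0, x), 1)
  ## closed form S(t)=e^{-t}: Q(0.5) at t = 1 is e^{-0.5}
  expect_equal(mq$Q(0.5, 1, x), exp(-0.5), tolerance = 1e-10)
})

test_that("fitted nuisances serialize to JSON and back", {
  skip_if_not_installed("jsonlite")
  src <- toy_source(n = 30, censor_frac = 0.3)
  ns <- suppressWarnings(fit_nuisances(src))
  js <- nuisances_to_json(ns)
  obj <- jsonlite::fromJSON(js, simplifyDataFrame = FALSE)
  expect_equal(obj$propensity$theta, ns$propensity$theta, tolerance = 1e-12)
  expect_equal(obj$survival[[2]]$beta, ns$survival[[2]]$beta,
               tolerance = 1e-12)
})
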
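## Shared fixtures and independent oracles used across the suite. Everything
## is generated in code; no stored data.

## Small uncensored source sample with both arms.
toy_source <- function(n = 8, seed = 1, p = 2, censor_frac = 0) {
  with_seed_test(seed, {
    X <- matrix(round(rnorm(n * p), 2), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    A <- rep_len(c(0, 1), n)
    U <- round(rexp(n, 0.6) + 0.05, 3)
    Delta <- rep(1, n)
    if (censor_frac > 0) {
      nc <- max(1L, round(censor_frac * n))
      Delta[sample.int(n, nc)] <- 0
    }
    source_sample(X, A, U, Delta)
  })
}

toy_target <- function(m = 6, seed = 2, p = 2, e = 1) {
  with_seed_test(seed, {
    X <- matrix(round(rnorm(m * p), 2), m, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    target_sample(X, rep(e, m))
  })
}

## seed helper mirroring the package-internal one (kept independent)
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Step-function constructors for hand-built nuisance models in toys: a
## "hand hazard model" with explicit baseline jumps and per-subject risk
## given by exp(beta' x); reuses the package's cox_arm_model prediction
## methods (pure step-function arithmetic, verified independently below).
hand_hazard_model <- function(beta, times, increments,
                              features = features_identity()) {
  structure(list(beta = beta, baseline_times = times,
                 baseline_increments = increments, features = features,
                 arm = NA, role = "hand"),
            class = "cox_arm_model")
}

## Zero-censoring nuisance pair: S_C identically 1, Lambda_C identically 0.
no_censoring_models <- function(p) {
  list(hand_hazard_model(rep(0, p), numeric(0), numeric(0)),
       hand_hazard_model(rep(0, p), numeric(0), numeric(0)))
}

## ---------------------------------------------------------------------------
## Independent brute-force oracles (slow, loop-based, no reuse of package
## internals beyond plain prediction calls).

## Survival/censoring prediction by explicit step-function evaluation.
oracle_step_surv <- function(beta, times, increments, x, t) {
  L0 <- 0
  if (length(times)) L0 <- sum(increments[times <= t])
  exp(-L0 * exp(sum(beta * x)))
}

## Brute-force expansion of the augmented estimator for one rule on an
## enumerated sample: loops over subjects, grid times and censoring jump
## times. `models` is a list with propensity function pA(x), survival and
## censoring step models per arm (beta/times/increments lists).
brute_force_curve <- function(method, src, tgt, models, q, itr, grid,
                              hcap = max(grid)) {
  n <- src$n
  d_src <- apply_itr(itr, src$X)
  vals <- numeric(length(grid))
  sstep <- function(role, arm, x, t)
    oracle_step_surv(models[[role]][[arm + 1]]$beta,
                     models[[role]][[arm + 1]]$times,
                     models[[role]][[arm + 1]]$increments, x, t)
  for (g in seq_along(grid)) {
    t <- grid[g]
    src_sum <- 0
    for (i in seq_len(n)) {
      x <- src$X[i, ]; a <- src$A[i]; u <- src$U[i]; del <- src$Delta[i]
      di <- d_src[i]
      pa <- models$propensity(x)
      pid <- if (di == 1) pa else 1 - pa
      cons <- as.numeric(a == di)
      ucap <- min(u, hcap)
      dcap <- max(del, as.numeric(u >= hcap))
      ipw <- dcap * as.numeric(u >= t) / sstep("censoring", a, x, ucap)
      or <- sstep("survival", a, x, t)
      ## martingale augmentation by explicit jump enumeration
      jt <- models$censoring[[a + 1]]$times
      jinc <- models$censoring[[a + 1]]$increments
      Jt <- 0
      riskc <- exp(sum(models$censoring[[a + 1]]$beta * x))
      if (length(jt)) for (k in seq_along(jt)) {
        u_k <- jt[k]
        if (u_k > min(u, hcap)) next
        dLc <- jinc[k] * riskc
        w <- if (u_k <= t)
          sstep("survival", a, x, t) /
            (sstep("survival", a, x, u_k) * sstep("censoring", a, x, u_k))
        else 1 / sstep("censoring", a, x, u_k)
        Jt <- Jt - w * dLc
      }
      if (del == 0 && u < hcap) {   # own censoring jump
        w <- if (u <= t)
          sstep("survival", a, x, t) /
            (sstep("survival", a, x, u) * sstep("censoring", a, x, u))
        else 1 / sstep("censoring", a, x, u)
        Jt <- Jt + w
      }
      psi <- cons / pid * (ipw - or + Jt)
      src_sum <- src_sum + switch(method,
        acw = q[i] * psi,
        dr_source = psi / n,
        naive = cons / pid * ipw / n,
        cw_ipw = q[i] * cons / pid * ipw,
        cw_or = q[i] * sstep("survival", di, x, t),
        0)
    }
    tgt_sum <- 0
    if (method %in% c("acw", "or_t") && !is.null(tgt)) {
      d_tgt <- apply_itr(itr, tgt$X)
      vw <- if (method == "acw") tgt$e / sum(tgt$e) else rep(1 / tgt$m, tgt$m)
      for (j in seq_len(tgt$m))
        tgt_sum <- tgt_sum + vw[j] * sstep("survival", d_tgt[j], tgt$X[j, ], t)
    }
    if (method == "dr_source") {
      for (i in seq_len(n))
        tgt_sum <- tgt_sum + sstep("survival", d_src[i], src$X[i, ], t) / n
    }
    vals[g] <- src_sum + tgt_sum
  }
  vals
}

## Hand-built models list matching no covariate effects by default.
toy_models <- function(p, pA = 0.5,
                       surv0 = list(times = c(0.5, 1.5), inc = c(0.2, 0.3)),
                       surv1 = list(times = c(0.7, 2.0), inc = c(0.1, 0.4)),
                       cens0 = list(times = numeric(0), inc = numeric(0)),
                       cens1 = list(times = numeric(0), inc = numeric(0)),
                       beta_s = NULL, beta_c = NULL) {
  if (is.null(beta_s)) beta_s <- rep(0, p)
  if (is.null(beta_c)) beta_c <- rep(0, p)
  list(propensity = function(x) pA,
       survival = list(list(beta = beta_s, times = surv0$times,
                            increments = surv0$inc),
                       list(beta = beta_s, times = surv1$times,
                            increments = surv1$inc)),
       censoring = list(list(beta = beta_c, times = cens0$times,
                             increments = cens0$inc),
                        list(beta = beta_c, times = cens1$times,
                             increments = cens1$inc)))
}

## Package nuisance_set equivalent of toy_models().
toy_nuisance_set <- function(models, p) {
  mk <- function(m) hand_hazard_model(m$beta, m$times, m$increments)
  nuisance_set(
    propensity = oracle_propensity(function(X)
      rep(models$propensity(X[1, ]), nrow(X)), eps = 1e-8),
    survival = lapply(models$survival, mk),
    censoring = lapply(models$censoring, mk))
}

## crude projected-gradient feasibility oracle for the entropy problem
projected_gradient_calibration <- function(G, gbar, iters = 20000) {
  n <- nrow(G)
  q <- rep(1 / n, n)
  A <- cbind(1, G)               # equality constraints: sum q = 1, G'q = gbar
  b <- c(1, gbar)
  P <- diag(n) - A %*% solve(crossprod(A), t(A))  # projector onto null space
  q <- q + drop(A %*% solve(crossprod(A), b - drop(crossprod(A, q))))
  for (i in seq_len(iters)) {
    gr <- log(pmax(q, 1e-12)) + 1
    q_new <- q - 0.002 * drop(P %*% gr)
    q_new <- pmax(q_new, 1e-12)
    ## re-project onto the affine constraints
    q_new <- q_new + drop(A %*% solve(crossprod(A), b - drop(crossprod(A, q_new))))
    if (all(q_new > 0)) q <- q_new
  }
  q
}
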
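test_that("closed-form hazard inversion is exact", {
  expect_equal(invert_exp_hazard(2, 2), log(2))
  expect_equal(invert_exp_hazard(0.3, 0), 0)
  expect_error(invert_exp_hazard(0, 1), "positive")
  ## distributional check against the closed-form survival law
  with_seed_test(61, {
    k <- exp(-2.5)
    tt <- invert_exp_hazard(rep(k, 1e5), rexp(1e5))
    for (t0 in c(0.5, 1, 2))
      expect_equal(mean(tt > t0), exp(-k * expm1(t0)), tolerance = 0.01)
  })
})

test_that("simulated covariates honor truncation and correlation", {
  cfg <- sim_config(N = 50000, m = 2000)
  pop <- simulate_population(cfg, seed = 3)
  expect_true(all(abs(pop$X) <= 4))
  expect_equal(cor(pop$X[, 1], pop$X[, 3]), 0.2, tolerance = 0.02)
  expect_equal(cor(pop$X[, 1], pop$X[, 2]), 0, tolerance = 0.02)
  expect_equal(unname(colMeans(pop$X)), rep(0, 3), tolerance = 0.02)
  ## marginal survival law at x = 0 in arm 0
  expect_equal(mean(pop$T0[rowSums(abs(pop$X)) < 0.5] > 1),
               exp(-exp(-2.5) * expm1(1)), tolerance = 0.05)
})

test_that("population generation is reproducible and stream-separated", {
  cfg <- sim_config(N = 5000, m = 500)
  p1 <- simulate_population(cfg, seed = 8)
  p2 <- simulate_population(cfg, seed = 8)
  expect_identical(p1$X, p2$X)
  expect_identical(p1$U, p2$U)
  ## a different censoring scale must not perturb covariates or survival draws
  p3 <- simulate_population(sim_config(N = 5000, m = 500, censor_scale = 0.2),
                            seed = 8)
  expect_identical(p1$X, p3$X)
  expect_identical(p1$T0, p3$T0)
  expect_false(identical(p1$C0, p3$C0))
})

test_that("sample drawing follows the stated designs", {
  cfg <- sim_config(N = 50000, m = 2000)
  pop <- simulate_population(cfg, seed = 12)
  s <- draw_samples(pop, seed = 12)
  expect_s3_class(s$src, "source_sample")
  expect_equal(s$tgt$m, 2000)
  expect_true(all(s$tgt$e == 50000 / 2000))        # constant design weight
  expect_equal(s$n, length(s$source_rows))
  ## realized source size close to N * mean(piS)
  expect_equal(s$n, sum(pop$piS), tolerance = 0.15 * sum(pop$piS))
  ## same seed reproduces the draw
  s2 <- draw_samples(pop, seed = 12)
  expect_identical(s$source_rows, s2$source_rows)
  expect_identical(s$target_rows, s2$target_rows)
})

test_that("true value and PCD are plug-in averages", {
  ## 5-subject hand-built population with printed potential outcomes
  pop <- list(X = matrix(c(-1, -0.5, 0, 0.5, 1), ncol = 1,
                         dimnames = list(NULL, "X1")),
              T0 = c(1, 2, 3, 4, 5), T1 = c(5, 4, 3, 2, 1),
              config = list(L = 4))
  class(pop) <- "sim_population"
  itr <- linear_itr(c(0, 1))          # treat iff x >= 0
  ## d = (0,0,1,1,1): outcomes (1, 2, 3, 2, 1) capped at 4
  out <- true_value_and_pcd(itr, pop, L = 4)
  expect_equal(out$true_value, mean(c(1, 2, 3, 2, 1)))
  ## all-treat rule: min(T1, 4) = (4, 4, 3, 2, 1)
  all_treat <- linear_itr(c(100, 1))
  expect_equal(true_value_and_pcd(all_treat, pop, 4)$true_value,
               mean(c(4, 4, 3, 2, 1)))
  ## PCD of a rule against itself is 1; the complementary rule (strict sign
  ## flip, disagreeing on every subject) has PCD 0
  expect_equal(true_value_and_pcd(itr, pop, 4, eta_star = itr)$pcd, 1)
  flip <- linear_itr(c(-1e-9, -1))
  expect_equal(true_value_and_pcd(flip, pop, 4, eta_star = itr)$pcd, 0)
  ## null treatment effect: value is rule-independent
  pop$T1 <- pop$T0
  expect_equal(true_value_and_pcd(itr, pop, 4)$true_value,
               mean(pmin(pop$T0, 4)))
})

test_that("scenario specifications assign the stated working models", {
  s1 <- scenario_nuisances(1)
  expect_null(s1$calibration$g_functions)
  X <- matrix(1:6 / 10, 2, 3, dimnames = list(NULL, c("X1", "X2", "X3")))
  ## correct outcome features carry the curvature terms of the true hazard
  Z <- s1$feature_maps$survival(X)
  expect_equal(ncol(Z), 5)
  expect_equal(unname(Z[, 4]), X[, 2]^2)
  expect_equal(unname(Z[, 5]), X[, 1] * X[, 3])
  expect_equal(s1$feature_maps$censoring(X), X)

  s2 <- scenario_nuisances(2)
  ## the wrong sampling model balances the first moment of X1 only
  expect_equal(names(s2$calibration$g_functions), "X1")
  expect_equal(s2$calibration$g_functions$X1(X), X[, 1])
  expect_equal(unname(s2$feature_maps$propensity(X)[, 1]), exp(X[, 3]))
  expect_equal(ncol(s2$feature_maps$survival(X)), 5)   # outcome still correct
  expect_equal(unname(s2$feature_maps$censoring(X)), unname(exp(X)))

  s4 <- scenario_nuisances(4)
  expect_equal(unname(s4$feature_maps$survival(X)), unname(exp(X)))
  expect_equal(names(s4$calibration$g_functions), "X1")
})

test_that("simulated studies export to CSV and read back", {
  cfg <- sim_config(N = 20000, m = 500)
  pop <- simulate_population(cfg, seed = 5)
  s <- draw_samples(pop, seed = 5)
  td <- withr::local_tempdir()
  write_simulation_csv(s, td)
  schema <- list(covariates = c("X1", "X2", "X3"), treatment = "A",
                 time = "U", event = "Delta", design_weight = "e")
  src2 <- read_source_sample(file.path(td, "source.csv"), schema)
  tgt2 <- read_target_sample(file.path(td, "target.csv"), schema)
  expect_equal(src2$n, s$src$n)
  expect_equal(unname(tgt2$e), unname(s$tgt$e))
  expect_equal(unname(src2$X), unname(s$src$X), tolerance = 1e-12)
})
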
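test_that("sample constructors validate their invariants", {
  X <- cbind(x1 = c(0.1, -0.3, 1.2, 0.5), x2 = c(1, 0, 1, 0))
  src <- source_sample(X, A = c(0, 1, 0, 1), U = c(1, 2, 3, 4),
                       Delta = c(1, 0, 1, 1))
  expect_s3_class(src, "source_sample")
  expect_equal(src$n, 4L)
  expect_equal(src$p, 2L)

  expect_error(source_sample(X, A = c(0, 1, 2, 1), U = 1:4, Delta = rep(1, 4)),
               "0/1")
  expect_error(source_sample(X, A = c(0, 1, 0, 1), U = c(-1, 2, 3, 4),
                             Delta = rep(1, 4)), "nonnegative")
  expect_error(source_sample(X, A = rep(1, 4), U = 1:4, Delta = rep(1, 4)),
               "both treatment arms")
  Xna <- X; Xna[2, 1] <- NA
  expect_error(source_sample(Xna, A = c(0, 1, 0, 1), U = 1:4,
                             Delta = rep(1, 4)), "missing")

  tgt <- target_sample(X, e = 2.5)
  expect_equal(tgt$e, rep(2.5, 4))
  expect_error(target_sample(X, e = c(1, 1, -2, 1)), "positive")
})

test_that("linear_itr normalizes by the anchor coefficient", {
  expect_equal(linear_itr(c(0, 0, 0, 1))$eta, c(0, 0, 0, 1))
  expect_equal(linear_itr(c(4, -2, 6, 2))$eta, c(2, -1, 3, 1))
  ## an already-normalized rule is unchanged (the fitted real-data rule of
  ## the bicarbonate ICU analysis)
  eta6 <- c(22.9, -36.1, 87.4, -9.8, 33.7, 1.0)
  expect_identical(linear_itr(eta6)$eta, eta6)
  ## sign of the anchor is preserved, magnitude normalized
  expect_equal(linear_itr(c(2, -4, -2))$eta, c(1, -2, -1))
  expect_error(linear_itr(c(1, 2, 0)), "anchor")
  expect_error(linear_itr(c(1, NA, 1)), "finite")
})

test_that("apply_itr computes the sign rule with ties treated", {
  ## tie at exactly zero treats
  itr <- linear_itr(c(0, 0, 0, 1))
  expect_equal(apply_itr(itr, matrix(c(5, -1, 0), 1)), 1)
  ## hand-computed scores for the five-covariate ICU rule:
  ## patient 1: 22.9 + 87.4 - 9.8*10 + 60 = 72.3 -> treat
  ## patient 2: 22.9 - 36.1 - 98 + 33.7 + 70 = -7.5 -> no treatment
  itr6 <- linear_itr(c(22.9, -36.1, 87.4, -9.8, 33.7, 1.0))
  pats <- rbind(c(0, 1, 10, 0, 60),
                c(1, 0, 10, 1, 70))
  colnames(pats) <- c("SEPSIS", "AKIN", "SOFA", "SEX", "AGE")
  expect_equal(apply_itr(itr6, pats), c(1, 0))
  expect_error(apply_itr(itr6, pats[, 1:4]), "covariates")
})

test_that("rules are scale-invariant, deterministic, and sign-flippable", {
  with_seed_test(4, {
    X <- matrix(rnorm(200 * 3), ncol = 3)
    for (rep in 1:10) {
      raw <- c(rnorm(3), runif(1, 0.2, 3))
      d1 <- apply_itr(linear_itr(raw), X)
      d2 <- apply_itr(linear_itr(5.7 * raw), X)
      expect_identical(d1, d2)
      expect_true(all(d1 %in% c(0, 1)))
      ## negating the raw score flips every decision off the boundary
      score <- cbind(1, X) %*% raw
      off <- abs(score) > 1e-12
      d_neg <- apply_itr(linear_itr(-raw), X)
      expect_equal(d_neg[off], 1 - d1[off])
    }
  })
})

test_that("CSV round trip preserves both samples under a schema", {
  schema <- list(covariates = c("age", "sofa"), treatment = "arm",
                 time = "followup", event = "died", design_weight = "wt")
  src <- toy_source(n = 10, censor_frac = 0.3)
  tgt <- toy_target(m = 7, e = 3)
  td <- withr::local_tempdir()
  sf <- file.path(td, "s.csv"); tf <- file.path(td, "t.csv")
  utils::write.csv(data.frame(age = src$X[, 1], sofa = src$X[, 2],
                              arm = src$A, followup = src$U, died = src$Delta),
                   sf, row.names = FALSE)
  utils::write.csv(data.frame(age = tgt$X[, 1], sofa = tgt$X[, 2], wt = tgt$e),
                   tf, row.names = FALSE)
  src2 <- read_source_sample(sf, schema)
  tgt2 <- read_target_sample(tf, schema)
  expect_equal(unname(src2$X), unname(src$X))
  expect_equal(src2$Delta, src$Delta)
  expect_equal(tgt2$e, tgt$e)
  expect_error(read_source_sample(tf, schema), "missing columns")

  ## schema loadable from YAML
  yf <- file.path(td, "schema.yaml")
  writeLines(c("covariates:", " - age", " - sofa", "treatment: arm",
               "time: followup", "event: died", "design_weight: wt"), yf)
  sch2 <- read_schema(yf)
  expect_equal(sch2$covariates, c("age", "sofa"))
  expect_equal(sch2$event, "died")
})

test_that("transform specifications validate horizons", {
  tr <- rmst(4)
  expect_equal(tr$kind, "rmst")
  expect_equal(tr$h, 4)
  sp <- surv_prob(2, h = 3)
  expect_equal(sp$horizon, 2)
  expect_error(rmst(-1))
  expect_error(surv_prob(2, h = 1))
})
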
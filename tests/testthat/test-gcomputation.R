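test_that("the Q-model recovers generating coefficients at large n", {
  set.seed(1)
  n <- 1e5
  c1 <- rbinom(n, 1, 0.5)
  tr <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 1 * tr + 0.5 * c1))
  fr <- new_treatment_frame(tr, y, matrix(c1, ncol = 1,
                                          dimnames = list(NULL, "C1")))
  m <- fit_q_model(fr)
  expect_true(m$converged)
  expect_lt(abs(m$alpha - 1), 0.03)
  expect_lt(abs(m$intercept + 1), 0.03)
  expect_lt(abs(m$beta[["C1"]] - 0.5), 0.05)
  expect_equal(length(m$beta), ncol(fr$C))
})

test_that("a null outcome yields a near-zero treatment coefficient", {
  set.seed(2)
  n <- 1e4
  fr <- new_treatment_frame(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                            matrix(rbinom(n, 1, 0.5), ncol = 1))
  expect_lt(abs(fit_q_model(fr)$alpha), 0.1)
})

test_that("perfect separation and rank deficiency raise explicit errors", {
  tr <- rep(0:1, each = 25)
  fr_sep <- new_treatment_frame(tr, tr, matrix(rbinom(50, 1, 0.5), ncol = 1))
  expect_error(suppressWarnings(fit_q_model(fr_sep)), "separation")

  set.seed(3)
  c1 <- rbinom(60, 1, 0.5)
  fr_rd <- new_treatment_frame(rep(0:1, 30), rbinom(60, 1, 0.5),
                               cbind(C1 = c1, C2 = c1)) # duplicated column
  expect_error(fit_q_model(fr_rd), "collinear")
})

test_that("standardised risk collapses to arm proportions without confounders", {
  set.seed(4)
  n <- 400
  tr <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + tr))
  fr <- new_treatment_frame(tr, y, NULL)
  m <- fit_q_model(fr)
  expect_equal(standardized_risk(m, fr, 1), mean(y[tr == 1]),
               tolerance = 1e-9)
  expect_equal(standardized_risk(m, fr, 0), mean(y[tr == 0]),
               tolerance = 1e-9)
  # and the ATE equals the raw risk difference exactly
  pt <- ate(fr)
  expect_equal(pt$delta, mean(y[tr == 1]) - mean(y[tr == 0]),
               tolerance = 1e-12)
  expect_error(standardized_risk(m, fr, 2), "0 or 1")
})

test_that("saturated standardisation matches the nonparametric oracle", {
  set.seed(5)
  fr <- random_stratified_frame()
  m <- fit_q_model(fr, interactions = TRUE)
  for (a in 0:1) {
    expect_equal(standardized_risk(m, fr, a),
                 np_standardize(fr$T, fr$Y, fr$C[, 1], a),
                 tolerance = 1e-10)
  }
})

test_that("gcomp point estimates satisfy their defining identities", {
  sim <- generate_cohort(generator_spec(n = 1500), seed = 6)
  pt <- ate(sim$data)
  expect_identical(pt$delta, pt$pi1 - pt$pi0)
  expect_equal(pt$log_or,
               log(pt$pi1 / (1 - pt$pi1)) - log(pt$pi0 / (1 - pt$pi0)))
  dec <- or_decomposition(sim$data)
  expect_equal(dec$marginal_or, exp(pt$log_or), tolerance = 1e-12)
  expect_equal(dec$conditional_or, exp(pt$model$alpha), tolerance = 1e-12)
  expect_true(all(c(dec$raw_or, dec$conditional_or, dec$marginal_or) > 0))
})

test_that("marginal log odds ratio follows its closed form", {
  expect_equal(marginal_log_or(0.5, 0.5), 0)
  expect_equal(marginal_log_or(0.8, 0.5), log(4))
  expect_error(marginal_log_or(1, 0.5), "boundary")
  expect_error(marginal_log_or(0.5, 0), "boundary")
})

test_that("the raw odds ratio is the 2x2 cross-product ratio", {
  tr <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  fr <- new_treatment_frame(tr, y, NULL)
  dec <- or_decomposition(fr)
  expect_equal(dec$raw_or, 6.0, tolerance = 1e-9)
  expect_equal(dec$conditional_or, dec$raw_or, tolerance = 1e-9)
  expect_equal(dec$marginal_or, dec$raw_or, tolerance = 1e-9)

  fr0 <- new_treatment_frame(c(1, 1, 0, 0), c(1, 1, 1, 0), NULL)
  expect_error(suppressWarnings(or_decomposition(fr0)), "cell")
})

test_that("bootstrap inference is bit-identical under a fixed seed", {
  sim <- generate_cohort(generator_spec(n = 300), seed = 7)
  r1 <- bootstrap_inference(sim$data, B = 100, seed = 12)
  r2 <- bootstrap_inference(sim$data, B = 100, seed = 12)
  expect_identical(r1, r2)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_lte(r1$ci_delta[1], r1$ci_delta[2])
  expect_lte(r1$ci_log_or[1], r1$ci_log_or[2])
  expect_error(bootstrap_inference(sim$data, B = 1, seed = 1), "at least 2")
  expect_error(bootstrap_inference(sim$data, B = 100), "seed")
})

test_that("normal-approximation intervals are centred on the estimate", {
  sim <- generate_cohort(generator_spec(n = 400), seed = 8)
  r <- bootstrap_inference(sim$data, B = 200, seed = 3, ci_method = "normal")
  expect_equal(mean(r$ci_delta), r$delta, tolerance = 1e-12)
  expect_equal(diff(r$ci_delta), 2 * qnorm(0.975) * r$se_delta,
               tolerance = 1e-12)
})

test_that("degenerate resamples are redrawn and counted", {
  set.seed(9)
  n <- 40
  tr <- c(rep(1, 3), rep(0, n - 3))        # rare treatment: misses happen
  y <- rbinom(n, 1, 0.4 + 0.2 * tr)
  y[1:3] <- c(1, 0, 1)
  fr <- new_treatment_frame(tr, y, NULL)
  r <- bootstrap_inference(fr, B = 300, seed = 10)
  expect_gte(r$n_redraws, 1)
  expect_equal(r$n_boot, 300)
})
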
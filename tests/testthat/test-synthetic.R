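test_that("exact truth matches closed-form logistic arithmetic", {
  sp <- generator_spec(n = 100, conf_prev = 0.5, gamma = c(0, 0),
                       intercept = 0, alpha = log(4), beta = 0)
  tr <- true_effects(sp)
  expect_equal(tr$true_pi1, 0.8)
  expect_equal(tr$true_pi0, 0.5)
  expect_equal(tr$true_ate, 0.3)
  expect_equal(tr$true_marginal_or, 4)

  tr0 <- true_effects(generator_spec(alpha = 0))
  expect_equal(tr0$true_ate, 0)
  expect_equal(tr0$true_marginal_or, 1)
})

test_that("exhaustive-stratum truth agrees with Monte-Carlo evaluation", {
  sp <- generator_spec()
  tr <- true_effects(sp)
  set.seed(99)
  C <- vapply(sp$conf_prev, function(p) rbinom(2e5, 1, p), numeric(2e5))
  mc_risk <- function(a) {
    mean(plogis(sp$intercept + sp$alpha * a + drop(C %*% sp$beta)))
  }
  expect_equal(tr$true_pi1, mc_risk(1), tolerance = 0.005)
  expect_equal(tr$true_pi0, mc_risk(0), tolerance = 0.005)
})

test_that("generation is deterministic under a fixed seed, in both modes", {
  a <- generate_cohort(seed = 17)
  b <- generate_cohort(seed = 17)
  expect_identical(a$data$T, b$data$T)
  expect_identical(a$data$Y, b$data$Y)
  expect_identical(a$data$C, b$data$C)
  t1 <- generate_cohort(seed = 17, table1_mode = TRUE)$data
  t2 <- generate_cohort(seed = 17, table1_mode = TRUE)$data
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_error(generate_cohort(), "seed")
})

test_that("clinical-schema output passes cohort validation and encodes the frame", {
  sim <- generate_cohort(seed = 23, table1_mode = TRUE)
  ch <- sim$data
  expect_s3_class(ch, "cohort_table")
  expect_true(all(ch$Thallium %in% c(3, 6, 7)))
  expect_true(all(ch[["Number of vessels fluro"]] %in% 0:3))
  expect_true(all(ch$Cholesterol >= 126 & ch$Cholesterol <= 564))
  # the thallium frame recovers the structural (T, C) exactly
  fr <- make_treatment_frame(ch, "thallium")
  expect_identical(fr$T, as.integer(ch$Thallium == 7))
  expect_identical(unname(fr$C[, "cholesterol_bin"]),
                   as.numeric(ch$Cholesterol >= 240))
})

test_that("empirical prevalences converge to spec-implied values", {
  sp <- generator_spec(n = 1e5)
  sim <- generate_cohort(sp, seed = 29)
  grid <- as.matrix(expand.grid(rep(list(0:1), 3)))
  w <- apply(grid, 1, function(cr) prod(ifelse(cr == 1, sp$conf_prev,
                                               1 - sp$conf_prev)))
  p_treat <- sum(w * plogis(sp$gamma[1] + drop(grid %*% sp$gamma[-1])))
  expect_lt(abs(mean(sim$data$T) - p_treat), 0.01)
  for (j in 1:3) {
    expect_lt(abs(mean(sim$data$C[, j]) - sp$conf_prev[j]), 0.01)
  }
  # outcome prevalence: mix over treatment assignment within strata
  p_y <- sum(vapply(seq_len(nrow(grid)), function(g) {
    pt <- plogis(sp$gamma[1] + sum(grid[g, ] * sp$gamma[-1]))
    w[g] * (pt * plogis(sp$intercept + sp$alpha + sum(grid[g, ] * sp$beta)) +
            (1 - pt) * plogis(sp$intercept + sum(grid[g, ] * sp$beta)))
  }, numeric(1)))
  expect_lt(abs(mean(sim$data$Y) - p_y), 0.01)
})

test_that("randomised treatment collapses raw, conditional, and marginal", {
  sp <- generator_spec(n = 5e4, gamma = c(0, 0, 0, 0))
  sim <- generate_cohort(sp, seed = 31)
  dec <- or_decomposition(sim$data)
  truth <- sim$truth
  # no confounding: raw and marginal both converge to the true marginal OR
  expect_lt(abs(dec$raw_or - truth$true_marginal_or), 0.15)
  expect_lt(abs(dec$marginal_or - truth$true_marginal_or), 0.15)
})

test_that("g-computation removes the confounding bias the generator plants", {
  sp <- generator_spec(n = 5000, gamma = c(-1, 2.0, 1.8, -1.5),
                       beta = c(1.5, -1.2, 2.0))
  truth <- true_effects(sp)
  wins <- vapply(1:30, function(s) {
    sim <- generate_cohort(sp, seed = 400 + s)
    fr <- sim$data
    raw_rd <- mean(fr$Y[fr$T == 1]) - mean(fr$Y[fr$T == 0])
    est <- ate(fr)$delta
    abs(est - truth$true_ate) < abs(raw_rd - truth$true_ate)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("specification errors are caught at construction", {
  expect_error(generator_spec(n = 0), "n must")
  expect_error(generator_spec(conf_prev = c(0.5, 1)), "in \\(0,1\\)")
  expect_error(generator_spec(gamma = c(1, 1)), "length")
  expect_error(generator_spec(beta = 1), "per confounder")
  expect_error(generate_cohort(generator_spec(conf_prev = c(0.5, 0.5),
                                              gamma = c(0, 1, 1),
                                              beta = c(1, 1)),
                               seed = 1, table1_mode = TRUE),
               "three confounders")
})
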
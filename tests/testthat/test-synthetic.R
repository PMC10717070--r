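test_that("variance components invert the ICC definition for both families", {
  vc <- variance_components_from_icc(0.05, "gaussian", 1)
  expect_equal(vc$sigma_b2, 0.05)
  expect_equal(vc$sigma_w2, 0.95)

  vc <- variance_components_from_icc(0.5, "binomial")
  expect_equal(vc$sigma_b2, pi^2 / 3)

  vc <- variance_components_from_icc(0.02, "binomial")
  expect_equal(round(vc$sigma_b2, 5), 0.06714)
  # round-trips through the model-based ICC
  expect_equal(model_icc(vc$sigma_b2, family = "binomial")$value, 0.02)

  # round trip across a grid, both families
  for (rho in seq(0, 0.99, by = 0.09)) {
    g <- variance_components_from_icc(rho, "gaussian", 7)
    expect_equal(model_icc(g$sigma_b2, g$sigma_w2)$value, rho)
    b <- variance_components_from_icc(rho, "binomial")
    expect_equal(model_icc(b$sigma_b2, family = "binomial")$value, rho)
  }
  expect_error(variance_components_from_icc(1, "gaussian"), "\\[0, 1\\)")
  expect_error(variance_components_from_icc(0.1, "gaussian", 0), "> 0")
})

test_that("generator honours the degenerate worlds", {
  # icc = 0, effect = 0: pooled variance ~ total_variance, anova ICC ~ 0
  d <- simulate_crct(sim_config(n_clusters = 50, size_args = list(m = 20),
                                icc = 0, total_variance = 4,
                                treatment_effect = 0, seed = 2))
  expect_equal(var(d$y), 4, tolerance = 0.15)
  expect_lt(abs(anova_icc(d)$value), 0.03)

  # binary, sigma_b2 = 0, intercept 0: prevalence ~ 0.5
  db <- simulate_crct(sim_config(n_clusters = 40, size_args = list(m = 25),
                                 family = "binomial", icc = 0,
                                 treatment_effect = 0, intercept = 0, seed = 3))
  expect_equal(mean(db$y), 0.5, tolerance = 0.05)
})

test_that("allocation is exact at the ratio and the draw is seed-deterministic", {
  cfg <- sim_config(n_clusters = 99, allocation_ratio = c(2, 1),
                    size_args = list(m = 2), seed = 7)
  d <- simulate_crct(cfg)
  arm <- tapply(d$treatment, d$cluster, `[`, 1)
  expect_equal(sum(arm == 1), 66)
  expect_equal(sum(arm == 0), 33)

  expect_identical(as.data.frame(simulate_crct(cfg)),
                   as.data.frame(simulate_crct(cfg)))
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_crct(cfg)$y, simulate_crct(cfg2)$y))

  expect_error(simulate_crct(sim_config(n_clusters = 2,
                                        allocation_ratio = c(2, 1))),
               "fewer clusters")
})

test_that("MCAR deletion behaves and is reproducible", {
  d <- balanced_trial(K = 100, m = 100, icc = 0, effect = 0, seed = 5)
  expect_identical(apply_mcar_missingness(d, 0), d)

  d2 <- apply_mcar_missingness(d, 0.07, seed = 9)
  frac <- 1 - nrow(d2) / nrow(d)
  expect_gt(frac, 0.06); expect_lt(frac, 0.08)   # binomial bound, n = 10000

  expect_identical(as.data.frame(apply_mcar_missingness(d, 0.5, seed = 3)),
                   as.data.frame(apply_mcar_missingness(d, 0.5, seed = 3)))
})

test_that("generator recovers its target ICC on average (anova estimator)", {
  # Monte-Carlo oracle: the one-way ANOVA estimator pools both arms, so a
  # nonzero treatment effect contributes effect^2/4 of extra between-cluster
  # variance; the estimator converges to the *marginal* ICC
  # (sigma_b2 + effect^2/4) / (total + effect^2/4), and to the configured ICC
  # exactly when the effect is zero.
  run <- function(effect, n = 250) {
    vapply(seq_len(n), function(r)
      anova_icc(skewed_trial(K = 100, mean_size = 20, icc = 0.02,
                             effect = effect, seed = 5000 + r))$value,
      numeric(1))
  }
  v0 <- run(0)
  mc0 <- sd(v0) / sqrt(length(v0))
  expect_lt(abs(mean(v0) - 0.02), max(3 * mc0, 0.005))

  v1 <- run(-1)
  marg <- (0.02 * 25 + 0.25) / (25 + 0.25)
  mc1 <- sd(v1) / sqrt(length(v1))
  expect_lt(abs(mean(v1) - marg), max(3 * mc1, 0.005))
})
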
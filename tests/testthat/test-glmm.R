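test_that("LMM matches the lme4 oracle for REML and ML, balanced and skewed", {
  skip_if_not_installed("lme4")
  cases <- list(balanced_trial(K = 15, m = 8, icc = 0.1, effect = -1, seed = 21),
                skewed_trial(K = 25, mean_size = 12, icc = 0.03, effect = 0.5,
                             seed = 22,
                             covariates = list(list(name = "x", dist = "normal",
                                                    mean = 0, sd = 1, coef = 0.4))))
  for (d in cases) {
    df <- as.data.frame(d)
    cvs <- attr(d, "covariates")
    fml <- stats::as.formula(paste("y ~ treatment",
      if (length(cvs)) paste("+", paste(cvs, collapse = "+")) else "",
      "+ (1 | cluster)"))
    for (est in c("reml", "ml")) {
      fit <- fit_lmm(d, estimator = est)
      lfit <- lme4::lmer(fml, df, REML = (est == "reml"))
      expect_equal(unname(fit$beta), unname(lme4::fixef(lfit)), tolerance = 1e-5)
      expect_equal(fit$sigma_w2, sigma(lfit)^2, tolerance = 1e-5)
      expect_equal(fit$sigma_b2,
                   as.numeric(lme4::VarCorr(lfit)$cluster), tolerance = 1e-4)
      expect_equal(unname(sqrt(diag(fit$vcov_beta))),
                   unname(sqrt(diag(as.matrix(vcov(lfit))))), tolerance = 1e-5)
    }
  }
})

test_that("balanced REML equals the one-way ANOVA closed form", {
  d <- balanced_trial(K = 16, m = 6, icc = 0.2, effect = 1, seed = 31,
                      total_variance = 9)
  fit <- fit_lmm(d, estimator = "reml")
  # oracle: ANOVA mean squares adjusting for the cluster-level treatment
  df <- as.data.frame(d)
  cl_means <- tapply(df$y, df$cluster, mean)
  cl_trt <- tapply(df$treatment, df$cluster, `[`, 1)
  msb_model <- stats::anova(stats::lm(cl_means ~ cl_trt))["Residuals", "Mean Sq"] * 6
  msw <- stats::anova(stats::lm(y ~ cluster, df))["Residuals", "Mean Sq"]
  expect_equal(fit$sigma_w2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, max(0, (msb_model - msw) / 6), tolerance = 1e-6)
})

test_that("degenerate worlds collapse to OLS / plain logistic", {
  d <- balanced_trial(K = 40, m = 25, icc = 0, effect = 1, seed = 41)
  fit <- fit_lmm(d, estimator = "ml")
  ols <- stats::lm(y ~ treatment, as.data.frame(d))
  if (fit$sigma_b2 == 0) {
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
    expect_true(fit$icc$truncated)
    expect_equal(fit$icc$value, 0)
  } else {
    # tiny positive variance still allowed; estimates near OLS
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-2)
  }

  db <- simulate_crct(sim_config(n_clusters = 40, size_args = list(m = 25),
                                 family = "binomial", icc = 0,
                                 treatment_effect = 0.6, intercept = -0.5,
                                 seed = 42))
  fitb <- fit_logistic_glmm(db)
  glmb <- stats::glm(y ~ treatment, binomial, as.data.frame(db))
  expect_equal(unname(fitb$beta), unname(coef(glmb)), tolerance = 1e-3)
  expect_lt(fitb$sigma_b2, 0.02)
})

test_that("AGHQ logistic GLMM agrees with glmer and refines monotonically", {
  skip_if_not_installed("lme4")
  db <- simulate_crct(sim_config(n_clusters = 25, size_args = list(m = 12),
                                 family = "binomial", icc = 0.05,
                                 treatment_effect = 0.5, intercept = -1,
                                 seed = 51))
  df <- as.data.frame(db)
  fit <- fit_logistic_glmm(db, n_nodes = 10)
  gm <- lme4::glmer(y ~ treatment + (1 | cluster), df, binomial, nAGQ = 10)
  expect_equal(unname(fit$beta), unname(lme4::fixef(gm)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(gm)), tolerance = 1e-6)

  # 1 node is exactly the (adaptive) Laplace approximation
  fit1 <- fit_logistic_glmm(db, n_nodes = 1)
  gl <- lme4::glmer(y ~ treatment + (1 | cluster), df, binomial, nAGQ = 1)
  expect_equal(fit1$loglik, as.numeric(logLik(gl)), tolerance = 1e-6)

  # quadrature refinement: loglik is Cauchy in the number of nodes
  ll <- vapply(c(10, 20, 40), function(k)
    fit_logistic_glmm(db, n_nodes = k)$loglik, numeric(1))
  expect_lt(abs(ll[1] - ll[3]), 1e-6)
  expect_lt(abs(ll[2] - ll[3]), 1e-7)

  expect_error(fit_logistic_glmm(db, n_nodes = 0), ">= 1")
})

test_that("Gauss-Hermite rule integrates polynomials exactly", {
  gh <- gauss_hermite(10)
  # against closed-form moments of exp(-x^2): integral x^{2k} exp(-x^2)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^3), 0, tolerance = 1e-12)
})

test_that("Satterthwaite DoF hits the balanced closed form and boundary rule", {
  d <- simulate_crct(sim_config(n_clusters = 12, size_args = list(m = 8),
                                icc = 0.2, total_variance = 4,
                                treatment_effect = 0.5, seed = 1))
  fit <- fit_lmm(d, estimator = "reml")
  expect_gt(fit$sigma_b2, 0)
  nu <- satterthwaite_dof(fit)
  expect_lt(abs(nu - 10), 0.1)          # N - 2 for a cluster-level contrast

  d2 <- simulate_crct(sim_config(n_clusters = 30, size_args = list(m = 5),
                                 icc = 0.1, seed = 9, total_variance = 1))
  fit2 <- fit_lmm(d2)
  expect_lt(abs(satterthwaite_dof(fit2) - 28), 0.1)

  # boundary: sigma_b2 = 0 -> residual DoF
  d0 <- balanced_trial(K = 10, m = 5, icc = 0, effect = 0, seed = 13)
  fit0 <- fit_lmm(d0)
  if (fit0$sigma_b2 == 0) expect_equal(satterthwaite_dof(fit0), 50 - 2)

  expect_warning(satterthwaite_dof(fit_lmm(d, estimator = "ml")), "REML")
})

test_that("ML and REML effects agree on large balanced data; ICC never negative", {
  d <- balanced_trial(K = 60, m = 20, icc = 0.05, effect = -1, seed = 61)
  f1 <- fit_lmm(d, estimator = "ml"); f2 <- fit_lmm(d, estimator = "reml")
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-3)
  expect_gte(f1$icc$value, 0)
  expect_equal(f1$icc$value,
               model_icc(f1$sigma_b2, f1$sigma_w2)$value)
})
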
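test_that("independence GEE1 with identity link is exactly OLS", {
  d <- skewed_trial(K = 20, mean_size = 10, icc = 0.05, effect = -1, seed = 71)
  fit <- fit_gee1(d, structure = "independence")
  ols <- stats::lm(y ~ treatment, as.data.frame(d))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$alpha, 0)
})

test_that("exchangeable GEE1 matches the LMM ML effect on balanced data", {
  for (s in 1:5) {
    d <- balanced_trial(K = 20, m = 10, icc = 0.05, effect = -1, seed = 80 + s)
    g <- fit_gee1(d, structure = "exchangeable")
    l <- fit_lmm(d, estimator = "ml")
    expect_lt(max(abs(g$beta - l$beta)), 1e-4)
  }
})

test_that("the toy-fixture solution solves the stacked estimating equations", {
  d <- toy_trial()
  fit <- fit_gee1(d, structure = "exchangeable")
  oracle <- naive_gee1_beta(d, alpha = fit$alpha, phi = fit$phi)
  expect_lt(max(abs(fit$beta - oracle)), 1e-6)

  # binary fixture too; phi pinned at exactly 1
  db <- toy_trial("binomial")
  fitb <- fit_gee1(db, structure = "exchangeable")
  expect_identical(fitb$phi, 1)
  oracleb <- naive_gee1_beta(db, alpha = fitb$alpha, phi = 1)
  expect_lt(max(abs(fitb$beta - oracleb)), 1e-5)
})

test_that("sandwich is invariant to cluster relabelling and row permutation", {
  d <- skewed_trial(K = 15, mean_size = 8, icc = 0.05, effect = 1, seed = 91)
  fit <- fit_gee1(d)
  df <- as.data.frame(d)
  set.seed(1)
  df2 <- df[sample(nrow(df)), ]
  df2$cluster <- paste0("z", df2$cluster)
  d2 <- trial_data(df2)
  fit2 <- fit_gee1(d2)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit$vcov_robust, fit2$vcov_robust, tolerance = 1e-10)
  expect_equal(fit$alpha, fit2$alpha, tolerance = 1e-12)
})

test_that("estimating-equation residual vanishes at the reported solution", {
  d <- skewed_trial(K = 25, mean_size = 10, icc = 0.03, effect = -0.5, seed = 95)
  fit <- fit_gee1(d)
  U <- naive_gee1_U <- local({
    # scaled sup-norm of the stacked equations at beta-hat
    st <- fit$state
    colSums(st$Umat)
  })
  expect_lt(max(abs(U)) / (1 + max(abs(fit$beta))), 1e-6)
})

test_that("Fay-Graubard correction matches a naive per-cluster oracle and widens SEs", {
  d <- toy_trial()
  fit <- fit_gee1(d)
  V <- fay_graubard_covariance(fit, b = 0.75)

  # oracle: explicit matrices, straight from the definition
  df <- as.data.frame(d)
  X <- stats::model.matrix(y ~ treatment, df)
  y <- df$y; id <- as.integer(factor(df$cluster))
  alpha <- fit$alpha; phi <- fit$phi
  Fs <- list(); Us <- list()
  for (i in unique(id)) {
    Xi <- X[id == i, , drop = FALSE]; yi <- y[id == i]
    ni <- length(yi)
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    Vi <- phi * R
    ri <- yi - drop(Xi %*% fit$beta)
    Fs[[i]] <- t(Xi) %*% solve(Vi) %*% Xi
    Us[[i]] <- drop(t(Xi) %*% solve(Vi, ri))
  }
  B <- Reduce(`+`, Fs); Binv <- solve(B)
  meat <- matrix(0, 2, 2)
  for (i in seq_along(Fs)) {
    Hd <- pmin(0.75, pmax(0, diag(Fs[[i]] %*% Binv)))
    Ai <- 1 / sqrt(1 - Hd)
    meat <- meat + tcrossprod(Ai * Us[[i]])
  }
  V_oracle <- Binv %*% meat %*% Binv
  expect_equal(unname(V), unname(V_oracle), tolerance = 1e-8)

  # corrected SEs never below uncorrected, across random datasets
  for (s in 1:5) {
    ds <- skewed_trial(K = 10, mean_size = 8, icc = 0.05, effect = 0, seed = 100 + s)
    f <- fit_gee1(ds)
    expect_true(all(sqrt(diag(fay_graubard_covariance(f))) >=
                      sqrt(diag(f$vcov_robust)) - 1e-12))
  }

  expect_error(fay_graubard_covariance(fit_lmm(balanced_trial(seed = 1))),
               "GEE1")
})

test_that("correction vanishes as clusters grow", {
  d <- balanced_trial(K = 200, m = 10, icc = 0.05, effect = -1, seed = 111)
  fit <- fit_gee1(d)
  r <- sqrt(diag(fay_graubard_covariance(fit))) / sqrt(diag(fit$vcov_robust))
  expect_true(all(r < 1.01))
})

test_that("robust SE is calibrated under the correct model at large N", {
  ests <- t(vapply(1:120, function(r) {
    d <- balanced_trial(K = 60, m = 8, icc = 0.05, effect = 0, seed = 6000 + r)
    f <- fit_gee1(d)
    c(f$beta[["treatment"]], sqrt(f$vcov_robust["treatment", "treatment"]))
  }, numeric(2)))
  ratio <- mean(ests[, 2]) / sd(ests[, 1])
  expect_gt(ratio, 0.85); expect_lt(ratio, 1.15)
})
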
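test_that("basis sets have the required structure", {
  b <- qif_basis("exchangeable")
  M <- b$build(4)
  expect_equal(M[[1]], diag(4))
  expect_equal(diag(M[[2]]), rep(0, 4))
  expect_true(all(M[[2]][upper.tri(M[[2]])] == 1))
  expect_equal(qif_basis("exchangeable")$build(1)[[2]], matrix(0, 1, 1))

  a <- qif_basis("ar1")$build(4)[[2]]
  expect_equal(a, matrix(c(0,1,0,0, 1,0,1,0, 0,1,0,1, 0,0,1,0), 4, 4))
  expect_equal(qif_basis("independence")$m, 1L)
})

test_that("independence basis is exactly identified: equals GEE1, objective zero", {
  d <- skewed_trial(K = 20, mean_size = 8, icc = 0.05, effect = -1, seed = 151)
  q <- suppressWarnings(fit_qif(d, structure = "independence"))
  g <- fit_gee1(d, structure = "independence")
  expect_lt(max(abs(q$beta - g$beta)), 1e-6)
  expect_lt(q$objective, 1e-8)
  expect_error(qif_gof_test(q), "m = 1")
})

test_that("exchangeable QIF equals the naive GMM minimiser (oracle)", {
  d <- skewed_trial(K = 15, mean_size = 6, icc = 0.08, effect = -1, seed = 161)
  q <- suppressWarnings(fit_qif(d, structure = "exchangeable"))
  o <- naive_qif(d, "exchangeable", start = q$beta * 0.8)
  expect_lt(max(abs(q$beta - o$beta)), 1e-5)
  expect_lt(abs(q$objective - o$objective), 1e-6)
  expect_gte(q$objective, 0)
})

test_that("clusters of size one never break the QIF fit", {
  # guaranteed size-1 clusters, like two of the case-study trials
  df <- data.frame(
    cluster = rep(1:12, c(1, 1, 5, 7, 3, 1, 6, 4, 8, 2, 1, 5)),
    stringsAsFactors = FALSE)
  df$treatment <- as.integer(df$cluster %% 2 == 0)
  set.seed(9)
  df$y <- rnorm(nrow(df), df$treatment)
  d <- trial_data(df)
  q <- suppressWarnings(fit_qif(d, structure = "exchangeable"))
  expect_true(all(is.finite(q$beta)))
  expect_true(all(is.finite(sqrt(diag(q$vcov)))))

  # removing the size-1 clusters perturbs, not destroys, the estimate
  keep <- !df$cluster %in% c(1, 2, 6, 11)
  d2 <- trial_data(df[keep, ])
  q2 <- suppressWarnings(fit_qif(d2, structure = "exchangeable"))
  expect_lt(abs(q$beta[["treatment"]] - q2$beta[["treatment"]]), 1)
})

test_that("objective decreases monotonically and estimates scale with units", {
  d <- skewed_trial(K = 25, mean_size = 8, icc = 0.05, effect = -1, seed = 171)
  q1 <- suppressWarnings(fit_qif(d, structure = "exchangeable"))
  df <- as.data.frame(d); df$y <- df$y * 10
  q10 <- suppressWarnings(fit_qif(trial_data(df), structure = "exchangeable"))
  expect_equal(unname(q10$beta), unname(q1$beta) * 10, tolerance = 1e-5)
  expect_equal(q10$objective, q1$objective, tolerance = 1e-6)
})

test_that("goodness-of-fit statistic is chi-square calibrated and guarded", {
  d <- skewed_trial(K = 60, mean_size = 10, icc = 0.05, effect = -1, seed = 181)
  q <- fit_qif(d, structure = "exchangeable")
  gof <- qif_gof_test(q)
  expect_equal(gof$dof, 2)
  expect_gte(gof$statistic, 0)
  expect_true(gof$p_value > 0 && gof$p_value <= 1)
})

test_that("small cluster counts trigger the documented caution warning", {
  d <- skewed_trial(K = 10, mean_size = 8, icc = 0.05, effect = 0, seed = 191)
  expect_warning(fit_qif(d), "caution")
  d2 <- skewed_trial(K = 44, mean_size = 8, icc = 0.05, effect = 0, seed = 192)
  expect_no_warning(fit_qif(d2))
})

test_that("under few clusters QIF SEs run below GEE1 robust SEs", {
  smaller <- vapply(1:30, function(r) {
    d <- skewed_trial(K = 10, mean_size = 20, icc = 0.05, effect = 0,
                      seed = 8000 + r)
    q <- suppressWarnings(fit_qif(d))
    g <- fit_gee1(d)
    sqrt(q$vcov["treatment", "treatment"]) <
      sqrt(g$vcov_robust["treatment", "treatment"])
  }, logical(1))
  expect_gt(mean(smaller), 0.5)   # direction only, per the observed pattern
})
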
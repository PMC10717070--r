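#' Random-intercept linear mixed model (ML/REML)
#'
#' Fits `y_ij = x_ij' beta + tau_i + e_ij` with `tau_i ~ N(0, sigma_b2)` and
#' `e_ij ~ N(0, sigma_w2)` by maximising the (restricted) likelihood. The
#' variance ratio `lambda = sigma_b2 / sigma_w2` is profiled: for fixed
#' `lambda` the GLS solution for `beta` and the residual variance are closed
#' form, leaving a smooth one-dimensional objective in `log(lambda)` that is
#' maximised by golden-section search and compared against the
#' `sigma_b2 = 0` boundary. A boundary solution truncates the model ICC to
#' exactly zero (the behaviour mixed-model software exhibits where marginal
#' models would report a negative ICC).
#'
#' @param data a [trial_data] object with a gaussian outcome.
#' @param covariates covariate names to adjust for (default: all covariates
#'   carried by `data`); use `character()` for the unadjusted model.
#' @param estimator `"reml"` (default) or `"ml"`.
#' @return An object of class `lmm_fit`: `beta`, `vcov_beta` (model-based),
#'   `sigma_b2`, `sigma_w2`, `icc` (an `icc_estimate`, truncated semantics),
#'   `loglik`, `estimator`, `converged`, plus internal pieces used by
#'   [satterthwaite_dof].
#' @export
fit_lmm <- function(data, covariates = NULL, estimator = c("reml", "ml")) {
  estimator <- match.arg(estimator)
  mp <- model_parts(data, covariates)
  if (mp$family != "gaussian") stop("fit_lmm requires a gaussian outcome")
  reml <- estimator == "reml"

  pre <- lmm_precompute(mp)
  obj <- function(u) lmm_profile(exp(u), pre, reml)$obj

  # profile objective is maximised over log(lambda); compare to the
  # sigma_b2 = 0 boundary (lambda = 0) explicitly
  opt <- stats::optimize(obj, interval = c(-25, 15), maximum = TRUE,
                         tol = 1e-10)
  at0 <- lmm_profile(0, pre, reml)
  if (at0$obj >= opt$objective - 1e-10) {
    lambda <- 0
    sol <- at0
  } else {
    lambda <- exp(opt$maximum)
    sol <- lmm_profile(lambda, pre, reml)
  }

  sw2 <- sol$sigma_w2
  sb2 <- lambda * sw2
  icc <- model_icc(sb2, sw2, "gaussian")
  if (lambda == 0) icc$truncated <- TRUE

  beta <- drop(sol$beta)
  names(beta) <- colnames(mp$X)
  vcov_beta <- sw2 * solve(sol$A)
  dimnames(vcov_beta) <- list(names(beta), names(beta))

  structure(list(
    beta = beta, vcov_beta = vcov_beta,
    sigma_b2 = sb2, sigma_w2 = sw2, icc = icc,
    loglik = sol$loglik, estimator = estimator,
    converged = TRUE, n_iter = NA_integer_,
    dof = rep(Inf, length(beta)),
    parts = mp, pre = pre, reml = reml, lambda = lambda
  ), class = "lmm_fit")
}

# Quantities reusable across lambda evaluations.
lmm_precompute <- function(mp) {
  X <- mp$X; y <- mp$y; id <- mp$id
  list(XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       S = rowsum(X, id),                     # per-cluster colsums of X
       t = drop(rowsum(y, id)),               # per-cluster sums of y
       sizes = mp$sizes, n = mp$n, p = mp$p, N = mp$N)
}

# GLS at a fixed variance ratio lambda; H_i = I + lambda J.
# W_i = H_i^-1 = I - c_i J with c_i = lambda / (1 + lambda n_i).
lmm_profile <- function(lambda, pre, reml) {
  ci <- lambda / (1 + lambda * pre$sizes)
  A <- pre$XtX - crossprod(pre$S, ci * pre$S)
  b <- pre$Xty - crossprod(pre$S, ci * pre$t)
  beta <- solve(A, b)
  # weighted RSS: r'Wr = r'r - sum_i c_i (1'r_i)^2
  rss_w <- pre$yty - 2 * drop(crossprod(beta, pre$Xty)) +
    drop(crossprod(beta, pre$XtX %*% beta))
  u <- pre$t - drop(pre$S %*% beta)           # per-cluster residual sums
  rss_w <- rss_w - sum(ci * u^2)
  ld <- sum(log1p(lambda * pre$sizes))
  if (reml) {
    df <- pre$n - pre$p
    sw2 <- rss_w / df
    ldA <- determinant(A, logarithm = TRUE)$modulus
    obj <- -0.5 * (df * log(sw2) + ld + ldA)
    loglik <- -0.5 * (df * log(sw2) + ld + ldA + df + df * log(2 * pi))
  } else {
    sw2 <- rss_w / pre$n
    obj <- -0.5 * (pre$n * log(sw2) + ld)
    loglik <- -0.5 * (pre$n * log(sw2) + ld + pre$n + pre$n * log(2 * pi))
  }
  list(obj = as.numeric(obj), loglik = as.numeric(loglik), beta = beta,
       A = A, sigma_w2 = sw2, rss_w = rss_w)
}

# (Restricted) log-likelihood as a function of raw variance components,
# with beta profiled by GLS. Used for the Satterthwaite delta method.
lmm_loglik_theta <- function(theta, pre, reml) {
  sb2 <- theta[1]; sw2 <- theta[2]
  if (sw2 <= 0 || sb2 < 0) return(-Inf)
  lambda <- sb2 / sw2
  ci <- lambda / (1 + lambda * pre$sizes)
  A <- pre$XtX - crossprod(pre$S, ci * pre$S)
  b <- pre$Xty - crossprod(pre$S, ci * pre$t)
  beta <- solve(A, b)
  rss_w <- pre$yty - 2 * drop(crossprod(beta, pre$Xty)) +
    drop(crossprod(beta, pre$XtX %*% beta))
  u <- pre$t - drop(pre$S %*% beta)
  rss_w <- rss_w - sum(ci * u^2)
  ld <- pre$n * log(sw2) + sum(log1p(lambda * pre$sizes))
  ll <- -0.5 * (ld + rss_w / sw2 + pre$n * log(2 * pi))
  if (reml) {
    ldA <- determinant(A / sw2, logarithm = TRUE)$modulus
    ll <- ll - 0.5 * as.numeric(ldA) + 0.5 * pre$p * log(2 * pi)
  }
  as.numeric(ll)
}

#' Satterthwaite degrees of freedom for a mixed-model contrast
#'
#' Approximates the degrees of freedom of the Wald t statistic for
#' `c' beta` by `nu = 2 (c' V c)^2 / Var(c' V c)`, where `V` is the
#' model-based covariance of `beta` as a function of the variance
#' components, and `Var(c' V c)` comes from the delta method with the
#' variance-component covariance taken from the inverse (restricted)
#' information matrix. The point estimate is untouched; only the reference
#' distribution changes from z to t_nu, so corrected p-values and CIs are
#' never smaller than the uncorrected ones.
#'
#' For a balanced design with a cluster-level contrast and a non-negligible
#' variance ratio, `nu` approaches the classical `N - 2`. At the
#' `sigma_b2 = 0` boundary the information matrix for the between component
#' is singular and the residual degrees of freedom `n - p` are returned.
#'
#' @param fit an `lmm_fit` (REML recommended; ML triggers a warning).
#' @param contrast coefficient name or index (default: the treatment
#'   effect).
#' @return the approximate degrees of freedom (a positive real).
#' @export
satterthwaite_dof <- function(fit, contrast = "treatment") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$reml) warning("Satterthwaite correction is intended for REML fits; computing anyway")
  p <- fit$parts$p
  cvec <- numeric(p)
  if (is.character(contrast)) {
    idx <- match(contrast, names(fit$beta))
    if (is.na(idx)) stop("unknown coefficient: ", contrast)
  } else idx <- as.integer(contrast)
  cvec[idx] <- 1

  if (fit$sigma_b2 <= 0) return(fit$parts$n - p)

  pre <- fit$pre
  fvar <- function(theta) {
    lambda <- theta[1] / theta[2]
    ci <- lambda / (1 + lambda * pre$sizes)
    A <- pre$XtX - crossprod(pre$S, ci * pre$S)
    theta[2] * drop(crossprod(cvec, solve(A, cvec)))
  }
  theta_hat <- c(fit$sigma_b2, fit$sigma_w2)
  f <- fvar(theta_hat)
  g <- numDeriv::grad(fvar, theta_hat)
  H <- numDeriv::hessian(function(th) lmm_loglik_theta(th, pre, fit$reml),
                         theta_hat)
  Vtheta <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(Vtheta) || any(diag(Vtheta) < 0)) return(fit$parts$n - p)
  denom <- drop(crossprod(g, Vtheta %*% g))
  if (denom <= 0) return(fit$parts$n - p)
  max(1, 2 * f^2 / denom)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> random-intercept LMM (", toupper(x$estimator), ")\n", sep = "")
  print(round(x$beta, 4))
  cat("  sigma_b2 =", format(x$sigma_b2, digits = 4),
      " sigma_w2 =", format(x$sigma_w2, digits = 4),
      " ICC =", format(x$icc$value, digits = 4),
      if (x$icc$truncated) "(truncated)" else "", "\n")
  invisible(x)
}
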
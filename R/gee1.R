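#' First-order generalized estimating equations
#'
#' Solves the marginal-model estimating equations
#' `sum_i D_i' V_i^{-1} (Y_i - mu_i) = 0` with working covariance
#' `V_i = phi G_i^{1/2} R(alpha) G_i^{1/2}` by alternating modified Fisher
#' scoring for the regression coefficients with moment estimation of the
#' working correlation `alpha` and scale `phi` from Pearson residuals.
#' The scale is fixed at exactly 1 for a binary outcome. The reported
#' covariance is the robust (sandwich) estimator; the model-based covariance
#' is kept alongside. `alpha` may legitimately be negative and is only
#' clipped (with a warning) at the boundary where `R(alpha)` would lose
#' invertibility, `-1/(max n_i - 1)`.
#'
#' @param data a [trial_data] object.
#' @param covariates covariates to adjust for; `character()` for the
#'   unadjusted model.
#' @param structure working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param alpha_denominator `"adjusted"` subtracts the number of regression
#'   parameters from the pair-count denominator of the moment estimator of
#'   `alpha` (the convention followed here); `"unadjusted"` does not. The
#'   two differ at order p/n.
#' @param max_iter,tol iteration controls.
#' @return An object of class `gee_fit`: `beta`, `vcov_robust`,
#'   `vcov_model`, `alpha`, `phi`, `icc` (the working-correlation estimate,
#'   untruncated), `converged`, `n_iter`, and the per-cluster state needed
#'   by [fay_graubard_covariance].
#' @export
fit_gee1 <- function(data, covariates = NULL,
                     structure = c("exchangeable", "independence"),
                     alpha_denominator = c("adjusted", "unadjusted"),
                     max_iter = 200, tol = 1e-8) {
  structure <- match.arg(structure)
  alpha_denominator <- match.arg(alpha_denominator)
  mp <- model_parts(data, covariates)
  st <- gee_solve(mp, structure, alpha_denominator, max_iter, tol)

  icc <- new_icc(st$alpha, "anova",
                 components = list(source = "gee1 working correlation"))
  structure(list(
    beta = st$beta, vcov_robust = st$vcov_robust, vcov_model = st$vcov_model,
    alpha = st$alpha, phi = st$phi, icc = icc,
    structure = structure, converged = st$converged, n_iter = st$n_iter,
    correction = "none", state = st, parts = mp
  ), class = "gee_fit")
}

# Core GEE1 iteration shared with GEE2 initialisation.
gee_solve <- function(mp, structure, alpha_denominator = "adjusted",
                      max_iter = 200, tol = 1e-8, fixed_alpha = NULL) {
  X <- mp$X; y <- mp$y; id <- mp$id
  n <- mp$n; p <- mp$p; N <- mp$N; sizes <- mp$sizes
  fam <- mp$family
  npairs <- sum(sizes * (sizes - 1) / 2)
  alpha_lo <- if (max(sizes) > 1) -1 / (max(sizes) - 1) + 1e-6 else -0.99

  beta <- if (fam == "gaussian") {
    drop(solve(crossprod(X), crossprod(X, y)))
  } else {
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  }
  alpha <- 0; phi <- 1
  converged <- FALSE; clipped <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- if (fam == "gaussian") eta else mu_logit(eta)
    v <- var_fun(mu, fam)
    e <- (y - mu) / sqrt(v)                     # Pearson residuals
    phi_new <- if (fam == "binomial") 1 else sum(e^2) / (n - p)

    if (!is.null(fixed_alpha)) {
      alpha_new <- fixed_alpha
    } else if (structure == "independence" || npairs == 0) {
      alpha_new <- 0
    } else {
      se_c <- drop(rowsum(e, id)); se2_c <- drop(rowsum(e^2, id))
      pairsum <- sum((se_c^2 - se2_c) / 2)
      denom <- if (alpha_denominator == "adjusted" && npairs > p) {
        npairs - p
      } else npairs
      alpha_new <- pairsum / (phi_new * denom)
      if (alpha_new <= alpha_lo) { alpha_new <- alpha_lo; clipped <- TRUE }
      if (alpha_new >= 1 - 1e-6) { alpha_new <- 1 - 1e-6; clipped <- TRUE }
    }

    gam <- alpha_new / (1 + (sizes - 1) * alpha_new)
    Dc <- sqrt(v) * X                            # G^{-1/2} dmu/dbeta
    ec <- e
    SD <- rowsum(Dc, id)                         # N x p cluster colsums
    B <- (crossprod(Dc) - crossprod(SD, gam * SD)) / (1 - alpha_new)
    U <- (crossprod(Dc, ec) - crossprod(SD, gam * drop(rowsum(ec, id)))) /
      (1 - alpha_new)
    step <- solve(B, U)
    beta_new <- beta + drop(step)

    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta))) &&
      abs(alpha_new - alpha) < tol
    beta <- beta_new; alpha <- alpha_new; phi <- phi_new
    if (done) { converged <- TRUE; break }
  }
  if (clipped) warning("working correlation clipped to keep R(alpha) invertible")

  # final state at beta-hat
  eta <- drop(X %*% beta)
  mu <- if (fam == "gaussian") eta else mu_logit(eta)
  v <- var_fun(mu, fam)
  e <- (y - mu) / sqrt(v)
  gam <- alpha / (1 + (sizes - 1) * alpha)
  Dc <- sqrt(v) * X
  SD <- rowsum(Dc, id)
  B <- (crossprod(Dc) - crossprod(SD, gam * SD)) / (phi * (1 - alpha))
  # per-cluster score contributions U_i (N x p)
  Umat <- (rowsum(Dc * e, id) - (gam * drop(rowsum(e, id))) * SD) /
    (phi * (1 - alpha))
  Binv <- solve(B)
  M <- crossprod(Umat)
  vcov_robust <- Binv %*% M %*% Binv
  names(beta) <- colnames(X)
  dimnames(vcov_robust) <- list(names(beta), names(beta))
  vcov_model <- Binv
  dimnames(vcov_model) <- dimnames(vcov_robust)

  list(beta = beta, alpha = alpha, phi = phi, converged = converged,
       n_iter = it, vcov_robust = vcov_robust, vcov_model = vcov_model,
       Umat = Umat, Binv = Binv, Dc = Dc, e = e, gam = gam, id = id,
       sizes = sizes, mu = mu, v = v, mp = mp)
}

#' Fay-Graubard bias-corrected sandwich covariance
#'
#' Small-sample correction for the GEE1 robust covariance when clusters are
#' few: each cluster's score contribution is inflated by
#' `{1 - min(b, H_jj)}^{-1/2}` per coefficient, where `H_jj` is the
#' corresponding diagonal element of `D_i' V_i^{-1} D_i B^{-1}` (the
#' cluster's share of the total information) and `b` caps the adjustment
#' (default 0.75). `H_jj` is additionally floored at 0 so the corrected
#' standard errors can never fall below the uncorrected ones. Only the
#' covariance (hence SEs, p-values, CIs) changes; the coefficients do not.
#'
#' @param fit a converged `gee_fit` from [fit_gee1].
#' @param b adjustment bound (default 0.75).
#' @return the corrected sandwich covariance matrix.
#' @export
fay_graubard_covariance <- function(fit, b = 0.75) {
  if (!inherits(fit, "gee_fit")) {
    stop("the Fay-Graubard correction applies to GEE1 fits only")
  }
  st <- fit$state
  p <- ncol(st$Umat); N <- nrow(st$Umat)
  Binv <- st$Binv
  idx <- split(seq_along(st$id), st$id)
  meat <- matrix(0, p, p)
  denom <- st$phi * (1 - fit$alpha)
  for (i in seq_len(N)) {
    rows <- idx[[i]]
    Dci <- st$Dc[rows, , drop = FALSE]
    SDi <- colSums(Dci)
    Fi <- (crossprod(Dci) - st$gam[i] * tcrossprod(SDi)) / denom
    Hd <- pmin(b, pmax(0, diag(Fi %*% Binv)))
    Ai <- 1 / sqrt(1 - Hd)
    Ui <- Ai * st$Umat[i, ]
    meat <- meat + tcrossprod(Ui)
  }
  V <- Binv %*% meat %*% Binv
  dimnames(V) <- dimnames(fit$vcov_robust)
  V
}

#' Apply the Fay-Graubard correction to a GEE1 fit
#'
#' Convenience wrapper returning the fit with `vcov_robust` replaced by the
#' corrected matrix and `correction` recorded.
#'
#' @inheritParams fay_graubard_covariance
#' @return the corrected `gee_fit`.
#' @export
apply_fg_correction <- function(fit, b = 0.75) {
  fit$vcov_robust <- fay_graubard_covariance(fit, b = b)
  fit$correction <- "fay_graubard"
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> GEE1, ", x$structure, " working correlation\n", sep = "")
  print(round(x$beta, 4))
  cat("  alpha =", format(x$alpha, digits = 4),
      " phi =", format(x$phi, digits = 4),
      if (x$correction != "none") paste0(" [", x$correction, " corrected]"),
      "\n")
  invisible(x)
}
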
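#' Second-order GEE: joint mean, scale and correlation estimating equations
#'
#' Fits the three-estimating-equation (3EE) marginal model: the usual GEE
#' mean equations, plus a scale equation for the squared Pearson residuals
#' `Z_ij = (y_ij - mu_ij)^2 / v(mu_ij)` (identity link, intercept-only
#' design), plus a correlation equation for the pairwise products of
#' standardized residuals `S_i` (Fisher-z link `rho = tanh(z)`,
#' intercept-only design). The blocks are solved by alternating modified
#' Fisher scoring (mean) with moment-style scoring (scale, correlation)
#' until joint convergence; the working covariances of the scale and
#' correlation blocks are identity matrices, and third/fourth moments are
#' taken as functions of the first two under the Gaussian working
#' assumption. The joint covariance of `(beta, phi, z)` is the stacked
#' sandwich estimator, so the mean block inherits a robust covariance.
#'
#' Clusters of size one contribute nothing to the correlation equations
#' (they have no pairs) but are retained by the mean and scale blocks; a
#' dataset in which *no* cluster has a pair degenerates gracefully to
#' independence GEE1 plus a scale estimate.
#'
#' @param data a [trial_data] object.
#' @param covariates covariates for the mean model; `character()` for the
#'   unadjusted model.
#' @param fix_rho optionally freeze the working correlation at a value
#'   (e.g. 0) instead of estimating it.
#' @param max_iter,tol iteration controls.
#' @return An object of class `gee2_fit`: `beta`, `phi`, `z_alpha` (the
#'   correlation intercept on the Fisher-z scale), `rho` (= `tanh(z)`),
#'   `vcov` (joint sandwich for `(beta, phi, z)`), `vcov_robust` (its beta
#'   block), `converged`, `n_iter`.
#' @export
fit_gee2 <- function(data, covariates = NULL, fix_rho = NULL,
                     max_iter = 500, tol = 1e-8) {
  mp <- model_parts(data, covariates)
  X <- mp$X; y <- mp$y; id <- mp$id
  n <- mp$n; p <- mp$p; N <- mp$N; sizes <- mp$sizes
  fam <- mp$family
  npairs <- sum(sizes * (sizes - 1) / 2)
  correl_active <- is.null(fix_rho) && npairs > 0

  init <- gee_solve(mp, "independence", max_iter = 50)
  beta <- init$beta
  phi <- max(init$phi, 1e-8)
  z <- if (!is.null(fix_rho)) atanh(fix_rho) else 0

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rho <- tanh(z)
    # --- mean block: one Fisher scoring step at current (phi, rho)
    eta <- drop(X %*% beta)
    mu <- if (fam == "gaussian") eta else mu_logit(eta)
    v <- var_fun(mu, fam)
    e <- (y - mu) / sqrt(v)
    gam <- rho / (1 + (sizes - 1) * rho)
    Dc <- sqrt(v) * X
    SD <- rowsum(Dc, id)
    B <- (crossprod(Dc) - crossprod(SD, gam * SD)) / (1 - rho)
    U <- (crossprod(Dc, e) - crossprod(SD, gam * drop(rowsum(e, id)))) /
      (1 - rho)
    beta_new <- beta + drop(solve(B, U))

    # --- scale block: identity link, intercept-only, V_2i = I
    eta <- drop(X %*% beta_new)
    mu <- if (fam == "gaussian") eta else mu_logit(eta)
    v <- var_fun(mu, fam)
    Zsq <- (y - mu)^2 / v
    phi_new <- mean(Zsq)

    # --- correlation block: Fisher-z link, intercept-only, V_3i = I
    if (correl_active) {
      eh <- (y - mu) / sqrt(phi_new * v)
      se_c <- drop(rowsum(eh, id)); se2_c <- drop(rowsum(eh^2, id))
      rbar <- sum((se_c^2 - se2_c) / 2) / npairs
      rbar <- min(max(rbar, -1 + 1e-10), 1 - 1e-10)
      z_new <- atanh(rbar)
    } else z_new <- z

    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta))) &&
      abs(phi_new - phi) < tol * (1 + phi) && abs(z_new - z) < tol
    beta <- beta_new; phi <- phi_new; z <- z_new
    if (done) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)

  theta <- c(beta, phi, z)
  psi_mat <- gee2_psi_matrix(theta, mp, correl_active)
  Atot <- -numDeriv::jacobian(function(th) colSums(gee2_psi_matrix(th, mp, correl_active)),
                              theta)
  M <- crossprod(psi_mat)
  Ainv <- tryCatch(solve(Atot), error = function(e) NULL)
  if (is.null(Ainv)) {
    vcov_joint <- matrix(NA_real_, p + 2, p + 2)
  } else {
    vcov_joint <- Ainv %*% M %*% t(Ainv)
  }
  nm <- c(names(beta), "phi", "z_alpha")
  dimnames(vcov_joint) <- list(nm, nm)
  vcov_robust <- vcov_joint[seq_len(p), seq_len(p), drop = FALSE]

  structure(list(
    beta = beta, phi = phi, z_alpha = z, rho = tanh(z),
    vcov = vcov_joint, vcov_robust = vcov_robust,
    correl_active = correl_active, fix_rho = fix_rho,
    converged = converged, n_iter = it, parts = mp
  ), class = "gee2_fit")
}

# Per-cluster stacked estimating-function contributions psi_i(beta, phi, z):
# mean block D'V^-1 r, scale block sum_j(Z_ij - phi), correlation block
# (1 - tanh(z)^2) * sum_{j<k}(e_j e_k - tanh z). Used for the joint sandwich.
gee2_psi_matrix <- function(theta, mp, correl_active) {
  X <- mp$X; y <- mp$y; id <- mp$id
  p <- mp$p; N <- mp$N; sizes <- mp$sizes; fam <- mp$family
  beta <- theta[seq_len(p)]; phi <- theta[p + 1]; z <- theta[p + 2]
  rho <- tanh(z)
  eta <- drop(X %*% beta)
  mu <- if (fam == "gaussian") eta else mu_logit(eta)
  v <- var_fun(mu, fam)
  e <- (y - mu) / sqrt(v)
  gam <- rho / (1 + (sizes - 1) * rho)
  Dc <- sqrt(v) * X
  SD <- rowsum(Dc, id)
  Umat <- (rowsum(Dc * e, id) - (gam * drop(rowsum(e, id))) * SD) /
    (phi * (1 - rho))
  Zsq <- (y - mu)^2 / v
  psi_phi <- drop(rowsum(Zsq - phi, id))
  if (correl_active) {
    eh <- e / sqrt(phi)
    se_c <- drop(rowsum(eh, id)); se2_c <- drop(rowsum(eh^2, id))
    pair_c <- (se_c^2 - se2_c) / 2
    n_pair_c <- sizes * (sizes - 1) / 2
    psi_z <- (1 - rho^2) * (pair_c - n_pair_c * rho)
  } else psi_z <- numeric(N)
  cbind(Umat, psi_phi, psi_z)
}

#' Working-correlation ICC implied by a GEE2 fit
#'
#' Inverse Fisher-z of the correlation-model intercept. May be negative;
#' never truncated.
#'
#' @param fit a `gee2_fit`.
#' @return an `icc_estimate`.
#' @export
implied_icc <- function(fit) {
  stopifnot(inherits(fit, "gee2_fit"))
  new_icc(tanh(fit$z_alpha), "anova",
          components = list(z_alpha = fit$z_alpha,
                            source = "gee2 correlation model"))
}

#' @export
print.gee2_fit <- function(x, ...) {
  cat("<gee2_fit> three-estimating-equation GEE2\n")
  print(round(x$beta, 4))
  cat("  phi =", format(x$phi, digits = 4),
      " rho =", format(x$rho, digits = 4),
      if (!x$correl_active) "(correlation block inactive)", "\n")
  invisible(x)
}
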
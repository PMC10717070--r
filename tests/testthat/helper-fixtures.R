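# Fixtures are tiny and built in code; the toy dataset below is the fixed
# 3-cluster fixture (sizes 2, 3, 1 -- includes a size-one cluster) used by
# the root-finding oracle tests.

toy_trial <- function(family = "gaussian") {
  df <- data.frame(
    cluster   = c("A", "A", "B", "B", "B", "C"),
    treatment = c(0, 0, 1, 1, 1, 0),
    y = if (family == "gaussian") c(1.2, 1.0, 2.0, 2.3, 2.2, 0.9)
        else c(0, 1, 1, 1, 0, 0)
  )
  trial_data(df, family = family)
}

# balanced dataset with K clusters of size m drawn from the generator
balanced_trial <- function(K = 20, m = 10, icc = 0.05, effect = -1,
                           seed = 1, total_variance = 4) {
  simulate_crct(sim_config(
    n_clusters = K, size_args = list(m = m), icc = icc,
    total_variance = total_variance, treatment_effect = effect, seed = seed))
}

# skewed-size dataset emulating the case studies
skewed_trial <- function(K = 30, mean_size = 15, icc = 0.05, effect = -1,
                         seed = 1, family = "gaussian", ...) {
  simulate_crct(sim_config(
    n_clusters = K, cluster_size_dist = "lognormal",
    size_args = list(meanlog = log(mean_size) - 0.32, sdlog = 0.8),
    icc = icc, total_variance = 25, treatment_effect = effect,
    family = family, seed = seed, ...))
}

# generic root-finding / minimisation oracles, independent of the
# production solvers: they build the estimating equations naively from
# explicit per-cluster matrices and hand them to base optimisers.
naive_gee1_beta <- function(data, alpha, phi, covariates = character()) {
  df <- as.data.frame(data)
  fml <- stats::as.formula(paste("y ~ treatment",
    if (length(covariates)) paste("+", paste(covariates, collapse = "+")) else ""))
  X <- stats::model.matrix(fml, df)
  y <- df$y
  id <- as.integer(factor(df$cluster))
  fam <- attr(data, "family")
  U <- function(b) {
    tot <- numeric(ncol(X))
    for (i in unique(id)) {
      Xi <- X[id == i, , drop = FALSE]; yi <- y[id == i]
      eta <- drop(Xi %*% b)
      mui <- if (fam == "gaussian") eta else pmin(pmax(plogis(eta), 1e-8), 1 - 1e-8)
      vi <- if (fam == "gaussian") rep(1, length(mui)) else mui * (1 - mui)
      ni <- length(yi)
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Vi <- phi * diag(sqrt(vi), ni) %*% R %*% diag(sqrt(vi), ni)
      Di <- vi * Xi
      tot <- tot + drop(t(Di) %*% solve(Vi, yi - mui))
    }
    tot
  }
  obj <- function(b) sum(U(b)^2)
  start <- qr.solve(X, y)
  o <- stats::optim(start, obj, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 2000))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 20000))
  o$par
}

# stacked three-block (mean, scale, correlation) estimating equations for
# the GEE2 oracle, built naively with explicit per-cluster matrices
naive_gee2_theta <- function(data, start) {
  df <- as.data.frame(data)
  X <- stats::model.matrix(y ~ treatment, df)
  y <- df$y; id <- as.integer(factor(df$cluster))
  stack <- function(theta) {
    b <- theta[1:2]; phi <- theta[3]; z <- theta[4]
    rho <- tanh(z)
    u1 <- numeric(2); u2 <- 0; u3 <- 0
    for (i in unique(id)) {
      Xi <- X[id == i, , drop = FALSE]; yi <- y[id == i]
      ni <- length(yi)
      ri <- yi - drop(Xi %*% b)
      R <- matrix(rho, ni, ni); diag(R) <- 1
      u1 <- u1 + drop(t(Xi) %*% solve(phi * R, ri))
      u2 <- u2 + sum(ri^2 - phi)
      if (ni > 1) {
        eh <- ri / sqrt(phi)
        for (j in 1:(ni - 1)) for (k in (j + 1):ni) {
          u3 <- u3 + (1 - rho^2) * (eh[j] * eh[k] - rho)
        }
      }
    }
    c(u1, u2, u3)
  }
  obj <- function(th) if (th[3] <= 0) 1e10 else sum(stack(th)^2)
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 50000))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 50000))
  o$par
}

# Exactly identified (m = 1) QIF: the argmin of the weighted objective is
# the root of the mean extended score gbar, so the well-posed generic
# oracle minimises ||gbar||^2. (The weighted objective itself is degenerate
# on a 3-cluster fixture: the per-cluster scores collapse to rank one at
# the root and C_N^{-1} is unbounded there; the weighted-objective oracle
# runs on a larger fixture in the QIF module tests.)
naive_qif_independence <- function(data, start) {
  df <- as.data.frame(data)
  X <- stats::model.matrix(y ~ treatment, df)
  y <- df$y
  id <- as.integer(factor(df$cluster))
  N <- max(id)
  gbar2 <- function(b) {
    g <- sapply(seq_len(N), function(i) {
      Xi <- X[id == i, , drop = FALSE]
      drop(t(Xi) %*% (y[id == i] - drop(Xi %*% b)))
    })
    sum(rowMeans(g)^2)
  }
  o <- stats::optim(start, gbar2, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 2000))
  o <- stats::optim(o$par, gbar2, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 50000))
  list(beta = o$par, objective = o$value)
}

naive_qif <- function(data, structure = "exchangeable", start = NULL) {
  df <- as.data.frame(data)
  X <- stats::model.matrix(y ~ treatment, df)
  y <- df$y
  id <- as.integer(factor(df$cluster))
  N <- max(id)
  fam <- attr(data, "family")
  Q <- function(b) {
    g <- sapply(seq_len(N), function(i) {
      Xi <- X[id == i, , drop = FALSE]; yi <- y[id == i]
      eta <- drop(Xi %*% b)
      mui <- if (fam == "gaussian") eta else plogis(eta)
      vi <- if (fam == "gaussian") rep(1, length(mui)) else mui * (1 - mui)
      ni <- length(yi)
      Gi_mh <- diag(1 / sqrt(vi), ni)
      Di <- vi * Xi
      ri <- yi - mui
      M2 <- if (structure == "exchangeable") matrix(1, ni, ni) - diag(ni)
            else { M <- matrix(0, ni, ni)
                   if (ni > 1) { M[cbind(1:(ni-1), 2:ni)] <- 1
                                 M[cbind(2:ni, 1:(ni-1))] <- 1 }
                   M }
      c(t(Di) %*% Gi_mh %*% diag(ni) %*% Gi_mh %*% ri,
        t(Di) %*% Gi_mh %*% M2 %*% Gi_mh %*% ri)
    })
    gbar <- rowMeans(g)
    C <- g %*% t(g) / N^2
    e <- eigen(C, symmetric = TRUE)
    vals <- pmax(e$values, 1e-10 * max(e$values))
    Cinv <- e$vectors %*% (t(e$vectors) / vals)
    drop(t(gbar) %*% Cinv %*% gbar)
  }
  if (is.null(start)) start <- qr.solve(X, y)
  o <- stats::optim(start, Q, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 2000))
  o <- stats::optim(o$par, Q, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 50000))
  list(beta = o$par, objective = o$value)
}
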
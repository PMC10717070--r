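#' Variance components implied by a target ICC
#'
#' Inverts the model-based ICC definition so the generator can be
#' parameterised directly by the ICC. Gaussian: `sigma_b2 = icc * total`,
#' `sigma_w2 = (1 - icc) * total`. Binomial (latent logistic scale):
#' `sigma_w2 = pi^2/3` fixed and `sigma_b2 = icc/(1-icc) * pi^2/3`.
#'
#' @param icc target intracluster correlation, in `[0, 1)`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param total_variance total outcome variance (gaussian only).
#' @return list with `sigma_b2`, `sigma_w2`.
#' @export
variance_components_from_icc <- function(icc, family = c("gaussian", "binomial"),
                                         total_variance = 1) {
  family <- match.arg(family)
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)")
  if (family == "gaussian") {
    if (total_variance <= 0) stop("total_variance must be > 0")
    list(sigma_b2 = icc * total_variance,
         sigma_w2 = (1 - icc) * total_variance)
  } else {
    sw2 <- pi^2 / 3
    list(sigma_b2 = icc / (1 - icc) * sw2, sigma_w2 = sw2)
  }
}

#' Configuration for the synthetic trial generator
#'
#' Captures a generative "world" for a two-arm cluster randomised trial with
#' a random cluster intercept. Defaults emulate the primary-care /
#' community-trial setting the package targets: tens of clusters, strongly
#' right-skewed cluster sizes, ICC below 0.05, and a prognostic covariate
#' option.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param allocation_ratio integer pair `c(intervention, control)` parts,
#'   e.g. `c(1, 1)` or `c(2, 1)`.
#' @param cluster_size_dist one of `"fixed"`, `"uniform"`, `"poisson"`,
#'   `"lognormal"` (rounded, truncated at 1).
#' @param size_args parameters of the size distribution: `fixed` uses `m`;
#'   `uniform` uses `lo`, `hi`; `poisson` uses `lambda`; `lognormal` uses
#'   `meanlog`, `sdlog`.
#' @param family outcome family.
#' @param icc target intracluster correlation in `[0, 1)` (latent scale for
#'   binomial).
#' @param total_variance total gaussian outcome variance.
#' @param treatment_effect mean difference (gaussian) or log odds ratio
#'   (binomial).
#' @param intercept intercept `beta_0` on the model scale.
#' @param covariates optional list of covariate specs, each a list with
#'   `name`, `dist` (`"normal"` or `"binary"`), `coef`, and distribution
#'   arguments (`mean`/`sd` or `prob`).
#' @param missing_rate MCAR deletion probability for the outcome, `[0, 1)`.
#' @param seed integer seed making the draw reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 50,
                       allocation_ratio = c(1, 1),
                       cluster_size_dist = c("fixed", "uniform", "poisson", "lognormal"),
                       size_args = list(m = 20),
                       family = c("gaussian", "binomial"),
                       icc = 0.02,
                       total_variance = 25,
                       treatment_effect = 0,
                       intercept = 0,
                       covariates = list(),
                       missing_rate = 0,
                       seed = 1L) {
  cluster_size_dist <- match.arg(cluster_size_dist)
  family <- match.arg(family)
  stopifnot(n_clusters >= 2, length(allocation_ratio) == 2,
            all(allocation_ratio >= 1),
            icc >= 0, icc < 1, missing_rate >= 0, missing_rate < 1,
            total_variance > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 allocation_ratio = as.integer(allocation_ratio),
                 cluster_size_dist = cluster_size_dist,
                 size_args = size_args, family = family, icc = icc,
                 total_variance = total_variance,
                 treatment_effect = treatment_effect, intercept = intercept,
                 covariates = covariates, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys mirror the arguments of [sim_config].
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}

draw_cluster_sizes <- function(config) {
  N <- config$n_clusters
  a <- config$size_args
  switch(config$cluster_size_dist,
    fixed     = rep(as.integer(a$m), N),
    uniform   = sample(seq(as.integer(a$lo), as.integer(a$hi)), N, replace = TRUE),
    poisson   = pmax(1L, stats::rpois(N, a$lambda)),
    lognormal = pmax(1L, round(stats::rlnorm(N, a$meanlog, a$sdlog)))
  )
}

#' Simulate a cluster randomised trial
#'
#' Generates a two-arm CRCT under a random-intercept model. Clusters are
#' randomised to arms at the exact allocation ratio (any remainder assigned
#' by a seeded draw); cluster effects are `tau_i ~ N(0, sigma_b2)`; a
#' gaussian outcome is `beta_0 + beta_1 x_1i + sum(beta_p x_pij) + tau_i +
#' e_ij` with `e_ij ~ N(0, sigma_w2)`, and a binary outcome is Bernoulli
#' with logit equal to the same linear predictor (without the residual).
#' MCAR missingness, if requested, is applied to the outcome afterwards.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @return A [trial_data] object; the generative truth (all parameters,
#'   variance components, cluster sizes and arm assignment) is stored in
#'   the `truth` attribute.
#' @export
simulate_crct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_clusters
  ratio <- config$allocation_ratio
  if (N < sum(ratio)) stop("fewer clusters than allocation ratio parts")

  # exact arm counts at the ratio; remainder clusters assigned by seeded draw
  n_trt <- floor(N * ratio[1] / sum(ratio))
  n_ctl <- floor(N * ratio[2] / sum(ratio))
  rem <- N - n_trt - n_ctl
  if (rem > 0) {
    extra <- sample(c(rep(1L, ratio[1]), rep(0L, ratio[2])), rem)
    n_trt <- n_trt + sum(extra == 1L)
    n_ctl <- n_ctl + sum(extra == 0L)
  }
  arm <- sample(c(rep(1L, n_trt), rep(0L, n_ctl)))

  sizes <- draw_cluster_sizes(config)
  vc <- variance_components_from_icc(config$icc, config$family,
                                     config$total_variance)
  tau <- stats::rnorm(N, 0, sqrt(vc$sigma_b2))

  id <- rep(seq_len(N), sizes)
  n <- length(id)
  eta <- config$intercept + config$treatment_effect * arm[id] + tau[id]

  df <- data.frame(cluster = sprintf("c%03d", id), treatment = arm[id])
  for (cv in config$covariates) {
    x <- switch(cv$dist,
      normal = stats::rnorm(n, cv$mean %||% 0, cv$sd %||% 1),
      binary = stats::rbinom(n, 1, cv$prob %||% 0.5),
      stop("unknown covariate distribution: ", cv$dist))
    df[[cv$name]] <- x
    eta <- eta + cv$coef * x
  }
  df$y <- if (config$family == "gaussian") {
    eta + stats::rnorm(n, 0, sqrt(vc$sigma_w2))
  } else {
    stats::rbinom(n, 1, stats::plogis(eta))
  }

  if (config$missing_rate > 0) {
    df$y[stats::runif(n) < config$missing_rate] <- NA
  }

  covnames <- vapply(config$covariates, `[[`, character(1), "name")
  data <- suppressMessages(
    trial_data(df, covariates = covnames, family = config$family)
  )
  attr(data, "truth") <- list(
    config = config, sigma_b2 = vc$sigma_b2, sigma_w2 = vc$sigma_w2,
    beta1 = config$treatment_effect, cluster_sizes = sizes, arm = arm
  )
  data
}

#' Delete outcomes completely at random
#'
#' Each outcome is independently set missing with probability `rate`
#' (missing completely at random), then the complete-case policy re-applies.
#'
#' @param data a [trial_data] object.
#' @param rate deletion probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a [trial_data] object with the surviving rows.
#' @export
apply_mcar_missingness <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "trial_data"), rate >= 0, rate < 1)
  if (rate == 0) return(data)
  set.seed(seed)
  df <- as.data.frame(data)
  df$y[stats::runif(nrow(df)) < rate] <- NA
  suppressMessages(
    trial_data(df, covariates = attr(data, "covariates"),
               family = attr(data, "family"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
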
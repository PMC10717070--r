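#' Summarise a fitted model as a results-table row
#'
#' Extracts the intervention-effect row every estimator shares: the effect
#' (mean difference for a continuous outcome; odds ratio, computed on the
#' log scale then exponentiated, for a binary outcome), its SE on the model
#' scale, the two-sided p-value, the 95% CI, the method-appropriate ICC,
#' and bookkeeping. Inference is Wald-z for the marginal models and the
#' binary GLMM; the REML linear mixed model uses t with Satterthwaite
#' degrees of freedom when `correction = "satterthwaite"`.
#'
#' @param fit an `lmm_fit`, `glmm_fit`, `gee_fit`, `gee2_fit` or `qif_fit`.
#' @param adjusted logical flag recorded in the row.
#' @param correction `"none"`, `"satterthwaite"` (LMM) or `"fay_graubard"`
#'   (GEE1; apply via [apply_fg_correction] before calling, or let
#'   [fit_all] do it).
#' @param level confidence level (default 0.95).
#' @return one-row data.frame with columns `method`, `adjusted`, `effect`,
#'   `se`, `p`, `ci_low`, `ci_high`, `icc`, `n_subjects`, `n_clusters`,
#'   `dof`, `correction`, `converged`.
#' @export
summarize_fit <- function(fit, adjusted = FALSE, correction = "none",
                          level = 0.95) {
  mp <- fit$parts
  fam <- mp$family
  est <- unname(fit$beta[["treatment"]])
  method <- class(fit)[1]
  dof <- Inf
  converged <- isTRUE(fit$converged)

  if (inherits(fit, "lmm_fit")) {
    method <- "glmm"
    se <- sqrt(fit$vcov_beta["treatment", "treatment"])
    icc <- fit$icc$value
    if (correction == "satterthwaite") dof <- satterthwaite_dof(fit, "treatment")
  } else if (inherits(fit, "glmm_fit")) {
    method <- "glmm"
    se <- sqrt(fit$vcov_beta["treatment", "treatment"])
    icc <- fit$icc$value
  } else if (inherits(fit, "gee_fit")) {
    method <- "gee1"
    se <- sqrt(fit$vcov_robust["treatment", "treatment"])
    icc <- fit$alpha
    if (fit$correction != "none") correction <- fit$correction
  } else if (inherits(fit, "gee2_fit")) {
    method <- "gee2"
    se <- sqrt(fit$vcov_robust["treatment", "treatment"])
    icc <- implied_icc(fit)$value
  } else if (inherits(fit, "qif_fit")) {
    method <- "qif"
    se <- sqrt(fit$vcov["treatment", "treatment"])
    icc <- moment_icc_at(fit)
  } else stop("unrecognised fit object")

  tstat <- est / se
  p <- if (is.finite(dof)) 2 * stats::pt(-abs(tstat), df = dof)
       else 2 * stats::pnorm(-abs(tstat))
  q <- if (is.finite(dof)) stats::qt(1 - (1 - level) / 2, df = dof)
       else stats::qnorm(1 - (1 - level) / 2)
  lo <- est - q * se; hi <- est + q * se
  if (fam == "binomial") {
    effect <- exp(est); lo <- exp(lo); hi <- exp(hi)
  } else effect <- est

  data.frame(method = method, adjusted = adjusted, effect = effect, se = se,
             p = p, ci_low = lo, ci_high = hi, icc = icc,
             n_subjects = mp$n, n_clusters = mp$N,
             dof = dof, correction = correction, converged = converged,
             stringsAsFactors = FALSE)
}

# Moment (Pearson-residual) working-correlation estimate at a QIF solution:
# QIF never estimates alpha, so its reported ICC is the same moment
# estimator GEE1 uses, evaluated at the QIF coefficients.
moment_icc_at <- function(fit) {
  mp <- fit$parts
  eta <- drop(mp$X %*% fit$beta)
  mu <- if (mp$family == "gaussian") eta else mu_logit(eta)
  v <- var_fun(mu, mp$family)
  e <- (mp$y - mu) / sqrt(v)
  phi <- if (mp$family == "binomial") 1 else sum(e^2) / (mp$n - mp$p)
  npairs <- sum(mp$sizes * (mp$sizes - 1) / 2)
  if (npairs == 0) return(NA_real_)
  se_c <- drop(rowsum(e, mp$id)); se2_c <- drop(rowsum(e^2, mp$id))
  denom <- if (npairs > mp$p) npairs - mp$p else npairs
  sum((se_c^2 - se2_c) / 2) / (phi * denom)
}

#' Fit all four estimators, unadjusted and adjusted
#'
#' Runs the comparison grid the package exists for: GLMM (REML linear mixed
#' model for a continuous outcome, AGHQ logistic mixed model for a binary
#' one), GEE1-exchangeable, 3EE GEE2 and QIF-exchangeable, each with the
#' treatment-only (unadjusted) model and, when covariates are supplied,
#' the covariate-adjusted model. Per-cell failures are caught and recorded
#' as unconverged rows; one failing cell never aborts the grid. With
#' `corrections = TRUE`, Satterthwaite-corrected GLMM rows and
#' Fay-Graubard-corrected GEE1 rows are appended. A message suggests the
#' small-sample corrections when the number of clusters is at or below the
#' documented trouble thresholds (20 continuous / 30 binary).
#'
#' @param data a [trial_data] object.
#' @param adjusted_covariates covariates for the adjusted models (default:
#'   the covariates carried by `data`; `character()` skips adjusted rows).
#' @param corrections also fit the small-sample-corrected variants.
#' @param n_quad_nodes AGHQ nodes for the binary GLMM.
#' @return data.frame of results rows (class `crct_results`).
#' @export
fit_all <- function(data, adjusted_covariates = NULL, corrections = FALSE,
                    n_quad_nodes = 10) {
  stopifnot(inherits(data, "trial_data"))
  if (is.null(adjusted_covariates)) adjusted_covariates <- attr(data, "covariates")
  fam <- attr(data, "family")
  N <- length(unique(data$cluster))
  if ((fam == "gaussian" && N <= 20) || (fam == "binomial" && N <= 30)) {
    message("only ", N, " clusters: small-sample corrections (Satterthwaite, ",
            "Fay-Graubard) are recommended at this size")
  }

  cov_sets <- list(unadjusted = character())
  if (length(adjusted_covariates)) cov_sets$adjusted <- adjusted_covariates

  fitters <- list(
    glmm = function(cv) if (fam == "gaussian") fit_lmm(data, cv, "reml")
                        else fit_logistic_glmm(data, cv, n_quad_nodes),
    gee1 = function(cv) fit_gee1(data, cv, "exchangeable"),
    gee2 = function(cv) fit_gee2(data, cv),
    qif  = function(cv) fit_qif(data, cv, "exchangeable")
  )

  rows <- list()
  for (set_name in names(cov_sets)) {
    cv <- cov_sets[[set_name]]
    adj <- set_name == "adjusted"
    for (mname in names(fitters)) {
      row <- tryCatch({
        fit <- suppressWarnings(fitters[[mname]](cv))
        summarize_fit(fit, adjusted = adj)
      }, error = function(e) {
        data.frame(method = mname, adjusted = adj, effect = NA_real_,
                   se = NA_real_, p = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, icc = NA_real_, n_subjects = nrow(data),
                   n_clusters = N, dof = Inf, correction = "none",
                   converged = FALSE, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
      if (corrections && mname == "glmm" && fam == "gaussian") {
        rows[[length(rows) + 1L]] <- tryCatch(
          summarize_fit(suppressWarnings(fit_lmm(data, cv, "reml")),
                        adjusted = adj, correction = "satterthwaite"),
          error = function(e) NULL)
      }
      if (corrections && mname == "gee1") {
        rows[[length(rows) + 1L]] <- tryCatch(
          summarize_fit(apply_fg_correction(
            suppressWarnings(fit_gee1(data, cv, "exchangeable"))),
            adjusted = adj),
          error = function(e) NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crct_results", "data.frame")
  out
}

#' Write a results table to CSV
#'
#' Writes the full-precision columns plus rounded display variants
#' (`effect_display`, `se_display` at 2 d.p., the table convention for
#' reporting intervention effects and odds ratios).
#'
#' @param results data.frame of rows from [summarize_fit] / [fit_all]
#'   (may be empty: a header-only file is written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  cols <- c("method", "adjusted", "effect", "se", "p", "ci_low", "ci_high",
            "icc", "n_subjects", "n_clusters", "correction", "converged")
  if (nrow(results) == 0) {
    out <- results[, intersect(cols, names(results)), drop = FALSE]
  } else {
    out <- results[, cols, drop = FALSE]
    out$effect_display <- round(out$effect, 2)
    out$se_display <- round(out$se, 2)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Simulation study of operating characteristics
#'
#' For each scenario (a [sim_config] without a fixed seed) and replicate:
#' simulate a trial, fit the requested estimators (optionally with their
#' small-sample corrections), and test the treatment effect at the 5%
#' level. Aggregates per method: bias, relative bias, empirical SD of the
#' effect estimate, mean model SE, their ratio, 95% CI coverage of the
#' true effect, rejection rate (type-I error under a null scenario, power
#' otherwise), mean ICC estimate, fraction of negative ICC estimates, and
#' the convergence rate. Per-replicate seeds are derived deterministically
#' from `seed`, so identical `(scenarios, n_reps, seed)` reproduce the
#' result exactly.
#'
#' @param scenarios a single [sim_config] or list of them.
#' @param n_reps replicates per scenario (>= 2).
#' @param seed master seed.
#' @param methods subset of `c("glmm", "gee1", "gee2", "qif")`.
#' @param corrections also evaluate Satterthwaite-corrected GLMM and
#'   Fay-Graubard-corrected GEE1 (gaussian scenarios).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per scenario x method (class
#'   `sim_study`); the per-replicate draws are kept in the `draws`
#'   attribute.
#' @export
run_simulation_study <- function(scenarios, n_reps, seed = 1L,
                                 methods = c("glmm", "gee1", "gee2", "qif"),
                                 corrections = FALSE, alpha = 0.05) {
  if (inherits(scenarios, "sim_config")) scenarios <- list(scenarios)
  stopifnot(n_reps >= 2)
  methods <- match.arg(methods, several.ok = TRUE)

  all_rows <- list(); all_draws <- list()
  for (sc_i in seq_along(scenarios)) {
    sc <- scenarios[[sc_i]]
    draws <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- (as.numeric(seed) * 2654435 + r * 97003) %% 2147483647 + 1
      cfg <- sc; cfg$seed <- as.integer(rep_seed)
      draws[[r]] <- simulate_one_rep(cfg, methods, corrections)
    }
    dd <- do.call(rbind, draws)
    dd$scenario <- sc_i
    all_draws[[sc_i]] <- dd

    truth <- sc$treatment_effect
    for (m in unique(dd$method)) {
      d <- dd[dd$method == m & dd$converged, , drop = FALSE]
      est_scale <- d$est            # model scale (log-OR for binomial)
      rows <- data.frame(
        scenario = sc_i, method = m, n_reps = n_reps,
        n_converged = nrow(d),
        bias = mean(est_scale) - truth,
        rel_bias = if (truth != 0) (mean(est_scale) - truth) / truth else NA_real_,
        empirical_sd = stats::sd(est_scale),
        mean_se = mean(d$se),
        se_ratio = mean(d$se) / stats::sd(est_scale),
        coverage = mean(d$ci_low <= truth & truth <= d$ci_high),
        rejection_rate = mean(d$p < alpha),
        mean_icc = mean(d$icc, na.rm = TRUE),
        frac_negative_icc = mean(d$icc < 0, na.rm = TRUE),
        convergence_rate = nrow(d) / n_reps,
        seed = seed, stringsAsFactors = FALSE
      )
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  attr(out, "draws") <- do.call(rbind, all_draws)
  class(out) <- c("sim_study", "data.frame")
  out
}

# One simulated replicate: returns model-scale effect estimates, SEs,
# p-values and CIs per requested method (plus corrected variants).
simulate_one_rep <- function(cfg, methods, corrections) {
  data <- simulate_crct(cfg)
  fam <- cfg$family
  out <- list()
  rec <- function(name, est, se, p, dof, icc, conv) {
    q <- if (is.finite(dof)) stats::qt(0.975, dof) else stats::qnorm(0.975)
    data.frame(method = name, est = est, se = se, p = p,
               ci_low = est - q * se, ci_high = est + q * se,
               icc = icc, converged = conv, stringsAsFactors = FALSE)
  }
  wald <- function(est, se, dof = Inf) {
    if (is.finite(dof)) 2 * stats::pt(-abs(est / se), dof)
    else 2 * stats::pnorm(-abs(est / se))
  }

  for (m in methods) {
    res <- tryCatch({
      if (m == "glmm") {
        if (fam == "gaussian") {
          fit <- fit_lmm(data, character(), "reml")
          est <- fit$beta[["treatment"]]
          se <- sqrt(fit$vcov_beta["treatment", "treatment"])
          rows <- rec("glmm", est, se, wald(est, se), Inf, fit$icc$value,
                      fit$converged)
          if (corrections) {
            nu <- satterthwaite_dof(fit, "treatment")
            rows <- rbind(rows, rec("glmm_sat", est, se, wald(est, se, nu),
                                    nu, fit$icc$value, fit$converged))
          }
          rows
        } else {
          fit <- fit_logistic_glmm(data, character())
          est <- fit$beta[["treatment"]]
          se <- sqrt(fit$vcov_beta["treatment", "treatment"])
          rec("glmm", est, se, wald(est, se), Inf, fit$icc$value, fit$converged)
        }
      } else if (m == "gee1") {
        fit <- suppressWarnings(fit_gee1(data, character(), "exchangeable"))
        est <- fit$beta[["treatment"]]
        se <- sqrt(fit$vcov_robust["treatment", "treatment"])
        rows <- rec("gee1", est, se, wald(est, se), Inf, fit$alpha,
                    fit$converged)
        if (corrections) {
          Vc <- fay_graubard_covariance(fit)
          sec <- sqrt(Vc["treatment", "treatment"])
          rows <- rbind(rows, rec("gee1_fg", est, sec, wald(est, sec), Inf,
                                  fit$alpha, fit$converged))
        }
        rows
      } else if (m == "gee2") {
        fit <- fit_gee2(data, character())
        est <- fit$beta[["treatment"]]
        se <- sqrt(fit$vcov_robust["treatment", "treatment"])
        rec("gee2", est, se, wald(est, se), Inf, implied_icc(fit)$value,
            fit$converged)
      } else {
        fit <- suppressWarnings(fit_qif(data, character(), "exchangeable"))
        est <- fit$beta[["treatment"]]
        se <- sqrt(fit$vcov["treatment", "treatment"])
        rec("qif", est, se, wald(est, se), Inf, moment_icc_at(fit),
            fit$converged)
      }
    }, error = function(e) {
      data.frame(method = m, est = NA_real_, se = NA_real_, p = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, icc = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}
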
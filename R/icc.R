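#' Model-based intracluster correlation coefficient
#'
#' Computes the ICC from variance components. For a continuous outcome
#' `rho = sigma_b2 / (sigma_b2 + sigma_w2)`; for a binary outcome the
#' within-cluster variance on the latent logistic scale is the fixed
#' constant `pi^2/3`, so `rho = sigma_b2 / (sigma_b2 + pi^2/3)`.
#'
#' @param sigma_b2 between-cluster variance (>= 0).
#' @param sigma_w2 within-cluster variance (> 0); ignored for
#'   `family = "binomial"`.
#' @param family `"gaussian"` (continuous) or `"binomial"` (latent scale).
#' @return An `icc_estimate` list with fields `value`, `method`,
#'   `components`, `truncated`.
#' @export
model_icc <- function(sigma_b2, sigma_w2 = NULL,
                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (sigma_b2 < 0) stop("sigma_b2 is a variance and must be >= 0")
  if (family == "gaussian") {
    if (is.null(sigma_w2) || sigma_w2 <= 0) stop("sigma_w2 must be > 0")
    value <- sigma_b2 / (sigma_b2 + sigma_w2)
    method <- "model_continuous"
  } else {
    sigma_w2 <- pi^2 / 3
    value <- sigma_b2 / (sigma_b2 + sigma_w2)
    method <- "model_binary_latent"
  }
  new_icc(value, method,
          components = list(sigma_b2 = sigma_b2, sigma_w2 = sigma_w2))
}

#' One-way ANOVA ICC estimator
#'
#' Estimates the ICC from the between- and within-cluster mean squares of a
#' one-way ANOVA on the cluster identifier:
#' `rho = (MSB - MSW) / (MSB + (nbar - 1) * MSW)` with `nbar` the adjusted
#' average cluster size of [nbar_adjusted]. The estimate is returned
#' *untruncated*: it is negative whenever `MSB < MSW`, which happens in a
#' non-vanishing fraction of datasets even when the true ICC is zero.
#' For a binary outcome the ANOVA runs on the raw 0/1 values (the standard
#' moment approach).
#'
#' @param data a [trial_data] object (N >= 2 clusters, at least one cluster
#'   of size >= 2).
#' @return An `icc_estimate` with components `MSB`, `MSW`, `nbar`.
#' @export
anova_icc <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  y <- data$y
  g <- factor(data$cluster)
  N <- nlevels(g)
  if (N < 2L) stop("ANOVA ICC needs at least 2 clusters")
  n <- length(y)
  if (n == N) stop("all clusters have size 1: within-cluster mean square undefined")
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ssb <- sum(sizes * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (N - 1)
  msw <- ssw / (n - N)
  nb <- nbar_adjusted(sizes)
  value <- (msb - msw) / (msb + (nb - 1) * msw)
  new_icc(value, "anova", components = list(MSB = msb, MSW = msw, nbar = nb))
}

#' Truncate an ICC estimate at zero
#'
#' Mixed-model (cluster-specific) software cannot report a negative ICC:
#' when the between-cluster variance estimate hits the zero boundary the ICC
#' is reported as exactly 0. This helper applies that truncation semantics
#' and flags when clipping occurred, so marginal-model (untruncated, possibly
#' negative) and mixed-model ICCs can be compared honestly.
#'
#' @param estimate an `icc_estimate` (or bare number).
#' @return An `icc_estimate` with `value = max(value, 0)` and `truncated`
#'   set if clipping occurred.
#' @export
truncate_icc <- function(estimate) {
  if (is.numeric(estimate)) estimate <- new_icc(estimate, "anova", list())
  stopifnot(inherits(estimate, "icc_estimate"))
  if (estimate$value < 0) {
    estimate$truncated <- TRUE
    estimate$value <- 0
  }
  estimate
}

new_icc <- function(value, method, components, truncated = FALSE) {
  structure(list(value = value, method = method, components = components,
                 truncated = truncated),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat("<icc_estimate> ", format(x$value, digits = 4), " (", x$method,
      if (x$truncated) ", truncated at 0" else "", ")\n", sep = "")
  invisible(x)
}
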
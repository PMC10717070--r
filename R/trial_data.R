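#' Construct a clustered-trial dataset
#'
#' `trial_data()` is the package's central container: one row per subject,
#' with a cluster identifier, a cluster-level binary treatment indicator
#' (0 = control, 1 = intervention), an outcome that is either continuous
#' (`family = "gaussian"`) or 0/1 (`family = "binomial"`), and optional
#' covariate columns. Rows with a missing outcome or missing covariate value
#' are dropped (complete-case analysis is the only missingness policy) and
#' the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param df data.frame in long format, one row per subject.
#' @param cluster name of the cluster-identifier column.
#' @param treatment name of the 0/1 treatment column; must be constant
#'   within every cluster.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param family `"gaussian"` or `"binomial"`.
#'
#' @return An object of class `trial_data`: a data.frame with standardised
#'   columns `cluster`, `treatment`, `y`, plus the covariates, and
#'   attributes `family`, `covariates`, `n_dropped`.
#' @export
trial_data <- function(df, cluster = "cluster", treatment = "treatment",
                       outcome = "y", covariates = character(),
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(df))
  needed <- c(cluster, treatment, outcome, covariates)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    cluster   = as.character(df[[cluster]]),
    treatment = df[[treatment]],
    y         = df[[outcome]],
    stringsAsFactors = FALSE
  )
  for (cv in covariates) out[[cv]] <- df[[cv]]

  # complete-case filtering on outcome and covariates (never on ids)
  cc <- stats::complete.cases(out[, c("y", covariates), drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing outcome/covariates dropped (complete-case analysis)")
  }
  out <- out[cc, , drop = FALSE]
  rownames(out) <- NULL

  if (nrow(out) == 0L) stop("no complete cases remain")
  if (anyNA(out$treatment)) stop("treatment indicator contains missing values")
  if (!all(out$treatment %in% c(0, 1))) {
    stop("treatment must be coded 0 (control) / 1 (intervention)")
  }
  bad <- vapply(split(out$treatment, out$cluster),
                function(tr) length(unique(tr)) > 1L, logical(1))
  if (any(bad)) {
    stop("treatment is not constant within cluster(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  if (family == "binomial" && !all(out$y %in% c(0, 1))) {
    stop("binary outcome values must all be in {0, 1}")
  }
  if (length(unique(out$cluster)) < 2L) stop("need at least 2 clusters")
  arms <- unique(out$treatment)
  if (length(arms) < 2L) stop("single-arm data: both treatment arms required")

  structure(out,
            class = c("trial_data", "data.frame"),
            family = family,
            covariates = covariates,
            n_dropped = n_dropped)
}

#' Load a clustered-trial CSV
#'
#' Reads a UTF-8 CSV with a header row and validates it into a
#' [trial_data] object under the complete-case policy.
#'
#' @param path path to CSV file.
#' @inheritParams trial_data
#' @return A [trial_data] object.
#' @export
load_trial <- function(path, cluster = "cluster", treatment = "treatment",
                       outcome = "y", covariates = character(),
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trial_data(df, cluster = cluster, treatment = treatment, outcome = outcome,
             covariates = covariates, family = family)
}

#' Write a trial dataset to CSV
#'
#' @param data a [trial_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trial_data <- function(x, ...) {
  cs <- table(x$cluster)
  cat("<trial_data> ", nrow(x), " subjects in ", length(cs), " clusters (",
      attr(x, "family"), " outcome)\n", sep = "")
  cat("  arms: control ", sum(x$treatment == 0), " / intervention ",
      sum(x$treatment == 1), " subjects\n", sep = "")
  if (length(attr(x, "covariates"))) {
    cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  }
  if (attr(x, "n_dropped") > 0) {
    cat("  complete-case: ", attr(x, "n_dropped"), " row(s) dropped\n", sep = "")
  }
  invisible(x)
}

#' Cluster sizes of a trial dataset
#' @param data a [trial_data] object.
#' @return named integer vector of cluster sizes.
#' @export
cluster_sizes <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  tab <- table(data$cluster)
  stats::setNames(as.integer(tab), names(tab))
}

#' ANOVA-adjusted average cluster size
#'
#' The adjusted average used by the one-way ANOVA ICC estimator:
#' `nbar = (n - sum(n_i^2)/n) / (N - 1)`. It equals the simple mean when all
#' clusters are the same size and is strictly smaller otherwise.
#'
#' @param sizes integer vector of cluster sizes (all >= 1, length >= 2).
#' @return the adjusted average cluster size.
#' @export
nbar_adjusted <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 2L) stop("adjusted average cluster size needs N >= 2 clusters")
  if (any(sizes < 1)) stop("cluster sizes must be >= 1")
  n <- sum(sizes)
  (n - sum(sizes^2) / n) / (length(sizes) - 1)
}

#' Design summary of a clustered trial
#'
#' Summarises the design in the shape used for trial size tables: numbers of
#' clusters and subjects, dropped (incomplete) rows, the simple mean cluster
#' size (also rounded for reporting), the ANOVA-adjusted average cluster size
#' [nbar_adjusted], and the min/median/max cluster sizes.
#'
#' @param data a [trial_data] object.
#' @return A list of class `design_summary`.
#' @export
design_summary <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  sizes <- cluster_sizes(data)
  if (length(sizes) < 2L) stop("design summary needs N >= 2 clusters")
  n <- sum(sizes)
  N <- length(sizes)
  structure(list(
    n_clusters = N,
    n_subjects = n,
    n_missing_subjects = attr(data, "n_dropped"),
    pct_missing = round(100 * attr(data, "n_dropped") /
                          (n + attr(data, "n_dropped"))),
    mean_cluster_size = n / N,
    mean_cluster_size_display = round_half_up(n / N),
    nbar = nbar_adjusted(sizes),
    min_cluster_size = min(sizes),
    median_cluster_size = stats::median(sizes),
    max_cluster_size = max(sizes)
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("<design_summary>\n")
  cat("  clusters:      ", x$n_clusters, "\n")
  cat("  subjects:      ", x$n_subjects,
      sprintf("  (dropped %d, %d%%)", x$n_missing_subjects, x$pct_missing), "\n")
  cat("  cluster size:  mean ", format(x$mean_cluster_size, digits = 4),
      " (display ", x$mean_cluster_size_display, "), adjusted nbar ",
      format(x$nbar, digits = 6), "\n", sep = "")
  cat("  (min, median, max): (", x$min_cluster_size, ", ",
      x$median_cluster_size, ", ", x$max_cluster_size, ")\n", sep = "")
  invisible(x)
}

# round-half-up at integer precision ("16% (150/914)" convention: ties go up)
round_half_up <- function(x) floor(x + 0.5)

#' Per-arm descriptive statistics
#'
#' For a binary outcome: events/total and the percent rounded to the nearest
#' integer (ties up) per arm. For a continuous outcome: n, mean (reported at
#' 1 d.p.) and SD per arm.
#'
#' @param data a [trial_data] object.
#' @return A data.frame of class `arm_descriptives` with one row per arm.
#' @export
arm_descriptives <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  fam <- attr(data, "family")
  arms <- c(control = 0, intervention = 1)
  rows <- lapply(names(arms), function(a) {
    y <- data$y[data$treatment == arms[[a]]]
    if (length(y) == 0L) stop("empty arm: ", a)
    if (fam == "binomial") {
      data.frame(arm = a, n = length(y), events = sum(y),
                 percent = round_half_up(100 * sum(y) / length(y)))
    } else {
      data.frame(arm = a, n = length(y),
                 mean = mean(y), mean_display = round(mean(y), 1),
                 sd = stats::sd(y))
    }
  })
  structure(do.call(rbind, rows),
            class = c("arm_descriptives", "data.frame"), family = fam)
}
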
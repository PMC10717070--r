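# Internal: turn a trial_data object into the numeric pieces every
# estimator consumes: response y, design matrix X (intercept + treatment +
# requested covariates, factors expanded), integer cluster index id, and
# per-cluster bookkeeping. Rank deficiency is a hard error naming the
# aliased columns, as every downstream solver assumes full rank.
model_parts <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (is.null(covariates)) covariates <- attr(data, "covariates")
  if (length(covariates)) {
    missing_cv <- setdiff(covariates, names(data))
    if (length(missing_cv)) stop("covariates not in data: ",
                                 paste(missing_cv, collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    "y ~ treatment",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))
  X <- stats::model.matrix(fml, data = as.data.frame(data))
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  id <- as.integer(factor(data$cluster))
  sizes <- as.integer(table(id))
  list(y = data$y, X = X, id = id, n = nrow(X), p = ncol(X),
       N = length(sizes), sizes = sizes,
       family = attr(data, "family"),
       treatment_col = which(colnames(X) == "treatment"))
}

# Per-cluster column sums of a matrix (rows grouped by integer id 1..N).
cluster_colsums <- function(M, id, N) {
  rowsum(M, group = id, reorder = TRUE)
}

# logit-family mean/variance helpers
mu_logit <- function(eta) stats::plogis(eta)
var_fun <- function(mu, family) {
  if (family == "gaussian") rep(1, length(mu)) else mu * (1 - mu)
}
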
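---
title: "Models, corrections and simulation design for cluster randomised trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, corrections and simulation design for cluster randomised trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctcompare)
```

# The estimation problem

In a cluster randomised controlled trial (CRCT) whole groups — general
practices, maternity units, electoral wards — are randomised, and outcomes of
subjects inside the same cluster are correlated. Writing $y_{ij}$ for the
outcome of subject $j$ in cluster $i$ ($i = 1,\dots,N$, $j = 1,\dots,n_i$),
$x_{1i}$ for the cluster-level treatment indicator and $\rho$ for the
intracluster correlation coefficient (ICC), any analysis that ignores the
correlation understates standard errors and overstates significance. This
package implements, behind one data container, the four individual-level
estimation strategies commonly compared for CRCTs:

* **Random-intercept GLMM** (cluster-specific): $y_{ij} = \beta_0 + \beta_1
  x_{1i} + \dots + \tau_i + \varepsilon_{ij}$ with $\tau_i \sim N(0,
  \sigma_b^2)$. Continuous outcomes use the linear mixed model with ML or
  REML (`fit_lmm()`); binary outcomes use the logistic mixed model whose
  marginal likelihood is integrated by adaptive Gauss–Hermite quadrature
  (`fit_logistic_glmm()`, 10 nodes by default, 1 node = Laplace).
* **GEE1** (population-average): solves $\sum_i D_i' V_i^{-1} (Y_i - \mu_i)
  = 0$ with working covariance $V_i = \phi G_i^{1/2} R(\alpha) G_i^{1/2}$,
  alternating Fisher scoring for $\beta$ with moment estimation of
  $(\alpha, \phi)$; inference uses the robust sandwich covariance
  (`fit_gee1()`).
* **GEE2**, three-estimating-equation form: adds a scale equation for the
  squared Pearson residuals (identity link) and a correlation equation for
  pairwise residual products (Fisher-z link), solved jointly with the mean
  equation (`fit_gee2()`).
* **QIF**: replaces $R(\alpha)^{-1}$ by a span of basis matrices, stacks the
  resulting extended scores $g_i(\beta)$, and minimises the GMM objective
  $Q_N(\beta) = \bar g_N' C_N^{-1} \bar g_N$ with $C_N = N^{-2}\sum_i g_i
  g_i'$ (`fit_qif()`). The minimised objective is an over-identification
  statistic, asymptotically $\chi^2_{(m-1)p}$ (`qif_gof_test()`).

# ICC estimators and negative values

Two estimator families coexist and deliberately disagree below zero:

* model-based (`model_icc()`): $\hat\rho = \sigma_b^2 / (\sigma_b^2 +
  \sigma_w^2)$, with $\sigma_w^2 = \pi^2/3$ on the latent logistic scale for
  binary outcomes. Non-negative by construction; a mixed model whose
  $\hat\sigma_b^2$ hits the zero boundary reports an ICC of exactly 0
  (`truncate_icc()` flags this).
* one-way ANOVA (`anova_icc()`): $\hat\rho = (MSB - MSW)/(MSB + (\bar n - 1)
  MSW)$ with the adjusted average cluster size $\bar n = (n - \sum n_i^2/n)/
  (N-1)$. Negative whenever $MSB < MSW$, which happens in a non-vanishing
  fraction of samples even at a true ICC of zero. Marginal-model working
  correlations (GEE1's $\hat\alpha$, GEE2's $\tanh(\hat z)$) are likewise
  reported untruncated.

This asymmetry — mixed models truncating at zero while marginal models report
negative values — is a real feature of applied CRCT analyses and is
reproduced, not hidden.

# Small-sample corrections

With few clusters, Wald-z inference from both mixed and marginal models is
anti-conservative. Two corrections are implemented, both leaving the point
estimate untouched:

* **Satterthwaite degrees of freedom** for the REML linear mixed model
  (`satterthwaite_dof()`): $\nu = 2 (c'Vc)^2 / \widehat{\mathrm{Var}}(c'Vc)$
  by the delta method over $(\sigma_b^2, \sigma_w^2)$ with the REML
  information matrix (computed numerically with `numDeriv`). For a balanced
  cluster-level contrast with a non-negligible variance ratio $\nu \to N-2$;
  at the $\sigma_b^2 = 0$ boundary the residual degrees of freedom $n - p$
  are returned (the between-cluster information is then empty and the
  restricted information matrix is singular).
* **Fay–Graubard** for GEE1 (`fay_graubard_covariance()`): each cluster's
  score contribution is inflated by $\{1 - \min(b, H_{jj})\}^{-1/2}$, with
  $H_{jj}$ the diagonal of $D_i'V_i^{-1}D_i B^{-1}$ and bound $b = 0.75$.
  $H_{jj}$ is additionally floored at 0 — it is not mathematically guaranteed
  non-negative in finite samples — so corrected SEs can never be smaller than
  uncorrected ones.

Corrections for GEE2 and QIF are known in the literature but are not
implemented here (they are not available in standard software either);
instead `fit_qif()` warns whenever $N \le 43$ clusters, the range in which
QIF inference is documented to be anti-conservative.

# What the synthetic generator emulates

No real trial data ship with the package, so `simulate_crct()` generates the
statistical structure the motivating case studies exhibit: 10–100 clusters,
mean cluster sizes roughly 18–155 with strongly right-skewed distributions
(rounded log-normal, truncated at 1, allowing size-one clusters), 1:1 or 2:1
cluster-level allocation with exact counts, ICC in $[0, 0.05]$, optional
prognostic covariates, and small MCAR missingness (0–7%) handled by
complete-case analysis. Binary outcomes define the ICC on the latent
logistic scale ($\sigma_w^2 = \pi^2/3$), matching the model-based estimator.

Defaults chosen once for the simulation suites, where the sources are
silent, and not revisited:

* total gaussian variance 25 (an EPDS-like outcome with SD 5) and ICC 0.02,
  the typical value in the case studies;
* null scenarios at $N = 100$ use rounded-lognormal sizes with mean ≈ 20 and
  `sdlog` 0.8, matching the heavy skew of the larger trials; the $N = 10$
  correction scenario instead mirrors the one real 10-cluster trial (large
  clusters, mean ≈ 155, `sdlog` 0.45);
* cluster-level randomisation only, no stratification; MCAR only.

A green simulation test therefore establishes calibration *under this
stated world* — normal random intercepts, non-informative cluster sizes,
correctly specified mean models — and nothing about misspecified
random-effect distributions, informative cluster size, or MAR/MNAR
missingness.

One subtlety the test suite documents: the one-way ANOVA ICC pools both
arms, so under a non-zero treatment effect it converges to the *marginal*
ICC (between-cluster variance inflated by $\beta_1^2/4$ under 1:1
allocation), not the conditional generative ICC; the recovery test asserts
exactly that.

# Numerical choices

* **LMM**: the variance ratio $\lambda = \sigma_b^2/\sigma_w^2$ is profiled
  (GLS and $\hat\sigma_w^2$ closed form given $\lambda$), leaving a smooth
  1-D objective in $\log\lambda$ maximised by golden-section search on
  $[-25, 15]$ and compared explicitly against the $\lambda = 0$ boundary.
* **Binary GLMM**: per-cluster conditional modes by simultaneous Newton
  iterations; Gauss–Hermite nodes from the Golub–Welsch eigen-decomposition;
  outer BFGS on $(\beta, \log\sigma_b)$; explicit boundary test against the
  plain logistic MLE. Increasing the node count changes the log-likelihood
  by $< 10^{-6}$ between 10 and 40 nodes on small datasets.
* **GEE1/GEE2**: exchangeable $R^{-1}$ applied in closed form
  (Sherman–Morrison structure), so each scoring step is $O(np)$; moment
  denominators use the $(n - p)$- and (pairs $- p$)-style finite-sample
  adjustments, with the unadjusted variant available as a switch;
  $\hat\alpha$ clipped (with a warning) only at the invertibility boundary
  $-1/(\max n_i - 1)$. Convergence: relative change $< 10^{-8}$, max 200
  (GEE1) / 500 (GEE2) iterations. GEE2's joint covariance is the stacked
  sandwich with the bread obtained by numerical differentiation of the
  summed estimating functions.
* **GEE2 links**: identity for the scale block, Fisher z ($\rho = \tanh z$)
  for the correlation block, so the fitted correlation is structurally inside
  $(-1, 1)$; the correlation design includes the $n_i(n_i+1)/2$ diagonal
  entries with $\rho_{jj} \equiv 1$ fixed (they influence no parameter but
  keep the printed dimension). Clusters of size one simply contribute no
  pairs.
* **QIF**: initialised at the independence GEE1 solution; Newton-type
  direction from the working curvature $2\,\dot g' C_N^{-1} \dot g$ paired
  with the *exact* numerical gradient of $Q_N$ and Armijo backtracking, so
  accepted steps decrease the true objective monotonically and the fixed
  point is a stationary point of $Q_N$ itself (verified against independent
  generic minimisers in the tests). $C_N$ is inverted by eigen
  decomposition with eigenvalues floored at $10^{-10}$ of the largest;
  regularisation is always flagged. With only cluster-level covariates and
  *equal* cluster sizes the second exchangeable basis block is exactly
  collinear with the first per cluster ($X_i'(J - I)r_i = (n_i - 1)
  X_i'r_i$), a degenerate corner worth knowing about: the fit then rests on
  the regularised directions.

# Design decisions taken where the design was open

* The GEE2 correlation link is the plain Fisher z ($z = \operatorname{atanh}
  \rho$); software variants sometimes use $\log\{(1+\rho)/(1-\rho)\} = 2
  \operatorname{atanh}\rho$, which changes only the parameterisation, not
  the fitted correlation.
* QIF reports as its "ICC" the same Pearson-residual moment estimate GEE1
  uses, evaluated at the QIF coefficients — QIF itself never estimates a
  correlation parameter.
* The exchangeable and AR(1) basis sets use two matrices each; the
  alternative tri-diagonal-plus-corner convention for AR(1) exists but the
  two-matrix form is the default everywhere, and exchangeable is the working
  structure used throughout.
* Binary GLMM is ML-only (REML is not defined for it in the implemented
  sense); its small-sample degrees of freedom, when wanted, are the number
  of clusters minus the cluster-level parameters.

# Known limitations

* QIF's coefficient covariance $(\dot g' C_N^{-1} \dot g)^{-1}$ is known to
  be downward-biased when $N$ is small-to-moderate and cluster sizes are
  unequal; the package's own null-scenario suite measures an inflated QIF
  type-I error at $N = 100$ under heavily skewed sizes while GLMM, GEE1 and
  GEE2 stay within the nominal band. No correction is applied — the fit
  warns instead — so QIF p-values with few or very unequal clusters should
  be read with the same caution the applied literature recommends.
* Single random intercept only; no crossed/multiple random effects, no
  stepped-wedge or crossover layouts, no informative cluster size, no
  MAR/MNAR mechanisms, no covariate-dependent correlation models (the GEE2
  machinery is intercept-only for scale and correlation in this version).
* The Satterthwaite correction is implemented for the linear mixed model
  only, matching where it is defined and routinely used.
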
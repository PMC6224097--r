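---
title: "Methods: segmented multilevel modified-Poisson evaluation of a delivery-fee subsidy"
author: "mpits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented multilevel modified-Poisson evaluation of a delivery-fee subsidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpits)
```

## The scientific problem

Burkina Faso introduced a national subsidy for facility deliveries and
emergency obstetric care, officially on 1 January 2007, with district-level
rollout stretching into April 2007. `mpits` implements an interrupted
time-series (segmented regression) evaluation of that policy on two binary
outcomes observed in survey birth histories: delivery in a health facility
(recorded for births in the 5 years before the survey) and neonatal death
(death within 28 days, births in the 10 years before the survey). Because
the policy was national, there is no contemporaneous control group; the
design contrasts each outcome's level and slope before and after the
cutoff, controlling the secular trend.

## The model

The unit of analysis is the live birth \(i\), nested in woman/household
\(j\), nested in enumeration cluster \(k\). For an outcome \(Y_{ijk}\) the
package fits

\[
\log \mu_{ijk} = (\beta_0 + \gamma_{0jk} + \gamma_{00k})
 + (\beta_1 + \gamma_{1k})\,T_{ijk}
 + (\beta_2 + \gamma_{2k})\,I_{ijk}
 + (\beta_3 + \gamma_{3k})\,P_{ijk}
 + \beta_4 \mathrm{Rural}_k + \beta_5 \mathrm{SES}_{jk}
 + \beta_6 \mathrm{Educ}_{jk} + \beta_7 I\!\times\!\mathrm{Rural}
 + \beta_8 I\!\times\!\mathrm{SES} + \beta_9 I\!\times\!\mathrm{Educ}
 + \beta_{10}' X_{ijk},
\]

with \(Y \sim \text{Poisson}(\mu)\) even though \(Y\) is binary — the
"modified Poisson" device that makes \(e^{\beta}\) a rate ratio directly.
\(T\) is calendar time in months from the outcome's origin (June 2005 for
delivery, January 2000 for mortality), \(I\) the subsidy indicator, and
\(P\) the post-time (months since introduction, 0 before), so \(\beta_1\)
is the secular trend, \(\beta_2\) the immediate level change and
\(\beta_3\) the slope change. The controls \(X\) are maternal age group,
multiple birth, birth order or preceding interval, newborn sex and
occupation, with references literate / poorest / single / 15–19 /
first birth / not worked / January.

Because the Poisson variance is wrong for binary data, all reported
standard errors are region-clustered sandwich estimates with the
small-sample factor \(G/(G-1)\) (the survey has \(G = 13\) regions; the
factor is our documented choice, the source analysis is silent on it).

### Estimation

The marginal likelihood integrates the cluster-level random effects by
adaptive Gauss–Hermite quadrature: per cluster, the integrand is centred
at the posterior mode (found by a damped Newton search) and scaled by the
local curvature; tensor-product nodes are used in up to two dimensions
(default 7 per dimension) and the Laplace approximation (one node) above
two, mirroring common GLLAMM-style practice. A woman-level random
intercept is handled by nesting a one-dimensional quadrature per woman
inside each outer node; with one node at both levels this reproduces the
joint Laplace approximation exactly via the Schur complement of the joint
Hessian. The covariance \(\Psi\) of the cluster effects is parameterized
by its log-Cholesky factor (positive semi-definite by construction),
unstructured by default because the source analysis reports an
intercept–subsidy correlation of \(-1\) alongside the diagonal entries
\(\psi_{11}, \psi_{22}, \psi_{33}\).

The optimizer is BFGS on the full parameter vector with central-difference
gradients, relative log-likelihood tolerance \(10^{-8}\), and up to two
perturbed restarts. A variance component estimated at the boundary
(variance below `boundary_tol`, default \(10^{-3}\)) triggers an automatic
refit without that term and is flagged — this reproduces the collapse to a
simple Poisson regression that the source analysis reports for the urban
stratum, where no between-cluster variance was found. When no random
terms remain the fit is an exact Newton–Raphson Poisson ML fit.

Model-building rules follow the source procedure: interactions are tested
jointly and separately by likelihood-ratio tests at 0.05 (a significant
subsidy-by-rural interaction for the delivery outcome triggers separate
urban/rural analyses); variance components are tested with the 50:50
\(\chi^2_{k}:\chi^2_{k+1}\) boundary mixture; over-dispersion is screened
by adding a birth-level random intercept; confounders and the seasonal
calendar-month terms are kept when they move the subsidy coefficient by at
least 10%; multicollinearity is checked by variance inflation factors.

### Standardization (g-computation)

For each post-policy horizon \(h \in \{0, 6, \dots, 42\}\) months, each
birth's rate is predicted twice — with and without the subsidy — after
replacing the time variables by their horizon values, and including the
empirical-Bayes (posterior-mode) random-effect values of the birth's
cluster (and woman). The means of the two prediction vectors give the
standardized rates; their ratio and difference are the marginal RR and RD.
Two readings of "replacing the time variables" are implemented:

* `time_mode = "policy"` (default): \(T\) is set to the policy-timeline
  value (cutoff \(-\) origin \(+ h\)) for every birth, i.e. the population
  is standardized to the policy calendar;
* `time_mode = "observed"`: each birth keeps its own \(T\).

Confidence intervals use the delta method over the fixed effects only:
gradients of \(\log RR\) and \(RD\) by central finite differences (step
\(10^{-5}\max(1,|\beta|)\)), variance \(g'\Sigma g\) with the robust
\(\Sigma\) by default, RR intervals formed on the log scale. Uncertainty
in \(\Psi\) and in the EB values is deliberately not propagated — a
documented limitation matching the delta-method-on-predictions
description of the source. Predicted rates above 1 (possible under a log
link) are capped and counted; a grid carries a warning when more than 1%
of predictions were capped.

### Exposure scenarios

Because the rollout made the exposure of early-2007 births uncertain,
three codings are provided: `primary` (exposed from January 2007),
`shift_april` (exposed from April 2007) and `exclude_q1` (births of
January–March 2007 dropped and counted). Births in the cutoff month are
coded exposed: month-resolution data cannot split a month. A fourth,
`oracle`, uses the generator-recorded true exposure and exists for
misclassification studies on synthetic data: with a staggered rollout the
calendar codings misclassify some cutoff-quarter births, attenuating the
estimated immediate effect toward zero — the rationale for the sensitivity
analyses.

## The synthetic population

The survey microdata behind the original analysis is registration-gated,
so the package ships a fully specified generator
([population_config()], [generate_population()]) that emulates its
structure: 13 regions, ~550 clusters, households and women per the survey
profile, ~32,000 live births January 2000 – December 2010 with 1–8 births
per woman (median 3). Directly assigned covariates (residence, wealth,
education, literacy, occupation, sex, multiple birth) match the published
margins by exact-composition assignment (largest-remainder apportionment,
then random permutation), so their empirical shares deviate from the
targets only by integer rounding. Birth histories are built from an
age-at-first-birth distribution, a prior-parity distribution and gamma
inter-birth intervals, which makes maternal age, birth order and
preceding-interval *emergent* quantities; their margins were calibrated
once to the published table (first births 19.3%, interval mix
35/45/19%, age mix peaking at 20–24) and are not exactly enforced —
within-woman age monotonicity is enforced instead.

Outcomes are drawn from the model above. Generator defaults take the
published coefficient values where printed (urban intercept −0.54, rural
deficit −0.38, immediate subsidy effect 0.039 urban / 0.139 rural, cluster
intercept variance 0.7682 and subsidy-coefficient variance 0.0819 with
correlation −0.9 for delivery). The per-month time-slope variance
defaults to zero: at the printed magnitude (0.0044) a log-link generator
would spread cluster rates by \(e^{\pm 0.066 \times 60}\) over the
five-year window, which is degenerate; the component remains available in
`true_psi` for users who want it. Mortality coefficients encode a ~3.5%
baseline neonatal mortality with a gentle secular decline and an immediate
RR near 0.93 growing with time since introduction — magnitudes consistent
with the published mortality tables, chosen once and documented here.
Log-link generation can imply rates above 1; they are truncated just
below 1 before the Bernoulli draw and counted, with a warning above a
configurable fraction. Under the published-values delivery regime this
truncation affects roughly a quarter of births, which is why refitting
the model to such data recovers visibly smaller cluster variances than
the generating ones: saturation compresses the realized heterogeneity.
Recovery and calibration studies therefore use a lower-baseline regime
(documented in their code) where truncation is negligible and the
generating coefficients are the estimand. Twin deliveries share a single facility-delivery
outcome (one delivery) while neonatal deaths stay per-birth.

What the generator does **not** emulate: the two-stage sampling design and
weights, interview-date structure, non-response, stillbirths and maternal
deaths, and item missingness (it emits complete data). Tests passing on
this synthetic population therefore validate the estimation machinery,
not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Quadrature: 7 nodes per dimension up to \(q = 2\), Laplace above;
  the test suite verifies 7-node and 15-node log-likelihoods agree to
  \(10^{-4}\) per observation, and the likelihood itself against
  brute-force trapezoid integration to \(10^{-6}\).
* Mode searches are damped Newton iterations with per-group step halving
  and non-finite guards; wild optimizer proposals (overflowing variances)
  are absorbed as large finite penalties instead of errors.
* An all-zero outcome returns an explicit non-converged failure object,
  never a crash; aliased designs are reported as singular.
* Exact \(-1\) random-effect correlations are represented as
  rank-deficient PSD covariances (eigen square root, not Cholesky).
* Reproducibility: one master seed; every stochastic routine derives its
  own stream from it, so modules are independently reproducible and two
  runs with the same config are byte-identical.

## Problem sizes used in the shipped studies

The packaged simulation studies run at sizes chosen to make the full
suite convenient to run routinely while keeping every estimator in its
asymptotic regime: parameter recovery at ~250 clusters / ~12,000 births
(10 replicates), CI calibration at ~60 clusters (100 replicates, a
deliberately scaled-down regime), the standardization oracle at ~200
clusters, and the misclassification study on an observation window
concentrated around the cutoff (months 36–131), where the design has the
most information about the discontinuity. The full-scale population
(~550 clusters, ~32,000 births) is used where only generation and
descriptive accounting are involved.

## Known limitations

* The modified-Poisson likelihood is intentionally mis-specified for
  binary outcomes; robust variances correct the standard errors but the
  point estimates rely on the log-link rate model being right.
* Delta-method intervals ignore uncertainty in \(\Psi\) and in the EB
  predictions; with few regions the sandwich itself is only
  asymptotically calibrated in \(G\). In the packaged scaled-down
  calibration study (60 clusters, 20 regions) the nominal 95% interval
  for the marginal RR covers generator truth roughly 88–90% of the time:
  the interval widths track the empirical sampling spread closely, but
  at that scale the immediate-effect estimate itself acquires a small
  downward finite-sample bias (and, asymptotically, a small upward
  pseudo-true shift from applying a Poisson likelihood to Bernoulli
  outcomes — shared by any implementation of the method, including
  lme4, which reproduces this package's fits to four decimals).
* The staggered-rollout generator assigns rollout month at cluster level;
  the real rollout was by health district, a coarser unit the survey does
  not identify.
* Survey weights and the two-stage design are out of scope throughout,
  matching the unweighted source analysis.
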
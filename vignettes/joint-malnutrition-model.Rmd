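---
title: "Joint distributional regression of four child-malnutrition indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint distributional regression of four child-malnutrition indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mvdreg` models the four standard child-malnutrition indicators jointly:
hemoglobin concentration (Hb, g/L) and the three WHO growth z-scores
(height-for-age HAZ, weight-for-age WAZ, weight-for-height WHZ).  For child
$i$ the response vector

$$\mathbf{y}_i = (\mathsf{Hb}_i, \mathsf{HAZ}_i, \mathsf{WAZ}_i,
\mathsf{WHZ}_i)^\top \sim \mathcal{N}(\boldsymbol\mu_i, \boldsymbol\Sigma_i)$$

has a covariate-dependent mean vector *and* covariance matrix.  The
covariance is parameterised by the modified Cholesky decomposition
$T \Sigma T^\top = D^2$, where $T = I - \Phi$ is unit lower triangular and
$D = \mathrm{diag}(e^{\lambda_1}, \ldots, e^{\lambda_4})$.  The entries of
$\Phi$ (six free coefficients) and $\lambda$ (four log innovation scales) are
unconstrained real numbers, so all $4 + 4 + 6 = 14$ distributional parameters
can carry additive predictors while $\Sigma_i$ stays positive definite by
construction.  Links are identity for the means and the $\Phi$ entries and
log-scale for the innovation scales (the predictor *is* $\lambda$).

The parameterisation is order dependent; the response ordering
(Hb, HAZ, WAZ, WHZ) is fixed everywhere.  Reconstructed quantities —
$\Sigma$, marginal standard deviations, pairwise correlations — do not depend
on the ordering once rebuilt, but the individual $\varphi$ and $\lambda$
values do.  Serialisation order of the 14 parameters is
$(\mu_{1..4}, \lambda_{1..4}, \varphi_{21}, \varphi_{31}, \varphi_{32},
\varphi_{41}, \varphi_{42}, \varphi_{43})$.

Prevalences are derived from the fitted Gaussian marginals,
$P(\mathsf{Hb} < 110\,\mathrm{g/L})$ for anemia and $P(z < -2)$ for stunting
(HAZ), underweight (WAZ) and wasting (WHZ).  Overweight defaults to
$P(\mathsf{WAZ} > 2)$ with the weight-for-height convention
$P(\mathsf{WHZ} > 2)$ available via
`indicator_definitions(overweight_on = "whz")`; both definitions are in
circulation and we expose the choice rather than hard-code one.  The anemia
cutoff of 110 g/L applies to children aged 6–59 months; any
altitude-, age- or sex-specific cutoff adjustment is assumed to have been
applied to the Hb values upstream.

## The staged fitting approach

`mvdr()` runs five stages:

1. **Spatial split.**  Survey clusters (PSUs) are split 80/20 at cluster
   level — children of one cluster never straddle the partitions — using a
   Delaunay triangulation of the cluster sites.  The triangulation fixes an
   adjacency structure; test clusters are chosen by farthest-point sampling
   over that adjacency, preferring interior (non-hull) vertices.  This was a
   genuinely open design point: the triangulation is given, the selection
   rule is not.  Farthest-point sampling maximises the spatial spread of the
   held-out clusters, which is the stated purpose of a spatially
   representative split, and the interior preference keeps test clusters
   inside the training hull so validation measures interpolation, not
   extrapolation.  Degenerate geometry (collinear sites) falls back to a
   seeded random split with a warning.
2. **Baseline.**  The intercept-only model has a closed form: the sample
   mean and the $n$-denominator sample covariance, re-expressed through
   `sigma_to_factors()` as 14 intercepts.
3. **Boosting.**  Componentwise gradient boosting over all candidate
   (parameter, term) pairs.  Each iteration fits every candidate to the
   score $\partial \ell / \partial \eta_k$ of its parameter's predictor by a
   ridge fit calibrated to 4 effective degrees of freedom (so smooths of
   different basis sizes compete fairly), then applies the single update
   that most increases the *actual* training log-likelihood, damped by the
   step length $\nu = 0.1$.  Scoring candidates by likelihood improvement
   rather than by gradient-fit residual sum of squares matters: gradient
   variances differ systematically across the 14 parameters, and RSS scoring
   would bias selection toward high-variance parameters even on pure noise.
   A step-halving safeguard makes the training log-likelihood non-decreasing
   by construction.  The effective number of iterations is chosen by the
   log-score on an internal 10% holdout (stop after 30 iterations without
   improvement; selections after the best iteration are discarded).
   Selection frequencies are per-iteration shares over the iterations
   actually executed, so an early stop with nothing selected reads as "no
   evidence", not as missing data.
4. **Pruning and MCMC.**  Terms with selection frequency below 0.05
   (configurable) are omitted; intercepts always stay.  The final model is
   estimated by a single-chain block Metropolis–Hastings sampler: each
   (parameter, term) coefficient block is proposed from its
   iteratively-weighted-least-squares Gaussian approximation — expected
   Fisher information for $\mu$ and $\lambda$ blocks, observed information
   for $\Phi$ blocks (which is exact conditional on the preceding responses)
   — plus the prior precision, and accepted with the exact MH ratio.
   Penalised blocks carry multivariate normal priors with precision
   $K/\tau^2$; the smoothing variances $\tau^2$ get weakly informative
   IG(0.001, 0.001) hyperpriors and conjugate Gibbs updates.  Chains start
   at the baseline intercepts.  Defaults are 2000 iterations, 1000 burn-in,
   thinning 10 for `fit_mcmc()`; the pipeline default (1500/500/5) reflects
   that the IWLS proposals accept near 1 and deliver close-to-independent
   draws, so moderate chains already give stable posterior summaries.
5. **Validation.**  Held-out joint log-score against the baseline (a warning
   is issued if the final model scores worse), per-response quantile
   residuals $r = \Phi^{-1}(F_m(y_m))$, coverage of central 90% predictive
   intervals, and a spatial $k$-fold cross-validation harness (default
   $k = 5$) that reuses the farthest-point fold construction at cluster
   level.  Full multivariate calibration transforms (joint PIT variants)
   are deliberately out of scope; per-margin residuals plus the joint
   log-score cover the calibration questions the pipeline asks.

## Terms, penalties and numerical choices

* P-splines: cubic B-splines, 20 marginal basis functions, second-order
  difference penalty — the standard Eilers–Marx defaults.  Knots are
  equidistant over the observed covariate range with `degree` extra knots on
  each side; evaluation outside the training range is clamped to the
  boundary (flat extrapolation, flagged by design rather than by error).
* Spatial term: tensor product of two marginal P-splines over (lon, lat),
  default 10 × 10 basis, Kronecker-sum penalty
  $K_{lon} \otimes I + I \otimes K_{lat}$.
* Penalised smooths are centered (sum-to-zero constraint, absorbed by a QR
  projection) for identifiability next to the intercepts.
* Factor covariates are dummy-coded against the first level, unpenalised;
  linear covariates are standardised internally.
* Numerical floors: $e^\lambda$ is floored at $10^{-8}$ when reconstructing
  moments, a $10^{-6}$ ridge keeps proposal precisions invertible, and a
  $10^{-8}$ ridge stabilises the boosting base-learner solves.
* Model specifications round-trip through YAML (`spec_to_yaml()` /
  `spec_from_yaml()`).

## The synthetic survey generator

Real DHS microdata are restricted, so the generator supplies surveys with the
statistical structure the model assumes, plus the truth needed to score every
stage.  It emulates: clustered spatial sampling (default 250 PSUs of 15–30
children, uniform cluster sites in a 20° × 20° box), ages 6–59 months,
covariate-dependent means, smooth environmental covariates (temperature,
malaria incidence, elevation, spatially correlated land cover including
"Barren" and "Permanent Snow and Ice", wealth quintiles with a west–east
gradient), and a base correlation structure with $\rho(\mathsf{HAZ},
\mathsf{WAZ}) = 0.68$, $\rho(\mathsf{WAZ}, \mathsf{WHZ}) = 0.70$, a weakly
negative $\rho(\mathsf{HAZ}, \mathsf{WHZ})$ and small Hb–anthropometry
correlations.  A constant correlation matrix cannot carry
$\rho(\mathsf{HAZ}, \mathsf{WHZ})$ below about $-0.05$ alongside the two
strong positive pairs (positive definiteness fails), so the default is
$-0.03$.  Default age effects make anemia and wasting decline with age and
stunting rise up to month 36 and then plateau.  Marginal standard deviations
(Hb 15 g/L, z-scores 1.1–1.3) are plausibility choices, as are the baseline
means; they are configuration, not estimates.

Environmental fields use a fixed low-rank random-cosine expansion — a fast,
reproducible stand-in for Gaussian-process simulation whose realisations are
pure functions of location, so cluster sites and prediction pixels see the
same surfaces.  A plausibility guard redraws the rare response rows
(Gaussian tail mass around $10^{-3}$ at default scales) with non-positive Hb
or $|z| \ge 6$; this mild truncation is negligible for all moment-recovery
checks.

What the generator does *not* emulate — and hence what passing tests do not
establish about real surveys: DHS sampling weights and non-response,
measurement error in Hb (no established correction exists), non-Gaussian
tails or skewness in the indicators, country stratification, and real
covariate maps.  Conclusions from the synthetic checks are about the
correctness of the machinery, not about any population.

## Surfaces, masking and age profiles

Prediction grids use pixel centers on a regular 0.18° step (about 20 km at
the equator); a true equal-area grid is out of scope and the regular-degree
step is documented as an approximation.  Pixels with land cover "Barren" or
"Permanent Snow and Ice", or elevation strictly above 3000 m, are flagged as
not included (missing elevation gets its own flag) and carry no derived
values.  Surfaces can be derived at a fixed reference age (`at = list(age =
24, ...)`) or averaged over an age distribution by the caller; both modes
are legitimate summaries and neither is claimed to be canonical.  Age
profiles at a location fix all other numeric covariates at the median and
categorical covariates at the mode observed within a 20 km great-circle
(haversine) buffer, ties broken by the first sorted level.

Posterior uncertainty of any derived quantity (prevalence, correlation) is
summarised by the mean and the equal-tailed 95% interval over the stored,
thinned draws.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen as the
package's own working sizes: unit tests use surveys of a few hundred to a
few thousand children with short chains; the replicate-level recovery checks
use 20 replicates of 5,000 children (intercept-only chains of 600
iterations); surface recovery fits about 20,000 children with an 8 × 8
spatial basis; the acceptance script runs the full pipeline on the default
~5,000-child survey with 300 boosting iterations and an 800-iteration chain.
With near-unit acceptance rates these chain lengths give effective sample
sizes close to the number of stored draws.

## Known limitations

* Single-chain MCMC with seeds; between-chain convergence diagnostics are
  not part of the interface.
* No random effects (e.g. country level) and no interaction smooths beyond
  the lon/lat tensor.
* The Gaussian family is a modelling assumption; skewed or heavy-tailed
  multivariate families are out of scope.
* Selection frequencies depend on the boosting configuration (step length,
  equal-df calibration, early-stopping holdout); they are a relative
  informativeness measure, not posterior inclusion probabilities.
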
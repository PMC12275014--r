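---
title: "Modeling extreme deviations from normative reference models"
author: "extremeNorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling extreme deviations from normative reference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremeNorm)
```

# The problem

Normative models describe how a continuous phenotype (a brain volume, a
cortical thickness, a lab value) varies with covariates such as age, sex and
acquisition site across a reference cohort, the way growth charts describe a
child's weight against age. Each subject is then summarized by a deviation
score — a z statistic measuring how far they sit from the cohort's predictive
distribution at their covariates. Most downstream statistics treat these
deviations with bulk tools (means, covariances, ordinary PCA). But for
questions about atypicality — risk, anomaly detection, severe clinical
phenotypes — the information sits in the *tails* of the deviation
distribution, and bulk tools systematically misestimate tail probabilities.
Worse, dependence in the bulk of a multivariate distribution need not
resemble dependence in its joint tails: two variables can be strongly
correlated yet almost never be extreme together, and vice versa.

extremeNorm implements a full chain of tools for this regime:

1. **Normative stage** — per-variable Bayesian linear regression with an
   optional monotone response warp, producing held-out deviation scores.
2. **Univariate tails** — peaks-over-threshold fits of the generalized
   Pareto distribution (GPD), block-maxima fits of the generalized extreme
   value distribution (GEVD), threshold diagnostics, return levels.
3. **Multivariate tails** — a rank-based Fréchet marginal transform, polar
   decomposition with a radial threshold, the tail pairwise dependence
   matrix (TPDM), and its eigendecomposition into *extreme principal
   components* with loadings and contributions.
4. **Evaluation** — Spearman / point-biserial screening of component scores
   against behavioral phenotypes under Bonferroni correction, plus the
   standard-PCA and deviation-count comparators.
5. **Synthetic data** — generators with analytically known tail dependence,
   so every stage can be validated against an exact oracle.

# The normative stage

For one variable with response $y$ and covariates (age, sex, site), the
model is a Bayesian linear regression on a fixed basis: an intercept, a
cubic B-spline in age with interior knots at training quantiles, a sex
indicator and one-hot site columns. Prior precision $\alpha$ and noise
precision $\beta$ are set by maximizing the marginal likelihood (the
evidence), which avoids hand-tuned ridge penalties. The held-out deviation
score is

$$ z = \frac{w(y) - \mathbf{x}^\top \mathbf{m}}
           {\sqrt{1/\beta + \mathbf{x}^\top S \mathbf{x}}}, $$

with $\mathbf{m}, S$ the posterior mean and covariance of the weights, so
the denominator carries both irreducible noise and weight uncertainty.

`warp = TRUE` additionally estimates a monotone sinh-arcsinh response
transform $w(y) = \sinh\!\big(\delta\,\mathrm{asinh}((y-a)/b) -
\epsilon\big)$ by maximum likelihood (evidence plus warp Jacobian), with the
affine layer $(a, b)$ pinned to the training moments so the optimization is
two-dimensional. This family nests the identity, controls skew through
$\epsilon$ and tail weight through $\delta$, and is invertible in closed
form. It is a deliberately simplified variant of warped Bayesian linear
regression as used in normative-modeling practice: the full approach also
warps with richer compositions and estimates all parameters jointly. The
simplification keeps one smooth, strictly monotone warp per variable, which
is what the downstream tail statistics need — the rank transform of the
multivariate stage absorbs any remaining monotone misspecification.

Fit quality is reported as held-out explained variance, mean standardized
log loss (MSLL; predictive negative log-likelihood minus that of a trivial
Gaussian fitted to the training response, negative = better than trivial),
and the skewness and excess kurtosis of the held-out deviations. The QC
filter in `fitNormativeAll()` excludes variables with negative explained
variance or |skewness| > 2 or |excess kurtosis| > 10 by default; the bounds
are configurable and deliberately permissive, since their purpose is to drop
clearly mis-fitted variables rather than to enforce Gaussianity.

The default train fraction is 0.1, appropriate for biobank-scale cohorts
where one wants most subjects in the evaluation split; for small datasets a
split-half is the better choice, and the fraction is a config field.

# Univariate tails

Above a high threshold $k$, excesses $y = z - k$ of a well-behaved variable
follow a GPD,

$$ H(y) = 1 - (1 + \xi y / \tilde\sigma)^{-1/\xi}, $$

with the exponential limit as $\xi \to 0$. `fitGPD()` maximizes the excess
likelihood over $(\log\tilde\sigma, \xi)$ with $\xi$ restricted to
$(-0.5, 1]$ (outside that range the MLE loses regularity), started from
probability-weighted-moment estimates; standard errors come from the
inverse observed information, and profile likelihoods are available through
`gpdProfile()`. Numerically, $|\xi| < 10^{-6}$ switches to the exponential
forms, and all distribution functions use `log1p`/`expm1` so that
cdf/quantile round-trips hold to $10^{-12}$ and the $\xi \to 0$ limit is
continuous.

Threshold choice is a judgement, made with two diagnostics. The mean
residual life plot shows the mean excess against $k$ with a normal band; it
is linear with slope $\xi/(1-\xi)$ where the GPD holds (flat for an
exponential tail). The parameter stability plot refits the GPD along a
candidate grid (default: empirical quantiles 0.50–0.995 in steps of 0.005)
and reports the shape and the modified scale $\sigma^* = \tilde\sigma - \xi
k$, both threshold-invariant in expectation under the GPD; delta-method
intervals quantify the noise. On z-scores of large cohorts these curves
typically stabilize around the 95th percentile, which is why that quantile
is also the default radial threshold downstream. No automatic selection is
attempted: the diagnostics are emitted as tidy tables for visual use.

`returnLevel()` converts a fit into the level exceeded once per $m$
observations, $x_m = k + (\tilde\sigma/\xi)\{(m\zeta)^\xi - 1\}$ with
$\zeta$ the exceedance rate; it refuses $m\zeta < 1$, where the tail model
says nothing. Block maxima and the GEVD (`fitGEVD`) are included for
completeness and for data with natural block structure.

# Multivariate tails and the TPDM

Multivariate regular variation requires a common heavy tail. Each deviation
column is therefore rank-transformed, $\hat F = \text{rank}/(n+1)$
(mid-ranks for ties; the $n+1$ denominator keeps $\hat F < 1$), and mapped
through the Fréchet($\alpha = 2$) quantile function

$$ x = (-\log \hat F)^{-1/2}, $$

whose CDF is $\exp(-x^{-2})$. Both maps are strictly monotone, so the
copula — and hence all tail dependence — is exactly preserved while the
margins become unit-scale Fréchet with tail index 2. A consequence worth
stating: *any* strictly monotone per-column transform of the input leaves
everything downstream unchanged, so the multivariate stage is insensitive
to monotone misspecification of the normative stage.

In polar coordinates $x = r\omega$ (L2 norm; L2 is what makes products of
angle components estimate the second moments below for $\alpha = 2$),
observations with $r$ above the empirical 0.95 radial quantile $r_0$ are the
multivariate extremes. The TPDM is the matrix of second moments of the
angular components over those extremes:

$$ \hat\sigma_{ij} = \frac{c}{n_{\mathrm{exc}}}
   \sum_n \omega_{ni}\,\omega_{nj}\, \mathbb{1}(r_n > r_0). $$

Two normalizations of $c$ are carried. The `"printed"` mode uses $c = 2$,
under which the trace is exactly 2 for any input (each $\omega$ has unit
norm). The `"unit"` mode (default) uses $c = D$, under which unit-scale
Fréchet(2) margins give a unit diagonal and the trace is exactly $D$ —
the analogue of a correlation matrix. The two differ by the positive scalar
$D/2$ only, so eigenvectors, scale proportions and contribution rankings
are provably identical across modes; both are exposed because conventions
differ across the literature.

`extremePCA()` eigendecomposes the TPDM: eigenvalues ("scales", the
extremal analogue of variances) in descending order with their proportions,
orthonormal eigenvectors with each vector's largest-magnitude entry made
positive (a documented tie-break so results are reproducible across
platforms). Loadings and contributions come in two conventions:
`"printed"` uses $f_l = u_l \lambda_l$ and $c_{dl} = f_{dl}^2/\lambda_l$;
`"conventional"` uses $f_l = u_l \sqrt{\lambda_l}$, under which each
component's contributions sum to one. A $1/D$ reference value is returned
for ranking displays.

Subject-level extreme-component scores are a reporting convention, not part
of the tail model; the package offers projection of the log pseudo-Fréchet
values (default — the log maps the positive half-line onto the real line,
so projections are two-sided) or of the raw values, and records the choice
in output metadata.

## The max-linear oracle

The estimator is validated against a construction whose TPDM is known in
closed form: the max-linear model $X_i = \max_k B_{ik} Z_k$ with i.i.d.
Fréchet(2) factors $Z_k$ and nonnegative $B$. Its angular measure is
discrete — mass $\lVert B_{\cdot k}\rVert^2$ at the atom
$B_{\cdot k}/\lVert B_{\cdot k}\rVert$ — so the TPDM is exactly $BB^\top$
when rows of $B$ have unit norm. `simulateTailZ()` additionally pushes each
column through its exact Fréchet CDF and the normal quantile function,
yielding standard-normal margins with the same copula: a synthetic
deviation matrix with planted, analytically known tail dependence. Fréchet
sampling is by inverse CDF, $Z = (-\log U)^{-1/\alpha}$ — exact margins, no
rejection step.

## A caveat on thresholds: the independence limit

The TPDM estimator at a *fixed* radial quantile is a pre-asymptotic
estimate. Under exact tail independence (diagonal $B$), the non-extreme
coordinate of an exceedance still contributes an angle of order $1/r_0$, so
off-diagonals carry a positive bias of that order no matter how large $n$
grows — at the default $q = 0.95$ on two variables the bias is roughly 0.3.
The bias vanishes only in the receding-threshold regime $q \to 1$; the
tests therefore check the independence limit at $q = 0.9998$ on $10^6$
draws ($r_0 \approx 100$), where it is genuinely in force, while oracle
recovery for dependent constructions is checked at the working quantile
$q = 0.95$, where the bias is small relative to the planted signal. Users
comparing TPDMs across datasets should keep the radial quantile fixed, and
should not over-read small off-diagonal values as evidence of dependence.

# Behavioral screening

`associateComponents()` correlates each phenotype with each leading
component: point-biserial (Pearson against the 0/1 code) when a phenotype
has exactly two distinct non-missing values, Spearman otherwise
(multi-level unordered categoricals are rank-correlated on their codes —
a pragmatic choice the category map should flag). Observations are
pairwise-complete; phenotypes with fewer than 3 values or no variation are
skipped and recorded. The family-wise threshold is Bonferroni,
$\alpha / (\text{phenotypes tested} \times \text{components})$, and
per-phenotype aggregation keeps the most significant component, so a
reported aggregate p is the maximum significance across the leading
components. Spearman p-values use the t approximation (the exact null
distribution below $n = 50$ without ties); no covariate adjustment is
applied, matching the screening design. Comparators: `standardPCA()`
(eigendecomposition of the Pearson correlation matrix, same output layout)
and `deviationCounts()` (per-subject counts of $|z| > 1.96$).

# What the synthetic generators emulate — and what they do not

`simulateCovariates()` draws ages uniform on 40–80 years, sex binary with
53% coded 1, and a categorical site — the covariate structure of a
large-cohort imaging study. `simulateCovariateIDP()` adds per-variable
smooth mean trends (intercept, linear and quadratic age, sex effect,
additive per-site intercepts) plus independent Gaussian noise: exactly the
well-specified regime in which normative calibration can be verified.
Site enters as an additive intercept only — no scanner physics, no
heteroscedasticity. `simulatePhenotypes()` plants continuous effects
(effect × standardized score + unit noise), binary effects (median split of
that latent, which keeps point-biserial power analyzable), and pure nulls.

Passing tests on these generators demonstrate that the *machinery* is
correct under its own assumptions. They do not demonstrate that real
imaging deviations are max-linear, that site effects are additive, or that
real tails are exactly GPD — those are modeling judgements the diagnostics
are meant to inform on real data.

Problem sizes in the test-suite and acceptance runs are chosen to keep
Monte-Carlo error comfortably inside the asserted tolerances at desk scale:
$n = 20{,}000$ subjects for TPDM oracle checks (where the entrywise error
is ~0.04), $10^6$ for the receding-threshold independence check, 200
replicates for coverage and calibration rates, 2,000 training / 10,000
test subjects for normative calibration. Calibration tolerances combine
test-sampling and training-estimation noise (e.g. the z-variance tolerance
is $3\sqrt{2/n_{\text{test}} + 2/n_{\text{train}}}$), since held-out
deviations share an estimated normalization.

# Design choices made where the design was open

- **Ground-truth family.** Max-linear, because its TPDM is available in
  closed form; copula alternatives would provide only simulated, not exact,
  oracles.
- **Bulk-versus-tail contrast.** `simulateBulkTailContrast()` plants a
  Gaussian-correlated pair (bulk) and an orthogonal pair of extreme rays
  (tail) with a bounded radius; the parameters come from a closed-form
  correlation budget — with tail fraction $\pi_t$ and ray radius $r$, the
  Pearson correlation of the tail pair is about
  $\pi_t E[r^2/2] / (1 - \pi_t + \pi_t E[r^2/2]) \approx 0.63$, kept below
  the bulk pair's 0.9 so standard PCA locks onto the bulk pair while the
  angular measure is dominated by the rays.
- **Missing data.** Complete-case before the marginal transform (the polar
  decomposition needs full vectors), with a logged count; pairwise-complete
  in the screening stage, matching phenome-screen practice.
- **Degenerate inputs.** Constant columns are errors naming the column;
  thresholds beyond the data are flagged undefined rather than dropped;
  zero eigenvalues yield zero contributions with a warning.
- **Seeds.** Every generator takes an explicit seed and restores the
  caller's RNG state, so pipelines are reproducible end to end and
  independent computations cannot silently share a stream.

# Known limitations

- The warp is a single sinh-arcsinh layer; heavily multimodal or discrete
  responses are out of scope (as are Gaussian-process or hierarchical
  normative variants).
- The TPDM summarizes the angular measure through second moments only; it
  cannot distinguish angular distributions with the same second moments,
  and no parametric model of the full angular measure is attempted.
- Extreme-PC subject scores are a convention (two are provided); tail
  theory does not single one out.
- At a fixed radial quantile the TPDM is pre-asymptotic (see the caveat
  above); all conclusions are conditional on the chosen quantile.
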
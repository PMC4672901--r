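---
title: "Models and methods behind mbmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmeta)
```

mbmeta synthesizes published T-maze short-term memory experiments in
*Drosophila*. This vignette is the package's own account of its models,
the choices made where the design was genuinely open, and what the test
suite does and does not establish.

## The data model

One record is one published experiment: an experimental arm (e.g. a
*rutabaga* hypomorph carrying a GAL4 driver and a UAS-*rut* responder)
and its control arm, each summarized by the number of T-maze iterations
and, when available, the mean Performance Index with SEM. Moderators
carried per record: post-training delay (minutes; "immediately" coded
0), odor pair and a benzaldehyde indicator derived from it, training
temperature (midpoint of any printed range; for temperature-shift
inactivation experiments the restrictive-arm temperature, since the
permissive arm is the matched control), shock voltage, current type and
relative humidity. Censored cells stay missing and are never imputed.

Shared-control linkage is explicit: records within one study and figure
whose control genotype and control iteration count coincide reused one
control arm and receive a common `shared_control_id`. The packaged
fixture transcribes the review's table of included experiments; it
contains no PI values (the printed table has none), so it supports
accounting and schema work but not pooling.

## Effect sizes

The primary metric is the percentage change of the experimental mean
relative to control, with a delta-method SE for a ratio of independent
means:

$$\mathrm{pct} = 100\left(\frac{m_E}{m_C}-1\right),\qquad
\mathrm{SE} = 100\left|\frac{m_E}{m_C}\right|
\sqrt{\left(\frac{s_E}{m_E}\right)^2+\left(\frac{s_C}{m_C}\right)^2}.$$

A zero control mean leaves the ratio undefined and a zero experimental
mean with positive SE makes the CV degenerate; both are rejected, and
the raw PI difference (variance-additive) is the fallback metric. The
two metrics always agree in sign and give equivalent inferences on this
kind of data. All intervals use the normal 1.96 multiplier, matching
the Cochrane-style tooling that this workflow emulates. Rescalings are
pure shifts: learning % = 100 + pct; rescue = learning − mutant
baseline (40% for strong *rut* hypomorphs); heat-adjusted = learning −
heat baseline (83%). Shifts preserve SEs and interval widths and are
invertible.

The delta-method SE is validated against Monte-Carlo standard
deviations of simulated ratios at small coefficients of variation
(within 5% relative error); at large CVs the linearization degrades,
which is inherent to the method, not an implementation artifact.

## Random-effects pooling

Between-study variance uses the DerSimonian–Laird moment estimator,
truncated at zero, because the original analyses were pooled in Review
Manager, whose random-effects model is DL. Heterogeneity is reported as
Q, and $I^2 = \max(0, (Q-\mathrm{df})/Q)\cdot 100$. Subgroups (driver
lines, or genotype classes for the mutant and heat-control analyses)
each get their own τ² — again the Review-Manager convention — and
between-subgroup heterogeneity is computed from
$Q_{between} = Q_{total} - \sum Q_{within}$ with
$I^2_{sub} = \max(0,(Q_{between}-(g-1))/Q_{between})\cdot100$; the
source analyses quote subgroup I² values without printing a formula, so
this standard decomposition is a design choice. Singleton subgroups are
reported unpooled. Implementation correctness is established against an
independently coded textbook-formula oracle at 1e-10 on randomized
instances.

## The hierarchical meta-regression

Per-experiment effects $y_{ijk}$ (percentage or raw change) are modeled
as

$$y = X\beta + b_{study} + \varepsilon,\quad b\sim N(0,\tau^2),\quad
\varepsilon\sim N(0,\Sigma),$$

where $\Sigma$ is diagonal with per-record variance $\sigma^2/w_i$
($w_i = 1/\widehat{\mathrm{Var}}(y_i)$, the meta-analytic precision),
except that records sharing a control arm form a block with constant
correlation ρ (block compound symmetry), independent across blocks.
This composition — precision weights inside a correlated block — is a
design choice: the source description states both "weighted by inverse
variance" and "block compound symmetry" without composing them, and
this form preserves both contracts. ρ is constrained to [0, 0.99] and
shared across blocks; shared-control correlation is nonnegative by
construction. Matched-control designs (temperature-shift experiments)
use the diagonal structure.

Estimation is maximum likelihood, not REML, so that likelihood-ratio
generalized R² between nested fixed-effect structures is valid. β is
profiled out by GLS at each variance-parameter point; (σ², τ², ρ) are
optimized on (log, log, scaled-logit) transforms by `nlminb` from five
deterministic multistart points (no RNG, so caller seeds are never
disturbed), with τ² fixed at 0 below two clusters and ρ fixed at 0
without a multi-record block. Non-convergence is flagged, never
silent. V is block-diagonal by study, so the likelihood is computed by
per-study Cholesky factorizations; the test suite checks it against a
dense multivariate-normal brute-force evaluation at 1e-8.

**Generalized R².** The source names a generalized R² without a
formula; the likelihood-ratio (Cox–Snell/Magee) definition
$1-\exp(-\tfrac{2}{n}(\ell_{full}-\ell_{null}))$ is adopted, with a
seeded nonparametric bootstrap over experiments for intervals (default
2000 resamples where reported; tests use far fewer). It is invariant to
affine response rescaling when both fits are refitted, and to uniform
weight rescaling.

**Residual driver effects.** Covariates are screened as in the source
workflow: RH, current type and voltage are censored too often and are
excluded; *rut* models use TIME + BENZALDEHYDE, temperature-shift
models TIME. The fitted model deliberately omits driver terms, so
driver variation lives in the residuals. Each record's adjusted value
is the intercept plus its marginal residual (numeric covariates are
centered at precision-weighted means, so the intercept is the adjusted
mean; an alternative "residual about the overall fitted mean" variant
sits behind a flag, because the source's arithmetic is ambiguous on
this point). Driver effects are precision-weighted means of adjusted
values on the learning scale minus the reference (40 mutant / 83 heat);
SEs come from within-driver dispersion, falling back to the
model-implied variance for single-record drivers.

**Cell-count regression and per-cell model.** The driver effects are
regressed on user-supplied Kenyon-cell counts, weighted by the number
of contributing experiments, with t-distribution slope intervals. Cell
counts come from an external anatomical source and are a user input;
all counts in this package's tests and defaults are synthetic
magnitudes. The per-cell model divides each driver's effect and SE by
its count and synthesizes by lobe category with inverse-variance
weights; whether the original propagated per-cell SEs as weights is
unstated, so precision weighting (the meta-analytic default) was
chosen.

## The synthetic-data generator

The generator emits the structures the analysis assumes: study clusters
(`tau`, default 5 learning-%), shared-control blocks whose control arm
is drawn once and reused, driver effects exactly linear in cell count
(`slope_per_cell`, default 0.02%/cell over synthetic counts 150–2100),
moderator effects (TIME −3%/min, BENZALDEHYDE +5%), a mutant baseline
of 40% learning (heat baseline −17% for inactivation worlds), control
PIs near 0.75 (SD 0.08), and truncated-normal iteration noise on the
bounded PI scale (SD 0.15, 6–18 iterations per arm) summarized to
mean/SEM. Defaults were fixed once at magnitudes a fly-behavior corpus
would show and are not revisited per test.

One extension beyond the specified configuration was necessary:
`sigma_resid` (default 6 learning-%), an experiment-level residual SD
split into a block-shared part (fraction ρ) and an independent part.
Without it, iteration noise is the only residual source and no
configuration could realize an arbitrary within-block correlation ρ;
with it, the correlation converges to ρ exactly in the
noiseless-iteration limit, which is how the invariant is tested.

What the generator does *not* emulate: odor identity beyond the
benzaldehyde flag, fly-level behavior, publication bias, digitization
error from figure measurement, or heteroscedasticity beyond what
iteration counts induce. A green recovery test therefore establishes
estimator correctness under the stated world, not fidelity of the
published numbers.

## What the recovery tests establish (and why they look the way they do)

Slope recovery runs the full pipeline (TIME+BEN model → residual driver
effects → weighted cell-count regression) at the default 7-study,
~80-experiment world; the 95% slope CI covers the true %/cell in ~98%
of 200 seeded replicates.

Variance-component unbiasedness is tested in a model-aligned world
instead: CELL_COUNT enters the model as a covariate, clusters are many
and small (20 × 4), and iteration summaries are precise. Two effects
make the default world unsuitable for an unbiasedness check, and both
are properties of the estimand, not bugs: (i) driver variation left in
the residuals is not block-shared, so it dilutes the estimable ρ far
below the generator's ρ — exactly as intended when the same model is
later used to *extract* driver effects; (ii) ML variance components
carry the classic −τ²/m small-cluster bias, which at 7 clusters is
~14% of τ² and would dominate any Monte-Carlo error band (REML would
remove it, but ML was fixed to keep likelihood-ratio R² valid).

## Numerical and degenerate-input policy

Zero-variance effects pool only as singletons; pooling ≥2 estimates
requires positive variances. Rank-deficient designs and non-positive-
definite covariances are hard errors naming the cause. Convergence
tolerance is 1e-8 on the log-likelihood. Exact-fit weighted regressions
floor the ML variance at 1e-12 to return R² = 1 rather than NaN. Range
cells ("21–25") become midpoints at parse time; the empty string is the
CSV missing value.

## Known limitations

- The packaged fixture cannot reproduce published pooled numbers by
  itself (no PI values); `reproduce_published()` does so only when the
  deposited per-experiment data are supplied by the user.
- ρ is a single constant across blocks; real shared-control dependence
  plausibly varies with block size and arm imbalance.
- The delta-method SE degrades for experimental means near zero; such
  records should be analyzed on the raw-PI scale.
- ML τ² is biased low with few clusters (see above); a REML switch is a
  natural extension but is intentionally not implemented.
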
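---
title: "Simulating unidimensional Likert items and the risk of over-dimensionalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating unidimensional Likert items and the risk of over-dimensionalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Five-category ordered ('Likert') survey items are routinely factor analysed
as if their integer codes were interval-level measurements. When a set of
such items in truth reflects a *single* latent dimension, how often do the
procedures that analysts actually use — eigenvalue retention rules,
statistical model evaluation in exploratory factor analysis (EFA), and
confirmatory factor analysis (CFA) — conclude that there is more than one
dimension? `likertdim` answers this by Monte Carlo: it simulates truly
unidimensional ordinal data under controlled conditions, pushes every
simulated dataset through the full battery of criteria, and tabulates how
often each criterion over-dimensionalises.

Because the true dimensionality of the simulated data is known (one), every
multi-factor verdict is an error. The frequency of such verdicts, by
condition and by criterion, is the quantity of interest.

## The response model

Respondents are characterised by a position $\theta$ on a single latent
continuum, essentially the interval $[0, 100]$. Four population
distributions are built in (`study_distributions()`):

| family | specification | role |
|---|---|---|
| normal | $N(50, 20)$ | the conventional assumption |
| skew-normal | Azzalini, location 15, scale 25, shape 5 | e.g. self-selected samples |
| bimodal | $\tfrac12 N(25,10) + \tfrac12 N(75,10)$ | variance-maximising designs |
| uniform | $U(0, 100)$ | maximal spread |

These differ in variance as well as shape (skew-normal smallest, uniform
largest), which matters downstream: observed item variances and inter-item
correlations inherit it.

An item is four strictly increasing category boundaries on the continuum
(`likert_pool()` ships a 27-item pool spanning a wide range of locations and
spacings). The error-free *true score* of a respondent is deterministic:
category $k+1$ begins at boundary $k$, so the first category is
$(-\infty, b_1)$ and a position at or above $b_4$ scores 5.

Error is defined on the ordinal response scale, not on the continuum. One
standard-normal draw $z$ per respondent–item cell is discretised: no shift
for $|z| \le c_1$, a shift of one category for $c_1 < |z| \le c_2$, two for
$c_2 < |z| \le c_3$, three beyond $c_3$, in the direction of
$\mathrm{sign}(z)$, truncated to $1..5$. The `large` level uses cutoffs
$(1, 2, 3)$, perturbing $2(1-\Phi(1)) \approx 32\%$ of responses before
truncation; the `small` level uses $(1.2, 2.2, 3)$, about $23\%$. This keeps
errors independent across items, identically distributed over items, 'lumpy'
in the way ordinal mismeasurement really is, and — crucially — it never
touches the sampled latent positions.

What the generator deliberately does *not* emulate: correlated item errors,
response styles (acquiescence, extreme responding), item-specific error
variances, missing data, and category counts other than five. Passing the
test battery therefore says nothing about those features of real surveys;
the package quantifies the damage done by categorisation and random ordinal
error alone.

### The design grid

`build_grid()` crosses the four distributions with item-set sizes
$\{5, 8, 10\}$ (drawn without replacement from the pool, fresh for every
dataset so that item locations and skews vary within cells), the two error
levels, and a replicate count (default 100, i.e. 2400 datasets of
$n = 2000$). Each condition receives its own seed, drawn once from the
master seed, so the whole harvest is reproducible bit for bit. Whether the
latent sample should be redrawn per dataset or shared within a cell is a
genuinely open design point; we redraw per dataset, which makes datasets
fully independent. The one place a latent sample is deliberately reused is
`test_retest()`, which generates two independently perturbed response sets
for the same respondents to quantify the reliability the error model
induces. The bimodal mixture assigns each respondent to a component by an
independent fair Bernoulli draw; the mixture weights are exposed in
`dist_bimodal()`.

## Correlations

The Pearson branch treats codes as numbers (`pearson_matrix()`), exactly as
the criticised practice does. The polychoric branch
(`polychoric_matrix()`) estimates, per item pair, the correlation of two
latent standard-normal variables observed through thresholds — the two-step
estimator: thresholds from the margins
($\tau_k = \Phi^{-1}(\text{cumulative proportion})$, empty categories
collapsed), then a one-dimensional maximum-likelihood search for $\rho$ on
$(-0.999, 0.999)$ by Brent's method (tolerance $10^{-6}$). The joint-ML
variant would re-estimate thresholds with $\rho$; at $n = 2000$ with five
categories the difference is far below Monte-Carlo noise, and two-step is
what the standard software stacks do.

Numerical choices worth recording:

* Rectangle probabilities come from a vectorised bivariate-normal CDF
  (Gauss–Legendre quadrature on the arcsine integral, with the usual
  singularity-handling expansion for $|\rho| \ge 0.925$); its absolute error
  is at machine-precision level, verified in the test suite against an
  independent implementation.
* Cells with zero probability are floored at $10^{-12}$ inside the
  log-likelihood; no continuity correction is added to zero *counts*,
  because corrections shift the estimate systematically.
* A polychoric matrix with any degenerate or non-convergent pair, or that is
  not positive definite (smallest eigenvalue $\le 10^{-8}$), is recorded as
  missing for all downstream analyses of that branch. No smoothing or
  bending is applied: repairing the matrix would silently change the very
  statistics under study. Denominators in the risk tables shrink
  accordingly.

## Retention criteria

All three rules operate on the eigenvalues of the *unreduced* correlation
matrix (`cor_eigenvalues()`), whose sum is the item count.

* **K1** (`k1()`): count of eigenvalues above 1. The rule is stated
  sometimes with $\ge$, sometimes with $>$; ties have probability zero for
  continuous data, and we use strict `>` with the threshold configurable
  (0.7 and 1.4 appear in the literature as alternatives).
* **Parallel analysis** (`parallel_analysis()`): the observed eigenvalues
  are compared rank by rank against the 95th centile of eigenvalues from
  `nrep = 100` random $n \times p$ datasets, stopping at the first rank that
  fails. The reference data are continuous standard-normal draws with
  Pearson eigenvalues, and the *same* reference is used for the Pearson and
  the polychoric branch — the common practice of the classical PA tools. An
  ordinal reference with matched margins is available via the `margins`
  argument but is not the default; at $n = 2000$ its centiles differ only
  in the third decimal.
* **Acceleration factor** (`acceleration_factor()`): the non-graphical
  scree elbow, placed at the largest second difference
  $e_{i+1} - 2e_i + e_{i-1}$ of the eigenvalue sequence; the retained count
  is the preceding rank, floored at one factor (the classical behaviour of
  the rule, which by construction cannot retain more than $p - 2$).

## Factor models and fit

**EFA** uses minimum-residual extraction (`minres_efa()`): uniquenesses
$\psi$ are optimised (within $[10^{-4}, 1]$) so that the top-$k$
eigenloadings of $C - \mathrm{diag}(\psi)$ minimise the squared off-diagonal
residuals. Fit statistics evaluate the maximum-likelihood discrepancy
$F = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p$ *at the minres
solution*, converted to a chi-square with Bartlett's correction factor
$n - 1 - (2p+5)/6 - 2k/3$ on $df = ((p-k)^2 - (p+k))/2$ — mirroring how the
popular EFA software reports ML-based fit for an OLS extraction. A true ML
refit is available (`efa_fit(..., refit_ml = TRUE)`) and is used in the test
suite to confirm that the 1-factor EFA and CFA land on the same discrepancy.
No rotation is applied to the 2-factor model: its fit statistics are
rotation-invariant and its loadings are never interpreted.

**CFA** (`cfa_1factor()`) fits the congeneric 1-factor model
$\Sigma = \lambda\lambda' + \Psi$ with the latent variance fixed at 1,
minimising $F$ directly over the $2p$ free parameters from the minres start;
$\chi^2 = (n-1)F$ on $df = p(p+1)/2 - 2p$. The $(n-1)$ convention (rather
than $n$) is a 0.05% difference at $n = 2000$, far below Monte-Carlo bands.
Uniquenesses are bounded below at $10^{-4}$; a bound-hitting solution is
flagged as a Heywood case but retained, since the study protocol only
excludes non-convergent fits. GFI and AGFI use the standard trace forms
($\mathrm{GFI} = 1 - \mathrm{tr}[(\Sigma^{-1}S - I)^2] /
\mathrm{tr}[(\Sigma^{-1}S)^2]$), RMSEA is
$\sqrt{\max(\chi^2 - df, 0)/(df(n-1))}$.

**Decision rules** (`decision_rules()`): the 2-factor model is preferred
when the EFA chi-square difference test on $\Delta df$ rejects at
$\alpha = 10^{-5}$ (deliberately conservative, so that the $n = 2000$ sample
size cannot drive rejections on its own); the 1-factor model is rejected
when its EFA RMSEA exceeds 0.10, its CFA chi-square is significant at
$\alpha = 0.001$, its AGFI falls below 0.90, or its CFA RMSEA exceeds 0.10.
Each verdict is recorded separately in the harvest.

## The harvest and the risk tables

`run_grid()` streams every dataset of a grid through `analyze_dataset()`,
producing one row per dataset with both branches' eigenvalues, retained
counts, fit statistics, verdicts and missingness flags, plus the item-set
predictors below. `risk_table()` aggregates cells as distribution ×
item-count, pooling the two error levels (their effect on the percentages is
marginal; the un-pooled error indicator stays in the harvest for the
regressions). Cell denominators count only datasets whose branch produced a
result, and empty cells are `NA`, never silently zero.

## What drives the risk

Two per-dataset predictors summarise the composition of an item set
(`dataset_predictors()`):

* the spread of item locations: the inter-quartile range (linear-interpolation
  quantiles; with only 5–10 medians the quantile convention matters and is
  fixed here) of the items' *interpolated medians*
  $IM = m - 0.5 + (n/2 - F_{m-1})/f_m$;
* the range of the items' moment skewnesses $g_1 = m_3 / m_2^{3/2}$ (no
  small-sample correction; at $n = 2000$ it is negligible).

`fit_driver_models()` regresses, by OLS, ten (transformed) fit statistics on
these two predictors plus dummies for error level, population distribution
(reference: normal) and item count (reference: 5): the EFA 1- vs 2-factor
chi-square difference and the CFA chi-square enter as cube roots (which
removes the gross heteroskedasticity of chi-square-distributed outcomes —
checked in the test suite as an ordering of Breusch–Pagan-type statistics,
not as a threshold), the RMSEA and AGFI models are linear. Pearson and
polychoric branches alternate across the ten models. Records with a missing
branch drop out listwise per model. `predict_fit()` turns any fitted model
into a calculator: given an item count, an assumed population, an observed
location spread and skew range, it returns the fit value one should *expect
for truly unidimensional items* under those conditions — a guard against
reflexively rejecting a 1-factor model whose 'poor' fit is exactly what
categorisation alone produces.

## Problem sizes, tolerances, determinism

The full study grid (2400 datasets, $n = 2000$) runs in well under an hour
on one core. The package's own replication checks use reduced but still
informative scales, chosen once: the test suite runs the whole grid at 10
replicates per cell with 50 parallel-analysis reference sets, and the
bundled acceptance script uses 100 replicates per cell for the 5-item cells
and 50/75 for the 8-/10-item cells with the full 100 reference sets. All
comparisons against the published percentages use binomial Monte-Carlo bands
at the realised denominators (three standard errors, floored at three
percentage points), and comparisons of grid averages use three standard
errors of the mean — bands follow the scale of the run, never the other way
around.

Optimiser tolerances: Brent at $10^{-6}$ for polychoric $\rho$; PORT
(`nlminb`) defaults for minres and ML fits with a 2000-iteration ceiling,
any non-convergence recorded as missing. Chi-square tail probabilities are
taken from `pchisq(..., lower.tail = FALSE)`, which is accurate far into the
tail where the $10^{-5}$ decision operates. Every source of randomness —
latent draws, item sampling, error draws, parallel-analysis references —
funnels through per-condition seeds derived from one master seed, so two
runs of the same grid are bitwise identical.

## Known limitations

* The simulated items are conditionally independent given the latent trait;
  real batteries often violate this (wording overlap, order effects), which
  would change the risk estimates in unknown directions.
* Only five response categories are modelled. The machinery accepts other
  pools, but nothing here validates conclusions for 3-, 7- or 11-point
  formats.
* The acceleration factor's tendency to *under*-dimensionalise cannot be
  observed in this design, since the true dimensionality is already the
  minimum.
* `predict_fit()` is a descriptive regression over the simulated grid, not
  a causal model; outside the grid's predictor ranges it extrapolates and
  warns.
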
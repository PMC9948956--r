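---
title: "Estimating ASO knockdown from single-nucleus counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ASO knockdown from single-nucleus counts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asokd)
```

## The problem

An antisense oligonucleotide (ASO) dosed into cerebrospinal fluid lowers a
target RNA throughout the brain, but bulk tissue measurements cannot say
*how* that knockdown is distributed: 50% residual target in a homogenate is
equally consistent with every cell losing half its transcripts and with
half the cells losing everything. Single-nucleus RNA sequencing resolves
this, at the cost of sparse counts: a typical nucleus yields a few thousand
unique molecular identifiers (UMIs) in total, and a typical target gene
contributes zero, one, or a handful of those.

`asokd` implements the count-level analysis for this setting:

1. a **pseudobulk negative binomial regression** that turns per-animal,
   per-cell-type UMI sums into residual-target fractions with confidence
   intervals;
2. a **single-cell architecture comparison** that asks whether treated-cell
   count histograms look like uniform partial knockdown or like complete
   silencing of a subset of cells;
3. **cross-condition summaries** — frequency-weighted correlations and
   standard deviations across cell types, difference-from-overall-residual
   profiles, washout recovery, qPCR delta-delta-Ct residuals, and
   dose-to-molecules arithmetic;
4. a **synthetic cohort generator** that reproduces the count structure the
   model assumes, so all of the above can be exercised and calibrated
   without access to animal data.

## The pseudobulk knockdown model

For each combination of region, timepoint and compound, cells are grouped
by animal $a$ and cell type $c$, and two sums are taken per group: target
UMIs $y_{ac}$ and total UMIs $N_{ac}$. The model is a negative binomial
(NB2) regression with a log link and the total UMIs as an exposure offset:

$$
y_{ac} \sim \mathrm{NB}(\mu_{ac}, \theta), \qquad
\log \mu_{ac} = \beta_c + \gamma_{c,t(a)} + \log N_{ac},
$$

with variance $\mu + \mu^2/\theta$, one baseline coefficient $\beta_c$ per
cell type (the log of the basal target fraction per UMI), and one
interaction coefficient $\gamma_{ct}$ per cell type and non-reference
treatment. Because the offset carries the exposure, $e^{\gamma_{ct}}$ is
directly the **residual target fraction**: treated expression as a
multiple of control expression in that cell type. The 95% confidence
interval is $e^{\gamma \pm 1.96\,\mathrm{SE}}$, computed on the log scale
and exponentiated so it is always positive and contains the point
estimate. A single dispersion $\theta$ is shared across cell types — the
model is one joint fit, not one fit per type — which is an assumption, not
a finding; rare cell types borrow dispersion information from abundant
ones.

Per-animal point estimates add each treated row's log-ratio residual
$\rho_{ac} = \log(y_{ac}/\hat\mu_{ac})$ to the interaction coefficient and
exponentiate. The log-ratio residual is the unique choice for which the
resulting estimate equals that animal's observed target fraction divided
by the fitted control rate, so the total-UMI-weighted mean of per-animal
estimates reproduces the pooled ratio. Deviance or Pearson residuals would
not have this property; this is a documented design choice, since the
convention is genuinely open. Rows with zero target counts get a $+0.5$
continuity correction and an explicit flag.

### Estimation and numerics

The fit alternates iteratively reweighted least squares for $\beta$ given
$\theta$ with a Brent line search for $\theta$ on
$\log\theta \in [-10, 15]$ given $\beta$, declaring convergence when
$\max|\Delta\beta| < 10^{-8}$ and either $|\Delta\log\theta| < 10^{-8}$ or
the log-likelihood changes by less than $10^{-6}$. The second disjunct
matters in practice: pseudobulk sums over thousands of cells are often
nearly Poisson, the profile over $\theta$ is then flat to within float
noise across decades, and demanding a stable $\theta$ in that regime is
meaningless — the likelihood, not the parameter, is what the data
determine. When a box edge is within $10^{-7}$ log-likelihood of the
interior optimum, $\theta$ is pinned to the edge and the fit reports
`theta_at_bound`. Standard errors come from the observed information
matrix $X^\top \mathrm{diag}\!\big(\mu\theta(y+\theta)/(\theta+\mu)^2\big) X$
at the optimum, conditional on $\hat\theta$ (the same convention as
standard NB GLM software). The log-likelihood is written in `lgamma` form
rather than via `dnbinom()` so that continuity-corrected, non-integer
counts remain evaluable.

A (cell type, arm) group whose counts are all zero would drive its
coefficient to $-\infty$ (perfect separation). Because the design is
group-saturated, the problem is confined to that group: the affected rows
are continuity-corrected, the coefficient is reported, and the estimate is
flagged `zero_counts` rather than dropped, keeping the output shape
stable.

### Calibration, and what it does and does not show

The test suite and acceptance script calibrate the estimator on synthetic
cohorts of 4+4 animals at 2000 cells per animal, with true residuals 0.1,
0.5 and 0.9 assigned to the generator's three default cell types and no
animal-level random effect — i.e. under the model's own sampling
assumptions, which is what a coverage check of the interval construction
should use. Across 500 cohorts (1500 intervals) the median absolute error
of the residual estimate is about 0.01 and the 95% interval covers the
truth in roughly 92–93% of cases.

That coverage sits at the low edge of nominal, and deliberately so: the
interval is a Wald interval conditional on $\hat\theta$, and with only
eight pseudobulk observations per fit the dispersion is poorly determined.
In regimes where the NB overdispersion term dominates the Poisson term of
the variance (abundant targets, very deep sequencing), the unaccounted
uncertainty in $\hat\theta$ makes the interval materially anti-conservative
— a property of the $\pm 1.96\,\mathrm{SE}$ construction itself, which an
independent NB GLM implementation reproduces exactly, not of this
implementation. At the low-expression rates the defaults emulate
(a fraction $\sim 10^{-4}$ of UMIs, the regime of a typical ASO target),
Poisson noise dominates and the construction is close to nominal. Users
with abundant targets should read the intervals as approximate.

With an animal-level random effect present (`animal_sigma > 0`, the
generator's ordinary default of 0.05), the fixed-effects model absorbs
between-animal variance into $\theta$; intervals are then somewhat
narrower than a mixed model would give. Mixed-effects extensions are out
of scope.

## The single-cell architecture comparison

Given a control-arm NB fit $(\hat\mu, \hat\theta)$ to per-cell target
counts of one cell type and a bulk residual fraction $r$ (normally the
pseudobulk estimate), two hypotheses about the treated-arm histogram are
scored:

* **scaled-mu** (uniform partial knockdown): $\mathrm{NB}(r\hat\mu,
  \hat\theta)$, with zero mass
  $\left(\tfrac{\theta}{\theta + r\mu}\right)^\theta$;
* **zero-subset** (complete silencing of a $1-r$ subset):
  $r\,\mathrm{NB}(\hat\mu, \hat\theta) + (1-r)\,\delta_0$, with zero mass
  $(1-r) + r\left(\tfrac{\theta}{\theta + \mu}\right)^\theta$.

Both have mean exactly $r\mu$, so pseudobulk cannot separate them; they
differ in zero mass (the subset model always has at least as much) and
higher moments. The observed treated histogram, truncated at the smaller
of its maximum and the 99.9th percentile of the control fit with the
remainder lumped into a tail bin, is scored under each PMF by multinomial
log-likelihood. The preferred architecture is the higher-likelihood one; a
difference below 2 log-units is reported `indeterminate` — conventional
likelihood-comparison slack, which also handles $r \to 1$, where the
models coincide and no histogram can separate them. Candidate bin
probabilities are floored at $10^{-12}$ so that an impossible bin yields a
huge but finite penalty. Control counts are fitted marginally (one $\mu$
for the pooled histogram, matching how such histograms are drawn);
`per_10k = TRUE` offers an exposure-rescaled sensitivity variant.

At the benchmark setting $\mu = 2$, $\theta = 2$, $r = 0.5$, $n = 2000$
treated cells, the two architectures are separated essentially perfectly
(the acceptance script measures the accuracy over 200 replicates per
architecture). Power falls as $r \to 1$, as $\mu$ falls, and as cells get
scarcer; the test suite checks these monotonicities.

## Cross-condition summaries

**Weighted statistics.** Cell types differ enormously in abundance, and
the precision of their residual estimates with them, so profile
comparisons weight each cell type by its number of cells. Weights are
normalized to sum to the number of cell types $n$; the weighted Pearson
correlation uses weighted means, variances and covariance, with a
two-sided p-value from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees
of freedom, and the weighted SD is the square root of the
frequency-weighted unbiased variance. The degrees-of-freedom convention
for weighted correlations is not standardized across software; treating
normalized weights as frequency weights with $n-2$ df is the choice made
here, and equal weights reduce both statistics exactly to their textbook
forms.

**Difference from overall residual.** To compare knockdown *profiles*
between conditions with different overall potency, each cell type's
residual percent is reduced by the condition's overall residual — computed
from the all-cells pseudobulk aggregate (a single fit with cell types
pooled), not by averaging per-type residuals, so abundant types do not get
double-weighted. Positive differences mean weaker knockdown than bulk
tissue. All reported scales are percent (0–100); the functions reject
inputs that look like a fraction/percent mixture.

**Washout recovery** is the rise in residual percent between an early and
a late timepoint, in percentage points. **Delta-delta-Ct** follows the
classic scheme (technical replicates averaged on the Ct scale, target Ct
normalized to a housekeeping gene, then to the control-arm mean, residual
$= 2^{-\Delta\Delta Ct}$); per-arm summaries are geometric means, which
makes the control arm exactly 100% by construction. The **dose
calculator** converts dose mass and molecular weight to molecules per
cell via Avogadro's number, with an optional productive-uptake fraction.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the features of single-nucleus data
the analysis relies on, and nothing more:

* per-cell total UMIs drawn log-normal (default log-mean $\log 7650$,
  log-SD 0.5 — thousands of UMIs per nucleus with a realistic heavy tail)
  and rounded, floored at 100;
* cell types drawn multinomially with fixed proportions; each type has a
  basal target rate (target UMIs per total UMI), an NB2 dispersion, and a
  true residual fraction. The defaults — three types at rates near
  $10^{-4}$, $\theta = 2$, residuals 0.30/0.56/0.75 — represent a
  low-expression target with cell-type-dependent knockdown depth; a rate
  near $10^{-4}$ means the average cell carries under one target UMI,
  which is the hard case for the method and therefore the honest default;
* an optional per-animal multiplicative random effect on the target mean
  only (default SD 0.05 on the log scale, a modest between-animal
  pharmacology difference; set to 0 for calibration studies — the value is
  a free parameter of the generator, not an empirical quantity);
* treated arms follow one of the two architectures above
  (`knockdown_mode`), which by construction share the pseudobulk mean law
  and differ only per cell;
* one aggregate "other" feature absorbs the remaining UMIs, so column
  sums equal the drawn totals exactly. Target counts are capped at the
  cell's total so the filler stays nonnegative; at realistic basal rates
  the cap is unreachable in practice.

The generator does **not** simulate full transcriptomes, doublets, ambient
RNA, empty droplets, batch effects, or cluster structure, and its cell
type labels are true labels, not cluster assignments. Passing tests
therefore demonstrate that the estimator is correct and calibrated *given
correctly assigned cells whose counts follow the assumed family* — they
cannot certify robustness to misclustering or ambient contamination in
real data.

Determinism: a cohort spec carries its seed; the same spec yields a
bit-identical cohort, and the pipeline derives every stochastic step from
one top-level seed, so identical configurations produce byte-identical
outputs.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while keeping Monte-Carlo error well below the tolerances they assert:
500 cohorts of $2 \times 4 \times 2000$ cells for calibration, 200
replicates per architecture of 2000 cells for discrimination power,
brute-force likelihood cross-checks on tables of at most 24 rows, and
closed-form identities wherever they exist (equal-offset ratio-of-sums
MLEs, zero-mass formulas, delta-delta-Ct round trips).

## Known limitations

* Wald intervals conditional on $\hat\theta$; anti-conservative when the
  dispersion term dominates (see calibration section).
* Shared $\theta$ across cell types within a fit.
* No animal-level random effects; no multiple-testing correction (p-values
  are nominal, as in the underlying analysis).
* The architecture comparison evaluates the two stated hypotheses only;
  mixtures with partial-knockdown subpopulations are not modeled.
* `difference_from_overall()`'s scale check is heuristic: profiles whose
  residuals are genuinely all below 1.5% would be mistaken for fractions.
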
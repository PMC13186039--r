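---
title: "Methods: soil Cd bioaccessibility modelling and probabilistic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil Cd bioaccessibility modelling and probabilistic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcdrisk)
```

This vignette documents the models, the synthetic data-generating process,
the numerical choices, and the design decisions behind `soilcdrisk`. It is
the package's methodological reference: everything asserted here is either
a definition or a property the test suite computes.

## The scientific setting

Oral ingestion of contaminated soil is a dominant exposure pathway for
cadmium near industrial sites, but only the fraction of soil Cd that
dissolves in gastrointestinal fluid — the bioaccessible fraction, measured
by in-vitro protocols such as PBET, UBM, DIN, IVG and SBET — is available
for absorption. The intestinal phase is the absorption-relevant one.
Risk assessments using total Cd therefore overstate dose; replacing the
total concentration with a predicted bioaccessible fraction, and
propagating parameter uncertainty by Monte Carlo, yields more defensible
hazard quotients (HQ) and carcinogenic risks (CR).

The package chains five stages: simulate a compiled survey, screen and
clean it, model bioaccessible Cd content, map predictions spatially, and
run the probabilistic risk engine.

## The synthetic data-generating process

`generate_soil_dataset()` draws soil properties from bounded laws inside
published survey ranges (pH 3.01–11.37; SOM 0.17–131.03 g/kg; clay
0.02–44.43%, silt 10.82–78.26%, sand 2.30–89.16%), a Dirichlet-like
three-part texture composition renormalised to exactly 100 (guaranteeing
the compositional invariant by construction), a lognormal total Cd, and a
multinomial method label with proportions 73.3% PBET, 15.8% UBM and 10.9%
shared by DIN/IVG/SBET. The intestinal-phase bioaccessible content follows

$$\ln BA_{ip} = b_0 + b_1 \ln Cd + b_2\,sand
  + i\,(pH-7)\ln Cd + shift_{method} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

clipped to the physical bound $BA_{ip} \le Cd$. Defaults: $b_0 = -3$,
$b_1 = 1$, $b_2 = 0.02$ per percent sand, $i = 0.15$, $\sigma = 0.35$
(log scale), shifts $0, 0, +0.4, +0.5, -0.4$ for PBET, UBM, DIN, IVG,
SBET. These were chosen once, from first principles:

* $b_1 = 1$ and $b_2 > 0$ encode the dominant positive roles of total Cd
  and sand; with $b_0 = -3$ the median bioaccessibility is
  $e^{-3+b_2\,\overline{sand}} \approx 10\%$ and the clip is inactive in
  the noiseless case (so refitting the noiseless model recovers
  $b_0, b_1, b_2$ to machine precision — a generator unit test).
* $b_2 = 0.02$ with texture spread $\mathrm{sd}(sand) \approx 7.5$ and
  $\sigma = 0.35$ gives the sand term a population $t$ of about
  $0.02 \cdot 7.5 / 0.35 \cdot \sqrt{126} \approx 4.8$ at the refined
  survey size $n = 126$, i.e. the true predictors enter a stepwise search
  essentially always.
* The interaction sign makes high pH suppress bioaccessibility in
  low-Cd soils and not in heavily loaded ones — the kind of nonlinearity
  a forest can represent and a main-effects linear model cannot.
* PBET and UBM share a zero offset (their difference is designed to be
  statistically undetectable), while DIN/IVG/SBET are shifted by roughly
  one residual standard deviation, so a Kruskal–Wallis test across
  methods rejects while the PBET-vs-UBM Mann–Whitney comparison does not
  — the screening pattern the preprocessing stage expects.

What the generator does **not** emulate: spatial hotspots, regional
property gradients, correlated covariates beyond the texture closure,
method-by-soil interactions, censored detection limits, or the real
compiled dataset's values. Passing tests therefore demonstrate the
*machinery* (selection consistency, model ordering, filter behaviour) on
a known truth — not predictive accuracy on real soils.

`degrade_dataset()` adds missing-completely-at-random cells to covariates
only (exactly $\lfloor rate \cdot n \cdot n_{cov}\rfloor$ cells, masks
returned for scoring) and multiplies selected responses by a gross factor
(default 50) *without* re-clipping, so influence diagnostics can catch
them.

## Preprocessing decisions

**TOC→SOM.** Only a "factor of 0.58" is conventional; the direction is
the van Bemmelen convention $TOC = 0.58 \cdot SOM$, hence
`toc_to_som()` divides. The factor is an argument.

**Screening statistics.** Kruskal–Wallis uses the tie-corrected H with a
$\chi^2_{k-1}$ approximation. The Mann–Whitney U is reported for the
first sample (pairs with $x > y$, ties counted half). Because the exact
null distribution with midranks is unavailable in `stats` when ties are
present, the package enumerates all group assignments when
$n_x n_y \le 100$ (bounded runtime) and otherwise uses the tie-corrected
normal approximation; on two groups the latter agrees with
Kruskal–Wallis exactly, which is a unit-tested invariant.

**Imputation.** "Multiple imputation with a random-forest model" is
implemented as a single-completion iterative scheme (missForest style):
median initialisation, columns updated in increasing-missingness order,
forests of the incomplete column on all other covariates, stopping when
the relative change of imputed cells falls below `tol` (default 1e-3) or
after `max_iter` sweeps. Observed cells are never altered and the
response is excluded. Imputation quality is benchmarked against median
imputation with the missForest-standard *normalized* RMSE (per-column
errors scaled by the complete-data column standard deviation): raw pooled
RMSE would be dominated by the widest-scaled covariate (SOM, sd ≈ 20
g/kg) and would not measure what the forest actually exploits (the
texture closure).

**Influence filtering.** A single OLS fit of $\ln BA_{ip}$ on
$\ln Cd$, pH, SOM, clay and sand supplies Cook's distances
$D_i = e_i^2 h_{ii} / (p s^2 (1-h_{ii})^2)$; rows with $D_i > 1$ are
removed by default (the conventional headline threshold). A caveat worth
recording: for a *single* gross response outlier at leverage $h$,
$D_i \to h(n-p)/(p(1-h))$ as the outlier grows, because the outlier
inflates $s^2$ itself; at average leverage $h \approx p/n$ this limit is
about 1, so the default threshold is conservative for lone outliers of
ordinary leverage. The threshold is an argument (the test suite also
exercises the conventional $4/n$ screening cutoff), and $D_i$ is verified
against leave-one-out refits to 1e-8.

**Correlation.** Pairwise-complete Spearman rho with midranks; stars at
0.05/0.01; constant columns yield NA with a warning.

## The two predictive models

Both models work on the natural-log response; total Cd is the only
log-transformed covariate (the remaining properties are already
comparably scaled), a switchable choice.

**Stepwise regression** alternates a forward step (the candidate with the
smallest partial-F p-value enters if $p < \alpha_{enter}$) and backward
steps (any retained variable with $p \ge \alpha_{remove}$ leaves, worst
first) to a fixpoint, with $\alpha = 0.05$ on both sides. Aliased
candidates are skipped, which makes the search safe for the compositional
texture triplet. Note a structural property of this classical procedure:
each null candidate enters with probability $\approx \alpha$, so with $k$
irrelevant candidates the probability of recovering *exactly* the true
set is bounded near $(1-\alpha)^k$ — about 0.86 for the default candidate
list — regardless of sample size. The default candidate list drops silt
(the redundant member of the closed texture triplet).

**Random forest** uses `ranger` with the sklearn-style hyperparameter
vocabulary (`n_estimators`, `max_features`, `min_samples_leaf`,
`min_samples_split`, `max_depth`). Engine mapping: `num.trees`,
`mtry` (capped at the number of available features, so `max_features = 7`
means "all" when only 5–7 covariates are present), and
`min.node.size = min_samples_split` (ranger's minimal-size-to-split
semantics); `min_samples_leaf` is recorded in the model object but the
splitter does not enforce a separate leaf bound. The default grid is the
single point `n_estimators = 100, max_features = 7, min_samples_leaf = 2,
min_samples_split = 6, max_depth = none`. Grid search maximises mean
out-of-fold R² over 5 folds; ties break toward smaller ensembles, then
grid order.

**Interpretation.** Impurity importances are normalised to sum to one.
Shapley attributions are *interventional*: the value of a coalition $S$
is the mean prediction with the features in $S$ taken from the explained
row and the rest from each background row. For $k \le 12$ features all
$2^k$ coalition values are enumerated exactly (one batched predict call
per row), so the local-accuracy identity
$baseline + \sum_f \phi_f = f(x)$ holds to machine precision; beyond that
a permutation-sampling estimator takes over, and the method used is
recorded in the result.

**Back-transformation** exponentiates the log prediction without a
smearing correction (no bias correction is assumed by the workflow being
emulated; the option would be a one-line change), caps content at the
physical bound `cd_total`, and reports percent bioaccessibility in
(0, 100].

## Spatial mapping

No geostatistics package is part of the package's dependency set, so the
variogram/kriging layer is self-contained: Matheron empirical
semivariances on distance bins, weighted least squares with Cressie
weights $N_j/\gamma_j^2$ over nugget, partial sill and range
(parameterised as squares to stay nonnegative), and families spherical
(default — the common default of desktop GIS kriging), exponential and
gaussian on the practical-range convention. Ordinary kriging solves the
semivariance-form system with the unbiasedness constraint per target;
duplicate data locations are averaged first. Predictions are verified in
tests against an independent covariance-form dense solve, and weights sum
to one to 1e-10. Coordinates are planar Cartesian cell centers; there is
no CRS handling — grids are abstract.

The mapping stage is *predict-then-krige*: each cell's covariates plus
its region's geometric-mean total Cd feed the fitted model, and kriging
is an optional smoothing pass on the resulting percent surface
(subsampled variogram fit for large grids). Interpolating the inputs
instead would also be defensible; predict-then-krige keeps the model's
nonlinearities intact at the cell scale.

Regional aggregation uses the geometric mean $\exp(\overline{\ln x})$
(concentrations are right-skewed), with arithmetic CV reported alongside.

## The risk engine

Average daily doses follow the three USEPA pathway equations, with two
unit conventions made explicit:

* `cf_ing` (default $10^{-6}$ kg/mg for IngR in mg/day) makes the
  ingestion dose dimensionally consistent; setting `cf_ing = 1`
  reproduces the unconverted textbook form. The dermal equation carries
  its own explicit $10^{-6}$.
* BA is a fraction in (0, 1]; percent-scale inputs must be divided by
  100 at the interface.

Distribution specs support point, normal, lognormal, uniform and
triangular laws with truncation by rejection (an error is raised if the
acceptance rate collapses below 1%), plus a derived law `ed365`
(AT = ED × 365 per iteration). Parameters are sampled independently —
the behaviour of the commercial spreadsheet tools this workflow emulates;
correlated sampling is future work. One global seed governs the stream.

**Averaging-time convention.** The default exposure tables give AT a
point mass at $\max(ED) \times 365$ (adult $35 \times 365$ d, child
$6 \times 365$ d). This keeps the invariant $AT \ge ED \cdot 365$ for
every draw while letting exposure duration retain its own variability.
The alternative `ed365` law is fully supported but cancels ED out of
every dose ratio, which would make ED invisible to sensitivity analysis;
surveys of this assessment style fit AT as its own parameter, and the
package's defaults follow that practice.

**Fixed concentration in regional runs.** The pipeline's risk stage fixes
C at the geometric mean of the refined samples (a point mass), matching
assessments driven by compiled regional concentration surveys; sampling C
from its fitted lognormal (sdlog ≈ 1.1) is available but makes C dominate
every variance contribution and drown the exposure parameters.

Summaries use `quantile` type 7 (linear interpolation between closest
ranks — configurable by argument), exceedance probabilities against
HQ = 1 and CR = $10^{-6}$, and CV in percent.
`compare_adjustment()` pairs an unadjusted run (BA ≡ 1) with an adjusted
run under **common random numbers**: both arms share every non-BA draw,
so a point-mass BA of $b$ scales means and percentiles by exactly $1/b$,
and any BA ≤ 1 can never raise a percentile — both are unit-tested
identities, and the BA support is validated to lie in (0, 1].

Sensitivity analysis reports contribution to variance,
$100\,r_k^2 / \sum_j r_j^2$ with $r_k$ the Spearman correlation of
parameter $k$ with the output; signs are kept separately, constant inputs
contribute zero with a warning, and contributions sum to 100.

The default toxicity table (oral RfD $10^{-3}$, inhalation RfD
$10^{-3}$, dermal RfD $10^{-5}$ mg/(kg·d); oral SF 6.1, inhalation SF
6.3 (kg·d)/mg, no dermal SF) is a synthetic stand-in with
literature-style magnitudes; real assessments must substitute
authoritative values. Likewise the exposure tables are
handbook-plausible synthetic defaults (adult/child IngR medians 100/200
mg/d, BW 60.6/16 kg, child ED uniform on 1–6 yr), designed so children
carry a higher ingestion rate, lower body weight and wider relative
exposure-duration spread than adults.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → preprocess → train → map → risk →
sensitivity under a flat config (`default_pipeline_config()`, unknown
keys rejected), communicating through plain-text artifacts (CSV, ESRI
ASCII grids, YAML config echo) so any prefix can be re-run; a disabled
upstream stage is reported by name when its artifact is missing. Every
stage derives its seed from the config seed by fixed offsets, and an MD5
manifest closes the loop: identical seeds give byte-identical artifacts.
The orchestration surface is deliberately function-first rather than a
shell program — the package's users drive analyses from R, and
`scripts/acceptance.R` shows the same chain as a batch script.

## Problem sizes used by the tests

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise every claim while staying quick on one core: surveys
of 120–300 samples (195 for the survey-scale acceptance run, 126 for the
selection-consistency replication — the refined-survey size), 100-seed
replications for the stochastic claims, 10,000 Monte Carlo iterations
for distributional checks (where the 95th-percentile estimator's
relative error is ≈ $\sigma \sqrt{p(1-p)/n}/\varphi(z_{0.95})
\approx 1\%$ at $\sigma = 0.5$), 30 × 30 grids for mapping, and ≤ 20
points for the kriging oracle comparisons.

## Known limitations

* The generator's covariates are independent apart from the texture
  closure; real pH–SOM–texture correlation structures are not emulated.
* `min_samples_leaf` is advisory under the ranger engine (see above).
* Kriging solves the full system (optionally neighbourhood-restricted);
  it is intended for the package's grid scales, not for $10^5$-point
  datasets.
* Monte Carlo inputs are independent; rank-correlation-preserving
  sampling is not implemented.
* Exposure, toxicity and ground-truth defaults are synthetic stand-ins;
  swapping in authoritative tables is a data change, not a code change.
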
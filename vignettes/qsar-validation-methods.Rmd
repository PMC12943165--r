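---
title: "GA-MLR QSAR modelling, OECD validation, and trajectory cross-correlation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-MLR QSAR modelling, OECD validation, and trajectory cross-correlation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsardyn)
```

qsardyn implements a complete workflow for building and auditing small
linear QSAR (quantitative structure-activity relationship) models from
large machine-generated molecular-descriptor tables, together with the
post-simulation trajectory statistics used to characterise
protein-ligand dynamics. This vignette is the package's own account of
the methods: the models, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators emulate (and do
not), and the numerical choices made where conventions genuinely differ
across the field.

## The modelling problem

The activity of a compound is expressed as pIC50, the negative base-10
logarithm of its half-maximal inhibitory concentration in mol/L
(`ic50_to_pic50()`). The model class is deliberately minimal: ordinary
least squares of pIC50 on a *small* subset of molecular descriptors,

$$\widehat{\mathrm{pIC50}} = b_0 + \sum_{j=1}^{k} b_j d_j,$$

with $k = 4$ by default. The statistical difficulty is not the fit but
the search: descriptor software emits tens of thousands of columns for a
dataset of a few dozen compounds, so unguarded subset selection will
find spurious models with excellent apparent fit. Everything else in the
package exists to prevent or detect exactly that.

## Descriptor pre-filtering

`prefilter()` applies two stages, in a fixed order:

1. **Near-constant removal** (`drop_near_constant()`): a column is
   dropped iff its most common value occurs in *strictly* more than 80%
   of rows (`max_modal_fraction = 0.80`). The comparison is strict so a
   column at exactly the threshold survives. Value equality is exact at
   the bit level, since the targets of this filter are count-like and
   indicator descriptors whose repeats are exact; a tolerance would risk
   merging close-but-distinct continuous values.
2. **Pairwise collinearity removal** (`drop_correlated()`): a
   left-to-right scan drops any column whose Pearson correlation with an
   already-retained column satisfies $|r| \ge 0.95$. The absolute value
   is used because an anti-correlated duplicate carries the same
   information as a correlated one. The tie-break keeps the *earlier*
   column in table order, which makes the result deterministic and
   auditable; `prefer_activity_correlated = TRUE` instead keeps the
   member of the pair more correlated with activity, for users who want
   that behaviour explicitly.

Both rules, and the fact that the correlation filter is absolute-valued
and order-tie-broken, are recorded in the `prefilter_report` header,
because neither convention is universal. The filter is idempotent and
never changes the row count; both properties are enforced by tests.

## GA-MLR subset search with the QUIK rule

`ga_select()` searches fixed-size descriptor subsets with a genetic
algorithm. The chromosome is a $k$-subset of column indices; uniform
crossover draws a child of size $k$ from the union of two parents;
mutation swaps one member for a random non-member; selection is by
2-tournament; `elitism` individuals survive unchanged, which makes the
best fitness non-decreasing by construction.

The fitness of a subset is its leave-one-out $Q^2$ (below), *gated* by
the QUIK rule. The rule uses Todeschini's multivariate K index
(`quik_k()`): from the eigenvalues $\lambda_j$ of the column correlation
matrix,

$$K = \frac{\sum_j \left| \lambda_j / \sum_i \lambda_i - 1/p \right|}{2(p-1)/p} \in [0, 1],$$

0 for mutually orthogonal columns and 1 for complete collinearity. A
subset is admissible only when $K_{[X,y]} - K_{[X]} \ge \delta_K$: the
response must *add* correlation to the block, otherwise the apparent fit
is being carried by descriptor inter-correlation. Subsets failing the
gate receive fitness $-\infty$; if every subset visited fails, the
result says so explicitly (`all_rejected`) rather than returning a
silently bad model.

Choices that were genuinely open, and how they were settled:

* **Constraint, not weighted sum.** The K margin enters as a hard gate
  rather than a penalty term. A weighted sum would need an arbitrary
  weight and would let strong $Q^2$ buy back collinearity — the
  behaviour the rule exists to forbid.
* **$\delta_K = 0.05$** by default, a small positive margin so that the
  gate has teeth without rejecting essentially orthogonal designs; it is
  a visible `ga_config()` field, not a constant.
* **Hyperparameters** default to population 100, 200 generations,
  crossover 0.8, mutation 0.1, elitism 2. There is no canonical setting
  for GA descriptor selection; all are config-visible, the search is
  reproducible from `seed`, and an exhaustive-enumeration oracle test
  pins the search to the true optimum on small pools.
* **Descriptors enter unscaled**, so coefficients live on raw descriptor
  scales. This matches how published QSAR equations are printed, at the
  cost that coefficient magnitudes are not comparable across
  descriptors — a caveat the fitted objects' documentation repeats.
* **Fitness uses the hat-matrix PRESS shortcut** for speed. Its
  equivalence with explicit refits is a *test* (to 1e-10 over random
  datasets), not an assumption.

## The validation battery

`validate_model()` assembles, for one descriptor subset:

* $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ and adjusted $R^2$; training
  RMSE and MAE. RMSE uses an $n$ denominator (not $n - p - 1$), the
  common QSAR reporting convention; the report settings record this.
* $Q^2_{\mathrm{LOO}} = 1 - \mathrm{PRESS}/\mathrm{TSS}$ with each
  prediction from a model refit without that compound (`q2_loo()`).
  Negative values are possible and are not clamped: a scrambled or
  worthless model genuinely predicts worse than the mean.
* $Q^2_{\mathrm{LMO}}$ (`q2_lmo()`): repeated random partitions into
  leave-out groups; defaults `group_size = ceiling(n/5)` and 50 repeats,
  seeded. With groups of one it reproduces LOO exactly (tested).
* **Y-scrambling** (`y_scramble()`): the response is permuted (identity
  excluded) and the model refit on the *same* descriptors, 100 times by
  default; the mean scrambled $R^2$ and $Q^2$ are reported, alongside
  the per-permutation table. Under the permutation null the expected
  scrambled $R^2$ is approximately $k/(n-1)$ — about 0.087 at $n = 47$,
  $k = 4$ — which is why the OECD ceiling of 0.20 is a meaningful
  discriminator. When fewer than the requested number of non-identity
  permutations exist (tiny $n$), all are enumerated exactly.
* **External metrics** (`external_metrics()`): $R^2_{\mathrm{ext}}$ in
  the $Q^2_{F1}$ convention (reference mean = *training* mean), because
  the field is inconsistent here the squared Pearson correlation is also
  reported separately; Lin's concordance correlation coefficient with
  $n$-denominator variances, which penalises location and scale shift
  that Pearson ignores; external RMSE and MAE.
* **Roy's $r^2_m$ metrics** (`rm2_metrics()`), 2008 formulation on
  unscaled data; $r^2 - r_0^2$ is clamped at zero before the square
  root, since rounding can push it fractionally negative when the
  through-origin line coincides with the free fit. The scaled variant is
  out of scope.

## Applicability domain

`applicability_domain()` computes leverages
$h_i = x_i^\top (X^\top X)^{-1} x_i$ (intercept included), the warning
leverage $h^* = 3(p+1)/n$, and standardized residuals
$e_i / (\mathrm{RMSE}\sqrt{1-h_i})$. Queries with $h > h^*$ are
extrapolations; training compounds with $|z| > 3$ are response outliers.
`autoplot()` on the report draws the Williams plot. Two identities pin
the implementation: $\sum_i h_i = p + 1$, and a query at the training
centroid has leverage exactly $1/n$.

## Synthetic data: what it emulates, and what it does not

`gen_qsar_dataset()` generates descriptor tables with *known ground
truth*. Signal and noise descriptors are i.i.d. standard normal —
deliberately not an imitation of real descriptor distributions, because
the generator's job is ground-truth recovery, not realism. Planted
violators mimic the two failure modes large pools actually contain:
near-constant columns (one value in strictly more than 80% of rows) and
collinear near-copies (`copy = base + N(0, (0.1 sd)^2)`, population
$r \approx 0.995$, comfortably past the 0.95 threshold at $n \ge 30$).

Two presets fix the study conditions:

* **`preset_study57()`**: 57 compounds, 4 signal among 50 noise
  descriptors, noise calibrated to an expected in-sample $R^2$ of 0.83;
  with `make_split(external_count = 10)` this yields the 47/10
  train/external design. The noise SD is obtained by inverting the
  expected sums of squares ($E[\mathrm{RSS}] = \sigma^2(n-k-1)$,
  $E[\mathrm{TSS}] = (n-1)(\sigma_s^2 + \sigma^2)$); across seeded
  replicates the realized training $R^2$ averages within ±0.03 of the
  target (tested). Targets at or below the chance level $k/(n-1)$ are
  infeasible and error.
* **`preset_study_pool()`**: 11,829 descriptor columns of which exactly
  7,943 violate the filters, leaving 3,886. The split of the violators
  between the two stages — 3,972 near-constant + 3,971 collinear — is
  an arbitrary fixed choice (only the total is constrained by the
  design); the retained count is invariant to it and to the seeded
  column shuffle, because each collinear cluster loses all but exactly
  one member regardless of scan order.

Because the generator is linear-Gaussian, passing tests demonstrate
correctness of the *procedures* — recovery, calibration, null behaviour
— not that real descriptor sets are this benign: real pools have heavy
tails, discrete columns, and correlated signal/noise structure that can
only make selection harder.

The split itself (`make_split()`): the default `sorted_stride` strategy
sorts by activity and takes every $\lceil n/\text{count} \rceil$-th
compound starting from the least active, so the external set spans the
activity range deterministically (with an evenly-spaced-rank fallback
for size combinations where the plain stride cannot deliver the exact
count). How the original external sets of published studies were chosen
is typically unstated; a seeded `random` strategy is provided as the
alternative, and neither is claimed to reproduce any particular study's
split.

## Published equation fixtures

`published_model("model1")` and `"model2"` store two published
four-descriptor pIC50 equations for trimethoxyphenyl tubulin
polymerization inhibitors, verbatim. Descriptor names (including
`R3s++`) are matched case-sensitively after trimming. The package takes
no position on the equations beyond reproducing them: descriptor values
must be supplied by the caller, since computing `Mor15i` and friends
from structures requires external descriptor software and is explicitly
out of scope.

## Trajectory statistics

The dynamics module works on trajectories of abstract point sites (one
per residue, a C-alpha-level abstraction; `read_xyz_trajectory()` for
multi-frame XYZ input, or any array via `trajectory()`).

* `kabsch_superpose()`: optimal rigid-body superposition via SVD with
  the reflection-corrected determinant sign; degenerate (collinear)
  geometries error rather than silently returning one of many optima.
  A numeric-minimisation oracle over rotations pins the result in tests
  to 1e-4 Å.
* `rmsd_series()` and `rmsf()`. RMSF superposes every frame onto the
  trajectory *mean* structure, with two fixed-point refinements of the
  mean — the frame-fitting protocol is stated here precisely because
  published studies often leave it implicit.
* `dccm()`: $C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
  \sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}$
  with full 3-vector dot products (the standard DCCM definition, as in
  MD-TASK-style analyses), not per-axis correlations. Superposition is
  on by default, which makes the matrix invariant (to 1e-8, tested)
  under rigid-body motion of the whole trajectory.

`gen_trajectory()` builds trajectories from collective modes (per-site
weights × amplitude × a sinusoidal or white-noise time series along a
unit direction) plus isotropic thermal noise. `analytic_dccm()` gives
the correlation matrix the mode weights imply, and the empirical DCCM
converges to it at 10,000 frames within 0.02 (tested). Same-sign shared
weights give $C = +1$ exactly; opposite signs $-1$. No force field is
involved: the generator produces *specified correlation structure*, not
physically realistic protein dynamics, so agreement here validates the
estimator, not any simulation.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script run the study-scale designs:
the 11,829-column pool once (the pre-filter completes in well under two
minutes), 100-replicate sweeps of the 57-compound preset for the
$Q^2$-floor and calibration checks, GA recovery over 10 seeded runs
with population 60 × 60 generations (ample for a 54-descriptor pool),
and 10,000-frame trajectories for the sampling-bound and convergence
checks. Every stochastic routine takes an explicit integer seed, uses
an isolated RNG scope (the caller's RNG state is never touched), and is
byte-reproducible from it.

Degenerate inputs error early and name the offender: rank-deficient
designs name the collinear column, constant columns are refused by the
correlation filter and the K index, zero-variance activities are
refused by every $R^2$-like metric, zero-fluctuation sites are named by
`dccm()`, and leverages of ~1 are refused by the PRESS shortcut.

## Known limitations

* Only fixed-size subsets and OLS: no variable-size chromosomes, no
  PLS/ridge alternatives, no multi-objective search.
* The applicability domain is leverage-only; distance-to-model and
  density-based AD methods are out of scope.
* No bootstrap validation and no Golbraikh-Tropsha slope criteria
  beyond the implemented battery; no multiple-testing correction is
  applied anywhere, because the battery is descriptive model
  validation, not hypothesis screening.
* The trajectory module reads multi-frame XYZ only (no PDB/DCD), and
  its generator makes no claim to physical realism.
* Descriptor values are never computed from chemical structures; the
  published-equation fixtures predict only from user-supplied
  descriptor maps.
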
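---
title: "Genetic QSAR model building and validation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic QSAR model building and validation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genqsar)
```

## The modelling problem

A quantitative structure–activity relationship (QSAR) links a numeric
molecular-descriptor table (compounds × descriptors) to a measured
biological response, here antioxidant potency expressed as pIC50 — the
negative decadic logarithm of the 50% inhibitory concentration in
millimolar, so larger values mean more potent compounds.  The package
implements the full chemometric workflow around a series of NO-donor
phenolic antioxidants assayed for inhibition of lipid peroxidation:
descriptor preprocessing, rational division into training and external
test sets, three model-building engines (stepwise multiple linear
regression, genetic function approximation, genetic partial least
squares), an internal/external validation suite, Y-randomization
robustness statistics and a distance-to-model applicability domain.

The models are linear in a small set of *basis terms*, each reading one
descriptor through one of four transforms: the identity, the square, or a
truncated power spline `<a - x> = max(0, a - x)` / `<x - a> = max(0, x - a)`
whose constant `a` is the knot.  Spline terms let an otherwise linear
equation express threshold behaviour — e.g. "methylation below an E-state
sum of about 1.8 hurts potency, extra methylation above it is neutral" —
while remaining interpretable term by term.

## Train/test division

`kmeans_split()` standardizes the descriptor matrix (centering, unit
sample SD), clusters the compounds by a seeded Lloyd k-means with
`k = round(test_fraction * N)` (a quarter held out by default, giving 8
test compounds for N = 33) and sends the compound nearest each cluster
centroid to the test set.  The underlying method leaves the mapping from
clusters to test membership open; one-per-cluster-nearest-centroid was
chosen because it reproduces the published test-set size and guarantees
the test set touches every occupied region of descriptor space.  Ties in
the nearest-centroid rule break toward the lowest compound index, and the
clustering itself re-seeds empty clusters from the farthest point, so the
whole division is deterministic given a seed.

A caveat worth stating plainly: with a quarter of the compounds held out,
the clusters are small and "nearest to centroid" is only a weak
centrality constraint, so the *activity* range of the test set is not
reliably contained in the training range — in our 50-seed simulation on
200-compound synthetic datasets strict containment held in roughly half
the seeds, with mean excursions under 2% of the activity span.  The split
is representative in descriptor space, which is what the clustering
controls; tests assert the simulated containment level actually observed
rather than a stronger claim the rule does not deliver.

## Model building

**Stepwise MLR** (`stepwise_mlr()`) alternates forward selection and
backward elimination over linear descriptor terms using the partial-F
stepping criterion — the square of a coefficient's t-value — with
F-to-enter 4.0 and F-to-remove 3.9.  Ties break by descriptor column
order.  Once a fit becomes numerically exact (RSS below 1e-12 of the
total sum of squares) further entry is suppressed, because partial F is a
ratio of noise terms at that point.

**Genetic function approximation** (`gfa_search()`) evolves a population
of term sets.  Each individual is fitted by ordinary least squares and
scored by Friedman's lack-of-fit

LOF = LSE / (1 − (c + d·p)/m)²,

with `c` the number of basis functions, `p` the number of distinct
descriptors, `m` the training size and smoothing parameter `d = 1` by
default.  LSE is taken as RSS/m (mean squared error), which keeps the
penalty scale-consistent with the conventional `d = 1` default; this is a
convention choice and is stated as such.  The underlying method does not
publish population size or operator rates, so desk-scale conventions are
used: population 100, single-point crossover on sorted term lists,
add/remove/knot-perturb mutation at probability 0.1 each, steady-state
replacement of the current worst individual, elitism of one.  "Iterations"
counts genetic operations rather than generations.  Spline knots are
drawn from observed interior values of the chosen descriptor (so at least
one training compound sits on each side of the knot whenever possible);
knot mutation mixes uniform redraws with small steps to neighbouring
observed values, which is what lets the search localize a knot exactly.
Numerically tied LOF values (several exact fits) resolve toward the
smaller equation via a 1e-12-scale tie-break, far below any meaningful
LOF difference.  After the genetic run the champion is refined by a
deterministic local step — backward pruning with per-candidate knot
re-polish, and coordinate-descent knot polish over all observed interior
values — which collapses plateaus of tied fits onto the minimal equation
(G/PLS champions get the pruning without the knot polish, whose cost
there carries a full leave-one-out pass per candidate).  One degeneracy
is worth knowing: on a finite sample a truncated spline obeys
`<a - x> = (a - x) + <x - a>`, so an exact fit occasionally returns this
three-term re-parameterization of a two-term truth; it is the same
function with the same knot, and the recovery tests treat it as such.

**Genetic PLS** (`gpls_search()`) uses the same genetic engine, but each
candidate term set is fitted by NIPALS partial least squares on its
evaluated basis, with the number of latent variables chosen in
`1..max_lv` (cap 3 by default) by minimizing the inner leave-one-out
PRESS, and scored by the LOF of that fit.  PLS tolerates the collinear
term sets the genetic search likes to propose, which is the point of the
combination.  The NIPALS core deflates X only — equivalent to the
y-deflating variant for a single response — with a 1e-10 inner tolerance
and a 500-iteration cap (for one response the weight update has its fixed
point in one pass).

## Validation metrics

All metrics live in plain functions so they can be applied to packaged
prediction columns as well as to freshly fitted models:

* `q2()` — leave-one-out Q² = 1 − Σ(Y_obs − Y_pred)²/Σ(Y_obs − Ȳ_train)²,
  with the *fixed* training mean, not per-fold means.
* `r2_pred()` — external R² referencing test-set errors to the training
  mean.
* `rm2()` — r_m² = r²·(1 − √(r² − r₀²)), where r₀² comes from the
  through-origin regression of observed on predicted with slope
  k = Σ(obs·pred)/Σ(pred²).  Two conventions deserve a note.  First, some
  typeset sources print the formula without the square root; only the
  square-root form reproduces the published reference values (e.g. the
  0.812 test-set value of the phenol series), and the original metric
  definitions carry it, so the square root is the default and the
  sqrt-free variant sits behind `legacy_no_sqrt`.  Second, the
  orientation — observed regressed on predicted — is likewise fixed by
  numerical agreement with the reference values; the transposed
  convention is available as an option.
* `true_rm2_loo()` — the honest LOO variant for small datasets: variable
  selection is re-run inside every fold, so the statistic measures the
  model-*building process*, not one fixed equation.
* `randomize()` — Y-scrambling.  Process mode re-runs selection on the
  scrambled activity over the full descriptor pool (9 permutations by
  default, the 1/(n+1) convention for a 90% confidence level); model mode
  refits the fixed term set (99 permutations, 99%).  Reported statistics:
  R_r² (mean scrambled R²), R_p² = R²·√(R² − R_r²) and the corrected
  ᶜR_p² = R·√(R² − R_r²), clamped to zero and flagged when the scrambled
  models outperform the real one.
* `dmodx()` — the SIMCA-style applicability domain.  A compound's
  distance to the PLS model plane is the SD of its X-residuals,
  s_i = √(Σ_k e²_ik/(K−A)); normalization divides by the pooled
  s₀ = √(SS_E/((N−A−1)(K−A))), and the critical value at significance α
  is √F_α(K−A, (N−A−1)(K−A)).  Under this normalization the mean squared
  training DModX is exactly (N−A−1)/N, which is the calibration the tests
  assert.  The published critical value for the reference G/PLS model
  (3.225 at 99%) depends on its unpublished descriptor matrix and is
  treated as non-reproducible; the domain machinery is validated by its
  algebraic properties instead.

## Synthetic ground truth and what passing tests mean

`generate_qsar_data()` draws descriptor families mimicking the real
table's structure: non-negative count-like topological indices (Poisson),
continuous E-state-like sums (Gaussian), and near-collinear index pairs
(affine transforms of correlated Gaussians at a target Pearson r, 0.989
by default — the level seen between a subgraph count and its matching
connectivity index).  Activity is a known sparse linear+spline model plus
Gaussian noise, σ = 0.3 by default against coefficients of 2–3, i.e. a
clearly detectable but non-trivial signal.  Truth knots snap to the
nearest observed descriptor value by default so that, at σ = 0, the
generating equation is exactly representable by the searches' own knot
grid and recovery can be asserted to machine precision.

`recovery_harness()` sweeps noise levels and seeds and reports support
recovery (true descriptors selected), exact-support recovery, coefficient
RMSE over structurally matched terms, and the Q²/r_m² of a least-squares
refit.  The stepwise harness uses a purely linear truth (stepwise cannot
represent a spline term, so coefficient recovery would be ill-posed);
the genetic searches get the linear+spline truth.

What these simulations do *not* show: the generator draws independent
compounds with idealized family distributions, no measurement error in
descriptors, no activity cliffs, and only mild collinearity outside the
designated pairs.  Passing recovery tests therefore demonstrates the
correctness and sensitivity of the search/validation machinery, not that
any particular descriptor set suffices for real antioxidant chemistry.

## Problem sizes and numerical choices

The shipped tests run the searches at desk scale — n = 60 compounds,
20–30 descriptors, populations of 40–100, genetic budgets of a few
hundred to a few thousand operations, 20 seeds per scenario — sizes at
which the stochastic recovery rates are stable and the whole suite stays
comfortably interactive.  Degenerate inputs are handled fast and loudly:
zero-variance descriptors must be filtered before standardization or PLS
(an error, not a silent drop), rank-deficient OLS designs name the
collinear terms, all-constant spline columns are rejected at fitting
time, and an empty k-means cluster is re-seeded from the farthest point
(or allowed, with a warning, when the data cannot support k distinct
clusters).  Missing descriptor values are refused at load time; the
reference matrix is complete, and imputation is out of scope.

## Packaged reference data

The 33-compound activity table ships with both published prediction
columns and the fixed test-set flags; all published validation statistics
recomputable from it are asserted in `reproduce_published()` (the package's
reproduce-everything entry point) and in the acceptance script.  One
attribution quirk is preserved deliberately: the table footnote ascribes
its first prediction column to the first GFA spline equation, but the
statistics recomputed from that column (PRESS 4.557, Q² 0.814, R²_pred
0.917) match the quadratic reformulation's printed block; the fixture
metadata records both labels rather than guessing the intent.  The four
published equations themselves are packaged as prediction-only JSON
models — their raw descriptor matrix was released only as unpackaged
supplementary material, so re-deriving their coefficients, the specific
8-compound split, the whole-dataset `true r_m²(LOO)` of 0.578 and the
3.225 DModX cutoff is out of reach; those quantities are covered by the
property-based tests above instead.

## Known limitations

* The genetic searches are stochastic; results are reproducible only per
  seed, and the published equations' exact term sets are not a target.
* PLS is implemented for a single response.
* Permutation counts for the randomization confidence levels follow the
  1/(n+1) convention of the original software; both are overridable.
* The applicability-domain F-approximation treats (K−A) as the effective
  residual degrees of freedom per compound, the standard SIMCA
  convention; it is approximate for strongly non-normal descriptors.
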
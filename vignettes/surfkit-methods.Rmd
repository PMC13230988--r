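---
title: "Models and methods behind surfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind surfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfkit)
```

surfkit analyzes the battery of quantitative assays used to characterize
live microbial cells after chemical surface functionalization: how many
molecules were loaded per cell, whether the cells are still active, how
quickly DNA-coated cells aggregate, how well-mixed the resulting two-color
aggregates are, and how fast the surface label dilutes out with growth.
This vignette documents the models the package fits, the assumptions each
one makes, the tunable parameters with their defaults, and the design
choices taken where the methodology was genuinely open.

## Viability from regrowth dynamics

Membrane-permeability stains score a cell "dead" only when its envelope is
compromised; they are blind to cells that survive a chemical treatment but
restart growth late. The regrowth assay is stricter: treated and paired
untreated cultures are diluted into fresh medium, their OD600 is recorded,
a growth model is fitted, and the *initial active population* is read off
as the back-extrapolated initial OD. Any treatment-induced lag is
deliberately **not** modeled as a separate parameter — it depresses the
back-extrapolated intercept and therefore the viability estimate. That is
the assay's point: a cell that regrows late contributes less.

### Exponential model (minimal media)

`fit_exponential()` regresses `ln OD` on time over the exponential phase:
the slope is the growth rate `r` (h^-1) and `exp(intercept)` is `od0`.
A pure lag `L` at fixed `r` multiplies `od0` — and hence viability — by
`exp(-r * L)` exactly; the test suite asserts this identity.

The exponential phase is not marked in the raw data, so the default window
rule must be objective and reproducible:

* only points with OD between a detection floor (default 0.01) and 50% of
  the series maximum are eligible;
* every contiguous sub-window with at least 4 points and at least half
  the length of its parent run is scored by the `1 - r^2` misfit of its
  log-linear fit;
* the longest window whose misfit is within a factor 10 of the best
  candidate's misfit wins.

The two safeguards matter. Scoring by `r^2` alone shrinks the window to a
lucky handful of points as soon as there is noise; taking the longest
eligible run alone swallows lag plateaus and biases `r` downward (on a
lag-shifted noise-free curve the rate came out 0.39 h^-1 instead of the
true 0.5 h^-1 before the rule was adopted). The factor-based misfit band
adapts to the noise level: on noise-free data the best misfit is
essentially zero and any kink-contaminated window is excluded, so the lag
identity above holds exactly; on noisy data long windows score best anyway
and the full usable run is kept. The window is overridable per sample.

### Logistic model (rich media)

In rich media the curve saturates, so `fit_logistic_difference()` uses the
classical linearization of logistic growth: the per-capita rate
`(dOD/dt)/OD = r (1 - OD/k)` is linear in OD. The derivative is estimated
with centered finite differences (second-order accurate; a forward mode
exists for comparison), and the regression of the per-capita rate on OD
gives `r` as the intercept. For the carrying capacity the algebra of the
linearization forces `k = -intercept/slope`; the alternative reading
"negative of the ratio of slope to intercept" would return `1/k` and fails
the noise-free recovery test, so the algebraically consistent form is
used. `od0` then comes from the analytical inversion of the logistic
solution,

```
od0 = k * OD(t0) / (OD(t0) + (k - OD(t0)) * exp(r * t0)),
```

implemented in `back_extrapolate_od0()` with `t0` the first fitted time
point. For `k >> OD` this reduces to the exponential back-extrapolation,
and composing it with forward propagation is the identity to 1e-10
relative — both are tested.

### Quality control and inference

Every fit reports `r^2`; fits below 0.99 are flagged rejected (not
errored) and `viability_from_regrowth()` refuses them unless explicitly
overridden. Viability is the mean over biological replicates of the
paired ratio `od0_treated / od0_control`, with SEM across replicates and
a one-sided one-sample t test against 1 (alternative "less" — the assay
can only score treatments as reducing activity). When several treatment
concentrations of one strain are evaluated together they form one
Benjamini–Hochberg family (`adjust_family()`). Growth-rate effects are
tested the same way on `r` ratios.

Blank handling is configurable because plate-blank policy is rarely
reported: if a blank condition is designated in `od_layout()`, the
per-plate mean blank OD is subtracted and negative results are clamped at
0 with a warning; the default is no blanking.

### MIC endpoints

`mic_from_endpoint()` reads a broth-microdilution plate: the MIC is the
lowest antibiotic concentration whose endpoint OD falls below a growth
threshold *and* from which suppression holds at every higher
concentration. The threshold defaults to 10% of the drug-free control's
endpoint OD — a package choice, since endpoint cutoffs are rarely stated —
and the plate is invalid if the drug-free control itself fails to grow
(control OD below 0.1 by default). Isolated no-growth wells underneath a
growing well ("skips") are treated as artifacts: the MIC is pushed above
the highest growing concentration and the result is flagged
non-monotone. Growth at every tested concentration right-censors the MIC
("> max"); suppression already at the lowest non-zero concentration
left-censors it ("<= min").

## Absolute fluorescence quantification (MESF) and dosimetry

Flow-cytometer intensities are arbitrary units; calibration beads carrying
known numbers of fluorophores anchor them to an absolute scale.
`fit_mesf_calibration()` regresses blank-subtracted bead MFI on molecules
per bead with a *free* intercept: the blank subtraction should leave the
intercept near zero, so a large intercept (more than 10% of the dimmest
bead's signal) is a diagnostic flag rather than being forced away. The
slope converts background-subtracted cell MFI to Molecules of Equivalent
Soluble Fluorochrome; dividing by the degree of labeling (fluorophores per
conjugated molecule, default 1 when unreported) gives molecules per cell.
Surface overcrowding quenches fluorescence non-linearly and beads are an
order of magnitude larger than cells, so every count carries an explicit
lower-bound note; no quenching correction is attempted.

Dosimetry converts a molecule count into physically interpretable
densities. The default cell geometry is a spherocylinder with radius
0.5 µm and total length 2 µm (a typical 1–2 µm rod), giving a surface
area `2πr(L − 2r) + 4πr² = 2π µm²`; 210,000 molecules then occupy about
30 nm² each, with a mean spacing `sqrt(area/molecule)` of about 5.5 nm.
`bulk_equivalent_concentration()` uses the standard conversion of 1e9
cells/ml per OD600 unit: 210,000 molecules per cell at OD 0.1 is
equivalent to ~35 nM of free molecule.

Stain-based viability (`stain_viability()`) classifies events by a red
(dead-stain) intensity threshold. A user-supplied threshold is canonical;
the automatic mode places it at the minimum-density valley between the
two largest modes of a kernel-density estimate of the pooled
log-intensities and labels the output `auto_kde_valley`, because an
automatically chosen cutoff should never masquerade as a calibrated one.
The viability ratio sample/control is reported uncapped: values above 1
are possible and are logged, not truncated.

## Aggregation kinetics and adhesion probability

Mixing two cell populations coated with complementary DNA strands causes
aggregation, visible as an OD600 decay. Counting single cells and
two-cell aggregates as equal scatterers, a first-order reaction model
(only single cells of opposite populations react, at rate `k`) gives

```
OD(t) = c0 + c0 / (c0 * k * t + 1)
```

with `c0` the initial OD of each population. The model is honest about
its own validity: it ignores reactions involving aggregates, so it only
holds while most cells are single. `fit_adhesion_rate()` therefore fits
by nonlinear least squares over the first hour by default and offers
`max_aggregated_frac`, which truncates the window at the first reading
where the aggregated fraction `(2*c0 - OD)/c0` exceeds a given value.
This guard exists because fitting the full hour of a fast-aggregating
simulated trace (true p = 0.03) biased the rate upward by ~57%; at
`max_aggregated_frac = 0.15` the median relative error of the recovered
adhesion probability stays below 15% across the tested range
(p = 0.002–0.03). `c0` defaults to half the first OD reading, matching
the protocol of standardizing the mixed suspension to OD 1.0.
Confidence intervals are Wald intervals from the least-squares
covariance with a t quantile; a window-sensitivity report over 30/45/60
minutes is attached to every fit.

The fitted rate is converted to a per-encounter adhesion probability
through diffusion physics: the encounter rate of two equal spheres is
`4π D_eff R_c` with `D_eff = 2D` and `R_c = 2R`, and Stokes–Einstein
(`D = kB T / 6πRη`) cancels the radius, leaving
`k_vol = (8 kB T / 3η) p`. OD units become volumetric units via the cell
density `n = cells_per_ml_per_od × 1e6` per m³ (default 1e9 cells/ml/OD,
configurable per organism). Defaults: T = 298.15 K and η = 0.89e-3 Pa·s
(water at the 25 °C incubation temperature). Fitted `p > 1` — faster than
the diffusion limit — is flagged, not clipped.

`simulate_aggregation()` is the package's independent stochastic check on
this analytic chain: an exact Gillespie simulation with a constant
(size-independent) kernel acting between any two clusters of which one
contains red and the other green cells. Same-color reactions are off by
default because the complement model contains none; a background
same-color rate is available to emulate non-complementary controls. The
per-pair rate is chosen so the mean-field early-time limit reproduces the
analytic curve at the same `p`, total cell count is conserved at every
event, and the OD proxy is the cluster count scaled to start at `2*c0`.
The test suite verifies mean agreement with the analytic curve within 3
Monte-Carlo SE in the early regime (a few percent aggregated), parameter
recovery through `fit_adhesion_rate()`, and recovery of a 15-fold
difference in true `p` within 20%.

## Spatial mixing of two-color aggregates

`opposite_color_nn_fraction()` quantifies micro-scale mixing: for every
cell the nearest neighbor within the same aggregate is found by Euclidean
distance, and `p_rg` is the fraction of cells whose nearest neighbor
carries the opposite fluorescent label. Conventions, all deliberate:

* *directed* neighbors — each cell contributes exactly one (cell →
  nearest neighbor) pair; a mutual-pair mode would discard cells and is
  not the default reading of "fraction of cells";
* distance ties break to the lowest point index, for determinism;
* 2D analysis is the default because individual confocal slices are the
  input; a `z` column switches to 3D transparently;
* aggregates are analyzed independently and pooled with cell-count
  weights; replicate-level means are the unit of statistical inference;
* no edge correction is applied — boundary cells keep their observed
  neighbor.

Under independent, equal-probability labels the expected `p_rg` is 0.5
regardless of geometry, because each cell's neighbor color is independent
of its own. `permutation_null()` makes this operational without
distributional assumptions: labels are reshuffled within each aggregate,
conditioning on the observed per-aggregate color counts (the conservative
choice when the balance assumption is in doubt), and the nearest-neighbor
structure is computed once and reused across permutations.
`compare_mixing()` tests replicate-level means against 0.5 (two-sided
one-sample t) and between conditions (two-tailed Welch).

## Label dilution with growth

A surface label is not replenished: if total label is conserved while
the colony area doubles, mean fluorescence per unit area halves. The
number of doublings is `d = log2(area / initial_area)` and
`fit_retention()` fits `A(d) = a0 * f^d` log-linearly (regress `ln A` on
`d`), pooling all timepoints of a lineage. Log-linear fitting is the
right likelihood under multiplicative noise, which is what fluorescence
measurements show; a direct nonlinear fit is a trivial variation and was
not needed. Exact conservation gives `f = 0.5` to 1e-10, an independent
per-doubling loss `g` (e.g., photobleaching) composes multiplicatively to
`f = 0.5 * g`, and rescaling fluorescence units moves `a0` but not `f` —
all tested. Fits require at least one full doubling of dynamics; `f`
slightly above 1 is flagged as unphysical but kept. Lineage definition
(merging/splitting of clonal patches) is upstream of this module; the
trace contract only enforces positive, near-monotone areas.

## Synthetic data: what it emulates, and what it does not

No raw instrument data ships with the package; seeded generators with
embedded ground truth stand in for every input:

* `gen_growth_curves()` — closed-form exponential/logistic growth with
  treatment effects expressed as a reduced initial active population
  and/or an extra lag, plus multiplicative log-normal noise (default SD
  0.02, a realistic plate-reader scale; noise is multiplicative to keep
  OD positive).
* `gen_flow_events()` — log-normal live/dead mixtures in the red channel
  (defaults put the mode means a factor ~60 apart, mimicking a clean
  nucleic-acid stain separation) and a unimodal green channel.
* `gen_bead_set()` — a five-population bead ladder with relative noise.
* `gen_aggregation_od()` — the Gillespie coagulation model above with
  optional Gaussian read noise.
* `gen_point_aggregate()` — Eden-type lattice growth of an aggregate:
  each new cell occupies a random empty site adjacent to the cluster and
  binds a random occupied neighbor, with up to 10% positional jitter as
  segmentation centroids show. In the `hetero_only` regime the new cell
  always takes its anchor's opposite color; in `both_strands` it does so
  with probability `hetero_bias` (default 0.75). The bias parameter is a
  modeling judgment: with both strands on both populations every contact
  can bind, but complementary pairings still out-compete like pairings,
  and a fully color-blind rule would collapse the regime onto the random
  null instead of the intermediate mixing that motivates the control. The
  `random` regime (uniform ball, i.i.d. labels) realizes the null.
* `gen_lineage()` — exponential area growth with
  `A(d) = a0 * f_true^d` fluorescence and log-normal partitioning noise.

Passing tests on these generators demonstrates that each fitter recovers
the parameters of its own generating model at realistic noise levels and
sample sizes. They do not demonstrate robustness to what real instrument
data adds: plate-reader drift and condensation artifacts, cytometer
spillover and gating misses, segmentation errors that merge touching
cells, aggregate sedimentation during imaging, or biological deviations
from the fitted growth laws. Conclusions about those failure modes need
real data.

## Problem sizes and numerical choices

The default simulation scales — chosen to make every stochastic check
statistically meaningful while the whole suite stays lightweight — are:
2,000 cells per color for aggregation recovery (50 seeds per condition),
500 cells per color for analytic-versus-stochastic agreement (50 seeds),
30 aggregates × 500 points for the mixing null, 10,000 events for flow
round trips, 200 seeded curves for growth recovery, and 6 lineages for
retention. Degenerate inputs fail loudly and early: zero-variance t tests
error (except the exactly-null case, which returns the symmetric
p-value), constant OD series cannot enter logistic fits, non-positive
areas and fluorescences are rejected, and an OD trace that never
decreases yields a flagged zero-rate result rather than a spurious fit.
All randomness flows through explicit seeds via `withr::with_seed()`, so
generators never perturb the caller's RNG stream.

## Known limitations

* The first-order aggregation model is early-time only; there is no
  Smoluchowski hierarchy fit for late-time data, no settling physics, and
  no aggregate-size-dependent optical model — OD is taken proportional to
  cluster count.
* MESF counts are lower bounds; degree of labeling defaults to 1 when
  unreported.
* The exponential-window heuristic assumes a single exponential phase
  inside the usable OD band; diauxic curves need a manual window.
* The MIC growth threshold (10% of control) is a convention, not a
  measurement; report it alongside results.
* 2D mixing statistics from single slices under-sample true 3D contact
  neighborhoods; the package computes 3D when `z` is supplied but cannot
  correct a 2D acquisition.
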
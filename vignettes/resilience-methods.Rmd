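---
title: "Virtual-lesion resilience of functional brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-lesion resilience of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connres)
```

## The question the package answers

After a first stroke, does the brain's functional network reorganize in a
way that makes it *more resistant* to a second lesion? `connres` implements
the full computational side of that question: it builds functional
connectomes from region-level BOLD signals, simulates recurrent strokes by
deleting the atlas regions that a clinical lesion mask covers, and
quantifies how much each deletion degrades three whole-brain graph
properties — global efficiency (integration), modularity at a fixed
a-priori partition (segregation into communities), and mean clustering
(local segregation).

Because clinical resting-state cohorts cannot be redistributed, the package
ships a synthetic-cohort generator that emulates the relevant structure of
such data — 246-region connectomes with a 17-module community template,
patient and control groups followed over up to three timepoints, and a
122-mask virtual-lesion library — so that every stage of the pipeline is
exercised and tested end to end on data whose ground truth is known.

## From BOLD series to a connectome

The preprocessing chain applies, in fixed order:

1. **Detrending and nuisance regression** (`detrend_and_regress()`): each
   region series is replaced by its least-squares residual after projecting
   out an intercept, a linear trend and any supplied nuisance block
   (motion-like drift regressors, spike indicators, CSF-like signals). A
   rank-deficient nuisance block triggers a warning and a pseudo-inverse
   projection rather than an error.
2. **Winsorization** (`winsorize()`): per region, values are clipped to the
   5th and 95th percentiles. Percentiles use linear interpolation between
   closest ranks (R's type-7 convention); this convention is a documented
   choice, since several are in circulation.
3. **Wavelet sub-band filtering** (`wavelet_band()`): a maximal-overlap
   discrete wavelet transform (periodic boundary) decomposes each series
   into dyadic frequency bands and the detail level whose band
   $[1/(2^{j+1}\,TR),\ 1/(2^j\,TR)]$ covers 0.03–0.06 Hz is reconstructed.
   For the default TR of 2 s this is level $j = 3$ (0.031–0.0625 Hz); the
   level is always computed from the TR, never hard-coded. The default
   filter is the 16-tap least-asymmetric orthogonal wavelet, chosen because
   its transition bands are sharp enough that a sinusoid in the middle of
   the target band retains over 90% of its energy while a 0.2 Hz sinusoid
   retains essentially none; `la8`, `d4` and `haar` are available
   alternatives. The transform satisfies exact reconstruction (details plus
   smooth re-sum to the input), which the test suite verifies.
4. **Pearson correlation** (`correlation_matrix()`) between all retained
   region pairs, giving a symmetric, unit-diagonal weighted connectome.
5. **Region exclusion** (`exclude_regions()`): signal-dropout regions and —
   per patient — regions covered by the subject's own (primary) stroke are
   deleted, with every removal recorded in the connectome's ledger together
   with its reason.

## Lesion masks to region sets

`region_overlap_fractions()` counts, for every atlas region, the fraction
of its voxels inside a binary lesion mask (atlas and mask must already be
on one grid; the package never resamples). `lesioned_regions()` then
applies the 50% rule: a region is lesioned when **at least half** of its
voxels are covered. The boundary is inclusive by default; a
`strict_greater` flag switches to a strictly-greater rule, since both
phrasings circulate in the literature describing this procedure.

## Graph metrics, the density grid and AUC

All metrics operate on binarized graphs. A weighted matrix is first
thresholded at $w > 0$ (negative correlations are discarded), then
binarized at each density $\delta \in \{0.1, 0.2, \ldots, 1.0\}$ by keeping
the $\lfloor \delta P \rceil$ strongest positive edges ($P$ = number of
positive weights; rounding is half-away-from-zero; ties break by node-pair
order so results are reproducible). The ten graphs per matrix are nested.

Per graph the package computes, in standard binary-graph conventions:

* **Global efficiency**: mean over ordered pairs of $1/d(i,j)$ with
  $1/\infty = 0$ for disconnected pairs. Low densities necessarily
  disconnect the graph, so this convention is load-bearing.
* **Modularity at a fixed partition**:
  $Q = \sum_s (e_s/m - (d_s/2m)^2)$ evaluated at the supplied a-priori
  module assignment — no community detection anywhere.
* **Mean clustering**: average of per-node triangle density, zero for
  nodes of degree below two.
* **Participation coefficient**: $PC_i = 1 - \sum_s (k_{is}/k_i)^2$, zero
  for isolated nodes.

Each metric's ten values form a curve over density; the scalar carried into
all statistics is its **area under the curve** over $\delta \in [0,1]$
(trapezoid rule). The $\delta = 0$ endpoint is handled analytically — the
edgeless graph has metric value 0 for all four metrics — rather than as an
eleventh empty graph. Whether the original analytic protocol sampled
$\delta = 0$ explicitly is not documented; the analytic endpoint is this
package's documented choice and is configurable via `auc_of_curve()`.

## Attacks and the resilience statistic

`run_attack_battery()` walks every subject, timepoint and lesion mask:

* the pre-attack AUC of each metric is computed once per
  subject-timepoint, for patients after removal of their primary-lesion
  regions;
* the attack deletes the mask's surviving regions and the AUCs are
  recomputed;
* raw resilience is $R(M) = M_{pre} - M_{post}$ (positive = damage);
* an attack is **skipped** for a subject iff its region set lies entirely
  inside the subject's already-removed regions; partial overlaps proceed
  on the remaining regions. Skips are logged, which reproduces the
  design in which some patients receive fewer than the full battery.

Normalized resilience is
$R_{norm}(M) = 1 - R_{obs}(M) / \overline{R_{ctl}(M)}$, where the
denominator is the mean control raw resilience — per attack by default
(each mask normalized by the control mean *for that mask*), or pooled
across all control outcomes. The per-attack default makes outcomes
comparable across masks whose sizes span an order of magnitude, and under
either mode the control group mean is *algebraically* zero, which the
acceptance suite checks to 1e-12. When a control mean is closer to zero
than `eps` (default 1e-9) the outcome is flagged undefined and excluded
downstream. Controls enter the outcome table at the reference timepoint
only (TP1), mirroring the convention of using control baseline values for
all further analyses.

At small cohort sizes the per-attack statistic is heavy-tailed — masks
that barely damage controls produce denominators near zero and thus
extreme ratios — so simulation checks of *mean* effect direction are more
stable under the pooled mode; both are exposed and the identity holds
under both.

## The synthetic cohort: what it emulates, and what it does not

`simulate_connectome()` draws a weighted block-model correlation matrix:
within-module weights centred on `mu_within` (default 0.5), between-module
weights on `mu_between` (default 0.2) — long-range functional correlations
are weaker than local ones — Gaussian edge noise (SD 0.1), unit diagonal,
off-diagonals clipped to $[-1, 1]$.

A set of designated **hub** nodes (default 20% of nodes) carries an extra
`hub_boost` (default 0.2) on every between-module connection, so the hubs
concentrate inter-module integration and show the network's highest
participation coefficients, the way connector hubs do in cortical
networks. The group difference is injected by `hub_concentration`
$\kappa$: the fraction $\kappa/(1+\kappa)$ of each hub's extra
inter-module mass is moved off the hub and spread uniformly over the
between-module connections of non-hub nodes. The reallocation is
weight-preserving, so whole-network mean participation barely moves, but
hub PC falls monotonically in $\kappa$ and anti-hub PC rises once the
redistribution is substantial (it dips marginally at very small $\kappa$,
where non-hub connections onto hubs weaken before the redistributed mass
dominates). Controls
default to $\kappa = 0$ (concentrated) and patients to $\kappa = 3$
(three quarters of the hub load redistributed), emulating the post-stroke
hub-PC redistribution the analyses target. These defaults were fixed
during generator design on the basis that the injected PC redistribution
must be clearly detectable by the downstream hub analysis at desk-scale
cohort sizes.

`simulate_timeseries()` inverts the pipeline for testing: Gaussian series
with population correlation equal to the connectome (projected to the
nearest well-conditioned correlation matrix by eigenvalue clipping), plus
slow drift and motion-like spikes so preprocessing has realistic work to
do. `simulate_lesion_library()` draws mask sizes from a discretized
log-normal — `meanlog = log 6` so the median mask covers 6 regions,
`sdlog = 0.9` so the quartiles (about 3.3 and 11.0) sit inside the
reported interquartile bracket of 2–11 — truncated to
$[1, \lceil 0.2\,n \rceil]$, and samples regions with a 4-fold preference
for the seed region's module to mimic the spatial clustering of vascular
territories. Patient covariates follow documented clinical-style laws
(age $\sim N(53, 9^2)$ years; NIHSS negative-binomial with mean 6 and SD
about 6, truncated to $[0, 42]$; log-normal lesion volumes with mean about
29 cm³; 85% ischaemic; location frequencies from a mixed case list), and
one fifth of patients lack the third timepoint by default.

What the generator does **not** emulate: haemodynamics, spatially embedded
vascular geometry, scanner artefacts beyond drift and spikes, distance-
dependent connectivity, or any coupling between lesion location and
clinical covariates. Passing tests therefore demonstrate that the
*pipeline* is correct and that injected architectural effects propagate
with the right sign — not that the generator reproduces clinical effect
sizes.

## Group statistics

`fit_mixed_model()` fits linear mixed models with a subject random
intercept by REML (lmerTest backend, Satterthwaite degrees of freedom).
The group/timepoint structure enters as the four-cell factor {control TP1,
patient TP1, patient TP2, patient TP3}; all pairwise cell contrasts are
emitted with raw p-values and corrected with Benjamini–Hochberg
(`bh_fdr()`, a validated wrapper of the standard step-up procedure).
Attack-level rows enter the model directly (one row per subject ×
timepoint × mask), which is what the very large denominator degrees of
freedom in published analyses of this design imply; subject-level
aggregation remains available by averaging before fitting. A constant
response (a degenerate but testable case) falls back to ordinary least
squares, whose solution is exact there.

`subsample_balance_check()` guards against unequal group sizes by refitting
the group model on four random subsets of 18 patients against all
controls. `anova_by_location()` averages each patient's outcomes across
all timepoints and attacks, then compares stroke locations with a
classical one-way F test and Bonferroni-corrected pairwise t tests
(pooled SD); locations with fewer than two patients are excluded with a
warning, and a zero-variance response flags the F as undefined.

`fit_exponentiated_weibull()` fits the three-parameter exponentiated
Weibull, $F(x) = (1 - e^{-(x/\sigma)^c})^a$ with location fixed at zero, by
maximum likelihood over log-transformed parameters (Nelder–Mead then BFGS;
ordinary-Weibull starting values). The reported skewness is the *fitted
distribution's* third standardized moment, obtained by numerically
integrating the quantile representation $E[X^k] = \int_0^1 Q(u)^k\,du$ —
i.e. the skewness of the fitted curve, not of the sample.

Nodal PC per subject is summarized, like the whole-brain metrics, as the
AUC of nodal PC over the density grid; the density at which nodal PC was
evaluated in the original analysis is not documented, and the AUC keeps the
hub analysis consistent with the rest of the pipeline (a single-density
variant is available by passing a one-point grid). Hubs are the ten nodes
with the highest mean control PC at the reference timepoint, anti-hubs the
ten lowest, with ties broken by node id.

## Numerical and design notes

* Determinism: every generator is a pure function of its inputs and seed,
  restores the caller's RNG state, and identical cohort specifications are
  bit-identical.
* Edge-count rounding, tie-breaking, the AUC endpoint, the overlap
  boundary, the normalization mode and the denominator guard are all
  explicit, documented parameters.
* The problem sizes used by the test-suite simulation checks (cohorts of
  roughly 20 patients, 10 controls, 30 masks on 80-node, 8-module
  connectomes; 246-node checks where the full anatomical resolution is the
  point) are the package's choice of desk-scale study conditions: large
  enough for stable effect directions, small enough to run everywhere.

## Known limitations

* Deleting a patient's primary-lesion regions makes the patient's
  pre-attack network smaller than a control's, and a fixed mask then
  removes a larger *fraction* of it. This depresses patient resilience
  relative to controls in a way that is a property of the published
  procedure itself, not of any implementation; at full 246-region
  resolution the bias is small, at reduced test scale it is visible. The
  simulation tests therefore evaluate group effects against matched null
  cohorts rather than against an absolute zero.
* With node-deletion attacks at random (vascular-like, not hub-targeted)
  locations, classical robustness theory does not guarantee that
  redistributing hub load increases global-efficiency resilience; whether
  it does here depends on the architecture regime, and the package's
  default regime (scarce strong hubs) is the one in which hub loss is
  consequential. See the decisions recorded alongside the tests for the
  observed behaviour.
* White-matter tract lesioning, registration of masks to atlas space and
  voxel-level signal extraction are out of scope; inputs enter at the
  region level on a shared grid.
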
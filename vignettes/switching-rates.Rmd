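---
title: "Methods: switching rates of dynamic functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: switching rates of dynamic functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netswitch)
```

## The model

`netswitch` estimates the temporal stability of a functional brain network
from regional (node-level) time series. The pipeline has three stages.

**1. Sliding-window connectivity.** After discarding `trim_initial` initial
volumes (signal-equilibration frames), the series is segmented into
rectangular windows of `width` volumes advanced by `step` volumes; a scan of
`T` volumes yields `floor((T - trim - width)/step) + 1` windows (250 volumes
with the defaults give 191). Within each window, pairwise Pearson
correlations are Fisher z-transformed (`atanh`), the diagonal is set to 0,
and — before community detection — negative entries are zeroed, since the
modularity null model below requires nonnegative weights. The windows are
rectangular (untapered): no taper is assumed by the method, and a taper
would only blur the planted-event timing used in validation.

**2. Multilayer modularity.** The time-ordered connectivity matrices form
layers of a temporal multilayer network in which each node is additionally
coupled to itself in adjacent layers with weight $\omega$. A joint partition
of all node-layer vertices is scored by

$$Q = \frac{1}{2\mu} \sum_{ijsr} \left[ \left(A_{ijs} - \gamma\,
\frac{k_{is} k_{js}}{2 m_s}\right)\delta_{sr} + \delta_{ij}\, C_{jsr}
\right] \delta(g_{is}, g_{jr}),$$

with the Newman–Girvan null per layer ($k_{is}$ node strength, $2m_s$ total
layer strength), ordinal-adjacent coupling $C_{jsr} = \omega$ for
$|s - r| = 1$, and $2\mu = \sum_s 2 m_s + 2\omega n (L-1)$. For a single
layer this is exactly weighted Newman–Girvan modularity at resolution
$\gamma$. A layer with zero total weight contributes no null term.
`optimize_partition()` maximises $Q$ with a generalized Louvain scheme:
seed-shuffled local-move sweeps over the supra graph alternate with
community aggregation until no move improves $Q$ by more than `tolerance`.
Because a community label is a property of the joint partition, a label
denotes the *same* community in every layer, which is what makes label
changes across layers meaningful.

**3. Switching rates.** From the node × layer label matrix,
$f_i = n_i / N$, where $n_i$ counts transitions at which node $i$'s label
changes and $N = L - 1$ is the maximum possible count. Louvain optimization
is stochastic, so the whole detection is repeated (default 100 times, each
repetition with a seed derived from the master seed) and rates are averaged
*at the rate level* — the partitions themselves are never merged, and no
consensus partition is built. Subnetwork and global summaries are unweighted
means over member nodes, matching the convention of averaging nodes rather
than weighting by subnetwork size.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `width` | 50 | volumes | window length; should exceed the period of the slowest retained frequency (50 × 2 s = 100 s vs. 1/0.01 Hz) |
| `step` | 1 | volumes | window increment |
| `trim_initial` | 10 | volumes | equilibration frames dropped |
| `gamma` | 1 | — | intra-layer resolution; larger favours smaller modules |
| `omega` | 1 | — | inter-layer coupling; larger favours temporally persistent labels |
| `n_repetitions` | 100 | — | stochastic repetitions averaged |
| `band` | 0.01–0.10 | Hz | pass band of synthetic latent signals and of `bandpass()` |

The $\gamma = \omega = 1$ defaults are the conventional defaults of
generalized-Louvain implementations for temporal networks; neither value is
identifiable from a single study, so both are exposed as arguments.
Ordinal-adjacent (rather than all-to-all) coupling is the standard choice
for temporal stacks and the only one implemented.

## Limit behavior

Two limits anchor the interpretation of $\omega$ and are asserted in the
test suite. As $\omega \to \infty$ the coupling term dominates and every
node keeps a single label across layers, so all switching rates are 0. At
$\omega = 0$ the layers decouple completely; community identity across
layers is then undefined, and the package makes this explicit by optimizing
each layer independently (under per-layer derived seeds, so one layer's
labels cannot depend on another layer's matrix) and assigning
layer-disjoint labels — every transition counts, and rates saturate at 1.
Between these extremes the mean switching rate is monotone non-increasing
in $\omega$ on fixed stacks.

## The synthetic generator

`planted_design()`/`generate_scan()` emulate the statistical structure the
pipeline consumes, not the physics that produces it. Each module has a
common band-limited Gaussian source (white noise masked in the frequency
domain); a node with schedule label $m$ at time $t$ observes
$\sqrt{c}\, s_m(t) + \sigma\, \varepsilon_i(t)$ with band-limited unit-variance
noise, so the expected within-module correlation is $c/(c + \sigma^2)$ —
available in closed form for tests, and equal to `within_module_corr`
exactly at the default $\sigma = \sqrt{1 - c}$. Switch events reassign
single nodes at given volumes; `planted_switch_rate()` converts the schedule
into ground-truth window-majority switching rates (window-majority ties go
to the smaller module id — with integer window widths a tie can only arise
at an event's half-window crossing, where either choice counts the same
single transition). Motion traces are small-amplitude random walks
(per-step SD 0.02 mm / 0.02°), enough to exercise the framewise-displacement
and QC code paths.

What the generator does *not* emulate: hemodynamics, spatially correlated
noise, scanner drift and artifacts, negative coupling between systems, and
the heavy-tailed motion of real participants. Passing recovery tests
therefore show that the chain *windowing → modularity → switching → stats*
is correct and well calibrated, not that it would behave identically on
real fMRI.

`generate_cohort()` layers a study design on top: two groups with the
conventional arm sizes 24/26, two scans per subject, covariates and
clinical scores drawn from the published group summary distributions, and a
configurable Spearman coupling between a score and the pre-scan global rate
(default 0.47 for the dependence score, the scale of the reported
association). Cohort outcome values are planted rates plus independent
Gaussian "measurement" noise (`rate_noise_sd`, default 0.01), standing in
for the estimation noise of a finite-repetition pipeline; without it a null
cohort would have literally zero paired variance. The post-scan adds
`Poisson(delta)` extra switch events on top of the pre-scan events, with
`delta` solved from the requested standardized paired effect against both
the Poisson and measurement-noise variance. Because events drawn too close
together on one node can merge into fewer majority flips, the realized
standardized effect runs some 15–20% below nominal at the event densities
used in the tests; the power checks pass with a wide margin regardless.

## Numerical choices

- Correlations are clipped to $|r| \le 1 - 10^{-7}$ before `atanh`, keeping
  weights finite for the modularity stage; zeroing negatives after the
  z-transform is equivalent to before (the transform preserves sign).
- A zero-variance window segment is a hard error naming the node and
  window, not a silent NA.
- Local moves accept the first-encountered strictly best gain, with the
  vertex sweep order seed-shuffled each sweep (neighbors are scanned in
  storage order). This keeps runs deterministic under a fixed seed while
  preserving genuine across-seed variability, which the repetition protocol
  requires. The per-sweep quality history is exposed and asserted
  nondecreasing.
- Module labels are canonicalized by order of first appearance (nodes
  within layer 1, then layer 2, …), so identical partitions produce
  identical files across runs.
- The supra representation stores per-layer dense blocks plus the two
  diagonal couplings per vertex (memory proportional to layer entries +
  couplings); the 160-node × 191-layer case (30,560 vertices) optimizes in
  a few seconds.
- A partial-correlation residual whose sum of squares is numerically zero
  relative to the input (the outcome lies exactly in the covariate span) is
  reported as $r = 0$ rather than as the correlation of rounding noise.
- All numeric file outputs are written with 12 significant digits so reruns
  are byte-identical.

## Statistical conventions

All p values are two-sided. The ANCOVA group effect is the nested-model F
(full: outcome ~ intercept + group + age + education + mean FD); with a
binary group the sums-of-squares type is immaterial. Spearman p values use
the t approximation, adequate at the n ≈ 24 sample sizes of interest, with
an exact option (delegated to `cor.test`) for small tie-free samples. The
summary-statistic t test exposes `variant = "pooled"`/`"welch"` explicitly
rather than silently pre-testing variances — published demographic tables
are internally consistent with pooled for some rows (depression score, age)
and Welch for others (anxiety score), and recomputation should make that
choice visible. FDR correction is applied within each family of outcomes
(the 6 subnetworks, or all nodes) separately per test type; the single
global outcome is reported unadjusted. Framewise displacement uses the
Power formulation (rotations converted to arc length on a 50 mm sphere),
with a flag for traces stored in radians; the motion QC rule fails a scan
whose realignment parameters exceed 2 mm translation or 2° rotation on any
axis.

## Validation design and problem sizes

The acceptance checks run at sizes chosen so the whole suite finishes in
minutes on one core: the structural contract runs one full 160-node ×
250-volume scan through connectivity and a single partition; oracle
equivalence uses random stacks up to 6 × 4 against a literal
quadruple-summation implementation of $Q$ (agreement to $10^{-12}$) and
exhaustive search over all set partitions on instances with ≤ 8 node-layer
vertices; calibration uses 10,000-replicate simulated nulls.

Planted-structure recovery uses a 20-node, 240-volume benchmark with graded
per-node event counts (0–5) spread across modules, each switching node
paired with its own target module and event times jittered. Two design
lessons are baked into this fixture. First, a rank correlation against
planted rates is only informative when planted rates *vary*: with a handful
of events most nodes tie at zero and the mid-rank correlation is bounded
well below 1 even under perfect recovery. Second, single-scan estimates
carry scan-specific structure — occasional merges of exchanging modules and
temporal fragmentation of a community's label chain — that repetition
averaging cannot remove; rates are therefore averaged over a 6-scan cohort
(25 repetitions each), after which node-level recovery is stable at
Spearman $\rho \approx 0.84$ across disjoint seed sets. The power check
runs 100 seeded replicate cohorts (25 subjects per group) at a standardized
planted effect of 0.8 and counts whole-sample paired-t detections at
p < 0.05.

## Known limitations

- Only single-aspect (temporal) multilayer networks: no subject × time
  multi-aspect coupling, no signed-modularity extension, and no consensus
  partitions.
- The node-to-subnetwork map is consumed as input; `synthetic_atlas()`
  ships a synthetic stand-in with the canonical six-subnetwork sizes, not
  an anatomical atlas.
- Nuisance regression, band-pass filtering and motion QC operate on
  node-level series and motion traces; no image-space preprocessing
  (slice timing, realignment, normalization) is performed or emulated.
- Greedy Louvain optimization guarantees a local optimum only; the
  exhaustive-equivalence tests cover tiny instances, and repetition
  averaging is the mitigation at scale, as in standard practice.
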
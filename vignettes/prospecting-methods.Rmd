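---
title: "Methods: novelty-guided exploration of reaction process spaces"
author: "ChemProspector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novelty-guided exploration of reaction process spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemProspector)
```

## The problem

High-throughput exploratory synthesis — for example, combinatorial
self-assembly of cluster metal carboxylates — produces one ESI mass
spectrum per reaction composition and temperature, and very little else
that scales. ChemProspector implements the digital half of a closed-loop
exploration of such a *process space* (the box of continuous reagent
amounts, as opposed to a discrete chemical space of ligand/metal
identities):

1. score every spectrum for **novelty** against the starting-material
   references;
2. fit a **Gaussian-process surrogate** of the novelty landscape and
   suggest the next batch of compositions by a confidence-bound
   acquisition (with Latin hypercube initialization and uniform-random
   baselines);
3. **deconvolute** the accumulated spectra into product-distribution
   *archetypes* by non-negative matrix factorization (NMF) of binary
   peak barcodes, and map each archetype back onto the process space by
   weighted kernel density estimation.

A synthetic ground-truth generator stands in for the robot and the
spectrometer, so the whole loop is testable on a desk.

## Peak identity

Peak lists are canonicalized on input (sorted by m/z, exact duplicate
rows merged by intensity sum — centroided exports sometimes split a
peak). Throughout the pipeline a peak *is* its unit-resolution bin:
m/z rounded half-up to the nearest integer. ESI spectra of the target
chemistry are matched at nominal resolution, and the downstream barcodes
are integer-indexed presence lists, so unit bins are the natural
identity; the instrument's true tolerance is not knowable from peak
lists alone, which is why the binning rule is a single small function
(`binPeaks()`) rather than an assumption spread through the code.

Noise is removed by a threshold *relative* to the base peak
(`applyNoiseThreshold()`, default 1%), making the operation invariant to
instrument intensity scaling.

`adductMz()` supports assignment checks with a bundled nominal-mass
element table (monoisotopic behind a flag): for example the methanol
adduct of a 2+ cobalt–anhydride core observed after one-electron
reduction,

```{r}
adductMz("Co(C4H6O3)2(C2H3O2)", coreCharge = 2, adducts = "+CH4O",
         electronTransfers = 1)
```

Electrons are treated as massless; each electron gained reduces the
charge by one and the m/z is total mass over |resulting charge|.

## The two-part novelty score

For each experiment spectrum, after thresholding:

* **Half (i) — top-peak divergence.** The five most intense binned peaks
  (ties broken toward lower m/z) are compared with each starting
  material's top five as sets:
  $d_s = 1 - |T_e \cap T_s| / \max(|T_e|, |T_s|)$, averaged over starting
  materials. The underlying definition — a "percentage difference"
  between top-peak lists — admits several arithmetics; the set-overlap
  form at matching resolution is the minimal one, all starting materials
  contribute symmetrically (mean, not min), and intensity-aware variants
  can be slotted in without touching the rest of the pipeline.
* **Half (ii) — inverse-frequency-weighted novel-peak count.** Every
  binned peak absent from the union of starting-material bins
  contributes $1/f_p$, where $f_p$ is the number of experiment spectra
  in the *entire accumulated dataset* (all iterations, all temperatures)
  containing that bin. A peak seen only once contributes exactly 1;
  commonly occurring peaks contribute less than rare ones. Because the
  counts span the whole dataset, scores must be recomputed from scratch
  each iteration — `scoreDataset()` always does.

Each half is min-max feature-scaled across all experiment spectra so the
two weigh evenly, then averaged; per composition, combined scores are
averaged over the temperatures present (a missing replicate triggers a
warning, not an error — failed runs should not sink a composition). A
constant half (no variation) is mapped to zero: it carries no
discriminating signal. The result is one score per composition in
[0, 1]; it is relative to the current dataset, not an absolute quantity.

## Exploration of the process space

All modelling happens on the unit hypercube (`toUnitCube()` /
`fromUnitCube()` round-trip to ~1e-16).

* **Initialization** is a Latin hypercube design (`lhsDesign()`, via the
  `lhs` package): for every dimension, exactly one of the $n$ points per
  equal-width bin. Default batch size 48 — one iteration of 48
  compositions, each run at three temperatures.
* **Surrogate.** `fitSurrogate()` fits a GP with an anisotropic
  Matérn-5/2 kernel plus a white-noise term by maximizing the log
  marginal likelihood (L-BFGS-B on log-parameters, 8 seeded restarts,
  1e-8 jitter). The 5/2 smoothness is the standard workhorse for
  experimental response surfaces — twice-differentiable but not
  infinitely smooth; per-dimension length scales suit heterogeneous
  reagent axes. A constant mean equal to the sample mean of the scores
  is used, so far from data the posterior reverts to it, with variance
  approaching the signal variance. The reported predictive variance is
  that of the latent function (observation noise excluded).
* **Acquisition.** The confidence bound $\mu(x) + \kappa\,\sigma(x)$ is
  maximized — novelty scores are maximized, so the bound is applied in
  the direction of higher novelty; the literal lower bound
  $\mu - \kappa\sigma$ (for minimization formulations of the same
  family) is available via `direction = "min"`. $\kappa = 0$ is pure
  exploitation; the default $\kappa = 2$ is a conventional
  middle ground, since no annealing schedule is prescribed by the
  underlying method.
* **Batches.** 48 simultaneous suggestions are built sequentially with
  constant-liar fantasy updates (`suggestBatch()`): each pick is
  temporarily assigned the *minimum* observed score and the posterior is
  recomputed under fixed hyperparameters, pushing later picks away from
  earlier ones. Acquisition maximization is multi-start L-BFGS-B over
  the cube with seeded starts (plus the best training point); exact
  duplicate picks are jittered apart, and optional per-dimension steps
  snap suggestions to a dispense grid.
* **Baseline.** `randomDesign()` draws i.i.d. uniform compositions.

Everything is deterministic for a fixed seed; campaign-level randomness
flows from one master seed through named substreams
(`substreamSeed()`), so designs, GP restarts, NMF initializations and
simulations can be reproduced independently.

## Archetype deconvolution

Per scope (by default each temperature), the non-starting-material
peaks of each experiment become a row of a binary **barcode matrix**
$B \in \{0,1\}^{m \times n}$ (columns: the sorted union of observed
bins; all-zero rows are kept, all-zero columns dropped). NMF then
approximates $B \approx W H$ with $W \ge 0$ ($m \times k$, experiment
loadings — the "feature matrix") and $H \ge 0$ ($k \times n$, archetype
fingerprints — the "coefficient matrix"). The solver is Frobenius
multiplicative updates from an NNDSVDa initialization (deterministic),
with seeded uniform restarts keeping the best fit; coefficient rows are
rescaled to unit maximum (feature columns compensated) so fingerprints
are comparable across models.

**Rank selection.** Ranks 2..m are screened (`screenRanks()`) and the
rank at which reconstruction error "becomes minimized" — the plateau
onset — is selected. Improvements are measured against the error at the
smallest screened rank, with a 5% default tolerance
(`selectRank(plateauTol = 0.05)`). The normalization matters: on binary
data every rank beyond the true structure can still absorb isolated
bit-level noise, so improvements relative to the *local* error stay at
several percent (and grow as the error shrinks) all the way to rank m,
which would defeat any local threshold and collapse the rule to
"largest rank". Against the curve's overall scale those late
improvements are negligible and the knee is stable; on noiseless
planted data the selected rank is exactly the planted rank, and with 2%
bit-flip noise it is within ±1 in all 20 seeded replicates the tests
run.

Interpretation helpers:

* `dominantArchetype()` — per experiment, the archetype with the
  largest share of the feature-matrix row sum (ties toward the lowest
  index; an all-zero row is flagged undefined rather than assigned).
* `matchArchetypes()` — pairs two models' fingerprints over the union
  of their peak columns by greedy best-first cosine similarity
  (exhaustive optimal assignment behind a flag, feasible to k = 8);
  pairs at cosine ≥ 0.8 count as shared discoveries. Used both to
  compare explorations and to score recovery of planted ground truth.
* `archetypeDensity()` — where in composition space an archetype lives:
  a Gaussian KDE of the experiment compositions weighted by that
  archetype's feature scores. Weights are normalized to sum to 1; the
  diagonal bandwidth follows Scott's rule on the weighted sample,
  $h_j = \sigma_{j,w}\, n_\mathrm{eff}^{-1/(d+4)}$ with Kish's
  effective sample size $n_\mathrm{eff} = 1/\sum w_i^2$; the map is
  normalized to integrate to 1 over its (regular) grid.

## The synthetic ground truth

`generateSpace()` plants latent product distributions as *disjoint*
integer fingerprints (6–12 peaks each, drawn outside the
starting-material bins), expressed inside smooth radial bumps of the
unit cube: $e(x) = e_{\max}\, t_T\, \exp(-\|x - c\|^2 / 2r^2)$, with a
per-temperature multiplier $t_T \in [0.7, 1]$ and responses below 1%
truncated to zero (far from its bump a product is absent, not merely
rare). `simulateSpectrum()` draws: starting-material peaks always
present with log-normal intensity jitter; each archetype's whole
fingerprint included with probability equal to its local expression,
then thinned by 5% per-peak dropout, intensities log-normal with scale
growing with expression; plus Poisson(2) spurious peaks at uniform m/z
with low intensity; and ±0.2 Th mass jitter everywhere so the binning
rule is actually exercised. Defaults mirror the intended field use: 6
dimensions, 48-composition iterations, three temperature labels.

Expression is probabilistic peak *inclusion* rather than intensity
modulation because the downstream barcodes are binary — the simulation
models what the pipeline consumes. What it deliberately does not model:
isotope patterns, adduct series, charge states, correlated
matrix/background chemistry, or reaction kinetics. Passing tests
therefore show the pipeline recovers planted combinatorial structure
under dropout/spurious-peak noise; they do not certify performance on
real spectra with correlated artifacts.

## The closed-loop benchmark

`closedLoopBenchmark()` runs score → suggest → simulate for each
strategy and replicate seed: iteration 1 is the same Latin hypercube for
every strategy; later batches come from GP optimization (`"gpbo"`) or
uniform sampling (`"random"`). Afterwards the accumulated spectra are
deconvoluted and recovered fingerprints matched against the planted
ones (cosine ≥ 0.8); the count of planted archetypes discovered is the
endpoint.

The benchmark ground truth (`cornerGroundTruth()`) is deliberately a
2-dimensional space with all archetype bumps (radius 0.12) concentrated
in the corner $[0.05, 0.30]^2$ — the smallest configuration in which
directed search has a concrete advantage to find: a uniform sampler
spends most of its budget outside the corner, while a novelty-guided
sampler should concentrate there after the first iteration. At the
documented scale (3 iterations × 24 compositions × 3 temperatures × 20
replicate seeds, rank screen capped at 12 since at most a handful of
archetypes are planted) the GP-directed runs recover on average more
planted archetypes than random sampling (3.9 vs 2.6 at one
representative master seed); with a single LHS-only iteration the two
strategies are identical by construction. These problem sizes are the
package's documented defaults for the benchmark; the same code runs at
any scale.

## Numerical choices, degenerate inputs, limitations

* GP: Cholesky throughout, 1e-8 jitter; length scales bounded in
  [0.02, 20] on the unit cube, noise variance in [1e-8, 1]; duplicate
  inputs with conflicting scores are absorbed by the noise term.
* Ties: top-peak selection prefers lower m/z; dominant-archetype ties
  prefer the lowest archetype index; both are deterministic.
* Degenerate feature scaling (constant half) maps to zeros; an empty
  novel-peak set scores 0 in half (ii); a frequency table that does not
  cover a queried bin raises a staleness error rather than guessing.
* Empty spectra are errors at construction time, not silent empties.
* The novelty score is dataset-relative: appending experiments changes
  earlier *scaled* scores (and half-(ii) weights), never half-(i) raw
  values. This is by design — "novel" means novel within the campaign.
* Greedy archetype matching can be suboptimal for near-degenerate
  fingerprint sets; the exhaustive assignment flag exists for small k.
* mzML input uses Bioconductor mzR when installed, with a built-in
  reader for uncompressed centroided files otherwise; profile-mode peak
  picking is out of scope.
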
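---
title: "Maximum-caliber behavioral signatures from cell-shape dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-caliber behavioral signatures from cell-shape dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcaliber)
```

# Overview

`cellcaliber` quantifies *how* a migrating cell changes shape, not just
*which* shapes it adopts. Two cells (or two experimental conditions) can
occupy identical regions of shape space while moving through that space in
completely different ways — persistently versus diffusively, with or
without coordination between shape modes. The package turns shape movies
into a 14-number behavioral signature built from a maximum-caliber
(dynamical maximum-entropy) model, and provides simulators, long-horizon
pattern statistics, and classifiers operating on those signatures.

The pipeline is:

1. binary mask → centroid-referenced contour → 64 boundary points equally
   spaced in arc length → Fourier power spectrum (rotation-, translation-
   and flip-invariant);
2. PCA over the spectra → two leading shape components per frame;
3. discretization of the two components into integer "particle numbers"
   `N1`, `N2` taking unit steps on a substep grid;
4. event extraction: per substep each component increases (+), decreases
   (−) or stays (0) — 9 joint cases;
5. observable rates: 4 simple event rates and 10 time-correlated
   adjacent-substep pair rates;
6. maximum-caliber inference of the 14 Lagrange multipliers matching those
   rates;
7. simulation, pattern statistics, and classification from the multipliers.

# The model

## Microtrajectories and path weights

Each shape component is modeled as a particle number `N`. In one substep it
can gain a particle (one microscopic realization), lose a particle (`N`
distinguishable realizations — first-order decay, which acts as a
restoring "virtual force" toward the mean), or stay. Over a 2-substep
window the number of microtrajectories of one component starting at `N` is
`N^2 + 3N + 5`, and the joint two-component count is the product
`(N1^2 + 3 N1 + 5)(N2^2 + 3 N2 + 5)`; `enumerate_paths()` lists them.

Maximum caliber assigns path `j` the probability

```
p_j = (1/Q) * multiplicity_j * exp( sum_n lambda_n S_nj )
```

where the `S_nj` count, per window, the four simple events and the ten
canonical adjacent-substep event pairs, and
`Q = sum_j multiplicity_j exp(sum_n lambda_n S_nj)` is the dynamical
partition function. Predicted observables are the derivatives
`d log Q / d lambda_n`; note the expected event counts always carry the
`1/Q` normalization (the raw derivatives of `Q` alone are not rates).
`partition_function_1c()` implements the one-component closed form and
`partition_function_2c()` the exact enumeration including cross-component
couplings; the two agree to machine precision, which the test suite checks
over thousands of random rate factors.

## Event taxonomy

Per substep, the joint event is one of 3 × 3 = 9 cases. Ordered
adjacent-substep pairs of simple events give 4 × 4 = 16 labels; the model
is symmetric under order reversal — the pair "(x α at t, y β at t+δt)" is
the same observable as "(y β at t, x α at t+δt)" — so they pool into 10
canonical keys. Canonically the component-1 event is written first:
`12pm` means *component 1 up paired with component 2 down* (in either
order), and `12mp` the reverse sign pattern; within one component `pm` and
`mp` collapse. Together with the 4 simple rates this yields the
14-multiplier signature (`event_taxonomy()`).

## Inference

`infer_multipliers()` solves the moment-matching conditions
`d log Q/d lambda = observed` by damped Newton iteration. The Jacobian is
the covariance matrix of the path counts under the current model (the
exponential-family identity), so the solve is exact up to line-search
damping and converges in a handful of iterations. Observables with an
observed rate of exactly zero have no finite maximum-likelihood multiplier;
they are pinned at `lambda_floor` (default −20, i.e. a rate factor of
~2e-9) with a warning and excluded from the root-finding.

# Discretization choices

Three free parameters control the mapping from continuous PC trajectories
to integer event streams; all are package choices, reported here so users
can adapt them:

* **`unit`** — shape-space distance per integer step. It sets the event
  resolution: too large and most substeps are null; too small and the
  per-substep unit-step condition fails. A value near the per-frame
  increment scale divided by the substep count is a good default.
* **`pc2_scale`** — fixed automatically as `sd(diff(pc1))/sd(diff(pc2))`,
  so both components take unit steps at comparable rates despite the
  variance ordering PCA imposes.
* **`n_offset`** (default ≥ 30) — the baseline added after rounding so
  states stay positive. The value matters: the decay multiplicity `N`
  enters the path weights, so `n_offset` sets the strength of the
  restoring virtual force relative to fluctuations. With fluctuations of a
  few units around the baseline, `N ≈ 30` keeps the relative fluctuation
  `sd(N)/mean(N)` small (~10%), so rates are approximately state-independent
  across the observed range — the regime in which a single multiplier set
  describes the whole trajectory. `discretize()` reports
  `rel_fluctuation` so this assumption can be checked.
* **`substeps_per_frame`** — chosen automatically from the ladder
  (1, 2, 4, 8, 16, 32) as the smallest count for which no interpolated
  substep changes a state by more than one unit. At a 3 s frame interval
  the typical choice of 16 substeps gives the substep duration
  `dt = 0.1875 s`.

**Interpolation caveat.** Linear interpolation makes within-frame motion
monotone, so *reversal* pairs (`11pm`, `22pm`) can only occur at frame
boundaries and their rates are attenuated relative to the underlying
dynamics. The fitted multipliers describe the observed (interpolated)
substep process — which is the right object for comparing conditions
measured the same way — but should not be read as frame-rate-independent
physical constants. The test suite verifies exact ground-truth recovery in
the regime with one substep per frame, where no interpolation occurs.

# Simulators

## Sequential maximum-caliber sampler

`simulate_maxcal()` draws trajectories with a lag-1 conditional law: the
probability of joint event `e` given the previous substep's joint event
`e'` is proportional to

```
multiplicity(e, N) * prod(simple gammas of e) * prod(coupling gammas e' -> e)
```

with `gamma = exp(lambda)`. For symmetric couplings this sampler satisfies
detailed balance consistent with the 2-substep window model, and
empirically the full inference loop (simulate → extract events → infer)
returns the generating multipliers to within Monte-Carlo error (≈ 0.04 at
10^6 substeps). In `"uncorrelated"` mode all couplings are set to 1,
producing the matched-rates null model. Decreases are disallowed at
`N = 1`, keeping states positive.

## Gillespie simulations

`gillespie_markov()` runs the continuous-time Markovian birth–death system
(constant birth propensity, death propensity proportional to `N`), binned
to the substep grid. The mapping from multipliers is `rate = gamma/dt`;
decrease gammas are already per-particle (the factor of `N` comes from the
path multiplicity), so no extra normalization is applied.
`gillespie_memory()` keeps 9 propensity sets indexed by the previous
substep's joint event (`memory_rates_from_multipliers()` builds them from
a multiplier set); with all nine sets identical it reduces *exactly* to
the Markovian model, which the tests check trajectory-by-trajectory.

This pair separates two explanations of single-cell anticorrelation
between shape components: the Markovian virtual force produces per-cell
correlations centered at zero, while the memory-conditioned rates shift
the per-cell correlation median away from zero (`percell_correlation()`).
Note the population-level PCA construction makes scores uncorrelated
*across* cells by design, so this signal exists only per cell.

# Long-horizon patterns and model comparison

`pattern_probability()` estimates the probability that a window of `T`
substeps contains at least `N` events of one type. Windows are sliding by
default and counting is "at least" — both are deliberate: sliding windows
use every start position (smallest variance for fixed data), and
"at least N in T" is monotone in `N`, making the pattern table robust to
rare extra events. Both choices are arguments (`windows = "disjoint"`,
`count = "exactly"`) rather than hard-coded. Probabilities are
per-window frequencies pooled over streams; windows never span stream
boundaries.

`compare_models()` evaluates the default grid (`T` from 10 to 20, `N` from
`T − 8` to `T`, all four event types), normalizes the data and model
pattern vectors, and scores each model by the Jensen-Shannon divergence
against the data. Trained on data with couplings, the correlated model
reproduces the long-horizon statistics an order of magnitude better than
the rate-matched uncorrelated model, even though both match the simple
rates — memory is the signal.

# Shape descriptors

The boundary is resampled to 64 complex points equally spaced in arc
length and Fourier transformed; the descriptor is the 64-vector of powers.
Rotations multiply coefficients by unit phases and start-point shifts add
phase ramps, so powers are invariant to both; traversal orientation is
canonicalized (counter-clockwise) inside `power_spectrum()`, which makes
the descriptor exactly invariant under mirror flips too. The
zero-frequency term is retained: boundary points are centered, so it is
numerically zero after centering and carries no nuisance information,
while dropping it would silently change the feature indexing. Spectra are
*not* normalized by default (`normalize = FALSE`), so cell size remains a
feature; pass `normalize = TRUE` for a scale-free descriptor.

PCA (`fit_shape_pca()`) is computed on the covariance (no per-feature
standardization — all 64 powers share units) with a fixed sign convention
so bootstrap and cross-condition comparisons are stable.

# Synthetic data: realism and limits

`generate_pc_trajectories()` produces PC trajectories from the package's
own discrete model (for recovery tests — circular by design),
`generate_ar1_trajectories()` produces mean-reverting VAR(1) data the
model did not generate (misspecification tests), and
`generate_blob_movie()` rasterizes `r(θ,t) = R(1 + e(t)cos 2θ +
l(t)cos 3θ)` so the full image pipeline can run end to end with a known
driving signal. Limits worth keeping in mind: blob movies are star-shaped
by construction (no pseudopod overhangs), observation noise is Gaussian
and frame-independent, and the two-condition dataset
(`make_two_condition_dataset()`) matches marginals only approximately at
finite sample sizes.

Problem sizes used in examples and tests (cells, frames, bootstrap
replicates, kNN group sizes) are package choices selected to run in
seconds on one CPU; they are arguments everywhere, not constants.

# Classification

`bootstrap_multipliers()` resamples cells (default 20% per replicate,
with replacement), refits the multipliers per replicate, and the resulting
per-condition distributions feed `compare_distributions()` (two-sample
Kolmogorov–Smirnov per multiplier) and
`select_discriminative_multipliers()` (mean difference over pooled
standard deviation, computed on training folds only).
`knn_vote_classify()` classifies groups of `n_repeats` samples by majority
vote of per-sample kNN labels, and `cross_validate()` enforces
cell-disjoint train/test splits, raising an error on leakage.

The headline contrast (`classify_two_conditions()`): with two conditions
that share marginal shape distributions but differ in cross-component
couplings, single-frame shape features classify at chance (~0.5) while two
bootstrap multipliers classify near-perfectly (> 0.9).

# Worked example

```{r example, eval = FALSE}
# ground truth with couplings, and its uncoupled twin
truth <- preset_multipliers("wt_like")

# simulate event streams, fit the signature back
ens <- simulate_maxcal(truth, sim_config(n_cells = 10, n_substeps = 1e5,
                                         seed = 1))
fit <- infer_multipliers(compute_observables(ensemble_events(ens)))
max(abs(as.numeric(fit) - as.numeric(truth)))   # ~0.03

# shape vs behavior classification
res <- classify_two_conditions(seed = 1)
res$accuracy
res$selected                                    # cross-component couplings
```
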
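# cellcaliber

Maximum-caliber behavioral signatures for migrating cells.

## What it does

Migrating amoeboid cells can adopt the same *shapes* while moving through
shape space in entirely different *ways* — persistently or diffusively,
with or without coordination between shape modes. `cellcaliber` quantifies
the *dynamics* of shape change, not just its statics:

1. **Shape descriptors** — binary masks are traced to centroid-referenced
   contours, resampled to 64 boundary points equally spaced in arc length,
   and Fourier transformed. The power spectrum is exactly invariant to
   translation, rotation, boundary start point and mirror flips.
2. **Shape space** — PCA over the spectra gives two leading shape
   components per frame.
3. **Event streams** — the two components are discretized into integer
   "particle numbers" taking unit steps on a substep grid (at the standard
   3 s frame interval and 16 substeps this gives a 0.1875 s substep). Each
   substep is one of 9 joint cases: each component goes up, down or stays.
4. **Behavioral signature** — a maximum-caliber (dynamical
   maximum-entropy) model over 2-substep microtrajectories is fitted to 14
   observed rates: 4 simple event rates plus 10 time-correlated
   adjacent-substep pair rates (16 ordered pair labels pooled under
   order-reversal symmetry). The 14 Lagrange multipliers are the
   signature. A decrease from state N has N microscopic realizations
   (first-order decay), so the model carries a built-in restoring force
   toward the mean — no ad hoc potential is fitted.
5. **Downstream** — sequential and Gillespie simulators (Markovian and
   9-memory-state), long-horizon pattern statistics with Jensen-Shannon
   model comparison, bootstrap multiplier distributions, and group-voted
   kNN classification with cell-disjoint cross-validation.

The punchline the package is built to demonstrate: two conditions with
matched shape distributions but different couplings are indistinguishable
to single-frame shape features (~50% classification accuracy) yet almost
perfectly separable by two behavioral multipliers (>95%).

## Worked example

Simulate event streams from a known coupled ground truth, fit the
signature back, and inspect the co-occurrence structure:

```r
library(cellcaliber)

truth <- preset_multipliers("wt_like")
ens   <- simulate_maxcal(truth, sim_config(n_cells = 10,
                                           n_substeps = 20000, seed = 1))
obs   <- compute_observables(ensemble_events(ens))
obs
#> observable set ( 199990 substeps; mean N = 30.53, 29.79 )
#> simple rates per substep:
#>      1p      1m      2p      2m
#> 0.12251 0.12254 0.12198 0.12203
#> correlated rates per window:
#>    11pp    11pm    11mm    22pp    22pm    22mm    12pp    12pm    12mp    12mm
#> 0.02217 0.00956 0.02196 0.02175 0.00949 0.02220 0.01557 0.06075 0.06059 0.01567

fit <- infer_multipliers(obs)
max(abs(as.numeric(fit) - as.numeric(truth)))
#> [1] 0.04536519

round(cooccurrence_matrix(ensemble_events(ens)), 2)
#>      1p   1m   2p   2m
#> 1p 1.48 0.32 0.52 2.03
#> 1m 0.32 1.46 2.03 0.52
#> 2p 0.52 2.03 1.46 0.32
#> 2m 2.03 0.52 0.32 1.49
```

The co-occurrence matrix (observed pair frequency over the product of
marginal rates; 1 = independence) shows exactly the planted structure:
up-in-one/down-in-the-other pairs are enhanced two-fold, reversals within
a component suppressed three-fold.

Shape features versus behavioral signatures on a matched-marginal
two-condition dataset:

```r
res <- classify_two_conditions(seed = 1)
res$accuracy
#>  feature_space n_repeats accuracy
#>      shape_pcs         1    0.510
#>      shape_pcs         3    0.455
#>      shape_pcs         5    0.430
#>    multipliers         1    0.990
#>    multipliers         3    1.000
#>    multipliers         5    1.000
res$selected
#> [1] "l12pp" "l12pm"
```

The feature selection (run on training folds only) picks out
cross-component couplings — the only thing that differs between the two
generating conditions.

## Command line

A thin wrapper over the stage functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cellcaliber.R", package = "cellcaliber"))')" \
    synth --seed 1 --out runs/synth
```

Stages (`synth`, `pca`, `events`, `fit`, `simulate`, `patterns`,
`classify`) communicate only via files and each writes a
`provenance.json`; see `?run_stage`.

## Documentation

See the methods vignette (`vignettes/behavioral-signatures.Rmd`) for the
model, the discretization free parameters (`unit`, `n_offset`, the substep
ladder), sampler and Gillespie design, the interpolation caveat on
reversal-pair rates, and the rationale behind the pattern-statistics and
classification choices.
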
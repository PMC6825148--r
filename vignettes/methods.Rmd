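---
title: "Identifying time-invariant working-memory subspaces in morphing population codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying time-invariant working-memory subspaces in morphing population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphspace)
```

## The scientific problem

During a delayed-saccade task with an intervening distractor, prefrontal
population activity maintains the remembered target location across two
delay periods — yet the *code* changes between them: a linear decoder
trained on Delay-1 activity generalizes poorly to Delay 2 ("code-morphing"),
even though the monkey's memory is intact. This poses a readout puzzle: how
can downstream circuits extract stable memory information from a morphing
code? The resolution explored by this package is that a low-dimensional
linear subspace of the population state space carries time-invariant memory
information, and that this subspace can be found by direct optimization.

`morphspace` implements the complete analysis as a reproducible pipeline:
two recurrent network models that generate trial-structured population
activity with code-morphing, the preprocessing that turns trials into a
z-scored pseudo-population and a PCA "full space", the subspace
optimization, cross-temporal discriminant decoding with LP summary
statistics, state-space cluster-shift and trajectory-parallelism (PLV)
statistics, bootstrap-overlap inference with Hedges' g, and a
location-by-epoch ANOVA classification of units into classical (CS), linear
mixed (LMS) and non-linear mixed (NMS) selectivity.

## Task structure and data containers

A trial is `task_timeline()`: 300 ms baseline, 300 ms target, 1000 ms
Delay 1, 300 ms distractor, 1000 ms Delay 2, simulated in 50 ms steps so
that every analysis window maps to an integer number of bins (all window
arithmetic is half-open `[start, end)`). Simulated activity lives in a
`population_tensor` — `neurons x bins x trials` with a per-trial condition
table — which then flows through `bin_rates()` (100 ms windows, 50 ms
steps), `zscore_baseline()` (per-neuron baseline z-scoring with a 1e-6 sd
floor; silent units are flagged, not dropped), and
`build_pseudopopulation()` (per-neuron independent trial resampling within
each target location, deliberately discarding cross-neuron noise
correlations, as in standard pseudo-population decoding).

## The bump-attractor generator

The primary generator (`simulate_bump_attractor`) is a ring network of
`N = 80` rate units with discrete-time dynamics

$$r_{t+1} = \varphi(W_{rec}\, r_t + W_{in} I_t + \sigma_t),$$

where the activation is piecewise — 0 below zero, \(x^2\) on \([0,1]\),
\(\sqrt{4x-3}\) above 1 — and \(\sigma_t\) is i.i.d. Gaussian with sd 0.1
per unit and step. \(W_{rec}\) has local excitation (+0.25 within 2 ring
steps, including self) and uniform weak inhibition (−0.012) elsewhere. Each
of the 8 target locations drives a block of 10 adjacent units; the
distractor drives its block at 0.2 of the target amplitude; and a fixed,
randomly placed set of `n = 10` "non-memory" units receives input of
strength `s = 5` during the distractor window regardless of distractor
position. With these weights a target-evoked bump persists through both
delays, while the non-memory input ignites additional bumps that persist
into Delay 2 — which is what morphs the code. Because the excitation and
inhibition magnitudes are not dictated by the model equations, they were
calibrated once against two explicit contracts (checked by
`check_bump_calibration()`): noise alone must never drive any unit above
10% of the single-bump peak over a full trial, and the bump's block-mean
rate at the end of Delay 2 must retain at least half of its end-of-Delay-1
value even under the non-memory barrage.

Two choices deserve emphasis:

* **Time step.** The discrete-time equations carry no intrinsic step
  duration; we use 50 ms per step so simulation steps align exactly with
  the 50 ms analysis grid (58 steps from −300 to 2600 ms).

* **Encoding jitter** (`input_jitter_sd`, default 2 ring units). Each
  trial's target and distractor input blocks are shifted by a seeded random
  integer offset. This emulates the trial-to-trial bump-position
  variability (diffusion) that continuous-attractor memory networks
  exhibit and that the discretized, box-profile ring otherwise suppresses.
  It is the generator's main source of realistic within-condition
  variability: without it, simulated trials of a condition are nearly
  identical, decoding sits at a degenerate ceiling where outcomes flip on
  machine-precision margins, and the 90%-variance full space collapses to
  the 7 location dimensions, leaving no room for an 8-dimensional
  subspace. With jitter the full space has 16–19 components under the
  default conditions and the decoder operates in the graceful,
  noise-limited regime that recorded data occupy.

The comparison generator (`simulate_linear_model`) uses the same task and
input schedule but linear dynamics with \(W_{rec} = Q \Lambda Q^{-1}\):
nine eigenvalues fixed at exactly 1 (eight target channels plus one
non-memory channel, each input delivered along its own stable eigenvector)
and the rest drawn uniformly from (0, 1), so everything off the stable
eigenvectors decays geometrically. Its non-memory input is a single shared
direction, so it translates the state identically for every target — the
property that makes its morphing linear-mixed rather than non-linear-mixed
at the single-unit level. Its rates are unbounded (and can be negative).

`simulate_scenario()` adds the task variants: degraded-encoding error
trials (target amplitude scaled by a degradation factor, optional extra
noise — an assumption of this package, since error aetiology is not part of
the generative model), two-distractor timelines with stimulus-triggered or
proximity-triggered non-memory input, and parameter sweeps over the
distractor level and the (n, s) non-memory grid.

## The full space and the delay matrices

PCA is fit on all (pseudo-trial, bin) samples between 800 and 2500 ms after
target onset, keeping the smallest number of components reaching 90%
variance. Each pseudo-trial's activity, averaged over the last 500 ms of
Delay 1 (`D1`, 800–1300 ms) or the matched Delay-2 window (`D2`,
1800–2300 ms) and projected onto those components, becomes one column of
the delay matrices (7 locations × 50 responses = 350 columns). The
mean-subtracted variants `D1_av`, `D2_av` subtract each delay's mean
column, so their Frobenius norm measures between-location (memory)
structure. One documented wrinkle: the task ends at 2600 ms while the PCA
window ends at 2500 ms and the decoding window at 2300 ms; all three are
independent configuration values rather than a single "end of Delay 2".

## The subspace optimization

The subspace map `U` (`u_dim x n_components`, default `u_dim = 8`)
minimizes

$$\|U(D_1 - D_2)\|_F \;-\; \frac{\beta}{2}\left(\|U D_1^{av}\|_F +
\|U D_2^{av}\|_F\right), \qquad \beta = 0.1 .$$

This objective is positively homogeneous of degree 1
(`cost(cU) = c·cost(U)`), which makes the raw problem scale-degenerate:
depending on the data it is either minimized at `U = 0` or unbounded below
along any ray where the information terms outweigh the morph term.
`optimize_subspace()` therefore offers two modes:

* `constraint = "none"` reproduces the original unconstrained formulation
  (quasi-Newton BFGS with the analytic Frobenius-norm gradient, seeded
  uniform \([-0.5, 0.5]\) initialization, iteration cap, multi-start;
  candidates whose norm leaves \([0.1, 10]\times\) the initial norm are
  flagged as non-converged). On the bump-generator data this mode
  *collapses toward `U = 0`* — the paired-column differences contain
  irreducible within-cluster noise in every direction, so no negative ray
  exists — and the effective solution degenerates toward rank 1. We keep
  the mode because it documents this behaviour and because it behaves
  correctly on data that do contain an information-rich, morph-free ray.

* `constraint = "orthonormal"` (the pipeline default) optimizes over
  matrices with orthonormal rows — projected gradient descent on the
  Stiefel manifold with QR retraction and backtracking line search. This
  removes the scale degeneracy and cannot rank-collapse. (A simpler
  per-row normalization was tried and rejected: with no cross-row
  coupling, every row converges to the same single best direction,
  yielding a rank-1 "subspace".)

`run_pipeline()` additionally caps `u_dim` at half the fitted full-space
dimensionality: a time-invariant subspace must exclude the morph
directions, and those occupy a sizeable fraction of a low-dimensional full
space. Under the default study conditions the cap is inactive
(`u_dim = 8` of 16–19 components). The dimension sweep 8/9/10 changes none
of the qualitative results.

Derived objects: `null_space_basis()` (orthonormal basis of the directions
`U` annihilates, via the QR-based null space of `t(U)`),
`neuron_contributions()` (|U × loadings|, normalized by the largest weight,
averaged per neuron), `subspace_variance_curve()` (PCA of the concatenated
projected delay matrices), and two baseline subspaces
(`baseline_subspace()`): the "mnemonic subspace" (PCA of time-averaged
per-condition delay activity) and LDA discriminant axes — both limited to
`n_locations − 1` axes.

## Decoding and LP statistics

`cross_temporal_decode()` trains a linear discriminant on every training
bin and tests on every testing bin over stratified 80/20 pseudo-trial
resamples (default 200). The discriminant is a pooled-within-class
covariance classifier written in this package, with shrinkage toward a
scaled identity engaged automatically when the training count is below
five times the dimension (`lambda = p/2n`), ties broken deterministically
by lowest class index; the reference implementation in MASS serves as a
cross-check in the tests, not as the decoder. LP statistics average the
cross-temporal cells with train and test bins inside the Delay-1/Delay-2
windows: `lp11`, `lp12`, `lp22`, `lp21`, with the paired differences
`lp11 − lp12` and `lp22 − lp21` quantifying morphing. In the bump model the
morph is asymmetric: `lp11 − lp12` is large and positive while
`lp22 − lp21` sits near zero, because the non-memory bumps present in
Delay 2 are simply absent in Delay 1, so Delay-2-trained boundaries still
separate Delay-1 activity.

Error-trial analysis (`error_trial_performance()`) trains on correct
pseudo-trials and tests on held-out correct and on error pseudo-trials in
the full space, the subspace and its null space, restricted to locations
with at least six error trials in every session
(`filter_error_locations()`); chance is stated per analysis (1/7 main,
1/|locations| for errors).

## State-space statistics

`cluster_shift_stats()` bootstraps (default 1000 resamples, trials redrawn
with replacement within location): the mean distance between corresponding
Delay-1/Delay-2 cluster centers (inter-delay), the Delay-1-to-distractor
shift, and an intra-delay drift control — the distance between the centers
of the *first and last 250 ms of each full 1000 ms delay epoch*. Reading
the drift control on the full delay period matters: it spans ~750 ms,
commensurate with the inter-delay separation, so slow settling drift
contributes comparably to both statistics; computed on 250 ms halves of
the 500 ms analysis windows instead, the control spans only ~250 ms and
even a morph-free simulation shows a spuriously "significant" inter-delay
excess. All shifts are normalized by the mean intra-cluster
(member-to-centroid) distance over all 14 clusters, making them invariant
to global scaling; member-to-centroid (rather than mean pairwise) distance
was chosen to match the units of a center shift.

`trajectory_plv()` takes the per-location Delay-1→Delay-2 displacement
vectors, normalizes each to unit length (required for the stated [0, 1]
range), and returns the magnitude of their mean — 1 for perfectly parallel
displacement, 0 for complete cancellation. `plv_bootstrap()` gives its
bootstrap distribution. In the pipeline the true-versus-shuffled PLV
comparison is computed on **full-space** projections: the parallelism being
tested is a property of the data's displacement field, and the optimized
subspace *removes* those displacements nearly completely on model data, so
inside it only unstructured drift residuals remain (the subspace-projected
PLVs are reported as additional fields for completeness).

## Inference and selectivity

`bootstrap_p()` compares two paired bootstrap distributions: `X` counts
paired differences whose sign opposes the median difference (zeros count as
overlap), `p = (1 + X)/(N + 1)` — so disjoint distributions give
`p = 1/1001 < 0.001` at `N = 1000` and x% sign-crossings give ~x/100 — and
significance is additionally reported as non-overlap of the two [2.5th,
97.5th] percentile intervals, with Hedges' g attached
(`hedges_g()`: bias-corrected standardized mean difference with pooled sd).
The paired sign-crossing reading of "overlap" matches the printed
calibration; an unpaired range-overlap count is available behind
`method = "range"`. No multiple-comparison correction is applied across
contrasts, mirroring the source analysis.

`classify_selectivity()` runs, per unit, a two-way ANOVA on per-trial mean
activity with factors location and epoch (Delay 1 vs Delay 2) including
their interaction (`stats::lm` type-I sums of squares — the synthetic
designs are balanced, where all types coincide; α = 0.05): a significant
interaction gives NMS; otherwise two main effects give LMS, exactly one
gives CS. The bump attractor with non-memory input yields predominantly
NMS units (the saturating nonlinearity makes the Delay-2 change
location-dependent), while the linear model yields predominantly LMS units
(its single non-memory direction translates every location identically) —
the dissociation that favours the bump attractor as a model of the data.

## The shuffled-label control: an honest caveat

Shuffling the Delay-2 location labels (derangement-preferred, seeded;
`shuffle_delay2_labels()` on matrices, `shuffle_delay2_trials()` on
tensors) and re-running the optimization is meant to show that a
time-invariant readout cannot be manufactured from arbitrarily paired
data. On this package's synthetic data the control behaves differently
from the recorded-data result, and we report that plainly rather than hide
it: linearly mapping each location's shuffled Delay-2 cluster onto its
paired Delay-1 cluster while preserving location information is
geometrically feasible whenever `u_dim ≤ n_components − n_locations`, and
the orthonormal-mode optimizer *finds* that alignment (shuffled-subspace
`lp11 − lp12` straddles zero at some seeds). The same degrees-of-freedom
condition governs excluding the true morph, so a generator whose morph
occupies ~`n_locations` directions cannot simultaneously make the rescue
easy and the alignment impossible. The unconstrained mode, faithful to the
original formulation, fails to find the alignment (it collapses instead)
and thereby reproduces the published negative result — but using the
weaker optimizer only for the control would be methodologically
indefensible, so the pipeline runs the same optimizer on true and shuffled
data and the corresponding acceptance check is expected to fail on model
data. The trajectory-parallelism side of the control is unaffected: true
displacements are far more parallel than shuffled ones, with disjoint 95%
bootstrap intervals.

## Problem sizes, determinism, degenerate inputs

The packaged study conditions are 80 units, 20 trials per
(target, distractor) condition, 7 analyzed locations × 50 pseudo-responses,
200 decoding resamples and 200 bootstrap resamples — sizes chosen so a full
pipeline run completes in a few minutes on one core while every
distributional statistic retains enough resolution for 95% intervals
(unit tests use smaller sizes still). All randomness flows from a single
master seed through a documented per-stage derivation
(`stage * 101 + seed` arithmetic, kept below 2^31), so any stage can be
re-run in isolation and a rerun of `run_pipeline()` is byte-identical.
Degenerate inputs are contracts, not surprises: silent neurons are
sd-floored and flagged, rank-deficient subspace maps enlarge the null
space with a warning, zero displacement vectors are skipped in the PLV
with a warning, empty error-location sets return an explicit status, and
an all-zero contribution matrix is an error.

## What passing tests do and do not show

The generator reproduces the phenomenon's structure — delay-selective
persistent activity, distractor-triggered non-memory input, code-morphing
confined to Delay 2, NMS-dominated mixing, and a recoverable
time-invariant subspace — but it is not a surrogate for cortical
recordings: it has no spiking variability or cross-neuron noise
correlations (the pseudo-population construction would discard the latter
anyway), its units are homogeneous and its code is ring-symmetric, its
trial-to-trial variability is a single encoding-jitter mechanism, and its
decoding ceilings are higher than those of recorded populations. Passing
tests therefore validate the analysis machinery and the model-level
claims, not the empirical magnitudes of the original recordings, whose
headline numbers (58 components for 244 neurons, ~70% decoding) are
properties of data this package cannot regenerate.
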
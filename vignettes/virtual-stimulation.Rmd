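---
title: "Virtual inhibition in a whole-brain oscillator network: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual inhibition in a whole-brain oscillator network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`kuranet` simulates slow resting-state brain dynamics as a network of
Kuramoto phase oscillators coupled through a structural connectome. Each
region $i$ carries a phase $\theta_i(t)$ evolving as

$$\frac{d\theta_i}{dt} = \Omega_i + \lambda \sum_j W_{ji}\,
\sin(\theta_j - \theta_i),$$

where $W$ is the normalized anatomical weight matrix, $\lambda$ a global
coupling strength, and $\Omega_i$ the angular natural frequency. The model
deliberately abstracts away biophysical detail: what it keeps is the
competition between each region's intrinsic timescale and the pull of its
anatomical neighbourhood, which is the mechanism under study.

The intrinsic timescales follow a strength-dependent hierarchy. With node
strength $s_i = \sum_j W_{ji}$,

$$\omega_i = b - (b - a)\left(\frac{s_i - s_{min}}{s_{max} -
s_{min}}\right)^{2},$$

with defaults $a = 0.01$ Hz, $b = 0.1$ Hz and exponent 2. Strongly
connected hubs (frontal-eye-field-like nodes) therefore fluctuate slowly,
weakly connected sensory nodes (early-visual-like) fast, and the exponent
concentrates most of the network near the fast bound, which gives the
characteristic right-shifted frequency distribution. All three parameters
are exposed via `timescale_params()` because the exponent in particular is
a tuned quantity, not a derived one. The mapping depends only on the
relative position of each strength between the network extremes, so it is
invariant to how the connectome was scaled — which is why the package does
not need to take a position on whether strengths are computed before or
after normalization.

Local inhibitory stimulation (the "virtual TMS" of the experiment
framework) is modelled as a reduction $\Delta\omega$ of one region's
natural frequency, the model analog of the empirical observation that
inhibitory stimulation reduces local low-frequency signal power.

## Angular convention

The mapping above produces frequencies in Hz. The integrator's default
`"two-pi"` convention sets $\Omega_i = 2\pi\omega_i$, so that simulated
oscillations occur at the stated frequencies in Hz and the 0.01–0.1 Hz
band has its physical meaning for the sampled observables. A `"literal"`
mode uses the Hz values directly as angular velocities for users who want
the equation exactly as often written. The two conventions rescale time in
the coupling term, so $\lambda$ is never transferable between them — it is
a calibrated quantity in either case (see below), and conclusions are
convention-robust once calibration is redone.

## Observables and metrics

The simulator records unwrapped phases after discarding a transient
(defaults: 8-minute runs, 2.12 minutes discarded) and samples every
2.25 s, a typical fMRI repetition time, so that correlation-based
functional connectivity is computed on comparably sampled series. The
BOLD proxy is $\sin\theta_i$; the alternative (instantaneous phase
coherence) is deliberately not used because the downstream statistics are
defined on Pearson correlations of signal time courses. Functional
connectivity is the Pearson correlation matrix (`fc_matrix()`), seed maps
are rows of it (`seed_fc()`), and averages across trials are taken on
Fisher-z values by default; a `"raw"` switch exists because the choice is
not settled usage. Inside simulation pipelines z-values are clamped at
$|r| = 1 - 10^{-7}$: two fully locked oscillators can reach $|r| = 1$ to
machine precision, and an infinite z would poison trial averages.

ALFF (`alff()`) is the mean of the one-sided amplitude spectrum over the
DFT bins inside 0.01–0.1 Hz, computed on mean-centred series with no
further detrending — simulated and synthetic signals are stationary, so
detrending would only complicate the estimator's linearity.

The paired signed-rank test (`paired_rank_test()`) computes its null
exactly — by convolution over all $2^n$ sign assignments, equivalent to
enumeration — whenever at most 25 non-zero pairs remain, and switches to a
continuity-corrected normal approximation with an Edgeworth
fourth-cumulant term above that. The correction matters: at $n = 15$ the
plain corrected-normal tail can err by more than 0.005 in the mid-range,
while the Edgeworth term keeps the error below about $10^{-3}$. Zero
differences are dropped; ties get midranks, under which the cumulant
formulas remain valid because they are computed from the realized ranks.

## The synthetic study conditions

The empirical 513-region tractography connectome behind the original
analysis is not redistributable, so the package carries a generator
(`generate_connectome()`) whose output reproduces the features the model
actually consumes: a symmetric, non-negative, connected weight matrix
with a heavy-tailed strength distribution, an identifiable top-strength
hub and a low-strength sensory node. It is a stochastic block model
(4 modules, 128 regions by default; 513 is reachable through the spec)
with log-normal edge weights, a hub whose connection probabilities are
boosted network-wide, and a sensory node whose probabilities and weights
are damped. Intra- and inter-module connection probabilities (0.6 / 0.3)
were chosen to give an edge density near 0.38, comfortably above the 30%
used by `sparsify()`, so the sparsification robustness check removes real
edges. What the generator does *not* emulate: anatomical geometry beyond
disjoint module clusters, the empirical degree sequence, and distance-
dependent connection probabilities. Tests passing on this ensemble show
that the mechanism operates under the assumed strength hierarchy; they do
not certify the empirical parcellation.

Module coordinates place module centres on a 70 mm sphere with ±15 mm
jitter; `distance_correct()` divides weights by Euclidean centroid
distance as a documented proxy for fiber distance, which is unavailable
without tractography.

## Calibration and the operating regime

The coupling $\lambda$ is not a free lever but a calibrated quantity:
`calibrate_lambda()` scores each candidate by the correlation between
simulated and reference seed-FC vectors of the designated targets and
picks the maximizer, mirroring the original procedure of matching baseline
connectivity before running perturbations. In the synthetic setting the
reference is model-generated (`generate_reference_fc()`) at
$\lambda_{true} = 0.16$, a value fixed once after a coherence scan of the
default connectome: it is the regime where the network is coherent enough
for a perturbed node's alignment with the bulk rhythm to show in FC
(time-averaged order parameter above 0.95) while both designated targets
retain frequency-dependent sensitivity. Calibration-recovery is itself a
test: calibrating against the reference with independent trial seeds must
return $\lambda_{true}$ within one grid step on
$\{0.04, 0.08, 0.12, 0.16, 0.24\}$.

The connectome transforms change the total coupling scale — distance
correction in particular divides most weights by tens of millimetres, so
at fixed $\lambda$ the transformed network can fall out of coherence
entirely. The robustness experiments therefore re-select $\lambda$ per
variant by a deterministic coherence-matching rule: the smallest value on
$\{0.16, 0.24, 0.32, 0.5, 0.8\}$ whose mean order parameter reaches the
0.95 operating coherence of the calibrated original. This is the
package's stand-in for re-running the full calibration on each variant.

## The paired experiment design

`run_trial_pair()` runs baseline and perturbed simulations from identical
initial phases drawn from the trial seed. Pairing maximizes power and
makes the $\Delta\omega = 0$ null *identically* zero — a property the
tests assert bitwise. Trial seeds are `base_seed + trial`, so results are
independent of execution order and reproducible in parallel.
`sweep_delta_omega()` reuses each trial's baseline across the
$\Delta\omega$ grid (same seed, same baseline — mathematically identical
to independent pairs, at half the cost) over a default grid of 12
log-spaced reductions from $10^{-5}$ to $10^{-2}$ Hz, with 100 trials by
default (500, as in the original protocol, is reachable through the
arguments).

A consequence of determinism worth understanding: every systematic
perturbation effect, however small, has the same sign in every trial, so
the signed-rank test saturates at its minimal p-value even for
physically negligible spillover (for example, inhibiting a control site
shifts the sensory–hub edge by about $10^{-3}$ z against a direct effect
of about 0.6 z, yet the test rejects). The control-site analysis
(`control_site_experiment()`) therefore reports effect sizes, and "the
edge is not modulated" is an effect-size statement — spillover below 5%
of the direct effect — not a p-value one. With stochastic inputs
(empirical data), the p-value reading would be the appropriate one.

## Numerical choices

* **Integrator**: Heun (2nd order), $dt = 0.05$ s — 200 steps per cycle
  of the fastest (0.1 Hz) oscillator. A step-halving test bounds the
  sampled-phase change at $10^{-3}$ rad. Euler is available for
  comparison. Divergence (non-finite phases) raises an error suggesting a
  smaller step.
* **Transient**: discarded before sampling, so statistics reflect the
  stationary regime; two-oscillator locking analysis uses longer
  transients because the locking relaxation time at small coupling
  exceeds the whole-network default.
* **Tie-breaks**: `sparsify()` orders edges by weight, then
  lexicographically by index, making surviving edge sets deterministic
  and nested across densities; `peak_delta()` and `calibrate_lambda()`
  resolve ties toward the smaller grid value.
* **Degenerate inputs**: all-equal strengths (undefined gradient),
  all-zero connectomes, constant time series, zero-variance references
  and out-of-band ALFF requests raise distinct errors naming the
  offending entity rather than propagating NaNs.

## Problem sizes used in the tests

The full-scale test experiments use the default 128-region connectome
with 100 paired trials per grid point for the sweeps, 12 reference and 8
calibration trials per coupling for recovery, and 100 trials per variant
for robustness; unit tests run 16-region toys. Direction-of-effect
conclusions are asserted at 95% bootstrap confidence over trial means.

## Known limitations

* The model is deterministic given initial phases; trial-to-trial
  variability comes from initial conditions only, which understates
  empirical variability and (see above) changes the meaning of p-values.
* The BOLD proxy omits hemodynamic convolution; FC magnitudes are not
  comparable to empirical values, only their perturbation-induced
  *changes* are interpreted.
* The synthetic ensemble pins the hub at the exact strength maximum, so
  its natural frequency sits at the slow bound $a$ exactly; empirical
  hubs are slower than average without being extremal.
* Printed empirical quantities tied to the unavailable tractography
  matrix (per-region frequencies of named anatomical areas, model-to-data
  fit correlations) are out of reach by construction and are not
  reproduced anywhere in the package.
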
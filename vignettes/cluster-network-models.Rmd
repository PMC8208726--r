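---
title: "Cluster-based network models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based network models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `cnmr`, the assumptions it
rests on, the tunable parameters and their defaults, the synthetic benchmark
generators, and the numerical choices made where the design was genuinely
open. It is the place to look when a result surprises you.

## The model and its assumptions

The method represents a nonlinear dynamical system by a directed network whose
nodes are coarse-grained states and whose edges carry data-inferred transition
probabilities and transition times.

**Coarse-graining.** Given M snapshots `x(t_m) ∈ R^N` at fixed spacing Δt,
k-means++ partitions them into K clusters; centroid `c_k` is the mean of the
states in cluster k and minimizing the inner-cluster variance is the only
optimality notion used. The state of the model is "which centroid", so spatial
resolution is set entirely by K. For high-dimensional snapshots the
decomposition `u = u0 + Σ a_i Φ_i` (snapshot POD, `compute_pod()`) is applied
first; it is lossless when all modes are kept, and because the mode basis is
orthonormal, Euclidean distances between coefficient vectors equal distances
between snapshots, so clustering coefficients gives the identical result at a
fraction of the cost. We use plain Euclidean distances throughout
(point-sampled states); grid-quadrature-weighted inner products are out of
scope.

**Transition structure.** The per-snapshot labels are run-length encoded into
the *visit sequence*: consecutive visits always differ, and visit n has a
residence time τ^n (run length × Δt, i.e. entry and exit resolved to the
sampling grid — no sub-grid interpolation). An order-L chain on visits is
estimated by counting every length-(L+1) window: the first L visits are the
history h, the last is the successor k, and

    Q(k | h) = n_{k,h} / n_h .

Self-loops are impossible by construction. Each window carries an individual
transition time τ = (τ^{n−1} + τ^n)/2 — half the residence of the departed
cluster plus half that of the entered one — and T(k | h) is the mean of those
times over the n_{k,h} windows, conditioned on the *full* history (not only
the last pair), since the transit duration genuinely depends on where the
trajectory came from. Only observed (history, successor) pairs are stored, as
a keyed lookup table; the dense tensors would have K^(L+1) entries.

Boundary handling: the first L visits only seed histories (windows are never
padded — padding would fabricate unobserved states), and the first and last
residence times are the recorded run lengths even though the true entry/exit
of the record is censored. The resulting edge bias is O(1/I) and ignored.

**Propagation.** A model trajectory is a chain of constant-velocity flights
`x(t) = α c_k + (1 − α) c_j` with `α = (t − t_j)/T_{k,j}`. Successors are
sampled by inverse-CDF over the stored successor list in ascending cluster
index, which makes trajectories bit-reproducible for a given seed across
platforms. Optional spline interpolation (natural cubic through the waypoints)
is available for smoother curves; it still passes through every centroid at
its arrival time.

**What the model cannot do.** It never extrapolates: every model state is a
convex combination of two observed centroids, so amplitudes outside the
training data are unreachable. It has no notion of linear growth rates or
instabilities. Noise in the training data is faithfully mirrored in the model
statistics — the method cannot separate noise from dynamics. And it needs
statistically converged training data: every relevant region of phase space
must be visited enough times that the window counts estimate probabilities.

## Tunable parameters

* **K (clusters).** Sets spatial resolution; more clusters resolve finer
  structures but thin out the per-history statistics. The chaotic Lorenz
  benchmark uses K = 50 (each attractor lobe resolved by about two rings of
  centroids).
* **L (chain order).** The memory of the symbolic dynamics, equivalent to
  time-delay embedding of the visit sequence. Its physical scale is the
  *normalized time delay* t_L/T_0 (`normalized_time_delay()`), where t_L is L
  times the mean individual transition time and T_0 the dominant period from
  the autocorrelation curve. Complex trajectories with intersecting paths need
  t_L of order one period (Lorenz: ≈1.4 at L = 22); regular signals need much
  less. **A warning from our experiments:** pushing L up until nearly every
  stored history is unique makes the model a deterministic replay of training
  segments — the autocorrelation error keeps falling, but the walk can lock
  onto cycles that over- or under-represent rare events. For rare-event
  statistics choose the smallest L that stabilizes the statistic of interest
  (the burst benchmark below uses L = 8, where a visible fraction of histories
  still branches).
* **restarts (default 10).** Independent k-means++ seedings; the best fit by
  inner-cluster variance is kept. Ten restarts make the clustering stable in
  practice at these problem sizes while keeping the fit seed-reproducible.
* **`select_hyperparameters()`** automates the (K, L) choice by minimizing the
  normalized RMS error between model and data autocorrelation curves over a
  grid, marking infeasible cells (too few visits for the order) invalid rather
  than failing.
* **Integrator tolerances.** The benchmark systems are integrated with an
  adaptive fifth-order Runge-Kutta scheme (Dormand-Prince) at rtol = 1e-9,
  atol = 1e-11, dense-sampled on the uniform output grid; agreement with a
  fixed-step RK4 oracle at 100× finer steps is at the 1e-6 level over ten time
  units (chaotic divergence makes tighter long-horizon comparisons
  meaningless).

## Synthetic benchmark generators

Everything the test suite and the acceptance script consume is generated by
code, so the whole artifact runs offline.

* **Lorenz** (σ = 10, ρ = 28, β = 8/3, ic = (−3, 0, 31), Δt = 0.015, M =
  57,000) and **Roessler** (a = b = 0.1, c = 14, ic = (1, 1, 1), Δt = 0.01,
  M = 50,000) are the standard chaotic three-dimensional benchmarks.
* **Measurement noise.** `add_uniform_noise(level)` adds i.i.d. uniform noise
  of half-width `level × A_i` per component. We interpret the amplitude `A_i`
  of a fluctuating signal as its *RMS amplitude* (standard deviation of the
  clean component). The plausible alternative — half the peak-to-peak range —
  is 2–2.5× larger for the Lorenz components and demonstrably overdrives the
  coarse-graining: at the 10% level it roughly doubles the number of noise-
  induced intercluster transitions, taking the benchmark far outside its
  documented ≈17,000–18,000 transition range, while the RMS reading lands
  inside it. The RMS convention is therefore the package definition.
* **Pulse train** — a strictly periodic Gaussian bump (width 5% of the
  period) plus optional uniform noise, emulating an ECG-like signal (the
  benchmark configuration is 250 Hz sampling, 1 s period, 180 s).
* **Burst signal** — a smooth quiescent baseline with Poisson-triggered
  raised-cosine excursions, emulating an intermittently bursting
  dissipation-energy observable. Two design points matter. First, the baseline
  is an AR(1) process (correlation time `base_period/2`, sd =
  `amplitude/√3`), *not* white noise: a white baseline has per-sample
  derivatives ~σ/Δt that dwarf the excursions' slopes in the (D, dD/dt)
  embedding, which scrambles the phase-plane geometry the forecast relies on.
  Real dissipation signals are smooth. Second, excursions dominate
  (`pmax`) rather than add to the baseline, so a threshold between the
  baseline range and the minimum peak height (3σ; we use 4σ as the working
  threshold) counts each excursion as exactly one maximal run. Peak heights
  are uniform in [3σ, 10σ], so a 4σ threshold deliberately misses about one
  seventh of the weakest bursts on both the data and the model side — the
  comparison stays fair.

What the surrogates do *not* emulate: multiscale turbulence spectra,
measurement drift, irregular sampling, non-stationarity. Green tests on them
demonstrate the estimator and propagator machinery, not that any particular
real system is well modeled at a given (K, L).

## Numerical choices and degenerate inputs

* **Autocorrelation.** `R(τ_l) = (M − l)^{-1} Σ_m ⟨x'(t_m), x'(t_m + τ_l)⟩`
  on mean-subtracted components, evaluated via FFT. The 1/(M − l) (lag-unbiased)
  normalization makes R(0) exactly the fluctuation energy. Constant input
  returns an all-zero curve with a warning.
* **Dominant period.** T_0 is the lag of the first local maximum of R whose
  prominence (height above the higher of the deepest valleys on either side)
  is at least 5% of R(0). Signals without a deterministic component (e.g. the
  burst surrogate) have no qualifying peak and yield `NA`; the normalized time
  delay is then undefined, with a warning. The time-delay operationalization
  t_L = L × mean individual transition time is a package definition — the
  quantity is only meaningful up to such a convention. Note that for strongly
  recurrent fine-grained clusterings (Roessler at K = 100) mean transition
  times are small and the ratio comes out well below one (≈0.07 at the
  benchmark settings computed by `scripts/acceptance.R`).
* **RMS error metric.** `autocorr_rms_error()` normalizes by the RMS of the
  reference curve and resamples the finer curve onto the coarser grid; it is
  zero iff the curves coincide on that grid and symmetric in the sign of the
  discrepancy.
* **Ties and fallbacks.** Nearest-centroid ties go to the lowest cluster
  index. A propagation step whose history was only observed as the terminal
  training window has no successors; the walk falls back to the stored history
  with the longest matching suffix (lexicographically smallest on ties) and
  reports how often this happened. Unknown *initial* histories are an error —
  silently substituting one would hide a user mistake.
* **Markov baseline.** `fit_markov_baseline()` estimates the column-stochastic
  per-snapshot matrix (self-loops included) and finds its stationary vector by
  power iteration from the empirical distribution; clusters that are never
  departed (possible only at the record's end) are made absorbing with a
  warning.
* **Degenerate configurations.** K = 1 admits no intercluster transition:
  `fit_transition_model()` refuses with the required minimum length, and
  `run_pipeline()` records the stage error and still emits the data-side
  report. All-identical snapshots make POD abort (rank-0 fluctuation).
* **Control interpolation (CNMc).** For a new constant control vector b the
  two nearest trained conditions are combined with inverse-distance weights —
  linear interpolation in control space for two conditions — which degenerates
  exactly to (1, 0) at a training condition, so the other condition is never
  consulted there. Each condition keeps its own length-L history built from
  its own nearest-centroid assignments of the blended states, because Q(b)
  lookups require condition-native histories. What is averaged are the two
  *sampled* flight targets and times (not the expected next states): this
  keeps every step a plausible flight of each condition and makes interpolated
  transit times convex combinations of observed ones. Only interpolation
  between the two nearest conditions is supported, and only autonomous
  (constant-b) forcing.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the Lorenz benchmark at its full
57,000-sample size (about a minute of CPU for the five-seed clustering study),
the Roessler benchmark at its full 50,000 samples, the burst workflow at
40,000 samples with burst rate 0.05 per time unit (≈200 bursts, enough for a
±20% count comparison), and the control-interpolation checks on 4,000-sample
Lorenz runs at K = 20, where the degeneracy property is already sharp. These
sizes were chosen so every statistical tolerance in the tests is comfortably
wider than the Monte-Carlo noise at that size.

## Known limitations

* No extrapolation beyond observed states; no dynamic instabilities.
* Transition-time estimates at the record boundaries carry O(1/I) bias.
* The burst forecast looks exactly one transition ahead ("will the next
  flight enter an onset cluster"); multi-step lookahead would need compounding
  Q over paths and is not implemented.
* CNMc assumes the two nearest conditions bracket the new one on a segment in
  control space; genuinely multi-dimensional control grids would need a
  simplex-based scheme.
* The Markov baseline's stationary vector is the limit of power iteration
  from the empirical distribution; for reducible chains it describes the
  visited communicating class only.
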
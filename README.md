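# cnmr — cluster-based network modeling of nonlinear dynamics

`cnmr` builds data-driven reduced-order models of complex nonlinear dynamical
systems — chaotic attractors, physiological signals, intermittently bursting
turbulence observables — directly from time-resolved snapshot data, with no
assumption of a low-dimensional subspace and no knowledge of the governing
equations. It is aimed at researchers who have a long multivariate time series
`x(t) ∈ R^N` sampled at a fixed interval Δt and want a compact stochastic model
that reproduces the long-term statistics (fluctuation energy, autocorrelation,
state occupancy, rare-event rates) and supports prediction and control-oriented
interpolation.

## The model

1. **Coarse-graining.** The M snapshots are partitioned into K clusters with
   k-means++; the centroids c_k (cluster means) become the nodes of a directed
   network. High-dimensional states are first reduced losslessly by snapshot
   POD, `u(t) = u0 + Σ_i a_i(t) Φ_i`, whose coefficient distances equal
   full-state distances `‖a_m − a_n‖ = ‖u_m − u_n‖`, so clustering mode
   coefficients is exact and cheap.
2. **Network identification.** The label sequence is run-length encoded into
   the visit sequence K_1, …, K_I (consecutive visits differ). An order-L
   Markov chain on visits gives the *direct transition probabilities*

       Q(k | k_{i−1}, …, k_{i−L}) = n_{k,h} / n_h ,   Q(j | …, j) = 0,

   estimated by counting length-(L+1) windows and stored sparsely (only
   observed transitions; the dense tensor would have K^(L+1) entries). Each
   transition also carries a *transition time*, the mean of the individual
   times τ = (τ^{n−1} + τ^n)/2 built from the residence times of the two
   clusters involved.
3. **Propagation.** Model trajectories are stochastic sequences of
   constant-velocity flights between centroids:

       x(t) = α c_k + (1 − α) c_j ,   α = (t − t_j) / T_{k,j},

   with the successor drawn from Q and the flight duration from T. Unlike a
   first-order Markov model on raw snapshots — whose population vector
   q^{l+1} = P q^l diffuses to a fixed point — the network model keeps moving
   and reproduces oscillatory autocorrelations over many periods.

Validation compares model and data autocorrelation functions R(τ) (R(0) is the
fluctuation energy), cluster probability distributions, and scalar PDFs. For
rare events, a scalar observable is embedded in (D, dD/dt), bursts are maximal
runs above a threshold, and every stored history gets a burst probability
(mass of Q flowing into burst-onset clusters) and a previewing time (expected
time to onset given a burst-bound flight). A control-oriented extension
interpolates Q and T between the two training conditions nearest to a new
constant control parameter b.

## Worked example

```r
library(cnmr)

lorenz <- simulate_lorenz(20000, dt = 0.015) |>     # chaotic benchmark
  add_uniform_noise(0.1, seed = 1)                  # 10% measurement noise

clusters <- fit_kmeanspp(lorenz, K = 50, restarts = 10, seed = 1)
visits   <- extract_visit_sequence(clusters)
model    <- fit_transition_model(visits, L = 22, K = 50)
model
#> transition model: order L = 22, K = 50 clusters
#> 5788 stored (history, successor) entries over 5721 histories (dense size K^(L+1) = 1.19e+39)

traj <- propagate(model, clusters, duration = 300, seed = 1)
traj
#> CNM trajectory: 6229 flights over 300 time units (linear interpolation)

ref <- autocorrelation(lorenz, 20)
mod <- autocorrelation(resample_uniform(traj), 20)
100 * abs(mod$R[1] - ref$R[1]) / ref$R[1]
#> R(0) data 219.8, model 209.4 -> relative error 4.8%
normalized_time_delay(model, visits, ref)
#> 1.38
```

The model's zero-lag autocorrelation (total fluctuation energy of the state)
matches the training data within a few percent even though the model is just a
random walk over 50 centroids; the normalized time delay t_L/T_0 ≈ 1.4 says
the order-22 history spans about one and a half characteristic oscillation
periods, which is what disambiguates the two attractor lobes. Plot helpers
(`autoplot()` on any fitted object, `plot_autocorrelation()`,
`plot_cluster_probability()`, `plot_bursts()`) draw the standard diagnostics,
and `tidy()`/`glance()` return the fitted quantities as tibbles.

`run_pipeline()` chains all stages from a flat key=value config, and
`inst/cli/cnm` exposes the same pipeline as a shell command.

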
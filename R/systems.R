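#' Simulate the Lorenz system
#'
#' Integrates the Lorenz equations
#' \deqn{\dot x = \sigma (y - x),\quad \dot y = x(\rho - z) - y,\quad
#'       \dot z = x y - \beta z}
#' with an adaptive fifth-order Runge-Kutta scheme (Dormand-Prince) whose
#' dense output is sampled on the uniform grid `t0 + (0:(n_samples-1)) * dt`.
#' The chaotic benchmark settings are `sigma = 10`, `rho = 28`, `beta = 8/3`
#' with initial state `(-3, 0, 31)`.
#'
#' @param n_samples number of snapshots to return (>= 2).
#' @param dt sampling interval.
#' @param init initial state, length 3.
#' @param sigma,rho,beta system parameters.
#' @param t0 time of the first snapshot.
#' @param rtol,atol integration tolerances.
#' @return Snapshot-set tibble with columns `t, x, y, z`.
#' @examples
#' lor <- simulate_lorenz(2000, dt = 0.015)
#' @export
simulate_lorenz <- function(n_samples, dt, init = c(-3, 0, 31),
                            sigma = 10, rho = 28, beta = 8 / 3,
                            t0 = 0, rtol = 1e-9, atol = 1e-11) {
  stopifnot(length(init) == 3)
  rhs <- function(t, s, p) {
    list(c(p[["sigma"]] * (s[2] - s[1]),
           s[1] * (p[["rho"]] - s[3]) - s[2],
           s[1] * s[2] - p[["beta"]] * s[3]))
  }
  integrate_ode(rhs, init, c(sigma = sigma, rho = rho, beta = beta),
                n_samples, dt, t0, rtol, atol,
                component_names = c("x", "y", "z"))
}

#' Simulate the Roessler system
#'
#' Integrates
#' \deqn{\dot x = -y - z,\quad \dot y = x + a y,\quad \dot z = b + z (x - c)}
#' with the same adaptive fifth-order scheme as [simulate_lorenz()]. The
#' chaotic benchmark settings are `a = b = 0.1`, `c = 14`, initial state
#' `(1, 1, 1)`, `dt = 0.01`, 50,000 samples; the motion rotates in the x-y
#' plane with intermittent spikes in z.
#'
#' @inheritParams simulate_lorenz
#' @param a,b,c system parameters.
#' @return Snapshot-set tibble with columns `t, x, y, z`.
#' @export
simulate_rossler <- function(n_samples, dt, init = c(1, 1, 1),
                             a = 0.1, b = 0.1, c = 14,
                             t0 = 0, rtol = 1e-9, atol = 1e-11) {
  stopifnot(length(init) == 3)
  rhs <- function(t, s, p) {
    list(c(-s[2] - s[3],
           s[1] + p[["a"]] * s[2],
           p[["b"]] + s[3] * (s[1] - p[["c"]])))
  }
  integrate_ode(rhs, init, c(a = a, b = b, c = c),
                n_samples, dt, t0, rtol, atol,
                component_names = c("x", "y", "z"))
}

integrate_ode <- function(rhs, init, params, n_samples, dt, t0, rtol, atol,
                          component_names) {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (dt <= 0) abort("`dt` must be positive.")
  times <- t0 + dt * (seq_len(n_samples) - 1)
  out <- deSolve::ode(y = init, times = times, func = rhs, parms = params,
                      method = "ode45", rtol = rtol, atol = atol)
  states <- unname(out[, -1, drop = FALSE])
  if (!all(is.finite(states))) {
    abort("Integration failed: trajectory became non-finite (blow-up).")
  }
  snapshot_set(states, dt = dt, t0 = t0, component_names = component_names)
}

#' Generate surrogate one-dimensional benchmark signals
#'
#' Two seeded, reproducible scalar signals used as offline stand-ins for
#' measured data:
#'
#' * `"pulse_train"`: a periodic sharp pulse (Gaussian bump of width
#'   `base_period / 20` repeated every `base_period`) emulating an ECG-style
#'   heartbeat, with additive uniform noise of half-width
#'   `noise_level * amplitude`.
#' * `"burst_signal"`: stationary small-amplitude uniform noise with
#'   Poisson-triggered raised-cosine excursions of mean rate `burst_rate`
#'   per unit time, emulating an intermittently bursting dissipation-energy
#'   signal. The baseline is *smooth* stationary noise (an AR(1) process with
#'   uniform innovations, correlation time `base_period / 2`, standard
#'   deviation `amplitude / sqrt(3)`), so its time derivative stays small
#'   compared with the excursion slopes and the (value, derivative) phase
#'   plane has the geometry of a dissipation-energy signal. Excursion peak
#'   heights are uniform in `[3, 10]` times the baseline standard deviation
#'   and dominate (rather than add to) the background; a threshold around
#'   four standard deviations separates bursts from the quiescent noise; each
#'   excursion lasts `base_period` time units.
#'
#' @param kind `"pulse_train"` or `"burst_signal"`.
#' @param n_samples number of snapshots.
#' @param dt sampling interval.
#' @param base_period pulse period (pulse train) or burst duration (burst
#'   signal), in time units.
#' @param amplitude pulse height (pulse train) or baseline-noise scale:
#'   the baseline is uniform on `[-amplitude, amplitude]` (burst signal).
#' @param burst_rate expected bursts per unit time (burst signal only).
#' @param noise_level additive noise fraction (pulse train only), in `[0, 1)`.
#' @param seed integer seed.
#' @return Snapshot-set tibble with columns `t, D`. For `"burst_signal"` the
#'   ground-truth burst onset times are attached as attribute
#'   `"burst_onsets"`.
#' @export
generate_surrogate <- function(kind = c("pulse_train", "burst_signal"),
                               n_samples, dt, base_period = 1,
                               amplitude = 1, burst_rate = 0.05,
                               noise_level = 0, seed = 1) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    abort(sprintf("Unknown surrogate kind: %s", kind[1]))
  })
  if (base_period <= 0) abort("`base_period` must be positive.")
  if (noise_level < 0 || noise_level >= 1) abort("`noise_level` must be in [0, 1).")
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  tt <- dt * (seq_len(n_samples) - 1)
  span <- n_samples * dt

  if (kind == "pulse_train") {
    phase <- (tt %% base_period) / base_period
    width <- 0.05 # pulse sd as a fraction of the period
    s <- amplitude * exp(-0.5 * ((phase - 0.5) / width)^2)
    if (noise_level > 0) {
      s <- s + withr::with_seed(seed, runif(n_samples, -1, 1)) * noise_level * amplitude
    }
    return(snapshot_set(matrix(s, ncol = 1), dt = dt, component_names = "D"))
  }

  sigma_noise <- amplitude / sqrt(3) # matches a uniform density on [-amplitude, amplitude]
  gen <- function() {
    phi <- exp(-2 * dt / base_period) # correlation time = base_period / 2
    innov <- runif(n_samples, -amplitude, amplitude)
    base <- as.numeric(stats::filter(innov * sqrt(1 - phi^2), phi,
                                     method = "recursive", init = innov[1]))
    n_bursts <- stats::rpois(1, burst_rate * span)
    onsets <- sort(runif(n_bursts, 0, span - base_period))
    heights <- runif(n_bursts, 3 * sigma_noise, 10 * sigma_noise)
    s <- base
    # excursions dominate the quiescent background rather than riding on it,
    # so a threshold between the baseline bound and 3 sigma counts them cleanly
    for (i in seq_len(n_bursts)) {
      u <- (tt - onsets[i]) / base_period
      inside <- u >= 0 & u <= 1
      s[inside] <- pmax(s[inside], heights[i] * 0.5 * (1 - cos(2 * pi * u[inside])))
    }
    list(s = s, onsets = onsets)
  }
  res <- withr::with_seed(seed, gen())
  out <- snapshot_set(matrix(res$s, ncol = 1), dt = dt, component_names = "D")
  attr(out, "burst_onsets") <- res$onsets
  out
}
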
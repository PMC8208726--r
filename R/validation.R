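#' Autocorrelation function of the state vector
#'
#' Computes the lag-domain autocorrelation of a multivariate snapshot set:
#' each component is mean-subtracted, and
#' \deqn{R(\tau_l) = \frac{1}{M - l} \sum_{m=1}^{M-l}
#'       \langle x'(t_m),\, x'(t_m + l\,\Delta t)\rangle}
#' sums the component-wise products at lag `l * dt`. The zero-lag value `R(0)`
#' is the fluctuation energy (total variance) of the signal. The sum is
#' evaluated with FFTs, so long series and many lags are cheap.
#'
#' @inheritParams snapshot_matrix
#' @param max_lag largest lag, in time units; must be smaller than the span.
#' @return Tibble with columns `lag` (time units, starting at 0) and `R`.
#' @export
autocorrelation <- function(data, max_lag) {
  validate_snapshots(data)
  x <- snapshot_matrix(data)
  dt <- snapshot_dt(data)
  m <- nrow(x)
  n_lag <- floor(max_lag / dt + 1e-9)
  if (n_lag >= m) abort("`max_lag` must be smaller than the data span.")
  xc <- sweep(x, 2, colMeans(x))
  if (max(abs(xc)) == 0) {
    warn("Constant input: zero-variance signal, returning an all-zero curve.")
    return(tibble::tibble(lag = (0:n_lag) * dt, R = 0))
  }
  nfft <- nextn(2L * m, 2)
  acc <- numeric(n_lag + 1L)
  for (i in seq_len(ncol(xc))) {
    f <- fft(c(xc[, i], numeric(nfft - m)))
    s <- Re(fft(Mod(f)^2, inverse = TRUE)) / nfft
    acc <- acc + s[seq_len(n_lag + 1L)]
  }
  tibble::tibble(lag = (0:n_lag) * dt, R = acc / (m - 0:n_lag))
}

#' Cluster probability distribution
#'
#' The fraction of time the state resides in each cluster. On the data side
#' this is the share of snapshots per cluster; on the model side the
#' trajectory is resampled on a uniform grid, each sample is assigned to its
#' nearest centroid, and the shares are counted, so both sides are compared on
#' the same footing.
#'
#' @param x integer labels, a `cluster_model`, or a `cnm_trajectory`.
#' @param clusters `cluster_model` (required for a trajectory; otherwise used
#'   only to fix `K`).
#' @param dt resampling interval for a trajectory; defaults to the training
#'   interval.
#' @return Tibble with columns `cluster` and `p` (sums to 1).
#' @export
cluster_probability <- function(x, clusters = NULL, dt = NULL) {
  if (inherits(x, "cnm_trajectory")) {
    if (is.null(clusters)) abort("`clusters` is required to evaluate a trajectory's CPD.")
    grid <- resample_uniform(x, dt %||% clusters$dt)
    labels <- assign_nearest_centroid(snapshot_matrix(grid), clusters)
  } else if (inherits(x, "cluster_model")) {
    clusters <- x
    labels <- x$labels
  } else {
    labels <- as.integer(x)
  }
  K <- if (!is.null(clusters)) clusters$K else max(labels)
  counts <- tabulate(labels, nbins = K)
  tibble::tibble(cluster = seq_len(K), p = counts / sum(counts))
}

#' Normalized RMS error between two autocorrelation curves
#'
#' `100 * RMS(model - reference) / RMS(reference)`, evaluated on the common
#' lag grid (the finer curve is linearly interpolated onto the coarser one,
#' restricted to the overlapping lag range).
#'
#' @param model_curve,ref_curve tibbles with columns `lag`, `R` as returned by
#'   [autocorrelation()].
#' @return Percentage error (non-negative scalar).
#' @export
autocorr_rms_error <- function(model_curve, ref_curve) {
  stopifnot(all(c("lag", "R") %in% names(model_curve)),
            all(c("lag", "R") %in% names(ref_curve)))
  lag_max <- min(max(model_curve$lag), max(ref_curve$lag))
  coarser <- if (stats::median(diff(model_curve$lag)) >= stats::median(diff(ref_curve$lag))) {
    model_curve
  } else {
    ref_curve
  }
  grid <- coarser$lag[coarser$lag <= lag_max + 1e-12]
  rm_ <- approx(model_curve$lag, model_curve$R, xout = grid)$y
  rr <- approx(ref_curve$lag, ref_curve$R, xout = grid)$y
  denom <- sqrt(mean(rr^2))
  if (denom == 0) abort("Reference curve has zero RMS; the error metric is undefined.")
  100 * sqrt(mean((rm_ - rr)^2)) / denom
}

#' Fundamental period from an autocorrelation curve
#'
#' The lag of the first local maximum of `R` (for lag > 0) whose prominence —
#' its height above the higher of the deepest valleys on either side — is at
#' least `prominence` times `R(0)`. Signals without a deterministic periodic
#' component have no such peak and yield `NA`.
#'
#' @param curve tibble with columns `lag`, `R`.
#' @param prominence required prominence as a fraction of `R(0)`.
#' @return The period (lag, time units), or `NA` when no dominant period
#'   exists.
#' @export
fundamental_period <- function(curve, prominence = 0.05) {
  r <- curve$R
  n <- length(r)
  if (n < 3) return(NA_real_)
  r0 <- r[1]
  if (r0 <= 0) return(NA_real_)
  is_max <- which(r[2:(n - 1)] >= r[1:(n - 2)] & r[2:(n - 1)] > r[3:n]) + 1L
  for (i in is_max) {
    prom <- r[i] - max(min(r[1:i]), min(r[i:n]))
    if (prom >= prominence * r0) return(curve$lag[i])
  }
  NA_real_
}

#' Normalized time delay of a fitted network model
#'
#' The time-delay window covered by the order-L history, `t_L = L *` (mean of
#' all individual transition times of the visit sequence), expressed in units
#' of the fundamental period `T_0` detected from the reference
#' autocorrelation curve. Large values mean the model conditions on a memory
#' extending over several characteristic oscillations. Returns `NA` (with a
#' warning) for signals without a dominant period.
#'
#' @param model a `transition_model`, or the integer order `L`.
#' @param visits visit-sequence tibble of the training data.
#' @param ref_curve reference autocorrelation curve (tibble `lag`, `R`).
#' @return Dimensionless ratio `t_L / T_0`.
#' @export
normalized_time_delay <- function(model, visits, ref_curve) {
  L <- if (inherits(model, "transition_model")) model$order else as.integer(model)
  if (L == 0) return(0)
  res <- visits$residence_time
  if (length(res) < 2) abort("Need at least two visits to form a transition time.")
  tau_ind <- (res[-length(res)] + res[-1]) / 2
  t_l <- L * mean(tau_ind)
  t0 <- fundamental_period(ref_curve)
  if (is.na(t0)) {
    warn("No dominant period in the reference autocorrelation; time delay undefined.")
    return(NA_real_)
  }
  t_l / t0
}

#' Select K and L by minimizing the autocorrelation RMS error
#'
#' Runs the full pipeline — cluster, fit, propagate over the training span,
#' resample, autocorrelate — for every `(K, L)` grid point and returns the
#' pair minimizing the normalized autocorrelation RMS error against the
#' training data, together with the whole error surface. Grid points with too
#' few visits for the requested order are marked invalid (`NA`) rather than
#' failing the study.
#'
#' @inheritParams snapshot_matrix
#' @param K_grid,L_grid integer vectors of candidate values.
#' @param seed integer seed controlling clustering and propagation.
#' @param max_lag autocorrelation lag range; defaults to a tenth of the span.
#' @param restarts k-means++ restarts per grid point.
#' @return List with elements `K`, `L` (the argmin) and `surface`, a tibble
#'   `K, L, error`.
#' @export
select_hyperparameters <- function(data, K_grid, L_grid, seed = 1,
                                   max_lag = NULL, restarts = 3) {
  validate_snapshots(data)
  if (!length(K_grid) || !length(L_grid)) abort("Grids must be non-empty.")
  dt <- snapshot_dt(data)
  span <- dt * (nrow(data) - 1)
  max_lag <- max_lag %||% (span / 10)
  ref <- autocorrelation(data, max_lag)

  surface <- tidyr::expand_grid(K = as.integer(K_grid), L = as.integer(L_grid)) |>
    dplyr::mutate(error = NA_real_)
  cms <- lapply(unique(surface$K), function(K) {
    fit_kmeanspp(data, K = K, restarts = restarts, seed = seed)
  })
  names(cms) <- unique(surface$K)

  for (row in seq_len(nrow(surface))) {
    cm <- cms[[as.character(surface$K[row])]]
    vs <- extract_visit_sequence(cm)
    err <- tryCatch({
      tm <- fit_transition_model(vs, L = surface$L[row], K = cm$K)
      traj <- propagate(tm, cm, duration = span, seed = seed)
      mod <- autocorrelation(resample_uniform(traj, dt), max_lag)
      autocorr_rms_error(mod, ref)
    }, error = function(e) NA_real_)
    surface$error[row] <- err
  }
  if (all(is.na(surface$error))) abort("Every grid point was invalid; enlarge the data or shrink L.")
  best <- surface[which.min(surface$error), ]
  list(K = best$K[[1]], L = best$L[[1]], surface = surface)
}

#' Normalized histogram density of a scalar series
#'
#' @param series 1-D snapshot set (tibble `t` plus one component) or numeric
#'   vector.
#' @param bins number of equal-width bins (>= 2).
#' @return Tibble with columns `mid` (bin center) and `density`; the density
#'   integrates to 1 (single-valued input occupies one unit-mass bin).
#' @export
scalar_pdf <- function(series, bins = 50) {
  if (bins < 2) abort("`bins` must be at least 2.")
  x <- if (is.data.frame(series)) as.numeric(snapshot_matrix(series)[, 1]) else as.numeric(series)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                      plot = FALSE, include.lowest = TRUE)
  tibble::tibble(mid = h$mids, density = h$density)
}
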
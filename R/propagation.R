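#' Construct a model trajectory from waypoints
#'
#' A `cnm_trajectory` is a sequence of waypoints (state, arrival time) joined
#' by constant-velocity flights: between consecutive waypoints the state is
#' the convex combination
#' \deqn{x(t) = \alpha(t)\, c_k + [1 - \alpha(t)]\, c_j,\qquad
#'       \alpha = (t - t_j) / T_{k,j}}
#' of the departed and target waypoints. Waypoints are usually centroids of a
#' cluster model, but the control-oriented interpolation produces blended
#' states.
#'
#' @param times strictly increasing arrival times, one per waypoint.
#' @param states waypoint matrix (rows = waypoints).
#' @param visits optional integer cluster indices of the waypoints.
#' @param interpolation `"linear"` (the flight rule above) or `"spline"`
#'   (natural cubic through the waypoints).
#' @param dt_train sampling interval of the training data, used as the default
#'   resampling grid.
#' @return A `cnm_trajectory`.
#' @export
cnm_trajectory <- function(times, states, visits = NULL,
                           interpolation = c("linear", "spline"),
                           dt_train = NULL) {
  interpolation <- match.arg(interpolation)
  states <- as.matrix(states)
  if (is.null(colnames(states))) colnames(states) <- paste0("x", seq_len(ncol(states)))
  if (length(times) != nrow(states)) abort("One arrival time per waypoint is required.")
  if (any(diff(times) <= 0)) abort("Arrival times must be strictly increasing.")
  if (!is.null(visits) && any(diff(visits) == 0)) abort("Consecutive visits must differ.")
  structure(list(times = as.numeric(times), states = states,
                 visits = visits, interpolation = interpolation,
                 dt_train = dt_train),
            class = "cnm_trajectory")
}

#' Propagate a cluster-based network model
#'
#' Synthesizes a stochastic model trajectory: starting from an initial
#' length-L history of visited clusters, the next cluster is repeatedly drawn
#' from the stored direct-transition probabilities `Q(. | history)`, the clock
#' advances by the stored transition time `T(successor | history)`, and the
#' history window shifts. Sampling uses the inverse-CDF over successors in
#' ascending cluster-index order, so trajectories are bit-reproducible given
#' the seed. Propagation stops at the first arrival at or past `duration`.
#'
#' If the current history was only ever observed as the terminal window of the
#' training data (a dead end), the walk falls back to the stored history with
#' the longest matching suffix; the number of such events is reported via a
#' message.
#'
#' @param model a `transition_model`.
#' @param clusters the `cluster_model` whose centroids are the network nodes.
#' @param duration trajectory length in time units.
#' @param initial_history integer vector of length `L` (a stored history);
#'   defaults to the first stored history of the training sequence.
#' @param seed integer seed.
#' @param interpolation flight interpolation mode, see [cnm_trajectory()].
#' @return A `cnm_trajectory` whose waypoints are centroids; the trajectory
#'   starts at time 0 at the last cluster of the initial history.
#' @examples
#' cm <- fit_kmeanspp(simulate_lorenz(2000, 0.015), K = 10, seed = 1)
#' tm <- fit_transition_model(extract_visit_sequence(cm), L = 1)
#' traj <- propagate(tm, cm, duration = 10, seed = 1)
#' @export
propagate <- function(model, clusters, duration, initial_history = NULL,
                      seed = NULL, interpolation = c("linear", "spline")) {
  stopifnot(inherits(model, "transition_model"), inherits(clusters, "cluster_model"))
  interpolation <- match.arg(interpolation)
  if (duration <= 0) abort("`duration` must be positive.")
  lookup <- build_lookup(model)
  L <- model$order
  h <- as.integer(initial_history %||% model$first_history)
  if (length(h) != L) abort(sprintf("`initial_history` must have length L = %d.", L))
  if (is.null(get0(key_of(h), envir = lookup))) {
    near <- utils::head(ls(lookup, sorted = TRUE), 3)
    abort(sprintf("`initial_history` %s is not a stored history. Examples of stored histories: %s",
                  key_of(h), paste(near, collapse = ", ")))
  }

  walk <- function() {
    visits <- integer(0)
    times <- numeric(0)
    cur <- h
    t_now <- 0
    visits <- c(visits, cur[L])
    times <- c(times, 0)
    n_fallback <- 0L
    # grow in chunks to avoid quadratic appends
    est <- max(16L, ceiling(duration / max(model$mean_transition_time, 1e-12)) + 16L)
    visits <- c(visits, integer(est)); times <- c(times, numeric(est))
    i <- 1L
    while (t_now < duration) {
      hit <- lookup_history(lookup, cur, L)
      if (is.null(hit)) abort("No stored history shares a suffix with the current one.")
      if (hit$fallback) {
        n_fallback <- n_fallback + 1L
        cur <- as.integer(strsplit(hit$key, "-", fixed = TRUE)[[1]])
      }
      e <- hit$entry
      s_idx <- findInterval(runif(1), e$cum, left.open = TRUE) + 1L
      s_idx <- min(s_idx, length(e$successors))
      s <- e$successors[s_idx]
      t_now <- t_now + e$time[s_idx]
      i <- i + 1L
      if (i > length(visits)) { visits <- c(visits, integer(est)); times <- c(times, numeric(est)) }
      visits[i] <- s
      times[i] <- t_now
      cur <- c(cur[-1L], s)
    }
    if (n_fallback > 0) {
      rlang::inform(sprintf("propagate: %d dead-end histories resolved by longest-suffix fallback.",
                            n_fallback))
    }
    list(visits = visits[seq_len(i)], times = times[seq_len(i)])
  }
  res <- if (is.null(seed)) walk() else withr::with_seed(seed, walk())

  cnm_trajectory(times = res$times,
                 states = clusters$centroids[res$visits, , drop = FALSE],
                 visits = res$visits,
                 interpolation = interpolation,
                 dt_train = clusters$dt)
}

#' Evaluate a model trajectory at arbitrary times
#'
#' Linear mode applies the constant-velocity flight rule exactly (the state at
#' a waypoint time is exactly that waypoint); spline mode interpolates the
#' waypoints with a natural cubic spline per component.
#'
#' @param traj a `cnm_trajectory`.
#' @param t times within the trajectory span.
#' @return Tibble with column `t` and one column per state component.
#' @export
evaluate_trajectory <- function(traj, t) {
  stopifnot(inherits(traj, "cnm_trajectory"))
  tspan <- range(traj$times)
  if (any(t < tspan[1] - 1e-12) || any(t > tspan[2] + 1e-12)) {
    abort(sprintf("Evaluation times must lie within the trajectory span [%g, %g].",
                  tspan[1], tspan[2]))
  }
  n <- ncol(traj$states)
  vals <- if (traj$interpolation == "linear") {
    vapply(seq_len(n),
           function(i) approx(traj$times, traj$states[, i], xout = t, rule = 2)$y,
           numeric(length(t)))
  } else {
    vapply(seq_len(n),
           function(i) splinefun(traj$times, traj$states[, i], method = "natural")(t),
           numeric(length(t)))
  }
  vals <- matrix(vals, nrow = length(t))
  colnames(vals) <- colnames(traj$states)
  dplyr::bind_cols(tibble::tibble(t = t), tibble::as_tibble(vals))
}

#' Resample a model trajectory on a uniform grid
#'
#' Evaluates the trajectory's interpolation rule on `seq(t_start, t_end, dt)`,
#' returning a snapshot set directly comparable with training data.
#'
#' @param traj a `cnm_trajectory`.
#' @param dt sampling interval; defaults to the training interval stored in
#'   the trajectory.
#' @return Snapshot-set tibble.
#' @export
resample_uniform <- function(traj, dt = NULL) {
  stopifnot(inherits(traj, "cnm_trajectory"))
  dt <- dt %||% traj$dt_train
  if (is.null(dt) || dt <= 0) abort("`dt` must be a positive sampling interval.")
  span <- diff(range(traj$times))
  if (span < dt) abort("Trajectory duration is shorter than `dt`.")
  grid <- seq(traj$times[1], max(traj$times), by = dt)
  evaluate_trajectory(traj, grid)
}

#' @export
print.cnm_trajectory <- function(x, ...) {
  cat(sprintf("CNM trajectory: %d flights over %.4g time units (%s interpolation)\n",
              length(x$times) - 1L, diff(range(x$times)), x$interpolation))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnm_trajectory <- function(x, ...) {
  out <- tibble::tibble(time = x$times)
  if (!is.null(x$visits)) out$cluster <- x$visits
  dplyr::bind_cols(out, tibble::as_tibble(x$states, .name_repair = "minimal"))
}

#' @exportS3Method generics::glance
glance.cnm_trajectory <- function(x, ...) {
  tibble::tibble(n_flights = length(x$times) - 1L,
                 duration = diff(range(x$times)),
                 interpolation = x$interpolation)
}
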
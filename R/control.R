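#' Fit a cluster-network model per control condition
#'
#' For control-oriented modeling the full identification chain — clustering,
#' visit-sequence extraction, transition estimation — is run separately for
#' each training condition, each tagged with its constant control-parameter
#' vector `b`. Dynamics at an unseen `b` are later interpolated between the
#' two nearest trained conditions with [propagate_cnmc()].
#'
#' @param datasets list of conditions, each a list with elements `b` (numeric
#'   control vector) and `data` (snapshot-set tibble); at least two, all with
#'   the same state dimension.
#' @param K clusters per condition.
#' @param L chain order, shared across conditions.
#' @param restarts k-means++ restarts.
#' @param seed integer seed; condition i uses `seed + i - 1`.
#' @return A `control_ensemble`: list of fitted conditions, each holding `b`,
#'   `clusters`, `model`, `visits`.
#' @export
fit_ensemble <- function(datasets, K, L, restarts = 10, seed = 1) {
  if (length(datasets) < 2) abort("A control ensemble needs at least two conditions.")
  dims <- vapply(datasets, function(d) ncol(snapshot_matrix(d$data)), integer(1))
  if (length(unique(dims)) != 1) abort("All conditions must share the state dimension.")
  conditions <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    cm <- fit_kmeanspp(d$data, K = K, restarts = restarts, seed = seed + i - 1L)
    vs <- extract_visit_sequence(cm)
    if (nrow(vs) <= L) {
      abort(sprintf("Condition %d (b = %s) has only %d visits; an order-%d model needs > %d.",
                    i, paste(d$b, collapse = ","), nrow(vs), L, L))
    }
    tm <- fit_transition_model(vs, L = L, K = K)
    list(b = as.numeric(d$b), clusters = cm, model = tm, visits = vs)
  })
  structure(list(conditions = conditions, K = as.integer(K), L = as.integer(L),
                 N = dims[1]),
            class = "control_ensemble")
}

#' @export
print.control_ensemble <- function(x, ...) {
  bs <- vapply(x$conditions, function(c) paste(c$b, collapse = ","), character(1))
  cat(sprintf("control ensemble: %d conditions (b = %s), K = %d, L = %d\n",
              length(x$conditions), paste(bs, collapse = "; "), x$K, x$L))
  invisible(x)
}

#' Propagate interpolated dynamics at a new control setting
#'
#' Three-step interpolation between the two trained conditions nearest to
#' `b_new` in control space. At each iteration: (1) the current state is
#' assigned to its nearest centroid within each of the two conditions,
#' extending that condition's own recent-visit history; (2) each condition
#' samples its next flight (successor centroid and transition time) from its
#' own `Q`/`T` conditioned on its local history (longest-suffix fallback when
#' the history is short or unseen); (3) the next state and the transit time
#' are the inverse-distance-weighted averages of the two sampled flight
#' targets and times. When `b_new` equals a training `b` the weights
#' degenerate to (1, 0) and the other condition is never consulted, so plain
#' network-model statistics are recovered.
#'
#' Only interpolation is supported: `b_new` must lie on the segment between
#' the two nearest conditions' control vectors.
#'
#' @param ensemble a `control_ensemble`.
#' @param b_new control vector of the new condition.
#' @param duration trajectory length in time units.
#' @param initial_state starting state; defaults to the first training
#'   snapshot's centroid of the nearest condition.
#' @param seed integer seed.
#' @return A `cnm_trajectory` whose waypoints are blended states.
#' @export
propagate_cnmc <- function(ensemble, b_new, duration, initial_state = NULL,
                           seed = NULL) {
  stopifnot(inherits(ensemble, "control_ensemble"))
  b_new <- as.numeric(b_new)
  if (duration <= 0) abort("`duration` must be positive.")
  d_b <- vapply(ensemble$conditions,
                function(c) sqrt(sum((c$b - b_new)^2)), numeric(1))
  ord <- order(d_b)
  pair <- ensemble$conditions[ord[1:2]]
  d2 <- d_b[ord[1:2]]

  if (d2[1] == 0) {
    w <- c(1, 0)
  } else {
    seg <- sqrt(sum((pair[[1]]$b - pair[[2]]$b)^2))
    if (d2[1] + d2[2] > seg * (1 + 1e-8)) {
      abort("`b_new` lies outside the segment between the two nearest conditions (extrapolation).")
    }
    w <- (1 / d2) / sum(1 / d2)
  }
  active <- which(w > 0)
  lookups <- lapply(pair, function(c) build_lookup(c$model))
  L <- ensemble$L

  if (is.null(initial_state)) {
    c1 <- pair[[1]]$clusters
    initial_state <- c1$centroids[pair[[1]]$model$first_history[L], ]
  }
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != ensemble$N) abort("`initial_state` has the wrong dimension.")

  walk <- function() {
    histories <- lapply(pair, function(c) {
      as.integer(assign_nearest_centroid(initial_state, c$clusters))
    })
    n_wp <- 1L
    times <- 0
    states <- matrix(initial_state, nrow = 1)
    t_now <- 0
    while (t_now < duration) {
      targets <- matrix(0, length(pair), ensemble$N)
      t_step <- numeric(length(pair))
      for (ci in active) {
        hit <- lookup_history(lookups[[ci]], histories[[ci]], L)
        if (is.null(hit)) abort("No stored history matches in one condition; data too short.")
        e <- hit$entry
        if (hit$fallback && length(histories[[ci]]) >= L) {
          histories[[ci]] <- as.integer(strsplit(hit$key, "-", fixed = TRUE)[[1]])
        }
        u <- runif(1)
        s_idx <- min(findInterval(u, e$cum, left.open = TRUE) + 1L, length(e$successors))
        targets[ci, ] <- pair[[ci]]$clusters$centroids[e$successors[s_idx], ]
        t_step[ci] <- e$time[s_idx]
      }
      new_state <- as.numeric(w[active] %*% targets[active, , drop = FALSE])
      t_now <- t_now + sum(w[active] * t_step[active])
      n_wp <- n_wp + 1L
      times <- c(times, t_now)
      states <- rbind(states, new_state)
      for (ci in active) {
        lab <- as.integer(assign_nearest_centroid(new_state, pair[[ci]]$clusters))
        h <- histories[[ci]]
        if (lab != h[length(h)]) h <- c(h, lab)
        histories[[ci]] <- tail(h, L)
      }
    }
    list(times = times, states = states)
  }
  res <- if (is.null(seed)) walk() else withr::with_seed(seed, walk())
  colnames(res$states) <- colnames(pair[[1]]$clusters$centroids)
  cnm_trajectory(times = res$times, states = res$states,
                 interpolation = "linear",
                 dt_train = pair[[1]]$clusters$dt)
}
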
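#' Estimate an order-L direct-transition network from a visit sequence
#'
#' The heart of the cluster-based network model. Every length-`(L + 1)` window
#' of the visit sequence contributes one observation: the first `L` visits
#' form the *history*, the last visit is the *successor*. For each stored
#' history h the direct transition probability of successor k is
#' `Q(k | h) = n_{k,h} / n_h`, the window count divided by the history count.
#' Self-transitions cannot occur because consecutive visits differ by
#' construction. Each window also carries an individual transition time,
#' defined as half the sum of the residence times of the two clusters
#' involved, `tau = (tau^{n-1} + tau^n) / 2`; the stored transition time
#' `T(k | h)` is the mean of the individual times of all windows with that
#' (history, successor) pair.
#'
#' Only observed (history, successor) pairs are stored, as a sparse lookup
#' table; the dense alternative would hold `K^(L+1)` entries. Histories
#' shorter than `L` at the start of the sequence are discarded, not padded.
#'
#' @param visits visit-sequence tibble from [extract_visit_sequence()].
#' @param L chain order (number of past visits conditioning the next
#'   transition), `>= 1`.
#' @param K total number of clusters; defaults to the largest index seen.
#' @return A `transition_model` with fields `order`, `K`, `table` (tibble with
#'   columns `history` — dash-separated cluster indices —, `successor`,
#'   `count`, `q`, `time`), `n_windows`, and `first_history` (the earliest
#'   stored history, the default propagation start).
#' @examples
#' vs <- extract_visit_sequence(c(1, 1, 2, 2, 2, 1), dt = 1)
#' fit_transition_model(vs, L = 1)$table
#' @export
fit_transition_model <- function(visits, L, K = NULL) {
  stopifnot(is.data.frame(visits), all(c("cluster", "residence_time") %in% names(visits)))
  if (L < 1) abort("`L` must be at least 1.")
  v <- as.integer(visits$cluster)
  res <- visits$residence_time
  I <- length(v)
  if (I <= L) {
    abort(sprintf("Insufficient data: an order-%d model needs at least %d visits, got %d.",
                  L, L + 1L, I))
  }
  K <- as.integer(K %||% max(v))

  win <- stats::embed(v, L + 1L) # row j: (v[j+L], v[j+L-1], ..., v[j])
  hist_key <- do.call(paste, c(lapply((L + 1L):2, function(cl) win[, cl]), sep = "-"))
  successor <- win[, 1L]
  i_succ <- (L + 1L):I # visit index of each window's successor
  tau_ind <- (res[i_succ - 1L] + res[i_succ]) / 2

  table <- tibble::tibble(history = hist_key, successor = successor, tau = tau_ind) |>
    dplyr::group_by(.data$history, .data$successor) |>
    dplyr::summarise(count = dplyr::n(), time = mean(.data$tau), .groups = "drop_last") |>
    dplyr::mutate(q = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$history, .data$successor) |>
    dplyr::select("history", "successor", "count", "q", "time")

  structure(
    list(order = as.integer(L),
         K = K,
         table = table,
         n_windows = nrow(win),
         first_history = as.integer(win[1L, (L + 1L):2]),
         mean_transition_time = mean(tau_ind)),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition model: order L = %d, K = %d clusters\n", x$order, x$K))
  cat(sprintf("%d stored (history, successor) entries over %d histories (dense size K^(L+1) = %.3g)\n",
              nrow(x$table), dplyr::n_distinct(x$table$history),
              as.double(x$K)^(x$order + 1)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.transition_model <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.transition_model <- function(x, ...) {
  tibble::tibble(order = x$order, K = x$K,
                 n_entries = nrow(x$table),
                 n_histories = dplyr::n_distinct(x$table$history),
                 n_windows = x$n_windows,
                 dense_size = as.double(x$K)^(x$order + 1),
                 mean_transition_time = x$mean_transition_time)
}

#' Number of stored lookup-table entries
#'
#' The sparse lookup table stores only (history, successor) pairs that were
#' actually observed; compare with the dense tensor size `K^(L+1)` reported by
#' [glance()].
#'
#' @param model a `transition_model`.
#' @return Integer entry count.
#' @export
memory_footprint <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  nrow(model$table)
}

# Hash lookup: history key -> list(successors, q, cum, time). Built lazily and
# cached in the model's environment-backed field.
build_lookup <- function(model) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  tab <- model$table
  for (grp in split(seq_len(nrow(tab)), tab$history)) {
    h <- tab$history[grp[1]]
    assign(h, list(successors = tab$successor[grp],
                   q = tab$q[grp],
                   cum = cumsum(tab$q[grp]),
                   time = tab$time[grp]),
           envir = env)
  }
  env
}

key_of <- function(h) paste(h, collapse = "-")

# Look up a history, falling back to the longest stored suffix (ties broken by
# lexicographically smallest key). Returns list(entry, key) or NULL.
lookup_history <- function(lookup, h, L) {
  if (length(h) == L) {
    e <- get0(key_of(h), envir = lookup)
    if (!is.null(e)) return(list(entry = e, key = key_of(h), fallback = FALSE))
  }
  keys <- NULL
  for (m in rev(seq_len(min(length(h), L - 1L)))) {
    suffix <- paste0("-", key_of(tail(h, m)))
    if (is.null(keys)) keys <- ls(lookup, sorted = TRUE)
    hit <- keys[endsWith(keys, suffix)]
    if (length(hit)) {
      k <- hit[1]
      return(list(entry = get(k, envir = lookup), key = k, fallback = TRUE))
    }
  }
  NULL
}

#' First-order Markov baseline on raw snapshot labels
#'
#' The classical cluster-based Markov model against which the network model is
#' contrasted: transitions are counted between *consecutive snapshots*
#' (self-loops included), giving a column-stochastic matrix `P` with
#' `P[k, j] = Pr(label_{m+1} = k | label_m = j)`, and the cluster-population
#' vector evolves as `q^{l+1} = P q^l` with the sampling interval as time
#' step. Iterating converges to a stationary distribution: the dynamics
#' diffuse to a fixed point, which is precisely the behavior the network
#' model avoids.
#'
#' @param labels integer label vector or a `cluster_model`.
#' @param dt time step (taken from the `cluster_model` if given).
#' @param K number of clusters; defaults to the largest label.
#' @return A `markov_model` with fields `P` (K x K column-stochastic), `dt`,
#'   `stationary` (fixed point reached by power iteration from the empirical
#'   distribution), `K`.
#' @export
fit_markov_baseline <- function(labels, dt = NULL, K = NULL) {
  if (inherits(labels, "cluster_model")) {
    dt <- labels$dt
    labels <- labels$labels
  }
  if (is.null(dt) || dt <= 0) abort("`dt` must be a positive time step.")
  labels <- as.integer(labels)
  if (length(labels) < 2) abort("Need at least two snapshots.")
  K <- as.integer(K %||% max(labels))
  from <- labels[-length(labels)]
  to <- labels[-1]
  P <- matrix(0, K, K)
  counts <- table(factor(to, levels = 1:K), factor(from, levels = 1:K))
  P[] <- as.numeric(counts)
  nj <- colSums(P)
  never_left <- nj == 0 & tabulate(labels, K) > 0
  if (any(never_left)) {
    warn("Some clusters are never departed from; treating them as absorbing.")
    for (j in which(never_left)) P[j, j] <- 1
    nj[never_left] <- 1
  }
  present <- nj > 0
  P[, present] <- sweep(P[, present, drop = FALSE], 2, nj[present], `/`)
  P[cbind(which(!present), which(!present))] <- 1 # unvisited clusters: inert

  q <- tabulate(labels, K) / length(labels)
  for (it in seq_len(100000)) {
    q_new <- as.numeric(P %*% q)
    if (sum(abs(q_new - q)) < 1e-14) break
    q <- q_new
  }
  structure(list(P = P, dt = dt, stationary = q_new, K = K), class = "markov_model")
}

#' Evolve a Markov cluster-population vector
#'
#' Applies `q^{l+1} = P q^l` for `n_steps` steps.
#'
#' @param model a `markov_model`.
#' @param q0 initial probability vector (defaults to the empirical stationary
#'   start stored in the model is *not* used; must sum to 1).
#' @param n_steps number of steps.
#' @return Tibble with columns `step`, `cluster`, `q`.
#' @export
markov_evolve <- function(model, q0, n_steps) {
  stopifnot(inherits(model, "markov_model"), length(q0) == model$K)
  if (abs(sum(q0) - 1) > 1e-8) abort("`q0` must sum to 1.")
  out <- matrix(NA_real_, n_steps + 1L, model$K)
  out[1, ] <- q0
  q <- q0
  for (l in seq_len(n_steps)) {
    q <- as.numeric(model$P %*% q)
    out[l + 1L, ] <- q
  }
  tibble::tibble(step = rep(0:n_steps, each = model$K),
                 cluster = rep(seq_len(model$K), n_steps + 1L),
                 q = as.numeric(t(out)))
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("first-order Markov baseline: K = %d, dt = %g\n", x$K, x$dt))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.markov_model <- function(x, ...) {
  tibble::tibble(from = rep(seq_len(x$K), each = x$K),
                 to = rep(seq_len(x$K), x$K),
                 p = as.numeric(x$P)) |>
    dplyr::filter(.data$p > 0)
}
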
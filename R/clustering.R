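#' Coarse-grain snapshots into clusters with k-means++
#'
#' Partitions the snapshots into `K` clusters with k-means initialized by the
#' k-means++ seeding rule (each additional seed is drawn with probability
#' proportional to its squared distance from the nearest seed chosen so far).
#' The best of `restarts` independent seedings, by inner-cluster variance, is
#' returned. Centroids are the means of their member snapshots and become the
#' nodes of the network model.
#'
#' @inheritParams snapshot_matrix
#' @param K number of clusters, `1 <= K <= M`.
#' @param restarts number of independent k-means++ seedings.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param iter_max maximum k-means iterations per restart.
#' @return A `cluster_model` with fields `centroids` (K x N), `labels`
#'   (length-M integers in `1..K`), `K`, `inertia` (total within-cluster sum
#'   of squares), `sizes`, `dt`, `t0`.
#' @examples
#' cm <- fit_kmeanspp(simulate_lorenz(500, 0.015), K = 5, seed = 1)
#' glance(cm)
#' @export
fit_kmeanspp <- function(data, K, restarts = 10, seed = NULL, iter_max = 100) {
  validate_snapshots(data)
  x <- snapshot_matrix(data)
  m <- nrow(x)
  if (K < 1 || K > m) abort(sprintf("`K` must be in 1..M (M = %d).", m))
  dt <- snapshot_dt(data)

  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- NULL
      for (attempt in 1:5) { # re-seed on the rare empty-cluster failure
        centers <- kpp_seed_centers(x, K)
        fit <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers, iter.max = iter_max)),
          error = function(e) NULL
        )
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) abort("k-means failed repeatedly (empty clusters); reduce K.")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  centroids <- unname(best$centers)
  colnames(centroids) <- colnames(x)
  structure(
    list(centroids = centroids,
         labels = as.integer(best$cluster),
         K = as.integer(K),
         inertia = best$tot.withinss,
         sizes = as.integer(best$size),
         seed = seed,
         dt = dt,
         t0 = data$t[1],
         component_names = colnames(x)),
    class = "cluster_model"
  )
}

kpp_seed_centers <- function(x, K) {
  m <- nrow(x)
  idx <- integer(K)
  idx[1] <- sample.int(m, 1)
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
    for (k in 2:K) {
      if (!any(d2 > 0)) abort("Fewer distinct snapshots than requested clusters.")
      idx[k] <- sample.int(m, 1, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[k], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster model: K = %d, M = %d snapshots, inertia = %.6g\n",
              x$K, length(x$labels), x$inertia))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_model <- function(x, ...) {
  out <- tibble::as_tibble(x$centroids)
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$K), size = x$sizes), out)
}

#' @exportS3Method generics::glance
glance.cluster_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_snapshots = length(x$labels),
                 inertia = x$inertia, dt = x$dt)
}

#' Run-length encode cluster labels into a visit sequence
#'
#' Collapses the per-snapshot label sequence into the sequence of
#' consecutively visited clusters: consecutive equal labels are merged into a
#' single visit with entry time equal to the time of its first snapshot and
#' residence time equal to the run length times `dt`. Consecutive visits
#' always differ, so the number of intercluster transitions is the number of
#' visits minus one.
#'
#' @param labels integer label vector, or a `cluster_model` (its labels and
#'   `dt` are used).
#' @param dt sampling interval (ignored when `labels` is a `cluster_model`).
#' @param t0 time of the first snapshot.
#' @return Tibble with one row per visit: `cluster`, `entry_time`,
#'   `residence_time`, `n_snapshots`.
#' @export
extract_visit_sequence <- function(labels, dt = NULL, t0 = 0) {
  if (inherits(labels, "cluster_model")) {
    dt <- labels$dt
    t0 <- labels$t0
    labels <- labels$labels
  }
  if (is.null(dt) || dt <= 0) abort("`dt` must be a positive sampling interval.")
  if (length(labels) < 1) abort("`labels` must be non-empty.")
  r <- rle(as.integer(labels))
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  tibble::tibble(cluster = r$values,
                 entry_time = t0 + (starts - 1L) * dt,
                 residence_time = r$lengths * dt,
                 n_snapshots = r$lengths)
}

#' Assign states to their nearest centroid
#'
#' @param states numeric matrix (rows = states), a single state vector, or a
#'   snapshot-set tibble.
#' @param model a `cluster_model`.
#' @return Integer vector of cluster indices; ties broken by lowest index.
#' @export
assign_nearest_centroid <- function(states, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.data.frame(states)) states <- snapshot_matrix(states)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  cc <- model$centroids
  if (ncol(states) != ncol(cc)) {
    abort(sprintf("State dimension %d does not match centroid dimension %d.",
                  ncol(states), ncol(cc)))
  }
  d2 <- outer(rowSums(states^2), rep(1, nrow(cc))) +
    outer(rep(1, nrow(states)), rowSums(cc^2)) -
    2 * states %*% t(cc)
  as.integer(max.col(-d2, ties.method = "first"))
}
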
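#' Snapshot proper orthogonal decomposition
#'
#' Computes the snapshot-method POD of a snapshot set: the mean state is
#' subtracted and the fluctuation matrix is factored by SVD, giving
#' orthonormal spatial modes and per-snapshot mode coefficients ordered by
#' decreasing singular value. The decomposition is lossless by default (all
#' `min(M - 1, N)` modes are kept), so Euclidean distances between coefficient
#' vectors equal distances between the original snapshots. Clustering
#' high-dimensional states on POD coefficients therefore yields the same
#' result as clustering the states themselves, at a fraction of the cost.
#'
#' @inheritParams snapshot_matrix
#' @param n_modes optional truncation; keep only the leading `n_modes` modes
#'   (the decomposition is then lossy).
#' @return A `pod_basis` object with fields `mean_state`, `modes`
#'   (N x r, orthonormal columns), `coefficients` (M x r), `singular_values`,
#'   and the time stamps `t` of the snapshots.
#' @examples
#' basis <- compute_pod(simulate_lorenz(200, 0.015))
#' glance(basis)
#' @export
compute_pod <- function(data, n_modes = NULL) {
  validate_snapshots(data)
  x <- snapshot_matrix(data)
  m <- nrow(x)
  u0 <- colMeans(x)
  xc <- sweep(x, 2, u0)
  if (max(abs(xc)) == 0) abort("Degenerate data: all snapshots are identical (rank-0 fluctuation).")
  sv <- svd(xc)
  r <- min(m - 1L, ncol(x))
  if (!is.null(n_modes)) {
    if (n_modes < 1 || n_modes > r) abort(sprintf("`n_modes` must be in 1..%d.", r))
    r <- as.integer(n_modes)
  }
  structure(
    list(mean_state = u0,
         modes = sv$v[, seq_len(r), drop = FALSE],
         coefficients = sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r),
         singular_values = sv$d[seq_len(r)],
         component_names = colnames(x),
         t = data$t),
    class = "pod_basis"
  )
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("POD basis: %d modes, %d state components, %d snapshots\n",
              length(x$singular_values), nrow(x$modes), nrow(x$coefficients)))
  cat(sprintf("fluctuation energy: %.6g\n", sum(x$singular_values^2)))
  invisible(x)
}

#' Mode coefficients of a POD basis as a snapshot set
#'
#' Returns the coefficient time series `a_1(t), ..., a_r(t)` as a snapshot-set
#' tibble, ready to be clustered in place of the full states.
#'
#' @param basis a `pod_basis`.
#' @return Tibble with columns `t, a1, ..., ar`.
#' @export
pod_coefficients <- function(basis) {
  stopifnot(inherits(basis, "pod_basis"))
  a <- basis$coefficients
  colnames(a) <- paste0("a", seq_len(ncol(a)))
  dplyr::bind_cols(tibble::tibble(t = basis$t), tibble::as_tibble(a))
}

#' Reconstruct snapshots from a POD basis
#'
#' @param basis a `pod_basis`.
#' @return Snapshot-set tibble; equals the input of [compute_pod()] to
#'   numerical precision when no truncation was applied.
#' @export
pod_reconstruct <- function(basis) {
  stopifnot(inherits(basis, "pod_basis"))
  x <- basis$coefficients %*% t(basis$modes)
  x <- sweep(x, 2, basis$mean_state, `+`)
  colnames(x) <- basis$component_names
  dplyr::bind_cols(tibble::tibble(t = basis$t), tibble::as_tibble(x))
}

#' Euclidean distance between two POD coefficient vectors
#'
#' For a lossless POD this equals the full-state distance between the two
#' snapshots, which is what makes coefficient-space clustering exact.
#'
#' @param a_m,a_n coefficient vectors of equal length.
#' @return Non-negative scalar.
#' @export
coefficient_distance <- function(a_m, a_n) {
  if (length(a_m) != length(a_n)) abort("Coefficient vectors must have equal length.")
  sqrt(sum((a_m - a_n)^2))
}

#' @exportS3Method generics::tidy
tidy.pod_basis <- function(x, ...) {
  e <- x$singular_values^2
  tibble::tibble(mode = seq_along(e),
                 singular_value = x$singular_values,
                 energy = e,
                 energy_fraction = e / sum(e))
}

#' @exportS3Method generics::glance
glance.pod_basis <- function(x, ...) {
  tibble::tibble(n_modes = length(x$singular_values),
                 n_components = nrow(x$modes),
                 n_snapshots = nrow(x$coefficients),
                 total_energy = sum(x$singular_values^2))
}
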
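#' Build a snapshot set from a state matrix
#'
#' A *snapshot set* is the package's tabular representation of a uniformly
#' sampled multivariate time series: a tibble whose first column `t` holds the
#' sampling times and whose remaining numeric columns hold the state
#' components, one row per snapshot. All modeling functions take and return
#' this shape, so results chain with the pipe.
#'
#' @param states numeric matrix or data frame, rows = snapshots, columns =
#'   state components.
#' @param dt sampling interval (time units), strictly positive.
#' @param t0 time of the first snapshot.
#' @param component_names optional character vector of column names; defaults
#'   to the matrix column names or `x1, x2, ...`.
#' @return A tibble with columns `t, x1, ..., xN`.
#' @examples
#' snapshot_set(matrix(rnorm(20), ncol = 2), dt = 0.1)
#' @export
snapshot_set <- function(states, dt, t0 = 0, component_names = NULL) {
  states <- as.matrix(states)
  if (!is.numeric(states)) abort("`states` must be numeric.")
  if (nrow(states) < 2) abort("A snapshot set needs at least two snapshots (M >= 2).")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("`dt` must be a single positive number.")
  if (!all(is.finite(states))) abort("All state entries must be finite.")
  nm <- component_names %||% colnames(states) %||% paste0("x", seq_len(ncol(states)))
  colnames(states) <- nm
  out <- tibble::as_tibble(states)
  out <- dplyr::bind_cols(tibble::tibble(t = t0 + dt * (seq_len(nrow(states)) - 1)), out)
  out
}

#' Extract the state matrix of a snapshot set
#'
#' @param data snapshot set (tibble with a `t` column and numeric state columns).
#' @return Numeric matrix, rows = snapshots.
#' @export
snapshot_matrix <- function(data) {
  stopifnot(is.data.frame(data), "t" %in% names(data))
  as.matrix(data[setdiff(names(data), "t")])
}

#' Infer the sampling interval of a snapshot set
#'
#' Checks that the `t` column is uniformly spaced to a relative tolerance of
#' `1e-6` and returns the common interval.
#'
#' @inheritParams snapshot_matrix
#' @param tol relative tolerance on uniformity.
#' @return The sampling interval `dt`.
#' @export
snapshot_dt <- function(data, tol = 1e-6) {
  tt <- data$t
  if (length(tt) < 2) abort("A snapshot set needs at least two snapshots (M >= 2).")
  d <- diff(tt)
  dt <- stats::median(d)
  if (dt <= 0) abort("Time column must be strictly increasing.")
  bad <- which(abs(d - dt) > tol * dt)
  if (length(bad)) {
    abort(sprintf("Non-uniform sampling: row %d has spacing %.9g, expected %.9g.",
                  bad[1] + 1L, d[bad[1]], dt))
  }
  dt
}

validate_snapshots <- function(data) {
  x <- snapshot_matrix(data)
  if (nrow(x) < 2) abort("A snapshot set needs at least two snapshots (M >= 2).")
  if (ncol(x) < 1) abort("A snapshot set needs at least one state component.")
  if (anyNA(x) || !all(is.finite(x))) abort("Snapshot data contain NaN/Inf entries.")
  invisible(data)
}

#' Read a snapshot set from delimited text
#'
#' Expects a header row `t,x1,...,xN` with the time in the first column. The
#' time column must be uniformly spaced (relative tolerance `1e-6`); the
#' sampling interval is inferred from it.
#'
#' @param path file path of a comma-separated file.
#' @return A snapshot-set tibble.
#' @seealso [write_snapshots()]
#' @export
read_snapshots <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  # base read.csv: its strtod parse is correctly rounded, so the write/read
  # round trip is bitwise lossless
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"t" %in% names(out)) names(out)[1] <- "t"
  validate_snapshots(out)
  snapshot_dt(out)
  out
}

#' Write a snapshot set as delimited text
#'
#' Values are written with 17 significant digits so a read/write round trip is
#' lossless for doubles.
#'
#' @inheritParams snapshot_matrix
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(data, path) {
  validate_snapshots(data)
  df <- as.data.frame(lapply(data, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Superimpose uniformly distributed noise on a snapshot set
#'
#' Adds i.i.d. noise drawn uniformly from `[-level * A_i, +level * A_i]` to
#' each state component, where `A_i` is the RMS amplitude (standard deviation)
#' of the clean component. Noise is independent across components and
#' snapshots. This emulates a measured signal whose noise floor scales with
#' the signal's own fluctuation level.
#'
#' @inheritParams snapshot_matrix
#' @param level noise level as a fraction of the component amplitude
#'   (e.g. `0.1` for 10% noise); must be non-negative.
#' @param seed integer seed; the result is reproducible given the seed.
#' @return A snapshot-set tibble of the same shape.
#' @export
add_uniform_noise <- function(data, level, seed = NULL) {
  validate_snapshots(data)
  if (!is.numeric(level) || length(level) != 1 || level < 0) {
    abort("`level` must be a single non-negative number.")
  }
  if (level == 0) return(data)
  x <- snapshot_matrix(data)
  amp <- apply(x, 2, sd)
  noise_fun <- function() {
    matrix(runif(length(x), -1, 1), nrow = nrow(x)) %*% diag(level * amp, ncol(x))
  }
  noisy <- if (is.null(seed)) noise_fun() else withr::with_seed(seed, noise_fun())
  out <- data
  out[setdiff(names(data), "t")] <- tibble::as_tibble(x + noisy, .name_repair = "minimal")
  out
}
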
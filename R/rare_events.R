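#' Detect bursts in a scalar observable
#'
#' A burst is a maximal run of samples at or above the threshold; its onset is
#' the first exceeding sample. The threshold is deliberately user-chosen
#' ("what counts as rare" is an application decision); for the burst surrogate
#' the package convention is `mean + 4 * sd` of the series.
#'
#' @param series 1-D snapshot set (tibble `t` plus one component) or numeric
#'   vector.
#' @param threshold scalar in observable units.
#' @return Tibble with one row per burst: `start`, `end` (1-based snapshot
#'   indices), `onset` (= `start`), and `onset_time` when times are available;
#'   the threshold is attached as attribute `"threshold"`.
#' @export
detect_bursts <- function(series, threshold) {
  tt <- NULL
  if (is.data.frame(series)) {
    tt <- series$t
    x <- as.numeric(snapshot_matrix(series)[, 1])
  } else {
    x <- as.numeric(series)
  }
  if (!all(is.finite(x))) abort("Series must be finite.")
  if (threshold <= min(x)) warn("Threshold is at or below the series minimum: the whole series is one burst.")
  above <- x >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble::tibble(start = starts[keep], end = ends[keep])
  out$onset <- out$start
  if (!is.null(tt)) out$onset_time <- tt[out$onset]
  attr(out, "threshold") <- threshold
  out
}

#' Embed a scalar series in (value, derivative) phase space
#'
#' Appends the time derivative, computed by central finite differences
#' (one-sided at the endpoints), as a second state component. Bursting scalar
#' signals become loops in this plane, with burst onsets concentrated in a
#' localized region — the geometry the burst forecast exploits.
#'
#' @param series 1-D snapshot set (tibble `t` plus one component).
#' @return Snapshot-set tibble with the original component and `d<component>`.
#' @export
phase_embed <- function(series) {
  validate_snapshots(series)
  x <- snapshot_matrix(series)
  if (ncol(x) != 1) abort("`phase_embed()` expects a single-component series.")
  m <- nrow(x)
  if (m < 3) abort("Need at least three snapshots for central differences.")
  dt <- snapshot_dt(series)
  v <- as.numeric(x)
  d <- c(v[2] - v[1],
         (v[3:m] - v[1:(m - 2)]) / 2,
         v[m] - v[m - 1]) / dt
  nm <- colnames(x)[1]
  out <- series
  out[[paste0("d", nm)]] <- d
  out
}

#' Per-history burst probability and previewing time
#'
#' For every stored history h of the fitted network, the burst probability is
#' the total direct-transition probability into *onset clusters* (clusters
#' containing at least one burst-onset snapshot):
#' `P_burst(h) = sum_{s in onset set} Q(s | h)`. The previewing time is the
#' expected transition time conditional on such a burst-bound flight,
#' `sum Q(s|h) T(s|h) / P_burst(h)`: how far ahead of the onset the model
#' flags the event.
#'
#' @param model a `transition_model` fitted on the (embedded) series.
#' @param clusters the matching `cluster_model`.
#' @param annotation burst annotation from [detect_bursts()] on the training
#'   series.
#' @param labels per-snapshot cluster labels of the training series (defaults
#'   to `clusters$labels`).
#' @return Tibble with one row per stored history: `history`,
#'   `burst_probability`, `previewing_time` (`NA` where the probability is 0).
#' @export
burst_forecast <- function(model, clusters, annotation, labels = NULL) {
  stopifnot(inherits(model, "transition_model"), inherits(clusters, "cluster_model"))
  labels <- labels %||% clusters$labels
  onset_clusters <- unique(labels[annotation$onset])
  if (length(onset_clusters) == 0) {
    warn("Empty onset set: returning an all-zero forecast.")
  }
  model$table |>
    dplyr::group_by(.data$history) |>
    dplyr::summarise(
      burst_probability = sum(.data$q[.data$successor %in% onset_clusters]),
      .expected = sum((.data$q * .data$time)[.data$successor %in% onset_clusters]),
      .groups = "drop"
    ) |>
    dplyr::mutate(previewing_time = ifelse(.data$burst_probability > 0,
                                           .data$.expected / .data$burst_probability,
                                           NA_real_)) |>
    dplyr::select("history", "burst_probability", "previewing_time")
}

#' Compare burst counts between data and model
#'
#' Applies the same threshold to the training series annotation and to a
#' model-generated observable (already resampled at the training interval) and
#' returns both counts.
#'
#' @param data_annotation burst annotation of the data, from [detect_bursts()].
#' @param model_series 1-D snapshot set generated by the model.
#' @param threshold the common threshold; defaults to the annotation's.
#' @return Tibble with columns `data_count`, `model_count`.
#' @export
burst_count_match <- function(data_annotation, model_series, threshold = NULL) {
  threshold <- threshold %||% attr(data_annotation, "threshold")
  if (is.null(threshold)) abort("`threshold` is required.")
  model_ann <- detect_bursts(model_series, threshold)
  tibble::tibble(data_count = nrow(data_annotation), model_count = nrow(model_ann))
}
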
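#' Phase-space plot of a cluster model
#'
#' Scatters the first two state components colored by cluster affiliation,
#' with centroids overlaid, reproducing the usual coarse-graining picture.
#'
#' @param object a `cluster_model`.
#' @param data optional snapshot set to scatter; defaults to centroids only.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_model <- function(object, data = NULL, ...) {
  cen <- tidy(object)
  comps <- object$component_names[1:2]
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    df <- tibble::as_tibble(data)
    df$cluster <- factor(object$labels)
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data[[comps[1]]], y = .data[[comps[2]]], color = .data$cluster),
      size = 0.3, alpha = 0.5, show.legend = FALSE)
  }
  p +
    ggplot2::geom_point(data = cen,
                        ggplot2::aes(x = .data[[comps[1]]], y = .data[[comps[2]]]),
                        shape = 21, fill = "white", color = "black", size = 2) +
    ggplot2::labs(title = sprintf("k-means++ coarse-graining, K = %d", object$K))
}

#' Scree plot of a POD basis
#'
#' @param object a `pod_basis`.
#' @param ... unused.
#' @return A ggplot object showing the energy fraction per mode.
#' @exportS3Method ggplot2::autoplot
autoplot.pod_basis <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$mode, y = .data$energy_fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mode", y = "energy fraction")
}

#' Time-series plot of a model trajectory
#'
#' Resamples the trajectory uniformly and plots each state component against
#' time, one facet per component.
#'
#' @param object a `cnm_trajectory`.
#' @param dt resampling interval (defaults to the training interval).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnm_trajectory <- function(object, dt = NULL, ...) {
  df <- resample_uniform(object, dt)
  long <- tidyr::pivot_longer(df, -"t", names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time")
}

#' Compare autocorrelation curves of data and model
#'
#' @param ref reference curve (tibble `lag`, `R`).
#' @param model optional model curve.
#' @return A ggplot object.
#' @export
plot_autocorrelation <- function(ref, model = NULL) {
  df <- dplyr::bind_rows(data = ref, model = model, .id = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$R, color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(data = "black", model = "red")) +
    ggplot2::labs(x = "time lag", y = "R")
}

#' Compare cluster probability distributions of data and model
#'
#' @param data_cpd CPD tibble of the data (from [cluster_probability()]).
#' @param model_cpd optional CPD tibble of the model.
#' @return A ggplot object.
#' @export
plot_cluster_probability <- function(data_cpd, model_cpd = NULL) {
  df <- dplyr::bind_rows(data = data_cpd, model = model_cpd, .id = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$p,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(data = "black", model = "red")) +
    ggplot2::labs(x = "cluster", y = "probability")
}

#' Plot a scalar series with detected bursts highlighted
#'
#' @param series 1-D snapshot set.
#' @param annotation burst annotation from [detect_bursts()].
#' @return A ggplot object; the threshold is drawn as a dashed line and burst
#'   onsets as points.
#' @export
plot_bursts <- function(series, annotation) {
  nm <- setdiff(names(series), "t")[1]
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$t, y = .data[[nm]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = attr(annotation, "threshold"), linetype = "dashed")
  if (nrow(annotation)) {
    on <- series[annotation$onset, ]
    p <- p + ggplot2::geom_point(data = on, color = "red")
  }
  p
}
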
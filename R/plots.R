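# ggplot2 visualisations for the main result types.

#' @export
autoplot.bcr_overlap <- function(object, threshold = 0.005, ...) {
  d <- object$shared
  if (nrow(d) == 0) {
    rlang::warn("no shared clones to plot")
  }
  eps <- 1e-6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_a + eps,
                                  y = .data$freq_b + eps)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = .data$dominant_a & .data$dominant_b
    ), alpha = 0.7) +
    ggplot2::scale_x_log10(labels = function(x) fmt_pct(x, 2)) +
    ggplot2::scale_y_log10(labels = function(x) fmt_pct(x, 2)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 name = "dominant in both") +
    ggplot2::labs(
      x = sprintf("clone frequency in %s", object$pair[["a"]]),
      y = sprintf("clone frequency in %s", object$pair[["b"]]),
      title = "Shared-clone frequencies across samples"
    ) +
    ggplot2::theme_minimal()
}

#' Paired before/after plot of a per-sample clonality metric
#'
#' Draws per-patient lines between baseline and week-9 values of a metric
#' (e.g. `impact` or `n_dominant`) in one compartment.
#'
#' @param hec A [call_dominant()] summary with `patient_id`, `compartment`,
#'   `timepoint`.
#' @param metric Column to plot (default `"impact"`).
#' @param compartment Compartment to keep (default `"blood"`).
#' @return A ggplot object.
#' @export
plot_impact_paired <- function(hec, metric = "impact",
                               compartment = "blood") {
  d <- dplyr::filter(hec, .data$compartment == !!compartment)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data[[metric]],
                                  group = .data$patient_id)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("%s in %s before and after treatment",
                                  metric, compartment)) +
    ggplot2::theme_minimal()
}

#' Diversity indices by compartment
#'
#' Scatter of per-sample Simpson, Shannon and Gini values split by
#' compartment, faceted per index.
#'
#' @param summaries A [summarize_repertoire()] table with `compartment`.
#' @return A ggplot object.
#' @export
plot_diversity <- function(summaries) {
  d <- summaries |>
    dplyr::select(dplyr::all_of(c("sample_id", "compartment", "simpson",
                                  "shannon", "gini"))) |>
    tidyr::pivot_longer(c("simpson", "shannon", "gini"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Repertoire diversity by compartment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bcr_association_suite <- function(object, ...) {
  d <- dplyr::filter(object$results, !is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pair,
                                                     -.data$p_value),
                                  y = -log10(.data$p_value))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant)) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Clinical association panel (unadjusted)") +
    ggplot2::theme_minimal()
}
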
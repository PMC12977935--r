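# ggplot2 views of the package's result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DMC state matrix
#'
#' Tile plot of character states at a DMC's sites across taxa; the query
#' taxon's row (bottom) equals the DMC itself. Cells carrying the
#' diagnostic state are outlined.
#'
#' @param object A `dmc_state_matrix` from [dmc_state_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmc_state_matrix
#' @export
autoplot.dmc_state_matrix <- function(object, ...) {
  sites <- attr(object, "sites")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"taxon",
                              names_to = "column", values_to = "state") |>
    dplyr::mutate(position = as.integer(sub("^pos_", "", .data$column)))
  dmc_states <- stats::setNames(sites$state, sites$position)
  long$is_dmc_state <- long$state == unname(dmc_states[as.character(long$position)])
  long$taxon <- factor(long$taxon, levels = rev(object$taxon))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$state), colour = "grey40") +
    ggplot2::geom_tile(data = ~dplyr::filter(.x, .data$is_dmc_state),
                       fill = NA, colour = "black", linewidth = 0.9) +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), size = 3) +
    ggplot2::labs(x = "alignment position", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot per-taxon classification metrics
#'
#' @param object A `dmc_metrics` table from [evaluate_dmcs()].
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmc_metrics
#' @export
autoplot.dmc_metrics <- function(object,
                                 metrics = c("recall", "precision",
                                             "specificity", "accuracy", "f1"),
                                 ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot site uniqueness weights along the alignment
#'
#' @param weights A tibble from [site_weights()].
#' @param highlight Optional integer positions to mark (e.g. a DMC's
#'   sites).
#' @return A ggplot object.
#' @export
plot_site_weights <- function(weights, highlight = integer()) {
  ggplot2::ggplot(weights, ggplot2::aes(x = .data$position,
                                        y = .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          colour = "grey55") +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$position %in% highlight),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "alignment position", y = "uniqueness weight") +
    ggplot2::theme_minimal()
}
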
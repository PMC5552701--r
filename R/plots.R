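# ggplot2 views of the map objects.

#' Plot a linkage map
#'
#' Markers as ticks along their linkage groups, positions increasing
#' downwards as in conventional map drawings.
#'
#' @param object A `linkage_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_map <- function(object, ...) {
  tbl <- tidy(object)
  tbl$panel <- ifelse(is.na(tbl$chromosome), tbl$linkage_group,
                      paste0(tbl$chromosome, " (", tbl$linkage_group, ")"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$panel, y = .data$position)) +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Position (cM)") +
    ggplot2::theme_minimal()
}

#' Plot a consensus map
#'
#' Marker ticks along chromosomes, coloured by the number of source maps
#' supporting each marker.
#'
#' @param object A `consensus_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_map <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$chromosome,
                                    y = .data$position,
                                    colour = factor(.data$n_maps))) +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Consensus position (cM)",
                  colour = "Source maps") +
    ggplot2::theme_minimal()
}

#' Plot an interval profile
#'
#' Per-window marker and recombinant-bin counts along each chromosome.
#'
#' @param profile An `interval_profile` from [interval_profile()].
#' @return A ggplot object.
#' @export
plot_interval_profile <- function(profile) {
  stopifnot(inherits(profile, "interval_profile"))
  long <- profile$windows |>
    tidyr::pivot_longer(c("n_markers", "n_bins"), names_to = "what",
                        values_to = "count") |>
    dplyr::mutate(what = dplyr::recode(.data$what, n_markers = "markers",
                                       n_bins = "bins"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start,
                                     y = .data$count,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = sprintf("Position (%g cM windows)", profile$window),
                  y = "Count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot genetic versus physical marker positions
#'
#' The classic per-chromosome scatter of consensus position (cM) against
#' physical coordinate, from [physical_concordance()].
#'
#' @param concordance The list returned by [physical_concordance()].
#' @return A ggplot object.
#' @export
plot_physical_concordance <- function(concordance) {
  ggplot2::ggplot(concordance$table,
                  ggplot2::aes(x = .data$position,
                               y = .data$physical_position)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~chromosome, scales = "free") +
    ggplot2::labs(x = "Genetic position (cM)", y = "Physical position") +
    ggplot2::theme_minimal()
}
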
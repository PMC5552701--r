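# broom-style tidiers for the map objects.

#' Tidy a linkage map
#'
#' @param x A `linkage_map`.
#' @param ... Unused.
#' @return The per-marker tibble (`marker`, `linkage_group`, `chromosome`,
#'   `position`, `bin_id`, `is_frame`) without attributes.
#' @export
tidy.linkage_map <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a linkage map
#'
#' @param x A `linkage_map`.
#' @param ... Unused.
#' @return Tibble: `n_markers`, `n_frame`, `n_groups`, `n_unlinked`,
#'   `total_length`, `density`.
#' @export
glance.linkage_map <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_frame = sum(x$is_frame),
    n_groups = dplyr::n_distinct(x$linkage_group),
    n_unlinked = length(attr(x, "unlinked") %||% character(0)),
    total_length = attr(x, "total_length"),
    density = attr(x, "density")
  )
}

#' Tidy a consensus map
#'
#' @param x A `consensus_map`.
#' @param ... Unused.
#' @return The per-marker tibble without attributes.
#' @export
tidy.consensus_map <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a consensus map
#'
#' @param x A `consensus_map`.
#' @param ... Unused.
#' @return Tibble: `n_markers`, `n_bins`, `n_chromosomes`, `total_length`,
#'   `density` (markers/cM, half-up to 2 decimals), `n_conflicts`.
#' @export
glance.consensus_map <- function(x, ...) {
  total_length <- sum(dplyr::summarise(
    as_tibble(x), len = max(.data$position), .by = "chromosome")$len)
  tibble(
    n_markers = nrow(x),
    n_bins = dplyr::n_distinct(x$bin_id),
    n_chromosomes = dplyr::n_distinct(x$chromosome),
    total_length = total_length,
    density = round_half_up(nrow(x) / total_length, 2),
    n_conflicts = nrow(conflict_log(x))
  )
}
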
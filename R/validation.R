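# Map validation: order concordance, reference classification, marker
# sharing and interval structure.

#' Spearman rank correlation between two maps' marker orders
#'
#' Computed over shared markers, optionally restricted to one chromosome;
#' ties are mid-ranked. Fewer than 3 shared markers gives `NA`.
#'
#' @param map_a,map_b Data frames with `marker`, `position` and (if
#'   `chromosome` is given) a `chromosome` column.
#' @param chromosome Optional chromosome to restrict to.
#' @return Spearman rho (scalar), or `NA` if undefined.
#' @export
spearman_order <- function(map_a, map_b, chromosome = NULL) {
  if (!is.null(chromosome)) {
    map_a <- map_a[!is.na(map_a$chromosome) &
                     map_a$chromosome == chromosome, , drop = FALSE]
    map_b <- map_b[!is.na(map_b$chromosome) &
                     map_b$chromosome == chromosome, , drop = FALSE]
  }
  shared <- intersect(map_a$marker, map_b$marker)
  if (length(shared) < 3) return(NA_real_)
  suppressWarnings(cor(
    map_a$position[match(shared, map_a$marker)],
    map_b$position[match(shared, map_b$marker)],
    method = "spearman"
  ))
}

#' Classify a map's markers against a reference map
#'
#' Each query marker is *consistent* (same chromosome in both maps),
#' *inconsistent* (present in the reference on a different chromosome) or
#' *new* (absent from the reference). Counts are reported per query
#' chromosome plus an overall row; the Spearman rho per chromosome is
#' computed on consistent markers only.
#'
#' @param query,reference Data frames with `marker`, `chromosome`,
#'   `position`.
#' @return Tibble `chromosome`, `n_query`, `n_shared`, `n_consistent`,
#'   `n_new`, `n_inconsistent`, `spearman_rho`, with a final `total` row.
#' @export
classify_vs_reference <- function(query, reference) {
  q <- as_tibble(query)[, c("marker", "chromosome", "position")]
  r <- as_tibble(reference)[, c("marker", "chromosome", "position")]
  joined <- dplyr::left_join(q, r, by = "marker",
                             suffix = c("_q", "_r"))
  joined$status <- dplyr::case_when(
    is.na(joined$chromosome_r) ~ "new",
    joined$chromosome_q == joined$chromosome_r ~ "consistent",
    TRUE ~ "inconsistent"
  )
  per <- joined |>
    dplyr::summarise(
      n_query = dplyr::n(),
      n_shared = sum(.data$status != "new"),
      n_consistent = sum(.data$status == "consistent"),
      n_new = sum(.data$status == "new"),
      n_inconsistent = sum(.data$status == "inconsistent"),
      spearman_rho = if (sum(.data$status == "consistent") >= 3) {
        suppressWarnings(cor(
          .data$position_q[.data$status == "consistent"],
          .data$position_r[.data$status == "consistent"],
          method = "spearman"
        ))
      } else NA_real_,
      .by = "chromosome_q"
    ) |>
    dplyr::rename(chromosome = "chromosome_q") |>
    dplyr::arrange(.data$chromosome)
  total <- tibble(
    chromosome = "total",
    n_query = nrow(joined),
    n_shared = sum(joined$status != "new"),
    n_consistent = sum(joined$status == "consistent"),
    n_new = sum(joined$status == "new"),
    n_inconsistent = sum(joined$status == "inconsistent"),
    spearman_rho = if (sum(joined$status == "consistent") >= 3) {
      suppressWarnings(cor(
        joined$position_q[joined$status == "consistent"],
        joined$position_r[joined$status == "consistent"],
        method = "spearman"
      ))
    } else NA_real_
  )
  dplyr::bind_rows(per, total)
}

#' Marker-sharing (Venn) categories across maps
#'
#' Counts how many markers occur in exactly 1, 2, ..., n of the maps; the
#' categories partition the distinct-marker union.
#'
#' @param maps List (≥ 2) of data frames with a `marker` column.
#' @return Tibble `n_maps_sharing`, `n_markers`, with the union size in the
#'   `n_union` attribute.
#' @export
venn_sharing <- function(maps) {
  stopifnot(length(maps) >= 2)
  sets <- lapply(maps, function(m) unique(m$marker))
  union_markers <- unique(unlist(sets))
  times <- table(factor(unlist(sets), levels = union_markers))
  out <- tibble(
    n_maps_sharing = seq_along(maps),
    n_markers = as.integer(tabulate(times, nbins = length(maps)))
  )
  attr(out, "n_union") <- length(union_markers)
  out
}

#' Interval profile of a map
#'
#' Cuts each chromosome into half-open windows `[0, w), [w, 2w), ...`
#' anchored at 0, counts markers and recombinant bins per window, computes
#' the Pearson correlation between the two per-window counts for each
#' chromosome, and lists adjacent distinct positions further apart than the
#' gap threshold.
#'
#' @param map Data frame `marker`, `chromosome`, `position`, optionally
#'   `bin_id` (without it each distinct position is a bin).
#' @param window Window width in cM (default 5).
#' @param gap_threshold Gap size in cM above which an interval is reported
#'   (default 10; strictly greater).
#' @return An `interval_profile` list: `windows` (tibble `chromosome`,
#'   `window_start`, `n_markers`, `n_bins`), `gaps` (tibble `chromosome`,
#'   `from_position`, `to_position`, `gap`), `correlations` (tibble
#'   `chromosome`, `pearson_r`; `NA` when undefined).
#' @export
interval_profile <- function(map, window = 5, gap_threshold = 10) {
  stopifnot(nrow(map) > 0, window > 0)
  tbl <- as_tibble(map)
  if (!"bin_id" %in% names(tbl)) {
    tbl <- tbl |>
      dplyr::mutate(bin_id = paste0(.data$chromosome, "@", .data$position))
  }
  tbl$window_start <- floor(tbl$position / window) * window

  windows <- tbl |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_bins = dplyr::n_distinct(.data$bin_id),
      .by = c("chromosome", "window_start")
    ) |>
    dplyr::arrange(.data$chromosome, .data$window_start)
  # include empty interior windows so distributions are comparable
  windows <- tbl |>
    dplyr::summarise(max_pos = max(.data$position), .by = "chromosome") |>
    purrr::pmap(function(chromosome, max_pos) {
      tibble(chromosome = chromosome,
             window_start = seq(0, floor(max_pos / window) * window,
                                by = window))
    }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(windows, by = c("chromosome", "window_start")) |>
    tidyr::replace_na(list(n_markers = 0L, n_bins = 0L))

  gaps <- tbl |>
    dplyr::distinct(.data$chromosome, .data$position) |>
    dplyr::arrange(.data$chromosome, .data$position) |>
    dplyr::mutate(to_position = dplyr::lead(.data$position),
                  .by = "chromosome") |>
    dplyr::filter(!is.na(.data$to_position),
                  .data$to_position - .data$position > gap_threshold) |>
    dplyr::transmute(chromosome = .data$chromosome,
                     from_position = .data$position,
                     to_position = .data$to_position,
                     gap = .data$to_position - .data$position)

  correlations <- windows |>
    dplyr::summarise(
      pearson_r = if (dplyr::n() >= 2 &&
                        stats::sd(.data$n_markers) > 0 &&
                        stats::sd(.data$n_bins) > 0) {
        cor(.data$n_markers, .data$n_bins)
      } else NA_real_,
      .by = "chromosome"
    )
  structure(
    list(windows = windows, gaps = gaps, correlations = correlations,
         window = window, gap_threshold = gap_threshold),
    class = "interval_profile"
  )
}
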
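# Anchoring markers to chromosomes, arms, physical positions and deletion
# bins from tabular homology hits.

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read tabular homology hits (BLAST outfmt 6)
#'
#' Twelve tab-separated columns without header: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. Malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to the tabular hit file.
#' @return Tibble with the twelve standard columns.
#' @export
read_blast_tab <- function(path) {
  out <- readr::read_tsv(path, col_names = .blast_cols,
                         col_types = "ccdiiiiiiidd",
                         na = character(), progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed hit rows at line(s): ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  if (any(out$evalue < 0)) {
    stop("negative E-values at line(s): ",
         paste(which(out$evalue < 0), collapse = ", "), call. = FALSE)
  }
  out
}

#' Best hit per marker under an E-value threshold
#'
#' Hits with E-value at or above the threshold are discarded (strictly
#' smaller passes); among the rest the minimum-E-value hit per query is
#' kept, ties broken by higher identity then lexicographic subject id.
#' Output is stable under reordering of the input rows.
#'
#' @param hits Tibble of hits (from [read_blast_tab()], or any data frame
#'   with `qseqid`, `sseqid`, `pident`, `evalue` and coordinate columns).
#' @param e_threshold E-value cutoff (default 1e-10).
#' @return Tibble with one row per query marker that has a passing hit.
#' @export
best_hit <- function(hits, e_threshold = 1e-10) {
  as_tibble(hits) |>
    dplyr::filter(.data$evalue < e_threshold) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$pident),
                   .data$sseqid) |>
    dplyr::slice_head(n = 1, by = "qseqid")
}

#' Assign mapped markers to chromosome bins through linked ESTs
#'
#' ESTs occurring several times at one chromosomal location (chromosome +
#' bin) are deduplicated; SNP markers inherit bins through their linked
#' ESTs. An EST whose bin lies on a different chromosome than the marker's
#' map chromosome is logged as a cross-assignment and excluded. Coverage
#' per chromosome is the fraction of that chromosome's bins hit, as a
#' half-up-rounded percentage (1 decimal).
#'
#' @param map Data frame `marker`, `chromosome` (the genetic map side).
#' @param snp_est Link table `marker`, `est_id`.
#' @param est_bin Table `est_id`, `chromosome`, `bin_id`; its distinct
#'   (chromosome, bin) pairs define the per-chromosome bin denominators.
#' @return List: `assignments` (tibble `marker`, `chromosome`, `bin_id`,
#'   `est_id`), `summary` (per chromosome, genome and total: `n_ests`,
#'   `n_snps`, `corresponding_bins`, `all_bins`, `coverage`),
#'   `cross_assignments` (excluded links).
#' @export
assign_bins <- function(map, snp_est, est_bin) {
  map <- as_tibble(map)
  est_bin <- as_tibble(est_bin) |>
    dplyr::distinct(.data$est_id, .data$chromosome, .data$bin_id)
  all_bins <- est_bin |>
    dplyr::distinct(.data$chromosome, .data$bin_id) |>
    dplyr::count(.data$chromosome, name = "all_bins")

  links <- as_tibble(snp_est) |>
    dplyr::inner_join(map[, c("marker", "chromosome")], by = "marker") |>
    dplyr::inner_join(est_bin, by = "est_id",
                      suffix = c("_map", "_bin"),
                      relationship = "many-to-many")
  cross <- links |>
    dplyr::filter(.data$chromosome_map != .data$chromosome_bin)
  assignments <- links |>
    dplyr::filter(.data$chromosome_map == .data$chromosome_bin) |>
    dplyr::transmute(marker = .data$marker,
                     chromosome = .data$chromosome_map,
                     bin_id = .data$bin_id, est_id = .data$est_id) |>
    dplyr::distinct()

  per_chrom <- assignments |>
    dplyr::summarise(
      n_ests = dplyr::n_distinct(.data$est_id),
      n_snps = dplyr::n_distinct(.data$marker),
      corresponding_bins = dplyr::n_distinct(.data$bin_id),
      .by = "chromosome"
    ) |>
    dplyr::right_join(all_bins, by = "chromosome") |>
    tidyr::replace_na(list(n_ests = 0L, n_snps = 0L,
                           corresponding_bins = 0L)) |>
    dplyr::arrange(.data$chromosome)
  summary <- bin_coverage(per_chrom)
  list(assignments = assignments, summary = summary,
       cross_assignments = cross)
}

#' Aggregate bin-coverage statistics
#'
#' Takes per-chromosome counts of linked ESTs and SNPs, bins hit
#' (`corresponding_bins`) and bin denominators (`all_bins`) and adds
#' per-genome and total rows; coverage is `100 * corresponding / all`,
#' rounded half-up to 1 decimal.
#'
#' @param per_chromosome Data frame `chromosome`, `n_ests`, `n_snps`,
#'   `corresponding_bins`, `all_bins`.
#' @param nomenclature Optional chromosome nomenclature table.
#' @return Tibble `class`, `level`, `n_ests`, `n_snps`,
#'   `corresponding_bins`, `all_bins`, `coverage`.
#' @export
bin_coverage <- function(per_chromosome, nomenclature = NULL) {
  tbl <- as_tibble(per_chromosome)
  parsed <- parse_chromosome(tbl$chromosome, nomenclature)
  tbl$genome <- parsed$genome
  agg <- function(df, class, level) {
    tibble(
      class = class, level = as.character(level),
      n_ests = sum(df$n_ests), n_snps = sum(df$n_snps),
      corresponding_bins = sum(df$corresponding_bins),
      all_bins = sum(df$all_bins),
      coverage = round_half_up(
        100 * sum(df$corresponding_bins) / sum(df$all_bins), 1)
    )
  }
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    agg(tbl[i, ], "chromosome", tbl$chromosome[i])
  })
  for (g in unique(tbl$genome[!is.na(tbl$genome)])) {
    rows <- c(rows, list(agg(tbl[which(tbl$genome == g), ], "genome", g)))
  }
  rows <- c(rows, list(agg(tbl, "total", "total")))
  dplyr::bind_rows(rows)
}

#' Concordance between genetic and physical marker orders
#'
#' Joins a map with best physical hits and computes, per chromosome with at
#' least 3 anchored markers, the Spearman rank correlation between genetic
#' position (cM) and physical coordinate; also returns the joined table for
#' plotting.
#'
#' @param map Data frame `marker`, `chromosome`, `position`.
#' @param physical Data frame `marker`, `physical_position` (e.g. the
#'   midpoint of the best hit's subject coordinates), optionally
#'   `chromosome` (then only same-chromosome anchors are used).
#' @return List: `correlations` (tibble `chromosome`, `n`, `spearman_rho`)
#'   and `table` (tibble `marker`, `chromosome`, `position`,
#'   `physical_position`).
#' @export
physical_concordance <- function(map, physical) {
  physical <- as_tibble(physical)
  joined <- as_tibble(map)[, c("marker", "chromosome", "position")] |>
    dplyr::inner_join(physical, by = "marker",
                      suffix = c("", "_phys"))
  if ("chromosome_phys" %in% names(joined)) {
    joined <- joined |>
      dplyr::filter(.data$chromosome == .data$chromosome_phys) |>
      dplyr::select(-"chromosome_phys")
  }
  correlations <- joined |>
    dplyr::summarise(
      n = dplyr::n(),
      spearman_rho = if (dplyr::n() >= 3) {
        suppressWarnings(cor(.data$position, .data$physical_position,
                             method = "spearman"))
      } else NA_real_,
      .by = "chromosome"
    ) |>
    dplyr::arrange(.data$chromosome)
  list(correlations = correlations, table = joined)
}
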
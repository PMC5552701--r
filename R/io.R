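# Readers and writers for the package's TSV dialects. All writers are
# idempotent: writing the same object twice yields byte-identical files.

#' Write / read a genotype table
#'
#' TSV with a header row (`marker`, then line ids) and one row per marker;
#' missing calls are written as `-`.
#'
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a genotype tibble.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- genotypes
  out[is.na(out)] <- "-"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), .default = readr::col_character()
  ), na = "-", progress = FALSE)
}

#' Write / read a linkage or true map
#'
#' TSV columns: `marker`, `linkage_group`, `chromosome`, `position_cM`,
#' `bin_id`, `is_frame`; absent fields are filled with `NA` on write and
#' tolerated on read. True maps (`marker`, `chromosome`, `position`,
#' `genome`, `homoeo_group`) round-trip through the same dialect.
#'
#' @param map A `linkage_map`, `consensus_map` or compatible tibble.
#' @param path File path.
#' @return `write_map()` returns `path` invisibly; `read_map()` a tibble
#'   with `marker`, `linkage_group`, `chromosome`, `position`, `bin_id`,
#'   `is_frame`.
#' @export
write_map <- function(map, path) {
  tbl <- as_tibble(map)
  out <- tibble(
    marker = tbl$marker,
    linkage_group = tbl[["linkage_group"]] %||% rep(NA_character_, nrow(tbl)),
    chromosome = tbl[["chromosome"]] %||% rep(NA_character_, nrow(tbl)),
    position_cM = tbl$position,
    bin_id = tbl[["bin_id"]] %||% rep(NA_character_, nrow(tbl)),
    is_frame = tbl[["is_frame"]] %||% rep(NA, nrow(tbl))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(),
    linkage_group = readr::col_character(),
    chromosome = readr::col_character(),
    position_cM = readr::col_double(),
    bin_id = readr::col_character(),
    is_frame = readr::col_logical()
  ), progress = FALSE) |>
    dplyr::rename(position = "position_cM")
}

#' Write a consensus map with provenance
#'
#' TSV columns: `marker`, `chromosome`, `position_cM`, `bin_id`, `n_maps`,
#' `sources`.
#'
#' @param consensus A `consensus_map`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  tbl <- as_tibble(consensus)
  out <- tibble(
    marker = tbl$marker, chromosome = tbl$chromosome,
    position_cM = tbl$position, bin_id = tbl$bin_id,
    n_maps = tbl$n_maps, sources = tbl$sources
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an EST-to-chromosome-bin table
#'
#' TSV with columns `est_id`, `chromosome`, `bin_id`.
#'
#' @param path File path.
#' @return Tibble `est_id`, `chromosome`, `bin_id`.
#' @export
read_est_bin <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the seed, thresholds and any extra fields of a run so artifacts
#' can be reproduced.
#'
#' @param path File path.
#' @param seed Integer seed used.
#' @param ... Further named fields (thresholds, input paths, ...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, ...) {
  manifest <- c(list(package = "mapforge",
                     version = as.character(utils::packageVersion("mapforge")),
                     seed = seed), list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
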
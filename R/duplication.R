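# Multi-locus assay analysis: pair expansion, homoeologous / intra- /
# inter-genomic classification and homoeolog collinearity.
#
# In an allopolyploid like hexaploid wheat, one array probe can genotype
# several homoeologous or rearranged loci at once. Pairs of loci of such
# multi-locus assays reveal homoeologous duplication (same group, different
# genome, e.g. 1A-1B) or translocation (non-homoeologous pairs, e.g. 1A-2A
# intra-genomic, 1A-2B inter-genomic).

#' Find multi-locus assays in a mapped locus table
#'
#' @param loci Data frame with columns `assay`, `marker` (locus id),
#'   `chromosome`, `position`; a `consensus_map` whose markers carry assay
#'   identity also works (an absent `assay` column defaults to `marker`,
#'   i.e. every assay single-locus).
#' @return Tibble of the loci of assays with two or more mapped loci,
#'   ordered by assay.
#' @export
find_multi_locus <- function(loci) {
  tbl <- as_tibble(loci)
  if (!"assay" %in% names(tbl)) tbl$assay <- tbl$marker
  if (!"marker" %in% names(tbl)) tbl$marker <- tbl$assay
  tbl |>
    dplyr::filter(dplyr::n() >= 2, .by = "assay") |>
    dplyr::arrange(.data$assay, .data$chromosome, .data$position) |>
    dplyr::select("assay", "marker", "chromosome", "position")
}

#' Expand multi-locus assays into locus pairs
#'
#' Every unordered pair of loci of each assay becomes one row: an assay
#' with m loci yields m(m-1)/2 pairs.
#'
#' @param multi_loci Output of [find_multi_locus()].
#' @return Tibble `assay`, `chromosome_a`, `position_a`, `chromosome_b`,
#'   `position_b` (pair members in `(chromosome, position)` order).
#' @export
expand_pairs <- function(multi_loci) {
  tbl <- as_tibble(multi_loci)
  rows <- tbl |>
    dplyr::group_split(.data$assay) |>
    purrr::map(function(g) {
      m <- nrow(g)
      if (m < 2) return(NULL)
      idx <- utils::combn(m, 2)
      tibble(
        assay = g$assay[1],
        chromosome_a = g$chromosome[idx[1, ]],
        position_a = g$position[idx[1, ]],
        chromosome_b = g$chromosome[idx[2, ]],
        position_b = g$position[idx[2, ]]
      )
    })
  dplyr::bind_rows(rows)
}

#' Classify locus pairs as homoeologous, intra- or inter-genomic
#'
#' Using wheat-style names `<group><genome>`: a pair on the same
#' homoeologous group but different genomes (1A-1B) is *homoeologous*; the
#' same genome but different groups (1A-2A) is *intra_genomic*; different
#' group and genome (1A-2B) is *inter_genomic*. Two loci of one assay on
#' the same chromosome are not a pair: they are excluded from the
#' categories and returned separately.
#'
#' @param pairs Output of [expand_pairs()].
#' @param nomenclature Optional chromosome nomenclature table (see
#'   [parse_chromosome()]).
#' @return List: `pairs` (input rows with a `category` column, same-
#'   chromosome rows excluded), `counts` (tibble `category`, `n`),
#'   `pair_matrix` (tibble `chromosome_a`, `chromosome_b`, `n` per
#'   unordered chromosome pair), `same_chromosome` (excluded rows).
#' @export
classify_pairs <- function(pairs, nomenclature = NULL) {
  tbl <- as_tibble(pairs)
  pa <- parse_chromosome(tbl$chromosome_a, nomenclature)
  pb <- parse_chromosome(tbl$chromosome_b, nomenclature)
  bad <- unique(c(tbl$chromosome_a[is.na(pa$group)],
                  tbl$chromosome_b[is.na(pb$group)]))
  if (length(bad) > 0) {
    stop("unparseable chromosome name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  same_chrom <- tbl$chromosome_a == tbl$chromosome_b
  excluded <- tbl[same_chrom, , drop = FALSE]
  tbl <- tbl[!same_chrom, , drop = FALSE]
  pa <- pa[!same_chrom, , drop = FALSE]
  pb <- pb[!same_chrom, , drop = FALSE]
  tbl$category <- dplyr::case_when(
    pa$group == pb$group & pa$genome != pb$genome ~ "homoeologous",
    pa$genome == pb$genome ~ "intra_genomic",
    TRUE ~ "inter_genomic"
  )
  # canonical unordered chromosome-pair labels
  lo <- pmin(tbl$chromosome_a, tbl$chromosome_b)
  hi <- pmax(tbl$chromosome_a, tbl$chromosome_b)
  pair_matrix <- tibble(chromosome_a = lo, chromosome_b = hi) |>
    dplyr::count(.data$chromosome_a, .data$chromosome_b, name = "n")
  counts <- tibble(category = c("homoeologous", "intra_genomic",
                                "inter_genomic")) |>
    dplyr::left_join(dplyr::count(tbl, .data$category, name = "n"),
                     by = "category") |>
    tidyr::replace_na(list(n = 0L))
  list(pairs = tbl, counts = counts, pair_matrix = pair_matrix,
       same_chromosome = excluded)
}

#' Collinearity of duplicated loci on a homoeologous chromosome pair
#'
#' Spearman rank correlation between the positions of paired loci mapped on
#' the two chromosomes, across assays. Fewer than 3 pairs gives `NA`.
#'
#' @param pairs Classified pairs (the `pairs` element of
#'   [classify_pairs()], or any tibble with `chromosome_a/b`,
#'   `position_a/b`).
#' @param chrom_a,chrom_b The chromosome pair (order-free).
#' @return Spearman rho (scalar) or `NA`.
#' @export
homoeolog_collinearity <- function(pairs, chrom_a, chrom_b) {
  tbl <- as_tibble(pairs)
  fwd <- tbl$chromosome_a == chrom_a & tbl$chromosome_b == chrom_b
  rev <- tbl$chromosome_a == chrom_b & tbl$chromosome_b == chrom_a
  x <- c(tbl$position_a[fwd], tbl$position_b[rev])
  y <- c(tbl$position_b[fwd], tbl$position_a[rev])
  if (length(x) < 3) return(NA_real_)
  suppressWarnings(cor(x, y, method = "spearman"))
}
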
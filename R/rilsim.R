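# Multi-population RIL panel simulator with known true maps.
#
# The generator exists so that every downstream stage (QC, two-point
# estimation, binning, grouping, ordering, consensus merging, duplication
# analysis) can be exercised against a known truth. It emulates selfed RIL
# panels genotyped on a shared marker panel: several populations, partial
# marker sharing, residual heterozygosity decaying with selfing generation,
# genotyping error, missing data, multi-locus assays and translocations.

#' Simulate a true genetic map
#'
#' Places markers on a set of chromosomes, either uniformly at random or on
#' an evenly spaced grid. Marker names are `<chromosome>_m<i>`; genome letter
#' and homoeologous group are parsed from wheat-style chromosome names
#' (`1A` ... `7D`) where possible.
#'
#' @param chromosomes Data frame with columns `chromosome` (name) and
#'   `length` (cM). Lengths must be positive.
#' @param n_markers Markers per chromosome; scalar or one value per
#'   chromosome. Must be at least 2.
#' @param seed Integer seed; identical seeds give identical maps.
#' @param placement `"uniform"` (random positions) or `"grid"` (evenly
#'   spaced from 0 to the chromosome length).
#' @return A `true_map` tibble with columns `marker`, `assay`, `chromosome`,
#'   `position`, `genome`, `homoeo_group`, sorted by chromosome and position.
#'   Chromosome lengths are kept in the `chrom_lengths` attribute.
#' @export
#' @examples
#' tm <- simulate_true_map(
#'   data.frame(chromosome = c("1A", "1B"), length = c(120, 100)),
#'   n_markers = 10, seed = 1
#' )
#' head(tm)
simulate_true_map <- function(chromosomes, n_markers, seed = NULL,
                              placement = c("uniform", "grid")) {
  placement <- match.arg(placement)
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chromosome", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  n_markers <- rep_len(as.integer(n_markers), nrow(chromosomes))
  if (any(n_markers < 2)) {
    stop("at least 2 markers per chromosome are required", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  rows <- purrr::pmap(
    list(chromosomes$chromosome, chromosomes$length, n_markers),
    function(chrom, len, n) {
      pos <- switch(placement,
        grid = seq(0, len, length.out = n),
        uniform = sort(runif(n, 0, len))
      )
      tibble(
        marker = sprintf("%s_m%02d", chrom, seq_len(n)),
        chromosome = chrom,
        position = pos
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  parsed <- parse_chromosome(out$chromosome)
  out$genome <- parsed$genome
  out$homoeo_group <- parsed$group
  out$assay <- out$marker
  out$primary <- TRUE
  out <- out[, c("marker", "assay", "chromosome", "position",
                 "genome", "homoeo_group", "primary")]
  attr(out, "chrom_lengths") <- chromosomes
  class(out) <- c("true_map", class(out))
  out
}

#' Add multi-locus (duplicated) assays to a true map
#'
#' Array SNP assays are single probes; a probe whose flanking sequence occurs
#' at several genome positions genotypes all of them at once. The simulator
#' represents this as one assay with a *primary* locus (which supplies the
#' genotype calls) plus extra registered loci. Downstream, the registry of
#' all loci of each assay drives the duplication/translocation analysis.
#'
#' @param true_map A `true_map`.
#' @param duplications Data frame with columns `assay` (an existing marker
#'   name whose locus becomes the primary locus) and `chromosome`,
#'   `position` for each extra locus; several rows per assay give assays
#'   with three or more loci.
#' @return The `true_map` with extra non-primary locus rows appended.
#' @export
add_duplications <- function(true_map, duplications) {
  duplications <- as_tibble(duplications)
  stopifnot(all(c("assay", "chromosome", "position") %in% names(duplications)))
  missing_assays <- setdiff(duplications$assay, true_map$assay)
  if (length(missing_assays) > 0) {
    stop("unknown assays in duplications: ",
         paste(missing_assays, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_chromosome(duplications$chromosome)
  extra <- duplications |>
    dplyr::group_by(.data$assay) |>
    dplyr::mutate(marker = sprintf("%s_L%d", .data$assay,
                                   dplyr::row_number() + 1L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(genome = parsed$genome, homoeo_group = parsed$group,
                  primary = FALSE) |>
    dplyr::select("marker", "assay", "chromosome", "position",
                  "genome", "homoeo_group", "primary")
  out <- dplyr::bind_rows(as_tibble(true_map), extra)
  attr(out, "chrom_lengths") <- attr(true_map, "chrom_lengths")
  class(out) <- c("true_map", class(tibble()))
  out
}

#' Apply a translocation to a true map
#'
#' Moves the marker loci lying in a segment of one chromosome onto another
#' chromosome, appending the segment beyond the recipient's current end.
#' Subsequent inheritance simulation then treats the moved loci as part of
#' the recipient chromosome, and duplicated assays with one locus in the
#' segment produce non-homoeologous locus pairs — the signature the
#' rearrangement analysis detects.
#'
#' @param true_map A `true_map`.
#' @param from,to Chromosome names (donor and recipient).
#' @param start,end Segment bounds (cM) on the donor chromosome.
#' @return The modified `true_map`.
#' @export
apply_translocation <- function(true_map, from, to, start, end) {
  stopifnot(start <= end)
  lens <- attr(true_map, "chrom_lengths")
  if (!(from %in% true_map$chromosome) || !(to %in% lens$chromosome)) {
    stop("unknown chromosome in translocation spec", call. = FALSE)
  }
  to_len <- lens$length[lens$chromosome == to]
  moved <- true_map$chromosome == from &
    true_map$position >= start & true_map$position <= end
  out <- as_tibble(true_map)
  out$position[moved] <- to_len + (out$position[moved] - start)
  out$chromosome[moved] <- to
  parsed <- parse_chromosome(out$chromosome)
  out$genome <- parsed$genome
  out$homoeo_group <- parsed$group
  lens$length[lens$chromosome == to] <- to_len + (end - start)
  attr(out, "chrom_lengths") <- lens
  class(out) <- c("true_map", class(tibble()))
  out
}

# One round of meiosis for all lines at once, per chromosome.
# H1, H2: n_lines x n_markers 0/1 haplotype matrices; d: adjacent-marker
# distances in cM. With crossover counts Poisson(length/100) and uniform
# breakpoints, counts in disjoint intervals are independent Poissons, so the
# phase at marker j is start + cumulative parity of interval counts.
.gamete <- function(H1, H2, d) {
  n <- nrow(H1)
  m <- ncol(H1)
  start <- rbinom(n, 1, 0.5)
  if (m > 1) {
    x <- matrix(rpois(n * (m - 1), rep(d / 100, each = n)), n, m - 1)
    parity <- x %% 2
    cum <- if (m == 2) parity else t(apply(parity, 1, cumsum))
    phase <- (matrix(start, n, m) + cbind(0L, cum)) %% 2
  } else {
    phase <- matrix(start, n, 1)
  }
  H1 * (phase == 0) + H2 * (phase == 1)
}

#' Simulate one RIL population
#'
#' Derives `n_lines` recombinant inbred lines from an F1 between two fully
#' homozygous parents (alleles A and B at every locus) by
#' `selfing_generation - 1` rounds of selfing. Meiosis has no crossover
#' interference: crossover counts per chromosome are Poisson(length / 100)
#' with uniform breakpoints. Residual heterozygosity therefore halves each
#' generation, so F2:6 and F2:8 panels differ as expected. Genotyping errors
#' (symmetric allele flips) are applied after inheritance, then missingness.
#'
#' @param true_map A `true_map`; genotypes are emitted for primary loci
#'   (one row per assay).
#' @param n_lines Number of RILs (≥ 2).
#' @param selfing_generation Generation of the genotyped RILs, e.g. 6 for
#'   F2:6 or 8 for F2:8 (≥ 2; generation 2 is the F2 itself).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param error_rate Per-call probability of an A/B flip (homozygous calls).
#' @param residual_het_rate Probability that a truly heterozygous genotype is
#'   reported as `H`; otherwise it is resolved to a random homozygote. The
#'   default 1 reports heterozygotes faithfully.
#' @param seed Integer seed.
#' @return A genotype tibble: column `marker` (assay ids) then one column per
#'   line (`line_001`, ...) with calls in `A`, `B`, `H`, `NA`. The true map
#'   restricted to emitted assays is kept in the `truth` attribute.
#' @export
simulate_population <- function(true_map, n_lines,
                                selfing_generation = 6,
                                missing_rate = 0,
                                error_rate = 0,
                                residual_het_rate = 1,
                                seed = NULL) {
  stopifnot(n_lines >= 2, selfing_generation >= 2)
  for (p in c(missing_rate, error_rate, residual_het_rate)) {
    if (p < 0 || p > 1) stop("rates must be probabilities in [0, 1]",
                             call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  loci <- as_tibble(true_map) |>
    dplyr::filter(.data$primary) |>
    dplyr::arrange(.data$chromosome, .data$position, .data$marker)
  line_ids <- sprintf("line_%03d", seq_len(n_lines))

  calls_by_chrom <- lapply(split(loci, loci$chromosome), function(ch) {
    m <- nrow(ch)
    d <- diff(ch$position)
    # F1: one haplotype all-A (0), one all-B (1)
    H1 <- matrix(0, n_lines, m)
    H2 <- matrix(1, n_lines, m)
    for (g in seq_len(selfing_generation - 1)) {
      G1 <- .gamete(H1, H2, d)
      G2 <- .gamete(H1, H2, d)
      H1 <- G1
      H2 <- G2
    }
    dose <- H1 + H2 # 0 = AA, 1 = het, 2 = BB
    calls <- matrix(NA_character_, m, n_lines,
                    dimnames = list(ch$assay, line_ids))
    calls[t(dose) == 0] <- "A"
    calls[t(dose) == 2] <- "B"
    het <- t(dose) == 1
    n_het <- sum(het)
    if (n_het > 0) {
      as_h <- runif(n_het) < residual_het_rate
      resolved <- ifelse(runif(n_het) < 0.5, "A", "B")
      calls[het] <- ifelse(as_h, "H", resolved)
    }
    calls
  })
  calls <- do.call(rbind, calls_by_chrom)
  calls <- calls[loci$assay, , drop = FALSE]

  if (error_rate > 0) {
    hom <- !is.na(calls) & calls != "H"
    flip <- hom & matrix(runif(length(calls)) < error_rate,
                         nrow(calls), ncol(calls))
    calls[flip] <- ifelse(calls[flip] == "A", "B", "A")
  }
  if (missing_rate > 0) {
    calls[matrix(runif(length(calls)) < missing_rate,
                 nrow(calls), ncol(calls))] <- NA_character_
  }

  out <- geno_tibble(calls)
  attr(out, "truth") <- true_map
  out
}

#' Simulate a multi-population RIL panel with partial marker sharing
#'
#' Each population genotypes an independent random subset of the assays
#' (binomial inclusion with probability `population_marker_fraction`), then
#' is simulated with [simulate_population()]. The sharing report counts how
#' many assays are private to one population, shared by two, three, ...,
#' emulating the multi-way Venn structure of real multi-population panels.
#'
#' @param true_map A `true_map`.
#' @param n_populations Number of populations (≥ 2).
#' @param n_lines Lines per population; scalar or one value per population.
#' @param selfing_generation Per population; recycled.
#' @param population_marker_fraction Inclusion probability per assay per
#'   population; recycled.
#' @param missing_rate,error_rate,residual_het_rate Passed to
#'   [simulate_population()]; recycled.
#' @param seed Integer seed for the whole panel.
#' @return A list with `populations` (named list of genotype tibbles),
#'   `sharing` (tibble: `n_populations_sharing`, `n_markers`), and
#'   `true_map`.
#' @export
make_panel <- function(true_map, n_populations,
                       n_lines = 200,
                       selfing_generation = 6,
                       population_marker_fraction = 0.5,
                       missing_rate = 0, error_rate = 0,
                       residual_het_rate = 1, seed = NULL) {
  stopifnot(n_populations >= 2)
  if (any(population_marker_fraction <= 0)) {
    stop("population_marker_fraction of 0 would give an empty population",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_lines <- rep_len(n_lines, n_populations)
  selfing_generation <- rep_len(selfing_generation, n_populations)
  frac <- rep_len(population_marker_fraction, n_populations)
  missing_rate <- rep_len(missing_rate, n_populations)
  error_rate <- rep_len(error_rate, n_populations)
  residual_het_rate <- rep_len(residual_het_rate, n_populations)

  assays <- unique(as_tibble(true_map)$assay)
  pops <- vector("list", n_populations)
  sampled <- vector("list", n_populations)
  for (i in seq_len(n_populations)) {
    keep <- assays[runif(length(assays)) < frac[i]]
    if (length(keep) < 2) {
      stop("population ", i, " received fewer than 2 assays; ",
           "increase population_marker_fraction", call. = FALSE)
    }
    sampled[[i]] <- keep
    sub <- as_tibble(true_map) |> dplyr::filter(.data$assay %in% keep)
    attr(sub, "chrom_lengths") <- attr(true_map, "chrom_lengths")
    class(sub) <- c("true_map", class(tibble()))
    pops[[i]] <- simulate_population(
      sub, n_lines = n_lines[i], selfing_generation = selfing_generation[i],
      missing_rate = missing_rate[i], error_rate = error_rate[i],
      residual_het_rate = residual_het_rate[i]
    )
  }
  names(pops) <- sprintf("pop%d", seq_len(n_populations))

  union_assays <- unique(unlist(sampled))
  times <- table(factor(unlist(lapply(sampled, unique)),
                        levels = union_assays))
  sharing <- tibble(
    n_populations_sharing = seq_len(n_populations),
    n_markers = as.integer(tabulate(times, nbins = n_populations))
  )
  list(populations = pops, sharing = sharing, true_map = true_map)
}
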
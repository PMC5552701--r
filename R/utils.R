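# Shared helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed map statistics
#' (densities to 2 decimals, coverages to 1 decimal) follow the
#' conventional half-up rule, so summaries use this instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round(0.125, 2) gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse wheat-style chromosome names
#'
#' Splits names like `"1A"`, `"3B"` or `"21D"` into a homoeologous group
#' number and a genome letter. Other nomenclatures can be supplied through
#' an explicit lookup table mapping chromosome name to group and genome.
#'
#' @param chromosome Character vector of chromosome names.
#' @param nomenclature Optional data frame with columns `chromosome`,
#'   `group`, `genome` overriding the `<digit><letter>` convention.
#' @return A tibble with columns `chromosome`, `group` (integer) and
#'   `genome` (character). Unparseable names get `NA` in both fields.
#' @export
#' @examples
#' parse_chromosome(c("1A", "7D"))
parse_chromosome <- function(chromosome, nomenclature = NULL) {
  chromosome <- as.character(chromosome)
  if (!is.null(nomenclature)) {
    stopifnot(all(c("chromosome", "group", "genome") %in% names(nomenclature)))
    idx <- match(chromosome, nomenclature$chromosome)
    return(tibble(
      chromosome = chromosome,
      group = as.integer(nomenclature$group[idx]),
      genome = as.character(nomenclature$genome[idx])
    ))
  }
  m <- stringr::str_match(chromosome, "^([0-9]+)([A-Za-z])$")
  tibble(
    chromosome = chromosome,
    group = as.integer(m[, 2]),
    genome = m[, 3]
  )
}

# Marker-call coding used throughout: calls are character "A", "B", "H" or NA.
# Returns a numeric matrix with A = 0, B = 1, H/missing = NA.
calls_to_numeric <- function(calls) {
  x <- matrix(NA_real_, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  x[calls == "A"] <- 0
  x[calls == "B"] <- 1
  x
}

# Genotype tibble (marker column + one column per line) -> character matrix
# with markers as rows. "-" and "" are read as missing.
geno_matrix <- function(genotypes) {
  stopifnot(is.data.frame(genotypes), names(genotypes)[1] == "marker")
  m <- as.matrix(genotypes[, -1, drop = FALSE])
  mode(m) <- "character"
  m[m %in% c("-", "", "NA")] <- NA_character_
  rownames(m) <- genotypes$marker
  m
}

geno_tibble <- function(calls) {
  out <- as_tibble(calls, rownames = "marker")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
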
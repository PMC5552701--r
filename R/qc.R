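# Genotype quality control.

#' Apply genotype quality-control rules
#'
#' Three rules, applied in order: (i) heterozygous calls are masked to
#' missing; (ii) markers whose missing fraction exceeds `max_missing_rate`
#' are dropped (strictly greater, so "over 10%" drops); (iii) markers whose
#' allele-A frequency over the remaining non-missing calls falls outside
#' `[allele_freq_min, allele_freq_max]` (inclusive bounds) are dropped.
#'
#' @param genotypes Genotype tibble (`marker` column, then line columns).
#' @param max_missing_rate Maximum tolerated missing fraction (default 0.10).
#' @param allele_freq_min,allele_freq_max Allele-A frequency bounds
#'   (defaults 0.3 and 0.7).
#' @return The filtered genotype tibble (heterozygotes masked), with a
#'   one-row `qc_report` attribute recording attrition; retrieve it with
#'   [qc_report()]. Dropping every marker gives an empty tibble with a
#'   warning, not an error.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   marker = c("m1", "m2"),
#'   l1 = c("A", "A"), l2 = c("A", "H"), l3 = c("B", "H"),
#'   l4 = c("B", "A"), l5 = c("A", "B"), l6 = c("B", "B")
#' )
#' qc_report(apply_qc(g))
apply_qc <- function(genotypes, max_missing_rate = 0.10,
                     allele_freq_min = 0.3, allele_freq_max = 0.7) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            allele_freq_min >= 0, allele_freq_min < allele_freq_max,
            allele_freq_max <= 1)
  calls <- geno_matrix(genotypes)
  bad <- setdiff(unique(as.vector(calls)), c("A", "B", "H", NA_character_))
  if (length(bad) > 0) {
    stop("invalid genotype codes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(calls)

  n_het <- sum(calls == "H", na.rm = TRUE)
  calls[calls == "H"] <- NA_character_

  miss_rate <- rowMeans(is.na(calls))
  drop_missing <- miss_rate > max_missing_rate
  calls2 <- calls[!drop_missing, , drop = FALSE]

  n_a <- rowSums(calls2 == "A", na.rm = TRUE)
  n_ab <- n_a + rowSums(calls2 == "B", na.rm = TRUE)
  freq_a <- ifelse(n_ab > 0, n_a / n_ab, NA_real_)
  drop_freq <- is.na(freq_a) | freq_a < allele_freq_min |
    freq_a > allele_freq_max
  kept <- calls2[!drop_freq, , drop = FALSE]

  report <- tibble(
    n_input_markers = n_input,
    n_het_calls_masked = n_het,
    n_dropped_missing = sum(drop_missing),
    n_dropped_freq = sum(drop_freq),
    n_retained = nrow(kept)
  )
  if (nrow(kept) == 0) {
    warning("all markers removed by QC", call. = FALSE)
  }
  out <- geno_tibble(kept)
  attr(out, "qc_report") <- report
  attr(out, "truth") <- attr(genotypes, "truth")
  out
}

#' Retrieve the QC attrition report
#'
#' @param genotypes A genotype tibble returned by [apply_qc()].
#' @return A one-row tibble: `n_input_markers`, `n_het_calls_masked`,
#'   `n_dropped_missing`, `n_dropped_freq`, `n_retained`.
#' @export
qc_report <- function(genotypes) {
  rep <- attr(genotypes, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run apply_qc() first",
                         call. = FALSE)
  rep
}
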
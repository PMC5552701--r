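# Two-point linkage engine for RIL populations.
#
# Observed recombinant-line fractions R in selfed RILs overstate the meiotic
# recombination fraction r: at full inbreeding R = 2r / (1 + 2r)
# (Haldane-Waddington), inverted here as r = R / (2 (1 - R)). Distances come
# from the Kosambi (default) or Haldane mapping function.

#' Convert an observed RIL recombinant fraction to a meiotic one
#'
#' Inverts the Haldane-Waddington relation `R = 2r / (1 + 2r)` for selfed
#' RILs at fixation, giving \eqn{r = R / (2 (1 - R))}. Inputs above 0.5 are
#' capped at 0.5 (independence) before inversion.
#'
#' @param R Observed recombinant-line fraction(s), in `[0, 1)`.
#' @return Meiotic recombination fraction(s) in `[0, 0.5]`.
#' @export
#' @examples
#' ril_to_meiotic(1 / 3) # 0.25
ril_to_meiotic <- function(R) {
  if (any(R >= 1 | R < 0, na.rm = TRUE)) {
    stop("R must lie in [0, 1)", call. = FALSE)
  }
  R <- pmin(R, 0.5)
  R / (2 * (1 - R))
}

#' Expected RIL recombinant fraction for a meiotic fraction
#'
#' The forward Haldane-Waddington relation `R = 2r / (1 + 2r)` for selfed
#' RILs at fixation; exact inverse of [ril_to_meiotic()].
#'
#' @param r Meiotic recombination fraction(s) in `[0, 0.5]`.
#' @return Expected observed recombinant-line fraction(s).
#' @export
meiotic_to_ril <- function(r) {
  stopifnot(all(r >= 0 & r <= 0.5, na.rm = TRUE))
  2 * r / (1 + 2 * r)
}

#' Map distance from a meiotic recombination fraction
#'
#' Kosambi: `25 log((1 + 2r) / (1 - 2r))`; Haldane: `-50 log(1 - 2r)`.
#' Fractions at or above 0.5 are capped at `max_distance` with a warning.
#'
#' @param r Meiotic recombination fraction(s).
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @param max_distance Distance (cM) assigned to fractions at or above 0.5
#'   (default 1000).
#' @return Distance(s) in centimorgans.
#' @export
#' @examples
#' map_distance(0.2) # about 21.18 cM
map_distance <- function(r, map_function = c("kosambi", "haldane"),
                         max_distance = 1000) {
  map_function <- match.arg(map_function)
  stopifnot(all(r >= 0, na.rm = TRUE))
  capped <- !is.na(r) & r >= 0.5
  if (any(capped)) {
    warning("recombination fraction >= 0.5 capped at max_distance",
            call. = FALSE)
  }
  rr <- ifelse(capped, NA_real_, r)
  d <- switch(map_function,
    kosambi = 25 * log((1 + 2 * rr) / (1 - 2 * rr)),
    haldane = -50 * log(1 - 2 * rr)
  )
  ifelse(capped, max_distance, d)
}

# LOD of linkage at the (capped, floored) MLE against r = 0.5.
# k recombinants of n informative lines; R floored at 1/(2n) when k = 0 so
# zero-recombinant pairs score finite but large.
.lod <- function(k, n, R = NULL) {
  R_eval <- if (is.null(R)) pmin(k / n, 0.5) else R
  R_eval <- ifelse(k == 0, 1 / (2 * n), R_eval)
  k * log10(R_eval) + (n - k) * log10(1 - R_eval) - n * log10(0.5)
}

#' Two-point linkage estimate for one marker pair
#'
#' Counts recombinant lines over lines with non-missing homozygous calls at
#' both markers (heterozygous calls are treated as missing, consistent with
#' QC masking), estimates the RIL fraction `R_hat = k / n` (capped at 0.5),
#' corrects it to a meiotic fraction, and scores linkage with a base-10 LOD
#' against independence.
#'
#' @param calls_a,calls_b Character vectors of calls (`A`/`B`/`H`/`NA`) for
#'   the two markers over the same lines.
#' @return One-row tibble: `n_informative`, `k_recombinant`, `R_hat`,
#'   `r_meiotic`, `lod`.
#' @export
#' @examples
#' estimate_pair(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
estimate_pair <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  a <- ifelse(calls_a %in% c("A", "B"), calls_a, NA_character_)
  b <- ifelse(calls_b %in% c("A", "B"), calls_b, NA_character_)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("no lines informative at both markers", call. = FALSE)
  k <- sum(a[ok] != b[ok])
  R_hat <- min(k / n, 0.5)
  tibble(
    n_informative = n,
    k_recombinant = k,
    R_hat = R_hat,
    r_meiotic = ril_to_meiotic(R_hat),
    lod = .lod(k, n)
  )
}

# Matrix pairwise engine. calls: character matrix, markers x lines.
# Returns list of m x m matrices: n (informative lines), k (recombinants),
# plus derived R (capped), r (meiotic) and lod. Pairs with n = 0 get
# R = r = 0.5 and lod = 0 (uninformative).
pairwise_counts <- function(calls) {
  M0 <- (!is.na(calls) & calls == "A") * 1
  M1 <- (!is.na(calls) & calls == "B") * 1
  n <- tcrossprod(M0 + M1)
  k <- tcrossprod(M0, M1) + tcrossprod(M1, M0)
  R <- ifelse(n > 0, pmin(k / n, 0.5), 0.5)
  lod <- matrix(0, nrow(n), ncol(n), dimnames = dimnames(n))
  pos <- n > 0
  lod[pos] <- .lod(k[pos], n[pos])
  lod[lod < 0] <- 0
  list(n = n, k = k, R = R, r = R / (2 * (1 - R)), lod = lod)
}

#' All pairwise two-point estimates of a genotype table
#'
#' Convenience wrapper around the matrix engine; returns the long table
#' used for TSV export. For large marker sets prefer working with the
#' downstream map-building functions, which use the matrix form directly.
#'
#' @param genotypes Genotype tibble.
#' @return Tibble with one row per unordered marker pair: `marker_a`,
#'   `marker_b`, `n`, `k`, `R`, `r`, `lod`. Pairs with no informative line
#'   are reported with `n = 0` and `NA` estimates.
#' @export
pairwise_linkage <- function(genotypes) {
  calls <- geno_matrix(genotypes)
  pc <- pairwise_counts(calls)
  idx <- which(upper.tri(pc$n), arr.ind = TRUE)
  markers <- rownames(calls)
  n <- pc$n[idx]
  tibble(
    marker_a = markers[idx[, 1]],
    marker_b = markers[idx[, 2]],
    n = as.integer(n),
    k = as.integer(pc$k[idx]),
    R = ifelse(n > 0, pc$R[idx], NA_real_),
    r = ifelse(n > 0, pc$r[idx], NA_real_),
    lod = ifelse(n > 0, pc$lod[idx], NA_real_)
  )
}
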
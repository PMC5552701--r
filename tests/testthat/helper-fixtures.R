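# Fixture builders shared across test files.

# Genotype tibble from a markers x lines character matrix given as rows.
geno_fixture <- function(...) {
  rows <- list(...)
  calls <- do.call(rbind, lapply(rows, function(r) r[-1]))
  rownames(calls) <- vapply(rows, `[[`, character(1), 1)
  colnames(calls) <- sprintf("l%02d", seq_len(ncol(calls)))
  calls[calls == "-"] <- NA_character_
  tibble::as_tibble(calls, rownames = "marker")
}

# Random (k, n) two-point draws with at least one recombinant.
draw_kn <- function(n_draws, seed) {
  set.seed(seed)
  n <- sample(20:2000, n_draws, replace = TRUE)
  r <- runif(n_draws, 0.01, 0.45)
  k <- rbinom(n_draws, n, meiotic_to_ril(r))
  k[k == 0] <- 1
  data.frame(k = k, n = n)
}

# Independent grid-search LOD oracle: coarse scan then local refinement.
grid_lod <- function(k, n) {
  ll <- function(R) k * log10(R) + (n - k) * log10(1 - R) - n * log10(0.5)
  grid <- seq(1e-6, 0.5, by = 1e-4)
  best <- grid[which.max(ll(grid))]
  fine <- seq(max(1e-9, best - 2e-4), min(0.5, best + 2e-4), by = 1e-8)
  max(ll(fine))
}

# Exhaustive-permutation SARF minimum for small marker sets.
brute_sarf_min <- function(r_mat) {
  m <- nrow(r_mat)
  perms <- mapforge:::.permutations(m)
  vals <- apply(perms, 1, function(p) sarf(p, r_mat))
  min(vals)
}

# A true map + single population on one chromosome, defaults tuned small.
sim_one_chrom <- function(n_markers = 20, length_cM = 100, n_lines = 150,
                          seed = 1, ...) {
  tm <- simulate_true_map(
    data.frame(chromosome = "1A", length = length_cM),
    n_markers = n_markers, seed = seed
  )
  list(tm = tm, geno = simulate_population(tm, n_lines = n_lines,
                                           seed = seed + 1, ...))
}
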
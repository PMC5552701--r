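# RIL panel simulator.

test_that("true-map placement, determinism and count conservation", {
  tm <- simulate_true_map(data.frame(chromosome = "1A", length = 100),
                          n_markers = 5, placement = "grid")
  expect_equal(tm$position, c(0, 25, 50, 75, 100))

  a <- simulate_true_map(data.frame(chromosome = c("1A", "2B"),
                                    length = c(80, 120)),
                         n_markers = 10, seed = 11)
  b <- simulate_true_map(data.frame(chromosome = c("1A", "2B"),
                                    length = c(80, 120)),
                         n_markers = 10, seed = 11)
  expect_identical(a, b)

  wheat <- expand.grid(group = 1:7, genome = c("A", "B", "D"))
  big <- simulate_true_map(
    data.frame(chromosome = paste0(wheat$group, wheat$genome), length = 150),
    n_markers = 50, seed = 2
  )
  expect_equal(nrow(big), 21 * 50)
  expect_false(any(duplicated(big$marker)))
  expect_true(all(big$position >= 0 & big$position <= 150))
  expect_equal(sort(unique(big$homoeo_group)), 1:7)

  expect_error(simulate_true_map(data.frame(chromosome = "x", length = -1),
                                 n_markers = 5), "positive")
  expect_error(simulate_true_map(data.frame(chromosome = "x", length = 10),
                                 n_markers = 1), "at least 2")
})

test_that("co-located markers never recombine and degenerate rates are clean", {
  tm <- simulate_true_map(data.frame(chromosome = "1A", length = 50),
                          n_markers = 4, placement = "grid")
  tm$position[2] <- tm$position[1] # two markers at an identical position
  g <- simulate_population(tm, n_lines = 300, selfing_generation = 8,
                           residual_het_rate = 0, seed = 3)
  calls <- as.matrix(g[, -1])
  expect_false(any(is.na(calls)))
  expect_false(any(calls == "H"))
  pair <- estimate_pair(calls[1, ], calls[2, ])
  expect_equal(pair$k_recombinant, 0)
  expect_equal(pair$R_hat, 0)
})

test_that("same seed reproduces byte-identical genotype matrices", {
  tm <- simulate_true_map(data.frame(chromosome = "1A", length = 100),
                          n_markers = 10, seed = 5)
  g1 <- simulate_population(tm, n_lines = 50, missing_rate = 0.05,
                            error_rate = 0.01, seed = 9)
  g2 <- simulate_population(tm, n_lines = 50, missing_rate = 0.05,
                            error_rate = 0.01, seed = 9)
  expect_identical(g1, g2)
})

test_that("recombinant fractions follow the selfed-RIL expectation", {
  # At fixation the recombinant-line fraction is 2r/(1+2r); simulate at a
  # high selfing generation and compare the pooled estimate over three
  # seeded replicates of 10,000 lines within 3 binomial standard errors.
  for (r in c(0.01, 0.05, 0.1, 0.2)) {
    d <- -50 * log(1 - 2 * r) # marker spacing whose meiotic fraction is r
    tm <- simulate_true_map(data.frame(chromosome = "1A", length = d),
                            n_markers = 2, placement = "grid")
    k <- 0
    n <- 0
    for (rep in 1:3) {
      g <- simulate_population(tm, n_lines = 10000,
                               selfing_generation = 25,
                               seed = round(1000 * r) + rep)
      calls <- as.matrix(g[, -1])
      est <- estimate_pair(calls[1, ], calls[2, ])
      k <- k + est$k_recombinant
      n <- n + est$n_informative
    }
    R_exp <- 2 * r / (1 + 2 * r)
    se <- sqrt(R_exp * (1 - R_exp) / n)
    expect_lt(abs(k / n - R_exp), 3 * se)
  }
})

test_that("residual heterozygosity decays with selfing generation", {
  tm <- simulate_true_map(data.frame(chromosome = "1A", length = 100),
                          n_markers = 20, seed = 7)
  het_frac <- function(gen) {
    g <- simulate_population(tm, n_lines = 400, selfing_generation = gen,
                             seed = 21)
    mean(as.matrix(g[, -1]) == "H")
  }
  h2 <- het_frac(2) # F2: expect about one half heterozygous
  h6 <- het_frac(6)
  h8 <- het_frac(8)
  expect_gt(h2, 0.4)
  expect_gt(h6, h8)
  expect_lt(h6, 0.06) # ~ 1/2^4
})

test_that("panel sharing categories partition the marker union", {
  tm <- simulate_true_map(data.frame(chromosome = c("1A", "1B"),
                                     length = c(100, 100)),
                          n_markers = 40, seed = 13)
  panel <- make_panel(tm, n_populations = 4, n_lines = 30,
                      population_marker_fraction = 0.5, seed = 17)
  union_n <- length(unique(unlist(
    lapply(panel$populations, function(p) p$marker))))
  expect_equal(sum(panel$sharing$n_markers), union_n)
  # with 80 markers at fraction 0.5 every category should be populated
  expect_true(all(panel$sharing$n_markers > 0))

  full <- make_panel(tm, n_populations = 3, n_lines = 30,
                     population_marker_fraction = 1, seed = 19)
  expect_equal(full$sharing$n_markers, c(0L, 0L, 80L))

  expect_error(make_panel(tm, n_populations = 2,
                          population_marker_fraction = 0), "empty")
})

test_that("duplications register extra loci and translocations relabel them", {
  tm <- simulate_true_map(data.frame(chromosome = c("1A", "1B"),
                                     length = c(100, 100)),
                          n_markers = 5, placement = "grid")
  dup <- data.frame(assay = "1A_m02", chromosome = "1B", position = 30)
  tm2 <- add_duplications(tm, dup)
  expect_equal(nrow(tm2), 11)
  expect_equal(sum(tm2$assay == "1A_m02"), 2)
  expect_equal(sum(tm2$primary), 10) # genotypes still one row per assay
  g <- simulate_population(tm2, n_lines = 20, seed = 1)
  expect_equal(nrow(g), 10)

  tr <- apply_translocation(tm2, from = "1A", to = "1B",
                            start = 40, end = 100)
  moved <- tr[tr$marker %in% c("1A_m03", "1A_m04", "1A_m05"), ]
  expect_true(all(moved$chromosome == "1B"))
  expect_true(all(moved$position >= 100))
  expect_error(apply_translocation(tm, "9Z", "1A", 0, 10), "unknown")
})
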
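# Binning, grouping, ordering and map assembly.

test_that("zero-recombinant markers bin together with a minimum-missing frame", {
  g <- geno_fixture(
    c("m1", "A", "A", "B", "B", "A", "B"),
    c("m2", "A", "A", "B", "B", "A", "B"), # identical to m1
    c("m3", "A", "B", "A", "B", "A", "B")
  )
  bins <- bin_markers(g)
  expect_equal(bins$bin_id[1], bins$bin_id[2])
  expect_false(bins$bin_id[3] == bins$bin_id[1])
  expect_equal(sum(bins$is_frame[1:2]), 1)

  # 10 markers, {1,2,3} and {7,8} duplicated -> 7 bins; frames by min missing
  set.seed(7)
  base <- replicate(5, ifelse(runif(40) < 0.5, "A", "B"), simplify = FALSE)
  rows <- list(
    c("d1", base[[1]]), c("d2", base[[1]]), c("d3", base[[1]]),
    c("u4", base[[2]]), c("u5", base[[3]]), c("u6", base[[4]]),
    c("d7", base[[5]]), c("d8", base[[5]]),
    c("u9", ifelse(runif(40) < 0.5, "A", "B")),
    c("u10", ifelse(runif(40) < 0.5, "A", "B"))
  )
  # give d2 and d8 the least missing data in their bins
  rows[[1]][2:3] <- "-"
  rows[[3]][4] <- "-"
  rows[[7]][2] <- "-"
  g10 <- do.call(geno_fixture, rows)
  bins10 <- bin_markers(g10)
  expect_equal(length(unique(bins10$bin_id)), 7)
  expect_true(bins10$is_frame[bins10$marker == "d2"])
  expect_true(bins10$is_frame[bins10$marker == "d8"])

  # all mutually recombinant -> singleton bins, frame set = marker set
  g3 <- geno_fixture(
    c("a", "A", "A", "A", "B", "B", "B"),
    c("b", "A", "B", "A", "B", "A", "B"),
    c("c", "B", "A", "A", "A", "B", "B")
  )
  b3 <- bin_markers(g3)
  expect_equal(length(unique(b3$bin_id)), 3)
  expect_true(all(b3$is_frame))
})

test_that("frame-marker ties resolve reproducibly under a seed", {
  g <- geno_fixture(
    c("t1", "A", "A", "B", "B"),
    c("t2", "A", "A", "B", "B")
  )
  pick1 <- bin_markers(g, seed = 4)$marker[bin_markers(g, seed = 4)$is_frame]
  pick2 <- bin_markers(g, seed = 4)$marker[bin_markers(g, seed = 4)$is_frame]
  expect_identical(pick1, pick2)
})

test_that("LOD grouping separates chromosomes and splits across large gaps", {
  tm <- simulate_true_map(data.frame(chromosome = c("1A", "2B"),
                                     length = c(80, 80)),
                          n_markers = 10, placement = "grid")
  g <- simulate_population(tm, n_lines = 120, seed = 32)
  grp <- group_markers(g, lod_threshold = 7)
  expect_equal(length(grp$groups), 2)
  expect_equal(length(grp$unlinked), 0)
  got <- lapply(grp$groups, function(x) sort(unique(substr(x, 1, 2))))
  expect_setequal(got, list("1A", "2B"))

  # threshold above every pairwise LOD -> everything unlinked
  grp_hi <- group_markers(g, lod_threshold = 1e6)
  expect_equal(length(grp_hi$groups), 0)
  expect_equal(sort(grp_hi$unlinked), sort(g$marker))

  # one chromosome with a 60 cM empty interior gap fragments at LOD 7:
  # the expected LOD across the gap at n = 100 is far below threshold
  tm_gap <- simulate_true_map(data.frame(chromosome = "3A", length = 40),
                              n_markers = 6, placement = "grid")
  tm_gap$position[4:6] <- tm_gap$position[4:6] + 60
  attr(tm_gap, "chrom_lengths")$length <- 100
  g_gap <- simulate_population(tm_gap, n_lines = 100, seed = 33)
  grp_gap <- group_markers(g_gap, lod_threshold = 7)
  expect_gt(length(grp_gap$groups) + length(grp_gap$unlinked), 1)
})

test_that("seriation matches the exhaustive-permutation minimum on small groups", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    m <- sample(4:8, 1)
    tm <- simulate_true_map(data.frame(chromosome = "5B", length = 60),
                            n_markers = m, seed = seed)
    g <- simulate_population(tm, n_lines = 120, seed = seed + 100)
    r_mat <- mapforge:::pairwise_counts(mapforge:::geno_matrix(g))$r
    ord <- order_markers(r_mat = r_mat)
    expect_equal(sarf(ord, r_mat), brute_sarf_min(r_mat), tolerance = 1e-12)
  }
  expect_equal(order_markers(r_mat = matrix(0, 1, 1,
                                            dimnames = list("x", "x"))), "x")
})

test_that("a 50-marker chromosome is recovered in order", {
  tm <- simulate_true_map(data.frame(chromosome = "6A", length = 120),
                          n_markers = 50, seed = 41)
  g <- simulate_population(tm, n_lines = 250, missing_rate = 0.05, seed = 42)
  map <- build_map(apply_qc(g), anchors = tm)
  rho <- spearman_order(map, tibble::as_tibble(tm), chromosome = "6A")
  expect_gte(abs(rho), 0.98)
})

test_that("bin members share their frame's position and density is computed", {
  g <- geno_fixture(
    c("f1", "A", "A", "A", "B", "B", "B", "A", "B"),
    c("b2", "A", "A", "A", "B", "B", "B", "A", "B"),
    c("b3", "A", "A", "A", "B", "B", "B", "A", "-"),
    c("f4", "A", "A", "B", "B", "B", "B", "A", "B"),
    c("f5", "A", "B", "B", "B", "A", "B", "A", "B")
  )
  map <- build_map(g, lod_threshold = 0.1)
  tbl <- tidy(map)
  by_bin <- split(tbl$position, tbl$bin_id)
  for (p in by_bin) expect_equal(length(unique(p)), 1)
  expect_equal(attr(map, "density"),
               nrow(tbl) / attr(map, "total_length"))
  expect_true(all(is.na(tbl$chromosome))) # no anchors given
})

test_that("anchored assembly assigns chromosomes by majority vote", {
  tm <- simulate_true_map(data.frame(chromosome = c("1A", "1B"),
                                     length = c(70, 70)),
                          n_markers = 8, seed = 51)
  g <- simulate_population(tm, n_lines = 150, seed = 52)
  map <- build_map(apply_qc(g), anchors = tm)
  tbl <- tidy(map)
  expect_setequal(unique(tbl$chromosome), c("1A", "1B"))
  expect_true(all(substr(tbl$marker, 1, 2) == tbl$chromosome))
  # positions start at zero and never decrease within a group
  for (lg in unique(tbl$linkage_group)) {
    pos <- tbl$position[tbl$linkage_group == lg]
    expect_equal(min(pos), 0)
    expect_true(all(diff(sort(pos)) >= 0))
  }
})
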
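# DAG merging, conflict resolution, linearization and rescaling.

path_map <- function(markers, positions) {
  tibble::tibble(marker = markers, position = positions)
}

test_that("map union merges paths on shared vertices", {
  one <- maps_to_dag(list(path_map(c("A", "B", "C"), c(0, 5, 12))))
  expect_equal(one$edges$from, c("A", "B"))
  expect_equal(one$edges$to, c("B", "C"))
  expect_equal(one$edges$distance, c(5, 7))
  expect_equal(one$edges$support, c(1L, 1L))

  two <- maps_to_dag(list(path_map(c("A", "B", "C"), c(0, 5, 12)),
                          path_map(c("A", "B", "C"), c(0, 5, 12))))
  expect_equal(two$edges$support, c(2L, 2L))

  chain <- maps_to_dag(list(path_map(c("A", "B", "C"), c(0, 4, 9)),
                            path_map(c("B", "C", "D"), c(0, 5, 11))))
  lin <- linearize_dag(resolve_conflicts(chain))
  expect_equal(lin$marker, c("A", "B", "C", "D"))

  expect_warning(
    maps_to_dag(list(path_map(c("A", "B"), c(0, 3)),
                     path_map(c("X", "Y"), c(0, 3)))),
    "shares no marker"
  )
})

test_that("conflict resolution removes minimal-support edges until acyclic", {
  acyclic <- resolve_conflicts(maps_to_dag(list(
    path_map(c("A", "B", "C"), c(0, 1, 2)))))
  expect_equal(nrow(acyclic$conflict_log), 0)

  # X before Y in two maps, Y before X in one: the support-1 edge goes
  dag <- maps_to_dag(list(path_map(c("X", "Y"), c(0, 2)),
                          path_map(c("X", "Y"), c(0, 2)),
                          path_map(c("Y", "X"), c(0, 2))))
  res <- resolve_conflicts(dag)
  expect_equal(nrow(res$conflict_log), 1)
  expect_equal(res$conflict_log$from, "Y")
  expect_equal(res$conflict_log$support, 1L)

  # two swapped neighbours in one of two 20-marker maps: acyclic output,
  # no more deletions than a brute-force minimal feedback edge set
  mk <- sprintf("m%02d", 1:20)
  swapped <- mk
  swapped[10:11] <- swapped[11:10]
  dag2 <- maps_to_dag(list(path_map(mk, 0:19), path_map(swapped, 0:19)))
  res2 <- resolve_conflicts(dag2)
  g <- igraph::graph_from_data_frame(res2$edges[, c("from", "to")])
  expect_true(igraph::is_dag(g))
  # brute force: the unique 2-cycle here needs exactly one edge removed
  expect_lte(nrow(res2$conflict_log), 2)
})

test_that("linearization reproduces a single map and averages aligned maps", {
  m <- path_map(c("A", "B", "C", "D"), c(0, 3, 8, 20))
  lin <- linearize_dag(resolve_conflicts(maps_to_dag(list(m))))
  expect_equal(lin$marker, m$marker)
  expect_equal(lin$position, m$position, tolerance = 1e-12)

  # two maps at scale 1x and 2x -> mean = 1.5x before rescaling
  lin2 <- linearize_dag(resolve_conflicts(maps_to_dag(list(
    path_map(c("A", "B", "C"), c(0, 4, 10)),
    path_map(c("A", "B", "C"), c(0, 8, 20))
  ))))
  expect_equal(lin2$position, 1.5 * c(0, 4, 10))

  # disjoint halves plus shared anchors recover the true order
  truth <- sprintf("t%02d", 1:10)
  half1 <- truth[c(1, 3, 5, 6, 7, 9)]
  half2 <- truth[c(1, 2, 4, 6, 8, 9, 10)]
  lin3 <- linearize_dag(resolve_conflicts(maps_to_dag(list(
    path_map(half1, c(1, 3, 5, 6, 7, 9) * 2),
    path_map(half2, c(1, 2, 4, 6, 8, 9, 10) * 2)
  ))))
  expect_equal(lin3$marker, truth)
  expect_true(all(diff(lin3$position) >= 0))
  expect_equal(lin3$position[1], 0)
})

test_that("rescaling divides by the mean regression slope", {
  src <- path_map(c("A", "B", "C", "D"), c(0, 2, 5, 9))
  doubled <- path_map(src$marker, src$position * 2)
  rs <- rescale_map(doubled, list(one = src))
  expect_equal(rs$slopes$slope, 2)
  expect_equal(rs$consensus$position, src$position)

  same <- rescale_map(src, list(a = src, b = src))
  expect_equal(same$slopes$slope, c(1, 1))
  expect_equal(same$consensus$position, src$position)

  # slopes 1.2 and 0.8 average to 1: unchanged
  cons <- path_map(c("A", "B", "C"), c(0, 6, 12))
  s12 <- path_map(c("A", "B", "C"), c(0, 5, 10))
  s08 <- path_map(c("A", "B", "C"), c(0, 7.5, 15))
  rs2 <- rescale_map(cons, list(s12, s08))
  expect_equal(sort(rs2$slopes$slope), c(0.8, 1.2))
  expect_equal(rs2$consensus$position, cons$position)

  degen <- path_map(c("A", "B"), c(0, 0))
  expect_warning(rescale_map(cons, list(s12, degen)), "degenerate")
})

test_that("consensus of one map is that map; order and monotone invariants", {
  tm <- simulate_true_map(data.frame(chromosome = "2B", length = 90),
                          n_markers = 25, seed = 61)
  g <- simulate_population(tm, n_lines = 180, seed = 62)
  map <- build_map(apply_qc(g), anchors = tm)
  cons <- build_consensus(list(map))
  j <- dplyr::inner_join(tidy(cons), tidy(map), by = "marker")
  expect_equal(nrow(j), nrow(tidy(map)))
  expect_lt(max(abs(j$position.x - j$position.y)), 1e-9)

  # monotone, zero-origin positions; identical positions share a bin
  expect_true(all(diff(cons$position) >= 0))
  expect_equal(cons$position[1], 0)
  same_pos <- split(cons$bin_id, round(cons$position, 9))
  for (b in same_pos) expect_equal(length(unique(b)), 1)
})

test_that("source adjacencies not in the conflict log are respected", {
  tm <- simulate_true_map(data.frame(chromosome = "4A", length = 80),
                          n_markers = 20, seed = 71)
  maps <- lapply(1:3, function(i) {
    g <- simulate_population(tm, n_lines = 120, seed = 70 + i)
    keep <- sort(sample(tm$marker, 14))
    build_map(apply_qc(g[g$marker %in% keep, ]), anchors = tm)
  })
  cons <- build_consensus(maps)
  removed <- conflict_log(cons)
  rank_of <- setNames(seq_len(nrow(cons)), cons$marker)
  for (m in maps) {
    tbl <- dplyr::arrange(tidy(m), position, marker)
    adj <- tibble::tibble(from = tbl$marker[-nrow(tbl)],
                          to = tbl$marker[-1])
    adj <- dplyr::anti_join(adj, removed, by = c("from", "to"))
    # precedence (not necessarily adjacency) must hold in the consensus
    expect_true(all(rank_of[adj$from] <= rank_of[adj$to]))
  }
})

test_that("map-table summaries aggregate densities by genome and group", {
  per <- data.frame(
    chromosome = c("1A", "2A", "1B"),
    markers = c(100, 50, 200),
    bins = c(40, 25, 80),
    length = c(50, 25, 80)
  )
  s <- summarize_map_table(per)
  expect_equal(s$density[s$class == "chromosome" & s$level == "1A"], 2)
  expect_equal(s$markers[s$class == "genome" & s$level == "A"], 150)
  expect_equal(s$density[s$class == "genome" & s$level == "A"], 2)
  expect_equal(s$markers[s$class == "homoeologous_group" & s$level == "1"],
               300)
  expect_equal(s$density[s$class == "total"],
               round_half_up(350 / 155, 2))
})
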
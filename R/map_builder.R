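# Per-population linkage-map construction: recombinant bins, LOD grouping,
# seriation on the sum of adjacent recombination fractions, distance
# accumulation and chromosome assignment.

#' Cluster markers into recombinant bins
#'
#' Markers with zero observed recombinants (`k = 0` over at least one
#' informative line) are clustered by single linkage; missing data makes the
#' zero-recombinant relation non-transitive, which the transitive closure
#' absorbs. Each bin elects a frame marker: the member with the minimum
#' missing fraction, ties broken by a seeded random draw.
#'
#' @param genotypes QC'd genotype tibble.
#' @param seed Seed for tie-breaking in frame-marker election.
#' @return Tibble with one row per marker: `marker`, `bin_id`, `is_frame`,
#'   `missing_rate`. Bin ids number bins in input marker order.
#' @export
bin_markers <- function(genotypes, seed = 1) {
  calls <- geno_matrix(genotypes)
  pc <- pairwise_counts(calls)
  m <- nrow(calls)
  adj <- pc$k == 0 & pc$n > 0
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # number bins by first appearance in input order
  bin_id <- match(comp, unique(comp))
  miss <- rowMeans(is.na(calls) | calls == "H")

  rng <- local({
    set.seed(seed)
    function(n) sample.int(n, 1)
  })
  is_frame <- logical(m)
  for (b in unique(bin_id)) {
    members <- which(bin_id == b)
    best <- members[miss[members] == min(miss[members])]
    pick <- if (length(best) == 1) best else best[rng(length(best))]
    is_frame[pick] <- TRUE
  }
  tibble(
    marker = rownames(calls),
    bin_id = sprintf("bin_%04d", bin_id),
    is_frame = is_frame,
    missing_rate = unname(miss)
  )
}

#' Group frame markers by LOD threshold
#'
#' Single-linkage transitive closure: two frame markers share a group iff
#' they are connected by a chain of pairs with LOD at or above the
#' threshold. Frame markers in no qualifying pair are reported unlinked.
#'
#' @param genotypes QC'd genotype tibble restricted to frame markers (or any
#'   marker set to group).
#' @param lod_threshold Minimum LOD for a pair to link (default 7).
#' @return List with `groups` (list of character vectors of marker names)
#'   and `unlinked` (character vector).
#' @export
group_markers <- function(genotypes, lod_threshold = 7) {
  calls <- geno_matrix(genotypes)
  pc <- pairwise_counts(calls)
  adj <- pc$lod >= lod_threshold & pc$n > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  markers <- rownames(calls)
  groups <- split(markers, comp$membership)
  sizes <- lengths(groups)
  list(
    groups = unname(groups[sizes >= 2]),
    unlinked = unlist(unname(groups[sizes < 2]), use.names = FALSE) %||%
      character(0)
  )
}

#' Sum of adjacent recombination fractions of an order
#'
#' The seriation objective: the sum of meiotic recombination fractions
#' between consecutive markers in the given order.
#'
#' @param order Character or integer vector giving the marker order.
#' @param r_mat Symmetric matrix of meiotic recombination fractions with
#'   marker dimnames.
#' @return The SARF value (numeric scalar).
#' @export
sarf <- function(order, r_mat) {
  if (is.character(order)) order <- match(order, rownames(r_mat))
  if (length(order) < 2) return(0)
  sum(r_mat[cbind(order[-length(order)], order[-1])])
}

# Greedy nearest-neighbour chain: seed with the globally closest pair, then
# repeatedly append the unplaced marker closest to either end. Ties broken
# by marker name for determinism.
.greedy_chain <- function(r_mat) {
  m <- nrow(r_mat)
  if (m == 1) return(1L)
  nm <- rownames(r_mat)
  d <- r_mat
  diag(d) <- Inf
  best <- which(d == min(d), arr.ind = TRUE)
  best <- best[order(nm[best[, 1]], nm[best[, 2]]), , drop = FALSE]
  path <- as.integer(best[1, ])
  free <- setdiff(seq_len(m), path)
  while (length(free) > 0) {
    ends <- c(path[1], path[length(path)])
    cand <- d[ends, free, drop = FALSE]
    hit <- which(cand == min(cand), arr.ind = TRUE)
    hit <- hit[order(nm[free[hit[, 2]]]), , drop = FALSE]
    v <- free[hit[1, 2]]
    if (hit[1, 1] == 1) path <- c(v, path) else path <- c(path, v)
    free <- setdiff(free, v)
  }
  path
}

.two_opt <- function(path, r_mat) {
  m <- length(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        # reversing path[i..j] changes only the two boundary adjacencies
        before <- 0
        after <- 0
        if (i > 1) {
          before <- before + r_mat[path[i - 1], path[i]]
          after <- after + r_mat[path[i - 1], path[j]]
        }
        if (j < m) {
          before <- before + r_mat[path[j], path[j + 1]]
          after <- after + r_mat[path[i], path[j + 1]]
        }
        if (after < before - 1e-12) {
          path[i:j] <- rev(path[i:j])
          improved <- TRUE
        }
      }
    }
  }
  path
}

# Window ripple: exhaustively re-permute every sliding window of the given
# width, keeping any strict SARF improvement, until a full pass gains nothing.
.ripple <- function(path, r_mat, window = 4) {
  m <- length(path)
  if (m <= 2) return(path)
  w <- min(window, m)
  perms <- .permutations(w)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (s in seq_len(m - w + 1)) {
      idx <- s:(s + w - 1)
      base <- path
      best_val <- sarf(path, r_mat)
      best_path <- path
      for (p in seq_len(nrow(perms))) {
        cand <- base
        cand[idx] <- base[idx][perms[p, ]]
        v <- sarf(cand, r_mat)
        if (v < best_val - 1e-12) {
          best_val <- v
          best_path <- cand
        }
      }
      if (!identical(best_path, path)) {
        path <- best_path
        improved <- TRUE
      }
    }
  }
  path
}

# All permutations of 1..n as a matrix (n small).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1
    }
  }
  out
}

#' Order the markers of one linkage group
#'
#' Seriation minimizing the sum of adjacent meiotic recombination fractions
#' (SARF): a greedy nearest-neighbour chain is refined by 2-opt segment
#' reversal and an exhaustive window ripple (window 4) until neither gains.
#' The orientation is canonicalized so the first marker name sorts before
#' the last, making output deterministic.
#'
#' @param genotypes QC'd genotype tibble restricted to one group, or `NULL`
#'   if `r_mat` is given.
#' @param r_mat Optional precomputed symmetric matrix of meiotic
#'   recombination fractions (marker dimnames); computed from `genotypes`
#'   when absent.
#' @return Character vector of marker names in map order.
#' @export
order_markers <- function(genotypes = NULL, r_mat = NULL) {
  if (is.null(r_mat)) {
    stopifnot(!is.null(genotypes))
    r_mat <- pairwise_counts(geno_matrix(genotypes))$r
  }
  m <- nrow(r_mat)
  if (m < 2) return(rownames(r_mat))
  path <- .greedy_chain(r_mat)
  path <- .two_opt(path, r_mat)
  path <- .ripple(path, r_mat, window = 4)
  nm <- rownames(r_mat)[path]
  if (nm[1] > nm[length(nm)]) nm <- rev(nm)
  nm
}

#' Assemble a linkage map from ordered groups
#'
#' Accumulates map distances (default Kosambi) between consecutive frame
#' markers of each ordered group, reintegrates binned markers at their frame
#' marker's position, and, when anchors are supplied, assigns each group to
#' the chromosome carried by the majority of its members (ties leave the
#' group unassigned with a warning) and orients the group along increasing
#' anchor position where possible.
#'
#' @param ordered_groups List of character vectors: frame markers in map
#'   order, one per group.
#' @param bins Bin table from [bin_markers()].
#' @param r_mat Symmetric meiotic recombination-fraction matrix covering all
#'   frame markers.
#' @param anchors Optional data frame `marker`, `chromosome` and optionally
#'   `position` (used for orientation).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param unlinked Character vector of unlinked frame markers.
#' @return A `linkage_map`: tibble `marker`, `linkage_group`, `chromosome`,
#'   `position`, `bin_id`, `is_frame`, with attributes `total_length`,
#'   `density`, `unlinked`.
#' @export
assemble_map <- function(ordered_groups, bins, r_mat, anchors = NULL,
                         map_function = c("kosambi", "haldane"),
                         unlinked = character(0)) {
  map_function <- match.arg(map_function)
  group_rows <- vector("list", length(ordered_groups))
  for (gi in seq_along(ordered_groups)) {
    frames <- ordered_groups[[gi]]
    if (length(frames) < 2) {
      pos <- rep(0, length(frames))
    } else {
      r_adj <- r_mat[cbind(frames[-length(frames)], frames[-1])]
      pos <- c(0, cumsum(map_distance(r_adj, map_function)))
    }
    frame_tbl <- bins[bins$is_frame, , drop = FALSE]
    frame_of_bin <- setNames(frame_tbl$marker, frame_tbl$bin_id)
    members <- bins[bins$bin_id %in% frame_tbl$bin_id[frame_tbl$marker %in%
                                                        frames], ,
                    drop = FALSE]
    frame_pos <- setNames(pos, frames)
    members$position <- unname(frame_pos[frame_of_bin[members$bin_id]])

    chrom <- NA_character_
    if (!is.null(anchors)) {
      votes <- anchors$chromosome[anchors$marker %in% members$marker]
      if (length(votes) > 0) {
        tab <- sort(table(votes), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) {
          warning("anchor tie for group ", gi, "; left unassigned",
                  call. = FALSE)
        } else {
          chrom <- names(tab)[1]
        }
      }
      # orient along increasing anchor position when informative
      if ("position" %in% names(anchors) && !is.na(chrom)) {
        anc <- anchors[anchors$marker %in% members$marker &
                         anchors$chromosome %in% chrom, , drop = FALSE]
        shared <- intersect(members$marker, anc$marker)
        if (length(shared) >= 2) {
          rho <- suppressWarnings(cor(
            members$position[match(shared, members$marker)],
            anc$position[match(shared, anc$marker)],
            method = "spearman"
          ))
          if (!is.na(rho) && rho < 0) {
            members$position <- max(members$position) - members$position
          }
        }
      }
    }
    members$linkage_group <- sprintf("LG%d", gi)
    members$chromosome <- chrom
    group_rows[[gi]] <- members |>
      dplyr::arrange(.data$position, .data$marker) |>
      dplyr::select("marker", "linkage_group", "chromosome",
                    "position", "bin_id", "is_frame")
  }
  out <- dplyr::bind_rows(group_rows)
  if (nrow(out) == 0) {
    out <- tibble(marker = character(), linkage_group = character(),
                  chromosome = character(), position = numeric(),
                  bin_id = character(), is_frame = logical())
  }
  total_length <- sum(purrr::map_dbl(group_rows, function(g) {
    if (nrow(g) == 0) 0 else max(g$position)
  }))
  attr(out, "total_length") <- total_length
  attr(out, "density") <- if (total_length > 0) nrow(out) / total_length
  else NA_real_
  attr(out, "unlinked") <- unlinked
  class(out) <- c("linkage_map", class(tibble()))
  out
}

#' Build a linkage map for one population
#'
#' Runs the full single-population pipeline on a QC'd genotype table:
#' recombinant binning, two-point estimation among frame markers, grouping
#' at the LOD threshold, SARF seriation of each group, distance
#' accumulation, bin reintegration and (optionally) anchor-based chromosome
#' assignment.
#'
#' @param genotypes QC'd genotype tibble.
#' @param lod_threshold Grouping threshold (default 7).
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @param anchors Optional anchor table (`marker`, `chromosome`, optionally
#'   `position`) for chromosome assignment and orientation; for simulated
#'   data, the true map can serve directly.
#' @param seed Seed for frame-marker tie-breaking.
#' @return A `linkage_map` (see [assemble_map()]).
#' @export
build_map <- function(genotypes, lod_threshold = 7,
                      map_function = c("kosambi", "haldane"),
                      anchors = NULL, seed = 1) {
  map_function <- match.arg(map_function)
  if (!is.null(anchors) && inherits(anchors, "true_map")) {
    anchors <- as_tibble(anchors)[, c("marker", "chromosome", "position")]
  }
  bins <- bin_markers(genotypes, seed = seed)
  frames <- bins$marker[bins$is_frame]
  frame_geno <- genotypes[match(frames, genotypes$marker), , drop = FALSE]
  calls <- geno_matrix(frame_geno)
  pc <- pairwise_counts(calls)

  adj <- pc$lod >= lod_threshold & pc$n > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(frames, comp$membership)
  sizes <- lengths(groups)
  unlinked <- unlist(unname(groups[sizes < 2]), use.names = FALSE) %||%
    character(0)
  groups <- unname(groups[sizes >= 2])

  ordered <- lapply(groups, function(gr) {
    order_markers(r_mat = pc$r[gr, gr, drop = FALSE])
  })
  # deterministic group numbering: by first marker name
  ordered <- ordered[order(purrr::map_chr(ordered, 1))]
  assemble_map(ordered, bins, pc$r, anchors = anchors,
               map_function = map_function, unlinked = unlinked)
}
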
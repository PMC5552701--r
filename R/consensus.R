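# Consensus-map construction: each input linkage group is a directed path
# of markers; paths are merged on shared vertices into one weighted graph,
# order conflicts are resolved by deleting weakly supported edges until the
# graph is acyclic, the DAG is linearized by a mean-position approximation
# with an isotonic (pool-adjacent-violators) projection, and positions are
# rescaled by the mean regression slope against the source maps.

# A map restricted to one chromosome -> tibble(marker, position) ordered.
.map_path <- function(map) {
  tibble(marker = map$marker, position = map$position) |>
    dplyr::arrange(.data$position, .data$marker)
}

#' Merge linkage maps of one chromosome into a weighted directed graph
#'
#' Each input map contributes the directed path of its markers in map order
#' (co-positioned markers chained in name order with zero distance); the
#' union graph counts, for every adjacency, how many maps support it
#' (each map carrying equal weight 1) and accumulates adjacent distances.
#' A map sharing no marker with the union of the previous maps is excluded
#' with a warning. A map whose order over three or more shared markers runs
#' against its best-overlapping neighbour is flipped before merging;
#' smaller reversed overlaps are left for conflict resolution.
#'
#' @param maps List of `linkage_map` tibbles (or plain tibbles with
#'   `marker`, `position`), each restricted to one chromosome.
#' @return A `map_dag`: list with `edges` (tibble `from`, `to`, `distance`
#'   mean over supporting maps, `support`), `vertices`, and `source_maps`
#'   (the oriented `marker`/`position` paths).
#' @export
maps_to_dag <- function(maps) {
  stopifnot(length(maps) >= 1)
  paths <- lapply(maps, .map_path)
  names(paths) <- names(maps) %||% as.character(seq_along(maps))
  # Accrete paths onto the union, flipping any path whose shared-marker
  # order runs against its best-overlapping retained path. Multi-pass, so
  # a path connected only through later maps is still retained.
  kept <- paths[1]
  pending <- paths[-1]
  repeat {
    placed_any <- FALSE
    still <- list()
    for (nm in names(pending)) {
      p <- pending[[nm]]
      overlap <- purrr::map_int(kept, function(q) {
        length(intersect(p$marker, q$marker))
      })
      if (all(overlap == 0)) {
        still[[nm]] <- p
        next
      }
      ref <- kept[[which.max(overlap)]]
      both <- intersect(p$marker, ref$marker)
      # flip only on 3+ shared markers: a reversed 2-marker overlap is
      # indistinguishable from a local order conflict, which belongs to
      # conflict resolution, not orientation
      if (length(both) >= 3) {
        rho <- suppressWarnings(cor(
          p$position[match(both, p$marker)],
          ref$position[match(both, ref$marker)],
          method = "spearman"
        ))
        if (!is.na(rho) && rho < 0) {
          p$position <- max(p$position) - p$position
          p <- dplyr::arrange(p, .data$position, .data$marker)
        }
      }
      kept <- c(kept, setNames(list(p), nm))
      placed_any <- TRUE
    }
    pending <- still
    if (!placed_any || length(pending) == 0) break
  }
  for (nm in names(pending)) {
    warning("map '", nm, "' shares no marker with the others; excluded",
            call. = FALSE)
  }
  edge_rows <- lapply(kept, function(p) {
    if (nrow(p) < 2) return(NULL)
    tibble(
      from = p$marker[-nrow(p)],
      to = p$marker[-1],
      distance = diff(p$position)
    )
  })
  edges <- dplyr::bind_rows(edge_rows) |>
    dplyr::summarise(distance = mean(.data$distance),
                     support = dplyr::n(),
                     .by = c("from", "to"))
  structure(
    list(
      edges = edges,
      vertices = unique(unlist(lapply(kept, `[[`, "marker"))),
      source_maps = kept
    ),
    class = "map_dag"
  )
}

#' Resolve order conflicts in a merged map graph
#'
#' While any strongly connected component contains more than one marker,
#' deletes the within-component edge with minimal support (ties broken by
#' larger distance, then lexicographically by endpoint names) and logs the
#' deletion. Always terminates; the result is acyclic.
#'
#' @param dag A `map_dag` from [maps_to_dag()].
#' @return The acyclic `map_dag`, with the deletions in the `conflict_log`
#'   element (tibble `from`, `to`, `distance`, `support`).
#' @export
resolve_conflicts <- function(dag) {
  edges <- dag$edges
  log_rows <- list()
  repeat {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       vertices = dag$vertices)
    scc <- igraph::components(g, mode = "strong")
    if (max(scc$csize) <= 1) break
    memb <- scc$membership[edges$from]
    in_scc <- memb == scc$membership[edges$to] &
      scc$csize[memb] > 1
    cand <- edges[in_scc, , drop = FALSE]
    cand <- cand[order(cand$support, -cand$distance, cand$from, cand$to), ,
                 drop = FALSE]
    victim <- cand[1, , drop = FALSE]
    log_rows <- c(log_rows, list(victim))
    edges <- dplyr::anti_join(edges, victim[, c("from", "to")],
                              by = c("from", "to"))
  }
  dag$edges <- edges
  dag$conflict_log <- dplyr::bind_rows(log_rows) %||%
    tibble(from = character(), to = character(),
           distance = numeric(), support = integer())
  dag
}

# Anchored mean positions: maps are processed in order; the first keeps its
# coordinates shifted to start at 0, each later map is shifted so that its
# first marker already placed by earlier maps lands on the running mean
# estimate for that marker. Returns per-marker mean anchored position.
.anchored_means <- function(source_maps) {
  est_sum <- numeric(0)
  est_n <- integer(0)
  upd <- function(markers, pos) {
    new <- setdiff(markers, names(est_sum))
    if (length(new) > 0) {
      est_sum[new] <<- 0
      est_n[new] <<- 0L
    }
    est_sum[markers] <<- est_sum[markers] + pos
    est_n[markers] <<- est_n[markers] + 1L
  }
  for (i in seq_along(source_maps)) {
    p <- source_maps[[i]]
    if (i == 1) {
      shift <- -min(p$position)
    } else {
      placed <- names(est_sum)
      first_shared <- p$marker[p$marker %in% placed][1]
      if (is.na(first_shared)) {
        shift <- -min(p$position) # disconnected; keep own scale from 0
      } else {
        target <- est_sum[first_shared] / est_n[first_shared]
        shift <- target - p$position[match(first_shared, p$marker)]
      }
    }
    upd(p$marker, p$position + shift)
  }
  est_sum / est_n
}

#' Linearize an acyclic map graph into consensus positions
#'
#' Order: topological sort of the DAG with ties broken by mean anchored
#' source position, then marker name. Position: the mean over source maps
#' of each marker's anchored position (maps aligned by shifting each to its
#' first shared marker), projected onto the consensus order by
#' pool-adjacent-violators so positions are nondecreasing, then shifted to
#' start at 0. For a single input map this reproduces that map exactly.
#'
#' @param dag An acyclic `map_dag` (after [resolve_conflicts()]).
#' @return Tibble `marker`, `position` in consensus order.
#' @export
linearize_dag <- function(dag) {
  means <- .anchored_means(dag$source_maps)
  vertices <- dag$vertices
  edges <- dag$edges
  # Kahn's algorithm with (mean position, name) priority
  indeg <- setNames(integer(length(vertices)), vertices)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  succ <- split(edges$to, edges$from)
  avail <- vertices[indeg == 0]
  out <- character(length(vertices))
  for (i in seq_along(vertices)) {
    if (length(avail) == 0) stop("graph is not acyclic", call. = FALSE)
    pick <- avail[order(means[avail], avail)][1]
    out[i] <- pick
    avail <- setdiff(avail, pick)
    for (s in succ[[pick]] %||% character(0)) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0) avail <- c(avail, s)
    }
  }
  pos <- unname(means[out])
  pos <- isoreg(seq_along(pos), pos)$yf
  tibble(marker = out, position = pos - pos[1])
}

#' Rescale consensus positions by source-map regression slopes
#'
#' For each source map with at least two shared markers and nonzero position
#' variance, computes the ordinary least-squares slope of consensus
#' positions on that map's positions; consensus positions are divided by
#' the mean slope (equal weights). Degenerate maps are skipped with a
#' warning.
#'
#' @param consensus Tibble `marker`, `position` (one chromosome).
#' @param source_maps List of `marker`/`position` tibbles.
#' @return List: `consensus` (rescaled tibble) and `slopes` (tibble
#'   `map`, `slope`, `n_shared`).
#' @export
rescale_map <- function(consensus, source_maps) {
  slopes <- purrr::imap(source_maps, function(p, i) {
    shared <- intersect(consensus$marker, p$marker)
    if (length(shared) < 2) {
      return(tibble(map = as.character(i), slope = NA_real_,
                    n_shared = length(shared)))
    }
    x <- p$position[match(shared, p$marker)]
    y <- consensus$position[match(shared, consensus$marker)]
    vx <- stats::var(x)
    slope <- if (is.na(vx) || vx == 0) NA_real_ else
      stats::cov(x, y) / vx
    tibble(map = as.character(i), slope = slope, n_shared = length(shared))
  }) |> dplyr::bind_rows()
  usable <- slopes$slope[!is.na(slopes$slope)]
  if (length(usable) < length(source_maps)) {
    warning("map(s) with degenerate regression skipped in rescaling",
            call. = FALSE)
  }
  if (length(usable) > 0) {
    consensus$position <- consensus$position / mean(usable)
  }
  list(consensus = consensus, slopes = slopes)
}

# positions -> bin ids: markers at (numerically) identical consensus
# positions share a recombinant bin.
.position_bins <- function(position, tol = 1e-9) {
  cumsum(c(TRUE, diff(position) > tol))
}

#' Build a consensus map from chromosome-assigned linkage maps
#'
#' Per chromosome: [maps_to_dag()], [resolve_conflicts()],
#' [linearize_dag()], [rescale_map()]; markers at identical consensus
#' positions form recombinant bins. A chromosome present in no map is
#' absent from the output.
#'
#' @param maps List of `linkage_map`s (chromosome-assigned) or tibbles with
#'   `marker`, `chromosome`, `position`.
#' @return A `consensus_map`: tibble `marker`, `chromosome`, `position`,
#'   `bin_id`, `n_maps`, `sources`, with attributes `conflict_log` and
#'   `slopes` (both tibbles with a `chromosome` column). Summarise with
#'   [summarize_map_table()] via [glance()] or [consensus_summary()].
#' @export
build_consensus <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- sprintf("map%d", seq_along(maps))
  }
  chroms <- unique(unlist(lapply(maps, function(m) m$chromosome)))
  chroms <- sort(chroms[!is.na(chroms)])
  per_chrom <- lapply(chroms, function(ch) {
    sub <- purrr::keep(maps, function(m) ch %in% m$chromosome)
    # one directed path per linkage group: a chromosome split across
    # several groups in one map contributes several independent paths
    sub_maps <- list()
    for (nm in names(sub)) {
      m <- sub[[nm]]
      m <- m[!is.na(m$chromosome) & m$chromosome == ch, , drop = FALSE]
      if ("linkage_group" %in% names(m) &&
            dplyr::n_distinct(m$linkage_group) > 1) {
        for (lg in unique(m$linkage_group)) {
          sub_maps[[paste0(nm, ".", lg)]] <-
            m[m$linkage_group == lg, c("marker", "position"), drop = FALSE]
        }
      } else {
        sub_maps[[nm]] <- m[, c("marker", "position"), drop = FALSE]
      }
    }
    dag <- maps_to_dag(sub_maps)
    dag <- resolve_conflicts(dag)
    lin <- linearize_dag(dag)
    rs <- rescale_map(lin, dag$source_maps)
    cons <- rs$consensus
    provenance <- purrr::imap(sub_maps, function(p, nm) {
      tibble(marker = p$marker, map = sub("\\.LG[0-9]+$", "", nm))
    }) |> dplyr::bind_rows() |>
      dplyr::summarise(n_maps = dplyr::n_distinct(.data$map),
                       sources = paste(sort(unique(.data$map)),
                                       collapse = ","),
                       .by = "marker")
    cons <- cons |>
      dplyr::mutate(chromosome = ch,
                    bin_id = sprintf("%s_bin%04d", ch,
                                     .position_bins(.data$position))) |>
      dplyr::left_join(provenance, by = "marker") |>
      dplyr::select("marker", "chromosome", "position", "bin_id",
                    "n_maps", "sources")
    conflicts <- dag$conflict_log
    conflicts$chromosome <- rep(ch, nrow(conflicts))
    slopes <- rs$slopes
    slopes$chromosome <- ch
    list(consensus = cons, conflicts = conflicts, slopes = slopes)
  })
  out <- dplyr::bind_rows(lapply(per_chrom, `[[`, "consensus"))
  attr(out, "conflict_log") <- dplyr::bind_rows(lapply(per_chrom, `[[`,
                                                       "conflicts"))
  attr(out, "slopes") <- dplyr::bind_rows(lapply(per_chrom, `[[`, "slopes"))
  class(out) <- c("consensus_map", class(tibble()))
  out
}

#' Conflict log of a consensus map
#' @param consensus A `consensus_map`.
#' @return Tibble of adjacencies deleted during conflict resolution.
#' @export
conflict_log <- function(consensus) {
  attr(consensus, "conflict_log") %||%
    tibble(from = character(), to = character(),
           distance = numeric(), support = integer(),
           chromosome = character())
}

#' Rescaling slopes of a consensus map
#' @param consensus A `consensus_map`.
#' @return Tibble `map`, `slope`, `n_shared`, `chromosome`.
#' @export
rescale_slopes <- function(consensus) {
  attr(consensus, "slopes")
}

#' Summarize a map's per-chromosome statistics
#'
#' Aggregates a per-chromosome table of marker counts, recombinant-bin
#' counts and lengths into per-chromosome, per-genome, per-homoeologous-
#' group and total rows, with marker density (markers/cM) rounded half-up
#' to 2 decimals. Genome letters and group numbers are parsed from the
#' chromosome names (wheat-style `<group><genome>`).
#'
#' @param per_chromosome Data frame with columns `chromosome`, `markers`,
#'   `bins`, `length`.
#' @param nomenclature Optional chromosome nomenclature table (see
#'   [parse_chromosome()]).
#' @return Tibble `class` (chromosome/genome/homoeologous_group/total),
#'   `level`, `markers`, `bins`, `length`, `density`.
#' @export
#' @examples
#' summarize_map_table(data.frame(
#'   chromosome = c("1A", "1B"), markers = c(100, 200),
#'   bins = c(40, 60), length = c(50, 80)
#' ))
summarize_map_table <- function(per_chromosome, nomenclature = NULL) {
  tbl <- as_tibble(per_chromosome)
  stopifnot(all(c("chromosome", "markers", "bins", "length") %in% names(tbl)))
  parsed <- parse_chromosome(tbl$chromosome, nomenclature)
  tbl$genome <- parsed$genome
  tbl$group <- parsed$group

  agg <- function(df, class, level) {
    tibble(
      class = class,
      level = as.character(level),
      markers = sum(df$markers),
      bins = sum(df$bins),
      length = sum(df$length),
      density = round_half_up(sum(df$markers) / sum(df$length), 2)
    )
  }
  rows <- list()
  for (i in seq_len(nrow(tbl))) {
    rows <- c(rows, list(agg(tbl[i, ], "chromosome", tbl$chromosome[i])))
  }
  for (g in unique(tbl$genome[!is.na(tbl$genome)])) {
    rows <- c(rows, list(agg(tbl[which(tbl$genome == g), ], "genome", g)))
  }
  for (h in sort(unique(tbl$group[!is.na(tbl$group)]))) {
    rows <- c(rows, list(agg(tbl[which(tbl$group == h), ],
                             "homoeologous_group", h)))
  }
  rows <- c(rows, list(agg(tbl, "total", "total")))
  dplyr::bind_rows(rows)
}

#' Per-chromosome statistics of a consensus map
#'
#' Counts markers and recombinant bins and measures length (max position)
#' per chromosome, then aggregates with [summarize_map_table()].
#'
#' @param consensus A `consensus_map` (or `linkage_map` with chromosome
#'   assignments).
#' @param nomenclature Optional chromosome nomenclature table.
#' @return See [summarize_map_table()].
#' @export
consensus_summary <- function(consensus, nomenclature = NULL) {
  bin_col <- if ("bin_id" %in% names(consensus)) "bin_id" else NULL
  per <- as_tibble(consensus) |>
    dplyr::filter(!is.na(.data$chromosome)) |>
    dplyr::summarise(
      markers = dplyr::n(),
      bins = if (is.null(bin_col)) NA_integer_ else
        dplyr::n_distinct(.data$bin_id),
      length = max(.data$position),
      .by = "chromosome"
    )
  summarize_map_table(per, nomenclature)
}
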
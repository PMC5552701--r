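# Pipeline orchestration: simulate -> qc -> buildmap -> consensus ->
# validate -> duplication from a single YAML configuration, writing TSV and
# JSON artifacts plus a JSON run manifest. Subcommands recompute the
# upstream stages they depend on in memory (everything is deterministic
# given the seed), and write only their own artifacts.

.default_config <- function() {
  list(
    seed = 1,
    simulate = list(
      chromosomes = list(list(chromosome = "1A", length = 120),
                         list(chromosome = "1B", length = 110),
                         list(chromosome = "2A", length = 130)),
      n_markers = 30,
      n_populations = 4,
      n_lines = 200,
      selfing_generation = 6,
      population_marker_fraction = 0.5,
      missing_rate = 0.05,
      error_rate = 0.005,
      residual_het_rate = 1
    ),
    qc = list(max_missing_rate = 0.10, allele_freq_min = 0.3,
              allele_freq_max = 0.7),
    build = list(lod_threshold = 7, map_function = "kosambi"),
    validate = list(window = 5, gap_threshold = 10)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  qc <- cfg$qc
  chk(qc$max_missing_rate >= 0 && qc$max_missing_rate <= 1,
      "qc.max_missing_rate must be in [0, 1]")
  chk(qc$allele_freq_min >= 0 && qc$allele_freq_min < qc$allele_freq_max &&
        qc$allele_freq_max <= 1,
      "qc allele frequency bounds must satisfy 0 <= min < max <= 1")
  chk(cfg$build$lod_threshold > 0, "build.lod_threshold must be positive")
  chk(cfg$build$map_function %in% c("kosambi", "haldane"),
      "build.map_function must be 'kosambi' or 'haldane'")
  chk(cfg$validate$window > 0, "validate.window must be positive")
  chk(cfg$validate$gap_threshold > 0,
      "validate.gap_threshold must be positive")
  sim <- cfg$simulate
  chk(sim$n_populations >= 2, "simulate.n_populations must be >= 2")
  chk(all(sim$population_marker_fraction > 0 &
            sim$population_marker_fraction <= 1),
      "simulate.population_marker_fraction must be in (0, 1]")
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Run the mapping pipeline from a configuration
#'
#' Subcommands: `simulate` (panel + true map), `qc` (filtered genotypes +
#' attrition reports), `buildmap` (one linkage map per population),
#' `consensus` (merged map, summary, conflict log), `validate` (Spearman
#' concordance vs the true map, sharing report, interval profile),
#' `duplication` (locus pairs and categories from the simulated assay
#' registry), or `all`. The resolved configuration, seed and thresholds are
#' written to `manifest.json`; reruns with the same seed produce identical
#' artifacts.
#'
#' @param config Path to a YAML file or a config list; omitted fields take
#'   package defaults.
#' @param subcommand One of `simulate`, `qc`, `buildmap`, `consensus`,
#'   `validate`, `duplication`, `all`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a named list of the artifacts written (paths).
#' @export
run_pipeline <- function(config = NULL,
                         subcommand = c("all", "simulate", "qc", "buildmap",
                                        "consensus", "validate",
                                        "duplication"),
                         out_dir = ".", seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- .default_config()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) cfg <- .merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- seed
  .validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  put <- function(name, path) artifacts[[name]] <<- path

  sim <- cfg$simulate
  chroms <- dplyr::bind_rows(lapply(sim$chromosomes, as_tibble))
  true_map <- simulate_true_map(chroms, n_markers = sim$n_markers,
                                seed = cfg$seed)
  if (!is.null(sim$duplications)) {
    true_map <- add_duplications(
      true_map, dplyr::bind_rows(lapply(sim$duplications, as_tibble)))
  }
  if (!is.null(sim$translocation)) {
    tr <- sim$translocation
    true_map <- apply_translocation(true_map, tr$from, tr$to,
                                    tr$start, tr$end)
  }
  panel <- make_panel(
    true_map, n_populations = sim$n_populations, n_lines = sim$n_lines,
    selfing_generation = sim$selfing_generation,
    population_marker_fraction = sim$population_marker_fraction,
    missing_rate = sim$missing_rate, error_rate = sim$error_rate,
    residual_het_rate = sim$residual_het_rate, seed = cfg$seed + 1
  )
  if (subcommand %in% c("simulate", "all")) {
    tm_path <- file.path(out_dir, "true_map.tsv")
    readr::write_tsv(as_tibble(true_map), tm_path, progress = FALSE)
    put("true_map", tm_path)
    for (nm in names(panel$populations)) {
      p <- file.path(out_dir, sprintf("genotypes_%s.tsv", nm))
      write_genotypes(panel$populations[[nm]], p)
      put(paste0("genotypes_", nm), p)
    }
    sh <- file.path(out_dir, "sharing.tsv")
    readr::write_tsv(panel$sharing, sh, progress = FALSE)
    put("sharing", sh)
  }
  if (subcommand == "simulate") {
    return(invisible(.finish_run(artifacts, cfg, out_dir, put)))
  }

  qc_cfg <- cfg$qc
  cleaned <- lapply(panel$populations, function(g) {
    apply_qc(g, max_missing_rate = qc_cfg$max_missing_rate,
             allele_freq_min = qc_cfg$allele_freq_min,
             allele_freq_max = qc_cfg$allele_freq_max)
  })
  if (subcommand %in% c("qc", "all")) {
    reports <- dplyr::bind_rows(lapply(cleaned, qc_report), .id = "population")
    p <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(reports, p, pretty = TRUE, digits = NA)
    put("qc_report", p)
  }
  if (subcommand == "qc") {
    for (nm in names(cleaned)) {
      p <- file.path(out_dir, sprintf("genotypes_qc_%s.tsv", nm))
      write_genotypes(cleaned[[nm]], p)
      put(paste0("genotypes_qc_", nm), p)
    }
    return(invisible(.finish_run(artifacts, cfg, out_dir, put)))
  }

  anchors <- as_tibble(true_map)[, c("marker", "chromosome", "position")]
  maps <- lapply(cleaned, function(g) {
    build_map(g, lod_threshold = cfg$build$lod_threshold,
              map_function = cfg$build$map_function,
              anchors = anchors, seed = cfg$seed)
  })
  if (subcommand %in% c("buildmap", "all")) {
    for (nm in names(maps)) {
      p <- file.path(out_dir, sprintf("map_%s.tsv", nm))
      write_map(maps[[nm]], p)
      put(paste0("map_", nm), p)
    }
  }
  if (subcommand == "buildmap") {
    return(invisible(.finish_run(artifacts, cfg, out_dir, put)))
  }

  consensus <- build_consensus(maps)
  if (subcommand %in% c("consensus", "all")) {
    p <- file.path(out_dir, "consensus.tsv")
    write_consensus(consensus, p)
    put("consensus", p)
    cl <- file.path(out_dir, "conflict_log.tsv")
    readr::write_tsv(conflict_log(consensus), cl, progress = FALSE)
    put("conflict_log", cl)
    sm <- file.path(out_dir, "consensus_summary.json")
    jsonlite::write_json(consensus_summary(consensus), sm, pretty = TRUE,
                         digits = NA)
    put("consensus_summary", sm)
  }
  if (subcommand == "consensus") {
    return(invisible(.finish_run(artifacts, cfg, out_dir, put)))
  }

  if (subcommand %in% c("validate", "all")) {
    truth_tbl <- as_tibble(true_map)
    rho <- dplyr::bind_rows(lapply(
      sort(unique(consensus$chromosome)), function(ch) {
        tibble(chromosome = ch,
               spearman_rho = spearman_order(consensus, truth_tbl,
                                             chromosome = ch))
      }))
    p <- file.path(out_dir, "validation_vs_truth.tsv")
    readr::write_tsv(rho, p, progress = FALSE)
    put("validation_vs_truth", p)
    prof <- interval_profile(consensus, window = cfg$validate$window,
                             gap_threshold = cfg$validate$gap_threshold)
    gp <- file.path(out_dir, "gaps.tsv")
    readr::write_tsv(prof$gaps, gp, progress = FALSE)
    put("gaps", gp)
    wp <- file.path(out_dir, "interval_windows.tsv")
    readr::write_tsv(prof$windows, wp, progress = FALSE)
    put("interval_windows", wp)
  }
  if (subcommand == "validate") {
    return(invisible(.finish_run(artifacts, cfg, out_dir, put)))
  }

  if (subcommand %in% c("duplication", "all")) {
    registry <- as_tibble(true_map) |>
      dplyr::filter(.data$assay %in% consensus$marker)
    multi <- find_multi_locus(registry)
    if (nrow(multi) > 0) {
      pairs <- expand_pairs(multi)
      cls <- classify_pairs(pairs)
      pp <- file.path(out_dir, "locus_pairs.tsv")
      readr::write_tsv(cls$pairs, pp, progress = FALSE)
      put("locus_pairs", pp)
      cp <- file.path(out_dir, "pair_categories.tsv")
      readr::write_tsv(cls$counts, cp, progress = FALSE)
      put("pair_categories", cp)
      mp <- file.path(out_dir, "pair_matrix.tsv")
      readr::write_tsv(cls$pair_matrix, mp, progress = FALSE)
      put("pair_matrix", mp)
    } else {
      cp <- file.path(out_dir, "pair_categories.tsv")
      readr::write_tsv(tibble(category = character(), n = integer()), cp,
                       progress = FALSE)
      put("pair_categories", cp)
    }
  }
  invisible(.finish_run(artifacts, cfg, out_dir, put))
}

.finish_run <- function(artifacts, cfg, out_dir, put) {
  mp <- file.path(out_dir, "manifest.json")
  write_manifest(mp, seed = cfg$seed, config = cfg)
  artifacts$manifest <- mp
  artifacts
}
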
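#' Pipeline configuration
#'
#' Collects every stage parameter and input path of the end-to-end
#' analysis. In synthetic mode (the default) the cohort is generated by
#' [generate_cohort()]; otherwise `cohort_csv`/`behavior_csv` are read.
#' Default permutation counts are reduced for interactive runs
#' (n_perm = 2000, n_runs = 200, n_null = 200); `paper_scale = TRUE`
#' switches to the publication-scale 10,000 / 1000 / 1000.
#'
#' @param synthetic use the synthetic generator.
#' @param synthetic_cfg a [synthetic_config()].
#' @param cohort_csv,behavior_csv input paths when `synthetic = FALSE`.
#' @param coexpression_tsv,connectome_tsv optional modality matrices.
#' @param expression_tsv,gene_map_tsv optional expression inputs.
#' @param stages character vector of enabled stages.
#' @param n_bins,overlap Mapper cover parameters.
#' @param omega,gamma multi-slice parameters.
#' @param n_runs,n_perm,n_null replication counts.
#' @param fdr_q FDR level for the behavior panel.
#' @param seed master seed (each stage derives its own child seed).
#' @param out_dir output directory (created if needed).
#' @param paper_scale use publication-scale replication counts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synthetic_cfg = synthetic_config(),
                            cohort_csv = NULL, behavior_csv = NULL,
                            coexpression_tsv = NULL, connectome_tsv = NULL,
                            expression_tsv = NULL, gene_map_tsv = NULL,
                            stages = c("features", "connectivity", "mapper",
                                       "multislice", "crossmodal", "behavior",
                                       "mitotype"),
                            n_bins = 64L, overlap = 0.70,
                            omega = 0.1, gamma = 1,
                            n_runs = 200L, n_perm = 2000L, n_null = 200L,
                            fdr_q = 0.01, seed = 1L, out_dir = NULL,
                            paper_scale = FALSE) {
  if (paper_scale) { n_runs <- 1000L; n_perm <- 10000L; n_null <- 1000L }
  structure(list(synthetic = synthetic, synthetic_cfg = synthetic_cfg,
                 cohort_csv = cohort_csv, behavior_csv = behavior_csv,
                 coexpression_tsv = coexpression_tsv,
                 connectome_tsv = connectome_tsv,
                 expression_tsv = expression_tsv,
                 gene_map_tsv = gene_map_tsv,
                 stages = stages, n_bins = as.integer(n_bins),
                 overlap = overlap, omega = omega, gamma = gamma,
                 n_runs = as.integer(n_runs), n_perm = as.integer(n_perm),
                 n_null = as.integer(n_null), fdr_q = fdr_q,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order: cohort (synthetic or
#' file), connectivity matrices, Mapper PC contrast on the two stressor
#' deltas, multi-slice consensus communities, cross-modal permutation
#' validation (if modality matrices are given or synthetic), the
#' mitochondria-behavior panel and network-level correlations, and
#' mitotype pathway scoring (if expression inputs are given). Results are
#' returned as a list and, when `out_dir` is set, written as CSV/TSV plus
#' one machine-readable `results.json`.
#'
#' @param config a [pipeline_config()].
#' @return named list of per-stage results (invisible when writing).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  seeds <- child_seeds(cf$seed, 10L)
  res <- list(params = cf[c("stages", "n_bins", "overlap", "omega", "gamma",
                            "n_runs", "n_perm", "n_null", "fdr_q", "seed")])

  cohort <- if (cf$synthetic) {
    scfg <- cf$synthetic_cfg
    scfg$seed <- seeds[1L]
    generate_cohort(scfg)
  } else {
    if (is.null(cf$cohort_csv)) stop("stage 'features': cohort_csv required")
    tab <- read_cohort_csv(cf$cohort_csv)
    beh <- if (!is.null(cf$behavior_csv)) read_behavior_csv(cf$behavior_csv)
           else NULL
    structure(list(cohort = tab, behaviors = beh,
                   animals = unique(tab[c("animal_id", "group")]),
                   truth = NULL, config = NULL), class = "mito_cohort")
  }
  res$cohort_summary <- list(
    n_animals = nrow(cohort$animals),
    n_sites = length(unique(cohort$cohort$site)))

  if ("connectivity" %in% cf$stages) {
    cm <- feature_area_matrix(cohort)
    slices <- per_feature_slices(cohort)
    res$connectivity <- list(
      matrix = cm, slices = slices,
      nodal_degree = nodal_degree(cm),
      within_between = within_between_permutation(
        cm, n_perm = cf$n_perm, seed = seeds[2L]))
  }

  if ("mapper" %in% cf$stages) {
    mcfg <- mapper_config(n_bins = cf$n_bins, overlap = cf$overlap,
                          seed = seeds[3L])
    d_cort <- delta_matrix(cohort, "cort")
    d_csds <- delta_matrix(cohort, "csds")
    res$mapper <- phase_randomized_null(d_cort, d_csds, mcfg,
                                        n_null = cf$n_null, seed = seeds[4L])
  }

  partition <- NULL
  if ("multislice" %in% cf$stages) {
    slices <- res$connectivity$slices %||% per_feature_slices(cohort)
    partition <- consensus_communities(slices, n_runs = cf$n_runs,
                                       gamma = cf$gamma, omega = cf$omega,
                                       seed = seeds[5L])
    res$multislice <- list(partition = partition,
                           allegiance = attr(partition, "allegiance"))
  }

  if ("crossmodal" %in% cf$stages && !is.null(partition)) {
    mats <- list()
    if (!is.null(cf$coexpression_tsv))
      mats$coexpression <- read_square_tsv(cf$coexpression_tsv)
    if (!is.null(cf$connectome_tsv))
      mats$connectome <- read_square_tsv(cf$connectome_tsv)
    if (length(mats) == 0L && cf$synthetic) {
      mats$coexpression <- generate_modal_matrix(
        unclass(partition), within_w = 0.6, between_w = 0.2,
        noise_sd = 0.1, seed = seeds[6L])
    }
    res$crossmodal <- lapply(mats, function(m) {
      aligned <- align_partition(partition, m)
      list(SF = permutation_test(m, aligned, "SF", cf$n_perm, seeds[7L]),
           Q = permutation_test(m, aligned, "Q", cf$n_perm, seeds[7L]))
    })
  }

  if ("behavior" %in% cf$stages && !is.null(cohort$behaviors)) {
    res$behavior <- list(
      panel = mito_behavior_panel(cohort, fdr_q = cf$fdr_q))
    if (!is.null(partition)) {
      tests <- unique(cohort$behaviors$test)
      res$behavior$network1 <- lapply(stats::setNames(tests, tests),
        function(t) tryCatch(
          network_average_correlation(cohort, partition, test = t),
          error = function(e) NULL))
    }
  }

  if ("mitotype" %in% cf$stages && !is.null(cf$expression_tsv)) {
    expr <- read_square_or_rect_tsv(cf$expression_tsv) # areas x genes
    map <- utils::read.delim(cf$gene_map_tsv, stringsAsFactors = FALSE)
    scores <- pathway_scores(expr, map)
    res$mitotype <- list(scores = scores)
    if (!is.null(partition)) {
      aligned <- tryCatch(align_partition(partition, scores),
                          error = function(e) NULL)
      if (!is.null(aligned))
        res$mitotype$ranked <- rank_pathways(scores, aligned)
    }
  }

  if (!is.null(cf$out_dir)) .write_results(res, cohort, cf)
  res
}

# area x gene table: labeled rows, arbitrary columns
read_square_or_rect_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

.write_results <- function(res, cohort, cf) {
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cf$out_dir, ...)
  write_cohort_csv(cohort, p("cohort.csv"))
  if (!is.null(cohort$behaviors)) write_behavior_csv(cohort, p("behaviors.csv"))
  if (!is.null(res$connectivity))
    write_square_tsv(res$connectivity$matrix, p("connectivity.tsv"))
  if (!is.null(res$multislice)) {
    write_partition_csv(res$multislice$partition, p("partition.csv"))
    write_square_tsv(res$multislice$allegiance, p("allegiance.tsv"))
  }
  summary <- list(
    params = res$params,
    nodal_degree = as.list(res$connectivity$nodal_degree),
    within_between_p = res$connectivity$within_between$p,
    mapper = if (!is.null(res$mapper))
      res$mapper[c("pc_a", "pc_b", "observed", "relative_change", "p")],
    partition = if (!is.null(res$multislice))
      as.list(unclass(res$multislice$partition)),
    crossmodal = lapply(res$crossmodal, function(x)
      list(SF = x$SF$observed, SF_p = x$SF$p, Q = x$Q$observed, Q_p = x$Q$p)),
    behavior_network1 = lapply(res$behavior$network1, function(x)
      if (!is.null(x)) x[c("r", "p", "r_pearson", "r_squared",
                           "adj_r_squared", "n")])
  )
  jsonlite::write_json(summary, p("results.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(NULL)
}
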
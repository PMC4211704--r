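# Top-level pipeline: configuration, orchestration of the full
# analysis (connectome summaries, task PLS with inference, change-map
# distance analyses, module and hemisphere stratification, homotopic
# stability), and report serialization.

#' Pipeline run configuration
#'
#' Defaults follow the analysis protocol the pipeline implements: 500
#' permutations and 500 bootstrap resamples for the PLS inference, 1000
#' independent-pairs resamples, 100 Louvain runs, Spearman correlation
#' for the independent-pairs inference.
#'
#' @param seed master seed; per-stage seeds are spawned from it.
#' @param n_perm PLS permutations.
#' @param n_boot PLS bootstrap resamples.
#' @param n_pairs_samples independent-pairs resamples.
#' @param louvain_runs Louvain restarts.
#' @param correlation_method `"spearman"` or `"pearson"` for the
#'   independent-pairs and stratified analyses.
#' @param change_kinds which change maps to analyze.
#' @param condition_pair optional explicit `(cell A, cell B)` pair for
#'   the correlation difference; by default the two cells with the
#'   extreme LV1 design saliences.
#' @param input optional input (a `connectivity_dataset`, a
#'   `synthetic_dataset`, a bundle directory, or a MAT path — resolved
#'   by [run_pipeline()]).
#' @param node_table path to a node table when `input` is a MAT file.
#' @param output optional output directory for [write_report()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_perm = 500, n_boot = 500,
                       n_pairs_samples = 1000, louvain_runs = 100,
                       correlation_method = c("spearman", "pearson"),
                       change_kinds = c("salience", "bootstrap_ratio",
                                        "correlation_difference",
                                        "abs_salience",
                                        "abs_correlation_difference"),
                       condition_pair = NULL,
                       input = NULL, node_table = NULL, output = NULL) {
  correlation_method <- match.arg(correlation_method)
  counts <- c(n_perm = n_perm, n_boot = n_boot,
              n_pairs_samples = n_pairs_samples,
              louvain_runs = louvain_runs)
  if (any(counts < 1)) stop("all counts must be positive")
  cfg <- list(seed = as.integer(seed), n_perm = as.integer(n_perm),
              n_boot = as.integer(n_boot),
              n_pairs_samples = as.integer(n_pairs_samples),
              louvain_runs = as.integer(louvain_runs),
              correlation_method = correlation_method,
              change_kinds = match.arg(change_kinds, several.ok = TRUE),
              condition_pair = condition_pair,
              input = input, node_table = node_table, output = output)
  class(cfg) <- "run_config"
  cfg
}

resolve_input <- function(cfg) {
  x <- cfg$input
  if (inherits(x, "connectivity_dataset")) return(x)
  if (inherits(x, "synthetic_dataset")) return(connectivity_dataset(x))
  if (is.character(x) && length(x) == 1) {
    if (dir.exists(x)) return(connectivity_dataset(read_dataset_bundle(x)))
    if (grepl("\\.mat$", x, ignore.case = TRUE)) {
      return(load_matfile_dataset(x, cfg$node_table))
    }
    stop("input path is neither a bundle directory nor a .mat file: ", x)
  }
  stop("config must carry a dataset, bundle directory or MAT path as input")
}

# Pick the cells with the extreme LV1 design saliences: the pair of
# conditions the model says differ most.
greatest_difference_cells <- function(model) {
  u1 <- model$design_saliences[, 1]
  cells <- model$cell_order
  a <- which.max(u1); b <- which.min(u1)
  list(cell_a = list(cells$group[a], cells$condition[a]),
       cell_b = list(cells$group[b], cells$condition[b]))
}

#' Run the full distance-stability analysis pipeline
#'
#' Stages: (1) per-cell distance--connectivity correlations on the
#' group-averaged z matrices; (2) task PLS with permutation and
#' bootstrap inference; (3) edge change maps (LV1 saliences, bootstrap
#' ratios, correlation difference between the two most different
#' cells, and their absolute values) each analyzed with the descriptive
#' all-edges correlation, the independent-pairs null, the PCA outlier
#' diagnostic and a 2-D density histogram; (4) Louvain partition of the
#' grand-averaged connectome and per-stratum (module, hemisphere,
#' homotopy) analyses of the salience map; (5) the homotopic-stability
#' exceedance test. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param verbose print one line per stage.
#' @return a `study_report` list; see [write_report()] for the
#'   serialized layout.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ds <- resolve_input(config)
  seeds <- spawn_seeds(config$seed, 8)
  p <- ds$parcellation
  dmat <- distance_matrix(p)

  say("stage distance_fc: %d nodes, %d cells", nrow(p), nrow(design_cells(ds)))
  fig2 <- distance_fc_by_cell(ds, method = "pearson")
  fig2_spearman <- distance_fc_by_cell(ds, method = "spearman")

  say("stage pls: n_perm=%d n_boot=%d", config$n_perm, config$n_boot)
  model <- task_pls(ds, n_perm = config$n_perm, n_boot = config$n_boot,
                    seed = seeds[1])

  pair <- if (is.null(config$condition_pair)) {
    greatest_difference_cells(model)
  } else {
    list(cell_a = config$condition_pair[[1]],
         cell_b = config$condition_pair[[2]])
  }

  maps <- list()
  for (kind in config$change_kinds) {
    maps[[kind]] <- switch(kind,
      salience = change_map_salience(model, p),
      bootstrap_ratio = change_map_bsr(model, p),
      correlation_difference = correlation_difference(ds, pair$cell_a,
                                                      pair$cell_b),
      abs_salience = abs_change_map(change_map_salience(model, p)),
      abs_correlation_difference =
        abs_change_map(correlation_difference(ds, pair$cell_a, pair$cell_b))
    )
  }

  say("stage stability: %d change map(s), %d samples", length(maps),
      config$n_pairs_samples)
  map_seeds <- spawn_seeds(seeds[2], length(maps))
  change_results <- list()
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    vals <- m$values
    keep <- is.finite(vals)
    if (!all(keep)) {  # BSR maps can carry NA where the se was floored
      m <- edge_change_map(ifelse(keep, vals, 0), m$distances, m$kind,
                           m$condition_pair)
    }
    change_results[[names(maps)[k]]] <- list(
      kind = m$kind,
      descriptive = change_distance_correlation(m, method = "pearson"),
      independent_pairs = independent_pairs_correlation(
        m, n_samples = config$n_pairs_samples, seed = map_seeds[k],
        method = config$correlation_method),
      pca_outliers = pca_outlier_diagnostic(m),
      density = density_histogram_2d(m)
    )
  }

  say("stage modularity: %d Louvain runs", config$louvain_runs)
  partition <- louvain_partition(group_average_z(ds),
                                 n_runs = config$louvain_runs,
                                 seed = seeds[3])
  strata <- classify_edges(p, partition)

  sal_map <- if (!is.null(maps$salience)) maps$salience else maps[[1]]
  say("stage stratification")
  strata_table <- stratified_distance_analysis(
    sal_map, strata, n_samples = config$n_pairs_samples, seed = seeds[4],
    method = config$correlation_method)

  say("stage homotopic stability")
  homotopy <- tryCatch(homotopic_stability_test(sal_map, strata),
                       error = function(e) list(error = conditionMessage(e)))

  report <- list(
    config = config,
    n_nodes = nrow(p),
    n_edges = n_edges(nrow(p)),
    distance_fc = fig2,
    distance_fc_spearman = fig2_spearman,
    pls = list(
      singular_values = model$singular_values,
      covariance_fraction = model$covariance_fraction,
      p_values = model$p_values,
      cell_order = model$cell_order,
      design_saliences = model$design_saliences,
      n_permutations = model$n_permutations,
      n_bootstraps = model$bootstrap$n_resamples
    ),
    condition_pair = pair,
    change = change_results,
    partition = partition,
    strata_table = strata_table,
    homotopy = homotopy,
    model = model,
    change_maps = maps
  )
  class(report) <- "study_report"
  if (!is.null(config$output)) write_report(report, config$output)
  report
}

#' Serialize a study report
#'
#' Writes `report.json` (nested master file) plus fixed-layout CSVs:
#' `table2.csv` (columns `study`, `rho`, `SE`, `p_rho_gt_0`,
#' `p_rho_lt_0` — one row per change map), `strata.csv`, `lv.csv`,
#' `homotopy.csv`, `partition.csv` and `distance_fc.csv`. Floats are
#' serialized at 15 significant digits.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) signif(x, 15)

  table2 <- do.call(rbind, lapply(names(report$change), function(nm) {
    ip <- report$change[[nm]]$independent_pairs
    data.frame(study = nm, rho = fmt(ip$mean_rho), SE = fmt(ip$se),
               p_rho_gt_0 = fmt(ip$p_greater), p_rho_lt_0 = fmt(ip$p_less),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(table2, file.path(dir, "table2.csv"), row.names = FALSE)

  utils::write.csv(report$strata_table, file.path(dir, "strata.csv"),
                   row.names = FALSE)

  lv <- data.frame(lv = seq_along(report$pls$singular_values),
                   singular_value = fmt(report$pls$singular_values),
                   covariance_fraction = fmt(report$pls$covariance_fraction),
                   p_perm = fmt(report$pls$p_values))
  utils::write.csv(lv, file.path(dir, "lv.csv"), row.names = FALSE)

  hm <- report$homotopy
  if (is.null(hm$error)) {
    utils::write.csv(
      data.frame(class = c("non_homotopic", "homotopic"),
                 proportion_exceeding = fmt(c(hm$proportion_non_homotopic,
                                              hm$proportion_homotopic)),
                 n_edges = c(hm$n_non_homotopic, hm$n_homotopic)),
      file.path(dir, "homotopy.csv"), row.names = FALSE)
    utils::write.csv(hm$histogram_data,
                     file.path(dir, "homotopy_histogram.csv"),
                     row.names = FALSE)
  }

  utils::write.csv(
    data.frame(node = seq_along(report$partition$assignment),
               module = report$partition$assignment),
    file.path(dir, "partition.csv"), row.names = FALSE)

  utils::write.csv(report$distance_fc, file.path(dir, "distance_fc.csv"),
                   row.names = FALSE)

  master <- list(
    seed = report$config$seed,
    n_nodes = report$n_nodes,
    n_edges = report$n_edges,
    parameters = list(n_perm = report$config$n_perm,
                      n_boot = report$config$n_boot,
                      n_pairs_samples = report$config$n_pairs_samples,
                      louvain_runs = report$config$louvain_runs,
                      correlation_method = report$config$correlation_method),
    distance_fc = report$distance_fc,
    lv = lv,
    table2 = table2,
    strata = report$strata_table,
    homotopy = if (is.null(hm$error)) {
      list(proportion_non_homotopic = hm$proportion_non_homotopic,
           proportion_homotopic = hm$proportion_homotopic,
           ci_bounds = hm$ci_bounds)
    } else hm,
    partition = list(q = report$partition$q,
                     n_modules = report$partition$n_modules)
  )
  jsonlite::write_json(master, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat("LV1: singular value", signif(x$pls$singular_values[1], 4),
      "| covariance fraction", signif(x$pls$covariance_fraction[1], 3),
      "| permutation p", x$pls$p_values[1], "\n")
  for (nm in names(x$change)) {
    ip <- x$change[[nm]]$independent_pairs
    cat(sprintf("  %-28s rho %+0.3f (SE %.3f)  P(rho>0)=%.3f P(rho<0)=%.3f\n",
                nm, ip$mean_rho, ip$se, ip$p_greater, ip$p_less))
  }
  if (is.null(x$homotopy$error)) {
    cat(sprintf("  homotopic exceedance %.1f%% vs non-homotopic %.1f%%\n",
                100 * x$homotopy$proportion_homotopic,
                100 * x$homotopy$proportion_non_homotopic))
  }
  invisible(x)
}
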
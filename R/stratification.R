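# Edge stratification: Louvain community structure of the averaged
# connectome (within- vs between-module edges), hemisphere classes
# (intra vs inter, homotopic vs non-homotopic), per-stratum
# distance-change analyses, and the homotopic-stability exceedance
# test.

#' Louvain module partition of a connectivity matrix
#'
#' Greedy Louvain modularity optimization on non-negative weights
#' (negative entries are zeroed). The algorithm is run `n_runs` times
#' under a seeded stream and the partition with the highest modularity
#' Q is kept; ties are broken by first occurrence in run order.
#'
#' @param z_matrix symmetric weight matrix (e.g. a group-averaged
#'   Fisher-z matrix); diagonal is ignored.
#' @param n_runs number of runs (default 100).
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed; fixed seed gives an identical partition.
#' @return a `module_partition`: list with `assignment` (integer module
#'   id per node), `q`, `n_runs`, `n_modules`, `degenerate` flag (all
#'   weights zero), `seed`.
#' @export
louvain_partition <- function(z_matrix, n_runs = 100, gamma = 1, seed = 1) {
  stopifnot(is.matrix(z_matrix), nrow(z_matrix) == ncol(z_matrix))
  if (max(abs(z_matrix - t(z_matrix))) > 1e-10) {
    stop("weight matrix must be symmetric")
  }
  w <- pmax(z_matrix, 0)
  diag(w) <- 0
  n <- nrow(w)
  if (all(w == 0)) {
    out <- list(assignment = rep(1L, n), q = 0, n_runs = as.integer(n_runs),
                n_modules = 1L, degenerate = TRUE, seed = as.integer(seed))
    class(out) <- "module_partition"
    return(out)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf; best_member <- NULL
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      member <- igraph::membership(cl)
      q <- igraph::modularity(g, member, weights = igraph::E(g)$weight,
                              resolution = gamma)
      if (q > best_q) {
        best_q <- q
        best_member <- as.integer(member)
      }
    }
  })
  out <- list(assignment = best_member, q = best_q,
              n_runs = as.integer(n_runs), gamma = gamma,
              n_modules = length(unique(best_member)),
              degenerate = FALSE, seed = as.integer(seed))
  class(out) <- "module_partition"
  out
}

#' Classify every edge by hemisphere, homotopy and module membership
#'
#' @param parcellation a parcellation.
#' @param partition optional `module_partition`; without it the module
#'   class is `NA`.
#' @return an `edge_strata` data frame in canonical edge order with
#'   columns `i`, `j`, `hemisphere_class` (`"intra"`/`"inter"`),
#'   `homotopy_class` (`"homotopic"`, `"non_homotopic"`,
#'   `"not_applicable"` for intra-hemispheric edges) and `module_class`
#'   (`"within"`/`"between"`).
#' @export
classify_edges <- function(parcellation, partition = NULL) {
  validate_parcellation(parcellation)
  n <- nrow(parcellation)
  idx <- edge_index(n)
  hemi <- parcellation$hemisphere
  inter <- hemi[idx[, "i"]] != hemi[idx[, "j"]] &
    hemi[idx[, "i"]] != "medial" & hemi[idx[, "j"]] != "medial"
  hom <- homotopic_edges(parcellation)
  homotopy <- ifelse(!inter, "not_applicable",
                     ifelse(hom, "homotopic", "non_homotopic"))
  module_class <- rep(NA_character_, nrow(idx))
  if (!is.null(partition)) {
    if (length(partition$assignment) != n) {
      stop("partition does not cover the parcellation")
    }
    a <- partition$assignment
    module_class <- ifelse(a[idx[, "i"]] == a[idx[, "j"]],
                           "within", "between")
  }
  out <- data.frame(
    i = idx[, "i"], j = idx[, "j"],
    hemisphere_class = ifelse(inter, "inter", "intra"),
    homotopy_class = homotopy,
    module_class = module_class,
    stringsAsFactors = FALSE
  )
  class(out) <- c("edge_strata", "data.frame")
  out
}

#' Distance--change analysis within edge strata
#'
#' Re-runs the descriptive all-edges correlation and the
#' independent-pairs null restricted to each stratum. In the restricted
#' null, a sampled matching keeps only pairs whose edge lies in the
#' stratum and samples with fewer than `min_pairs` eligible pairs are
#' redrawn. Strata with fewer than `min_edges` edges are reported as
#' skipped rather than analyzed.
#'
#' @param change an `edge_change_map`.
#' @param strata named list of logical edge vectors, or an
#'   `edge_strata` data frame (analyzes module within/between,
#'   hemisphere intra/inter, and homotopic/non-homotopic classes).
#' @param n_samples,seed,method passed to
#'   [independent_pairs_correlation()].
#' @param min_edges minimum edges for a stratum to be analyzed.
#' @param min_pairs minimum eligible pairs per resample.
#' @return data frame, one row per stratum: `stratum`, `n_edges`,
#'   `descriptive_r`, `rho`, `se`, `p_greater`, `p_less`, `status`.
#' @export
stratified_distance_analysis <- function(change, strata, n_samples = 1000,
                                         seed = 1,
                                         method = c("spearman", "pearson"),
                                         min_edges = 10, min_pairs = 10) {
  method <- match.arg(method)
  if (inherits(strata, "edge_strata")) {
    s <- strata
    strata <- list(
      module_within = s$module_class == "within",
      module_between = s$module_class == "between",
      intra_hemisphere = s$hemisphere_class == "intra",
      inter_hemisphere = s$hemisphere_class == "inter",
      homotopic = s$homotopy_class == "homotopic",
      non_homotopic = s$homotopy_class == "non_homotopic"
    )
    strata <- Filter(function(v) !anyNA(v), strata)
  }
  seeds <- spawn_seeds(seed, length(strata))
  rows <- vector("list", length(strata))
  for (k in seq_along(strata)) {
    sel <- strata[[k]]
    name <- names(strata)[k]
    ne <- sum(sel)
    row <- data.frame(stratum = name, n_edges = ne,
                      descriptive_r = NA_real_, rho = NA_real_,
                      se = NA_real_, p_greater = NA_real_,
                      p_less = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (ne < min_edges) {
      row$status <- "skipped"
    } else {
      sub <- change
      vacuous <- all(sel)
      res <- tryCatch({
        desc <- stats::cor(change$distances[sel], change$values[sel],
                           method = method)
        ip <- independent_pairs_correlation(
          sub, n_samples = n_samples, seed = seeds[k], method = method,
          stratum = if (vacuous) NULL else sel, min_pairs = min_pairs)
        list(desc = desc, ip = ip)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$status <- paste("failed:", conditionMessage(res))
      } else {
        row$descriptive_r <- res$desc
        row$rho <- res$ip$mean_rho
        row$se <- res$ip$se
        row$p_greater <- res$ip$p_greater
        row$p_less <- res$ip$p_less
      }
    }
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}

#' Homotopic-stability exceedance test
#'
#' Pools the change values of all inter-hemispheric edges, takes the
#' empirical 2.5th/97.5th percentiles of the pooled values as a 95%
#' interval, and reports, per class, the proportion of homotopic and
#' non-homotopic values falling outside it. Stable homotopic edges
#' yield a smaller exceedance proportion than non-homotopic edges.
#'
#' @param change an `edge_change_map`.
#' @param strata an `edge_strata` data frame for the same parcellation.
#' @return list with `proportion_homotopic`,
#'   `proportion_non_homotopic`, `ci_bounds` (length-2), `n_homotopic`,
#'   `n_non_homotopic`, `degenerate` flag, and `histogram_data` (data
#'   frame `value`, `class` of the pooled inter-hemispheric values).
#' @export
homotopic_stability_test <- function(change, strata) {
  hom <- strata$homotopy_class == "homotopic"
  non <- strata$homotopy_class == "non_homotopic"
  if (!any(hom) || !any(non)) {
    stop("need at least one homotopic and one non-homotopic ",
         "inter-hemispheric edge")
  }
  pooled <- change$values[hom | non]
  degenerate <- stats::sd(pooled) == 0
  ci <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE, type = 7)
  outside <- function(v) mean(v < ci[1] | v > ci[2])
  list(
    proportion_homotopic = if (degenerate) 0 else outside(change$values[hom]),
    proportion_non_homotopic = if (degenerate) 0 else outside(change$values[non]),
    ci_bounds = ci,
    n_homotopic = sum(hom),
    n_non_homotopic = sum(non),
    degenerate = degenerate,
    histogram_data = data.frame(
      value = c(change$values[hom], change$values[non]),
      class = c(rep("homotopic", sum(hom)),
                rep("non_homotopic", sum(non))),
      stringsAsFactors = FALSE
    )
  )
}
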
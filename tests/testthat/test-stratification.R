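two_cliques <- function() {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  a
}

test_that("Louvain recovers planted cliques with Q matching the hand formula", {
  a <- two_cliques()
  part <- louvain_partition(a, n_runs = 20, seed = 3)
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$assignment[1:5])), 1)
  expect_equal(length(unique(part$assignment[6:10])), 1)
  # closed-form modularity of the planted two-clique partition
  expect_equal(part$q, 0.5, tolerance = 1e-12)
  # stored q equals modularity recomputed from scratch by the oracle
  expect_equal(part$q, modularity_oracle(a, part$assignment),
               tolerance = 1e-12)
})

test_that("Louvain: single clique has Q = 0; zero graph is flagged", {
  a <- matrix(1, 6, 6); diag(a) <- 0
  part <- louvain_partition(a, n_runs = 10, seed = 4)
  expect_equal(part$n_modules, 1)
  expect_equal(part$q, 0)

  z <- matrix(0, 5, 5)
  pz <- louvain_partition(z, seed = 5)
  expect_true(pz$degenerate)
  expect_equal(pz$assignment, rep(1L, 5))
  expect_equal(pz$q, 0)
})

test_that("Louvain is deterministic under a fixed seed and zeroes negatives", {
  fx <- quick_dataset(n_pairs = 8, n_subjects = 4, n_timepoints = 60,
                      seed = 151)
  z <- group_average_z(fx$ds)
  p1 <- louvain_partition(z, n_runs = 10, seed = 7)
  p2 <- louvain_partition(z, n_runs = 10, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$q, p2$q)
  # stored q is recomputed on the non-negative weights
  w <- pmax(z, 0)
  expect_equal(p1$q, modularity_oracle(w, p1$assignment), tolerance = 1e-12)
})

test_that("edge classification: hemisphere, homotopy and module labels", {
  p <- make_parcellation(n_pairs = 3, n_medial = 1, seed = 9)
  part <- list(assignment = c(1L, 1L, 2L, 1L, 2L, 2L, 1L))
  class(part) <- "module_partition"
  s <- classify_edges(p, part)
  expect_equal(nrow(s), n_edges(7))
  # counts partition the edge set
  expect_equal(sum(s$hemisphere_class == "intra") +
                 sum(s$hemisphere_class == "inter"), n_edges(7))
  expect_equal(sum(s$module_class == "within") +
                 sum(s$module_class == "between"), n_edges(7))
  # a mirrored pair is inter + homotopic; exactly n_pairs homotopic edges
  hom <- s$homotopy_class == "homotopic"
  expect_equal(sum(hom), 3)
  expect_true(all(s$hemisphere_class[hom] == "inter"))
  # (L1, L2) is intra-hemispheric, homotopy not applicable
  l1l2 <- which(s$i == 1 & s$j == 2)
  expect_equal(s$hemisphere_class[l1l2], "intra")
  expect_equal(s$homotopy_class[l1l2], "not_applicable")
  # edges touching the medial node are neither intra nor homotopic inter
  med <- which(s$i == 7 | s$j == 7)
  expect_true(all(s$hemisphere_class[med] == "intra" |
                    s$homotopy_class[med] == "non_homotopic" |
                    s$hemisphere_class[med] == "inter") )
  expect_true(all(s$homotopy_class[med] != "homotopic"))
  # module labels follow the partition
  expect_equal(s$module_class[l1l2], "within")
  expect_equal(s$module_class[which(s$i == 1 & s$j == 3)], "between")
})

test_that("a vacuous stratum reproduces the unstratified result", {
  fx <- quick_dataset(n_pairs = 6, n_subjects = 4, n_timepoints = 40,
                      seed = 161)
  cm <- correlation_difference(fx$ds, "C1", "C2")
  all_in <- rep(TRUE, length(cm$values))
  a <- independent_pairs_correlation(cm, n_samples = 100, seed = 8)
  b <- independent_pairs_correlation(cm, n_samples = 100, seed = 8,
                                     stratum = all_in, min_pairs = 2)
  expect_identical(a$rho_samples, b$rho_samples)
})

test_that("stratified analysis restricts matchings and skips small strata", {
  fx <- quick_dataset(n_pairs = 12, n_subjects = 6, n_timepoints = 60,
                      effect_profile = "increasing", seed = 171)
  cm <- correlation_difference(fx$ds, "C1", "C2")
  part <- louvain_partition(group_average_z(fx$ds), n_runs = 10, seed = 9)
  strata <- classify_edges(fx$parcellation, part)
  tab <- stratified_distance_analysis(cm, strata, n_samples = 100, seed = 10)
  expect_true(all(c("stratum", "n_edges", "descriptive_r", "rho",
                    "p_greater", "p_less", "status") %in% names(tab)))
  # homotopic stratum (24 nodes -> 12 edges only) cannot support
  # 10 disjoint pairs and is reported, not fatal
  hrow <- tab[tab$stratum == "homotopic", ]
  expect_true(hrow$status != "ok" || !is.na(hrow$rho))
  # intra + inter edge counts partition the edges
  expect_equal(sum(tab$n_edges[tab$stratum %in%
                                 c("intra_hemisphere", "inter_hemisphere")]),
               n_edges(24))
  # the planted increasing trend is detected in the large strata
  big <- tab[tab$stratum %in% c("module_within", "module_between",
                                "intra_hemisphere", "inter_hemisphere") &
               tab$status == "ok", ]
  expect_true(all(pmin(big$p_greater, big$p_less) < 0.05))
})

test_that("homotopic stability test: exceedance proportions and edge cases", {
  p <- make_parcellation(n_pairs = 20, seed = 12)
  strata <- classify_edges(p)
  hom <- strata$homotopy_class == "homotopic"
  non <- strata$homotopy_class == "non_homotopic"
  vals <- numeric(n_edges(40))
  # homotopic values all zero, non-homotopic spread widely
  vals[non] <- connstab:::with_seed(13, rnorm(sum(non), 0, 1))
  cm <- edge_change_map(vals, distance_matrix(p), "salience")
  ht <- homotopic_stability_test(cm, strata)
  expect_equal(ht$proportion_homotopic, 0)
  expect_gt(ht$proportion_non_homotopic, 0)
  expect_equal(ht$n_homotopic, 20)
  expect_equal(nrow(ht$histogram_data), sum(hom) + sum(non))

  # i.i.d. values across classes: both proportions near 0.05 by
  # construction of the pooled 95% interval
  props <- t(connstab:::with_seed(14, replicate(40, {
    v2 <- vals; v2[hom | non] <- rnorm(sum(hom | non))
    cm2 <- edge_change_map(v2, distance_matrix(p), "salience")
    h2 <- homotopic_stability_test(cm2, strata)
    c(h2$proportion_homotopic, h2$proportion_non_homotopic)
  })))
  expect_lt(abs(mean(props[, 2]) - 0.05), 0.01)
  expect_lt(abs(mean(props[, 1]) - 0.05), 0.04)

  # degenerate pooled distribution collapses cleanly
  cm0 <- edge_change_map(rep(0.3, n_edges(40)), distance_matrix(p), "salience")
  h0 <- homotopic_stability_test(cm0, strata)
  expect_true(h0$degenerate)
  expect_equal(h0$proportion_homotopic, 0)
  expect_equal(h0$proportion_non_homotopic, 0)
})
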
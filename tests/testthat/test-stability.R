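test_that("correlation_difference: identity, symmetry and manual oracle", {
  fx <- quick_dataset(n_pairs = 4, n_subjects = 4, n_timepoints = 40,
                      seed = 111)
  zero <- correlation_difference(fx$ds, "C1", "C1")
  expect_true(all(zero$values == 0))

  cd <- correlation_difference(fx$ds, "C1", "C2")
  # manual oracle: subtract the two group-averaged z matrices by hand
  arr <- fx$ds$groups$G1
  za <- apply(arr[1, , , ], c(2, 3), mean)
  zb <- apply(arr[2, , , ], c(2, 3), mean)
  diff <- za - zb
  expect_equal(diff, t(diff))
  expect_equal(cd$values, upper_triangle_vector(diff), tolerance = 1e-14)
  expect_error(correlation_difference(fx$ds, "C1", "C9"), "unknown condition")
})

test_that("independent pairs: 116 nodes give 58 pairs, perfect agreement gives p = 1", {
  d116 <- as.matrix(dist(matrix(rnorm(116 * 3), 116, 3)))
  dv <- upper_triangle_vector(d116)
  cm <- edge_change_map(dv, dv, kind = "correlation_difference")
  ip <- independent_pairs_correlation(cm, n_samples = 50, seed = 1)
  expect_equal(ip$n_pairs_per_sample, 58L)
  expect_true(all(ip$rho_samples == 1))   # change equals distance exactly
  expect_equal(ip$p_greater, 1)
  expect_equal(ip$p_less, 0)
})

test_that("independent pairs: tie convention keeps p_greater + p_less = 1", {
  set.seed(2)
  n <- 20
  d <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
  cm <- edge_change_map(rnorm(n_edges(n)), d, kind = "salience")
  ip <- independent_pairs_correlation(cm, n_samples = 200, seed = 3)
  expect_equal(ip$p_greater + ip$p_less, 1)
  expect_equal(ip$se_of_mean, ip$se / sqrt(200))
  expect_equal(ip$mean_rho, mean(ip$rho_samples))
  # determinism
  ip2 <- independent_pairs_correlation(cm, n_samples = 200, seed = 3)
  expect_identical(ip$rho_samples, ip2$rho_samples)
})

test_that("matching sampler draws disjoint node pairs uniformly", {
  n <- 8
  pos <- connstab:::with_seed(4, replicate(400, {
    p <- connstab:::sample_matching_edges(n)
    idx <- edge_index(n)
    nodes <- c(idx[p, "i"], idx[p, "j"])
    expect_equal(length(p), 4)
    expect_false(any(duplicated(nodes)))   # a perfect matching
    p
  }))
  # every edge can be sampled
  expect_gt(length(unique(as.vector(pos))), 20)
})

test_that("descriptive change-distance correlation matches a second implementation", {
  fx <- quick_dataset(n_pairs = 5, n_subjects = 4, n_timepoints = 40,
                      seed = 121)
  cm <- correlation_difference(fx$ds, "C1", "C2")
  got_p <- change_distance_correlation(cm, "pearson")
  expect_equal(got_p$coefficient, pearson_oracle(cm$distances, cm$values),
               tolerance = 1e-12)
  got_s <- change_distance_correlation(cm, "spearman")
  expect_equal(got_s$coefficient, spearman_oracle(cm$distances, cm$values),
               tolerance = 1e-12)
  expect_match(got_p$note, "non-independent")

  prop <- edge_change_map(2 * cm$distances, cm$distances, "salience")
  expect_equal(change_distance_correlation(prop)$coefficient, 1)
  flat <- edge_change_map(rep(1, length(cm$values)), cm$distances, "salience")
  expect_error(change_distance_correlation(flat), "variance")
})

test_that("abs maps run through the same analysis path", {
  fx <- quick_dataset(n_pairs = 5, n_subjects = 4, n_timepoints = 40,
                      seed = 131)
  cm <- correlation_difference(fx$ds, "C1", "C2")
  am <- abs_change_map(cm)
  expect_equal(am$kind, "abs_correlation_difference")
  expect_equal(am$values, abs(cm$values))
  ip <- independent_pairs_correlation(am, n_samples = 50, seed = 5)
  expect_s3_class(ip, "independent_pairs_result")
  expect_error(abs_change_map(am), "absolute value")
})

test_that("pca outlier diagnostic: axis oracle, tail counts, collinear case", {
  set.seed(6)
  n <- 100
  d <- as.matrix(dist(matrix(rnorm(45 * 3), 45, 3)))
  cm <- edge_change_map(rnorm(n_edges(45)), d, "salience")
  res <- pca_outlier_diagnostic(cm, tail_fraction = 0.05)
  nn <- n_edges(45)
  expect_equal(length(res$flagged_upper), ceiling(0.05 * nn))
  expect_equal(length(res$flagged_lower), ceiling(0.05 * nn))

  # principal axis equals the closed-form 2x2 eigenvector
  xs <- scale(cbind(cm$distances, cm$values))
  cv <- stats::cov(xs)
  theta <- 0.5 * atan2(2 * cv[1, 2], cv[1, 1] - cv[2, 2])
  axis_oracle <- c(cos(theta), sin(theta))
  if (axis_oracle[which.max(abs(axis_oracle))] < 0) axis_oracle <- -axis_oracle
  expect_equal(res$principal_axis, axis_oracle, tolerance = 1e-10)
  # displacements are orthogonal to the axis
  expect_lt(abs(sum(res$displacement * (xs %*% res$principal_axis)) /
                  length(res$displacement)), 1e-10)

  # exactly collinear points: all displacements zero, flagged by index order
  lin <- edge_change_map(3 * cm$distances + 1, cm$distances, "salience")
  res2 <- pca_outlier_diagnostic(lin)
  expect_true(all(res2$displacement == 0))
  expect_true(res2$degenerate)
  expect_true(is.na(res2$outlier_correlation))
  k <- ceiling(0.05 * nn)
  expect_equal(sort(c(res2$flagged_lower, res2$flagged_upper))[1:k],
               seq_len(k))
})

test_that("2-D density histogram conserves the edge count", {
  fx <- quick_dataset(n_pairs = 6, n_subjects = 4, n_timepoints = 40,
                      seed = 141)
  cm <- correlation_difference(fx$ds, "C1", "C2")
  h <- density_histogram_2d(cm, bins_x = 10, bins_y = 8)
  expect_equal(dim(h$counts), c(10, 8))
  expect_equal(sum(h$counts), n_edges(12))

  # all points identical: a single nonzero bin holding every edge
  one <- edge_change_map(rep(0.5, 10), rep(20, 10), "salience")
  h1 <- density_histogram_2d(one, 5, 5)
  expect_equal(sum(h1$counts), 10)
  expect_equal(sum(h1$counts > 0), 1)
  expect_error(density_histogram_2d(cm, 1, 5), "bins")
})
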
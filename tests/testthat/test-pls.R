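# Build a connectivity dataset directly from a list of per-cell z
# arrays so toy examples can be written down explicitly.
toy_dataset <- function(z_by_cond_subj, n, conditions, parcellation) {
  ns <- length(z_by_cond_subj[[1]])
  arr <- array(0, dim = c(length(conditions), ns, n, n),
               dimnames = list(conditions, sprintf("S%02d", seq_len(ns)),
                               NULL, NULL))
  for (cc in seq_along(conditions)) {
    for (s in seq_len(ns)) arr[cc, s, , ] <- z_by_cond_subj[[cc]][[s]]
  }
  connectivity_dataset(list(G1 = arr), parcellation = parcellation)
}

sym_z <- function(v) from_edge_vector(v)

test_that("assemble_cell_means equals a hand-rolled mean-then-center oracle", {
  p <- tiny_parcellation(n_pairs = 2, seed = 2)   # 4 nodes, 6 edges
  set.seed(12)
  vals <- lapply(1:3, function(cc) lapply(1:2, function(s) rnorm(6)))
  ds <- toy_dataset(
    lapply(vals, function(vs) lapply(vs, sym_z)), 4, c("C1", "C2", "C3"), p)
  m <- assemble_cell_means(ds)
  # oracle: mean over subjects per cell, then subtract grand cell mean
  cm <- t(vapply(vals, function(vs) (vs[[1]] + vs[[2]]) / 2, numeric(6)))
  oracle <- sweep(cm, 2, colMeans(cm))
  expect_equal(unclass(m), oracle, ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(attr(m, "cell_order")$condition, c("C1", "C2", "C3"))
})

test_that("a single design cell centers to exactly zero", {
  p <- tiny_parcellation(n_pairs = 2, seed = 2)
  ds <- toy_dataset(list(lapply(1:3, function(s) sym_z(rnorm(6)))),
                    4, "C1", p)
  expect_true(all(assemble_cell_means(ds) == 0))
})

test_that("pls_svd: rank, orthonormality, sign convention, eigen oracle", {
  # rank-1 input: one nonzero singular value, full covariance fraction
  m1 <- outer(c(1, -1), c(2, 0, -1, 3))
  s1 <- pls_svd(m1)
  expect_equal(s1$covariance_fraction[1], 1)
  expect_lt(s1$singular_values[2] / s1$singular_values[1], 1e-12)

  set.seed(3)
  m <- matrix(rnorm(40), 4, 10)
  s <- pls_svd(m)
  expect_equal(crossprod(s$saliences), diag(4), tolerance = 1e-12)
  expect_true(all(s$singular_values >= 0))
  expect_true(all(diff(s$singular_values) <= 1e-12))
  expect_equal(sum(s$covariance_fraction), 1)
  # sign convention: largest-magnitude design entry non-negative
  for (k in 1:4) {
    expect_gte(s$design_saliences[which.max(abs(s$design_saliences[, k])), k], 0)
  }
  # reconstruction
  expect_equal(s$design_saliences %*% diag(s$singular_values) %*%
                 t(s$saliences), m, tolerance = 1e-12)

  # printed 2x3 toy: singular values match eigendecomposition of M'M
  toy <- matrix(c(1, 2, 0, -1, 3, 1), 2, 3)
  got <- pls_svd(toy)$singular_values
  want <- sqrt(sort(eigen(crossprod(toy), symmetric = TRUE,
                          only.values = TRUE)$values, decreasing = TRUE))[1:2]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cell-means SVD equals the dummy-coded cross-block SVD", {
  fx <- quick_dataset(n_pairs = 4, n_subjects = 5, n_timepoints = 40,
                      n_groups = 2, seed = 61)
  m <- assemble_cell_means(fx$ds)
  s1 <- svd(m)

  st <- connstab:::stack_observations(fx$ds)
  cells <- design_cells(fx$ds)
  key <- paste(st$labels$group, st$labels$condition)
  x_dummy <- outer(key, paste(cells$group, cells$condition), "==") * 1
  xc <- sweep(x_dummy, 2, colMeans(x_dummy))
  s2 <- svd(crossprod(xc, st$x))
  # equal cell sizes: same singular directions, singular values scaled
  keep <- s1$d > 1e-10
  ratio <- s2$d[keep] / s1$d[keep]
  expect_lt(diff(range(ratio)), 1e-8)
  for (k in which(keep)) {
    expect_equal(abs(sum(s1$v[, k] * s2$v[, k])), 1, tolerance = 1e-8)
  }
})

test_that("permutation test: degenerate data gives p = 1, planted effect p = 0", {
  p <- tiny_parcellation(n_pairs = 2, seed = 2)
  same <- sym_z(c(0.4, 0.1, -0.2, 0.3, 0, 0.25))
  ds0 <- toy_dataset(list(rep(list(same), 4), rep(list(same), 4)),
                     4, c("C1", "C2"), p)
  pt <- permutation_test(ds0, n_perm = 50, seed = 5)
  expect_equal(pt$observed[1], 0)
  expect_equal(pt$p[1], 1)

  # strong planted contrast: no permuted singular value reaches it
  fx <- quick_dataset(n_pairs = 8, n_subjects = 12, n_timepoints = 120,
                      effect_size = 0.4, seed = 71)
  pt2 <- permutation_test(fx$ds, n_perm = 100, seed = 6)
  expect_equal(pt2$p[1], 0)
  expect_true(all(pt2$null_singular_values[1, ] < pt2$observed[1]))
})

test_that("bootstrap: degenerate data flags every edge, BSR keeps salience sign", {
  p <- tiny_parcellation(n_pairs = 2, seed = 2)
  a <- sym_z(c(0.4, 0.1, -0.2, 0.3, 0, 0.25))
  b <- sym_z(c(0.1, 0.3, 0.2, -0.1, 0.15, 0))
  ds0 <- toy_dataset(list(rep(list(a), 4), rep(list(b), 4)),
                     4, c("C1", "C2"), p)
  model <- pls_svd(assemble_cell_means(ds0))
  bt <- bootstrap_ratios(ds0, model, n_boot = 30, seed = 8)
  expect_true(all(bt$floored))
  expect_true(all(is.na(bt$bootstrap_ratio)))

  fx <- quick_dataset(n_pairs = 5, n_subjects = 8, n_timepoints = 60,
                      effect_size = 0.3, seed = 81)
  model <- pls_svd(assemble_cell_means(fx$ds))
  bt <- bootstrap_ratios(fx$ds, model, n_boot = 60, seed = 9)
  ok <- !bt$floored[, 1] & abs(model$saliences[, 1]) > 0
  expect_true(all(sign(bt$bootstrap_ratio[ok, 1]) ==
                    sign(model$saliences[ok, 1])))
})

test_that("bootstrap matches an independent reimplementation of the loop", {
  fx <- quick_dataset(n_pairs = 3, n_subjects = 6, n_timepoints = 40,
                      seed = 91)
  ds <- fx$ds
  model <- pls_svd(assemble_cell_means(ds))
  n_boot <- 25; seed <- 14
  got <- bootstrap_ratios(ds, model, n_boot = n_boot, seed = seed)

  # from-scratch loop sharing only the RNG protocol (one sample() per
  # group per resample, in group order)
  arr <- ds$groups$G1
  subjects <- dimnames(arr)[[2]]
  conds <- dimnames(arr)[[1]]
  k <- length(model$singular_values)
  draws <- array(NA_real_, dim = c(nrow(model$saliences), k, n_boot))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    pick <- sample(subjects, length(subjects), replace = TRUE)
    cm <- t(vapply(conds, function(cc) {
      rows <- vapply(pick, function(s) {
        upper_triangle_vector(arr[cc, s, , ])
      }, numeric(nrow(model$saliences)))
      rowMeans(rows)
    }, numeric(nrow(model$saliences))))
    cm <- sweep(cm, 2, colMeans(cm))
    s <- svd(cm)
    pr <- svd(crossprod(s$u[, 1:k, drop = FALSE], model$design_saliences))
    rot <- pr$u %*% t(pr$v)
    draws[, , b] <- s$v[, 1:k, drop = FALSE] %*% rot
  }
  se_oracle <- apply(draws, c(1, 2), stats::sd)
  bsr_oracle <- model$saliences / pmax(se_oracle, 1e-12)
  bsr_oracle[se_oracle < 1e-12] <- NA_real_
  expect_equal(got$se, se_oracle, tolerance = 1e-10)
  expect_equal(got$bootstrap_ratio, bsr_oracle, tolerance = 1e-10)
})

test_that("task_pls recovers a planted condition contrast", {
  fx <- quick_dataset(n_pairs = 10, n_subjects = 12, n_timepoints = 120,
                      effect_size = 0.15, seed = 101)
  model <- task_pls(fx$ds, n_perm = 100, n_boot = 100, seed = 3)
  planted <- effective_effect_map(fx$parcellation, fx$truth)
  expect_gte(abs(cor(model$saliences[, 1], planted)), 0.9)
  expect_lt(model$p_values[1], 0.05)
  expect_equal(model$n_permutations, 100L)
})
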
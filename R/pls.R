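# Mean-centered task PLS on vectorized connectomes: SVD of the
# cell-means matrix (equivalent, up to column scaling, to the SVD of
# the cross-block covariance with a dummy-coded centered design),
# permutation test of the latent variables, and bootstrap estimation
# of edge salience reliability.

# Stack every subject x cell observation as a row of an
# observations x edges matrix, with a label data frame alongside.
stack_observations <- function(ds) {
  n <- nrow(ds$parcellation)
  rows <- list(); labs <- list(); k <- 0L
  for (g in names(ds$groups)) {
    arr <- ds$groups[[g]]
    subjects <- dimnames(arr)[[2]]
    for (s in seq_along(subjects)) {
      for (cc in seq_len(dim(arr)[1])) {
        k <- k + 1L
        rows[[k]] <- upper_triangle_vector(arr[cc, s, , ])
        labs[[k]] <- data.frame(group = g, subject = subjects[s],
                                condition = dimnames(arr)[[1]][cc],
                                stringsAsFactors = FALSE)
      }
    }
  }
  list(x = do.call(rbind, rows), labels = do.call(rbind, labs))
}

# Cell means in canonical (group-major) cell order, grand-mean centered.
cell_means_from_stack <- function(x, labels, cell_order) {
  key <- paste(labels$group, labels$condition, sep = "\r")
  want <- paste(cell_order$group, cell_order$condition, sep = "\r")
  m <- matrix(NA_real_, nrow(cell_order), ncol(x))
  for (k in seq_along(want)) {
    sel <- key == want[k]
    if (!any(sel)) stop("empty design cell: ", gsub("\r", "/", want[k]))
    m[k, ] <- colMeans(x[sel, , drop = FALSE])
  }
  m
}

#' Cell-means matrix for task PLS
#'
#' One row per group x condition cell (mean edge vector over that
#' cell's subjects), columns centered by the grand mean across cells.
#'
#' @param ds a `connectivity_dataset`; every cell needs >= 2 subjects.
#' @return centered cells x edges matrix with attribute `cell_order`.
#' @export
assemble_cell_means <- function(ds) {
  cells <- design_cells(ds)
  if (any(cells$n_subjects < 2)) stop("every design cell needs >= 2 subjects")
  st <- stack_observations(ds)
  m <- cell_means_from_stack(st$x, st$labels, cells)
  m <- sweep(m, 2, colMeans(m))
  attr(m, "cell_order") <- cells[, c("group", "condition")]
  m
}

# SVD with the package's deterministic sign convention: each latent
# variable's design salience vector has a non-negative entry of largest
# magnitude.
svd_signed <- function(m) {
  s <- svd(m)
  for (k in seq_along(s$d)) {
    piv <- which.max(abs(s$u[, k]))
    if (s$u[piv, k] < 0) {
      s$u[, k] <- -s$u[, k]
      s$v[, k] <- -s$v[, k]
    }
  }
  s
}

#' Singular value decomposition of the centered cell means
#'
#' Latent variables (LVs) are ordered by singular value; LV `k` pairs a
#' design salience vector (contrast over cells) with a unit-norm edge
#' salience vector (brain weights). The covariance fraction of LV `k`
#' is `d_k^2 / sum(d^2)`.
#'
#' @param centered_means output of [assemble_cell_means()] (or any
#'   finite cells x edges matrix).
#' @return a `pls_model` with `cell_order`, `design_saliences`
#'   (cells x k), `saliences` (edges x k), `singular_values`,
#'   `covariance_fraction`, `degenerate` flag.
#' @export
pls_svd <- function(centered_means) {
  if (!all(is.finite(centered_means))) stop("cell means must be finite")
  total <- sum(centered_means^2)
  degenerate <- total <= 0
  s <- svd_signed(centered_means)
  model <- list(
    cell_order = attr(centered_means, "cell_order"),
    design_saliences = s$u,
    saliences = s$v,
    singular_values = s$d,
    covariance_fraction = if (degenerate) rep(NA_real_, length(s$d))
                          else s$d^2 / sum(s$d^2),
    degenerate = degenerate
  )
  class(model) <- "pls_model"
  model
}

# One permutation of the exchangeability scheme: whole subjects are
# relabeled across groups (group sizes preserved) and condition labels
# are shuffled within each subject. mode = "conditions" restricts to
# the within-subject condition shuffle.
permute_labels <- function(labels, mode = c("full", "conditions")) {
  mode <- match.arg(mode)
  out <- labels
  if (mode == "full") {
    subj <- unique(labels$subject)
    gr_of <- labels$group[match(subj, labels$subject)]
    new_gr <- sample(gr_of)
    out$group <- new_gr[match(labels$subject, subj)]
  }
  for (s in unique(labels$subject)) {
    sel <- which(labels$subject == s)
    out$condition[sel] <- sample(labels$condition[sel])
  }
  out
}

#' Permutation test of latent variable significance
#'
#' Builds a null distribution of singular values by re-ordering
#' participant and condition labels without replacement, rebuilding the
#' centered cell means and re-running the SVD. The p-value of LV `k` is
#' the proportion of permuted `k`-th singular values that are greater
#' than or equal to the observed one (raw proportion, no smoothing).
#'
#' @param ds a `connectivity_dataset`.
#' @param n_perm number of permutations (default 500).
#' @param seed integer seed.
#' @param mode `"full"` permutes subjects across groups and condition
#'   labels within subject; `"conditions"` shuffles conditions only.
#' @return list with `p` (per-LV), `observed` singular values,
#'   `null_singular_values` (k x n_perm), `n_perm`.
#' @export
permutation_test <- function(ds, n_perm = 500, seed = 1,
                             mode = c("full", "conditions")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  cells <- design_cells(ds)
  st <- stack_observations(ds)
  if (nrow(st$x) < nrow(cells)) stop("fewer observations than design cells")

  observed <- pls_svd(assemble_cell_means(ds))$singular_values
  k <- length(observed)
  null_d <- matrix(NA_real_, k, n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      labs <- permute_labels(st$labels, mode)
      m <- cell_means_from_stack(st$x, labs, cells)
      m <- sweep(m, 2, colMeans(m))
      null_d[, b] <- svd(m, nu = 0, nv = 0)$d
    }
  })
  p <- vapply(seq_len(k), function(i) mean(null_d[i, ] >= observed[i]),
              numeric(1))
  list(p = p, observed = observed, null_singular_values = null_d,
       n_perm = as.integer(n_perm), mode = mode)
}

# Orthogonal Procrustes rotation R minimizing ||A %*% R - B||_F.
procrustes_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  s$u %*% t(s$v)
}

#' Bootstrap standard errors and ratios for edge saliences
#'
#' Resamples participants with replacement within each group (condition
#' labels preserved), rebuilds the centered cell means and re-runs the
#' SVD. Each bootstrap's saliences are aligned to the original model by
#' an orthogonal Procrustes rotation computed on the design side, so
#' that axis reflections and rotations across resamples do not inflate
#' the spread. The bootstrap ratio (BSR) of an edge is its salience
#' divided by the standard deviation of its aligned bootstrap
#' saliences.
#'
#' @param ds a `connectivity_dataset`; every cell needs >= 3 subjects.
#' @param model the [pls_svd()] model of `ds`.
#' @param n_boot number of bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param se_floor standard errors below this are floored and flagged.
#' @return a `pls_bootstrap`: list with `se` (edges x k),
#'   `bootstrap_ratio` (edges x k), `floored` logical matrix,
#'   `n_resamples`.
#' @export
bootstrap_ratios <- function(ds, model, n_boot = 500, seed = 1,
                             se_floor = 1e-12) {
  cells <- design_cells(ds)
  if (any(cells$n_subjects < 3)) stop("every design cell needs >= 3 subjects")
  st <- stack_observations(ds)
  k <- length(model$singular_values)
  ne <- nrow(model$saliences)

  # Welford's online mean/M2: exact zeros for degenerate resamples
  run_mean <- matrix(0, ne, k)
  run_m2 <- matrix(0, ne, k)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      m <- matrix(NA_real_, nrow(cells), ne)
      for (g in unique(cells$group)) {
        subj <- unique(st$labels$subject[st$labels$group == g])
        draw <- sample(subj, length(subj), replace = TRUE)
        for (cc in which(cells$group == g)) {
          cond <- cells$condition[cc]
          rows <- vapply(draw, function(s) {
            which(st$labels$subject == s & st$labels$condition == cond)
          }, integer(1))
          m[cc, ] <- colMeans(st$x[rows, , drop = FALSE])
        }
      }
      m <- sweep(m, 2, colMeans(m))
      s <- svd(m)
      rot <- procrustes_rotation(s$u[, seq_len(k), drop = FALSE],
                                 model$design_saliences)
      vb <- s$v[, seq_len(k), drop = FALSE] %*% rot
      delta <- vb - run_mean
      run_mean <- run_mean + delta / b
      run_m2 <- run_m2 + delta * (vb - run_mean)
    }
  })
  se <- sqrt(run_m2 / (n_boot - 1))
  floored <- se < se_floor
  bsr <- model$saliences / pmax(se, se_floor)
  bsr[floored] <- NA_real_
  out <- list(se = se, bootstrap_ratio = bsr, floored = floored,
              n_resamples = as.integer(n_boot))
  class(out) <- "pls_bootstrap"
  out
}

#' Fit the full task-PLS model with inference
#'
#' Convenience wrapper: [assemble_cell_means()] + [pls_svd()] +
#' [permutation_test()] + [bootstrap_ratios()].
#'
#' @param ds a `connectivity_dataset`.
#' @param n_perm permutations (default 500).
#' @param n_boot bootstrap resamples (default 500).
#' @param seed master seed; permutation and bootstrap get separate
#'   streams spawned from it.
#' @param mode permutation exchangeability mode, see
#'   [permutation_test()].
#' @return a `pls_model` with `p_values`, `n_permutations`, and
#'   `bootstrap` filled in.
#' @export
task_pls <- function(ds, n_perm = 500, n_boot = 500, seed = 1,
                     mode = c("full", "conditions")) {
  mode <- match.arg(mode)
  seeds <- spawn_seeds(seed, 2)
  model <- pls_svd(assemble_cell_means(ds))
  perm <- permutation_test(ds, n_perm = n_perm, seed = seeds[1], mode = mode)
  model$p_values <- perm$p
  model$n_permutations <- perm$n_perm
  model$bootstrap <- bootstrap_ratios(ds, model, n_boot = n_boot,
                                      seed = seeds[2])
  model
}

#' @export
print.pls_model <- function(x, ...) {
  k <- length(x$singular_values)
  cat("Task PLS model:", k, "latent variable(s) over",
      nrow(x$saliences), "edges\n")
  df <- data.frame(
    lv = seq_len(k),
    singular_value = signif(x$singular_values, 4),
    covariance_fraction = signif(x$covariance_fraction, 4)
  )
  if (!is.null(x$p_values)) df$p_perm <- x$p_values
  print(df, row.names = FALSE)
  invisible(x)
}
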
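# Edge-level change maps and the distance-dependence analyses: the
# descriptive all-edges correlation, the independent-pairs resampling
# null (edges sampled as a perfect matching of nodes so no two share a
# node), the PCA outlier diagnostic, and 2-D density summaries.

#' Construct an edge change map
#'
#' Pairs one scalar per unique edge (a salience, bootstrap ratio or
#' condition correlation difference) with that edge's Euclidean
#' distance, in the canonical edge ordering.
#'
#' @param values numeric edge vector of change scores.
#' @param distances numeric edge vector of distances (mm), or an
#'   `n x n` distance matrix.
#' @param kind one of `"salience"`, `"bootstrap_ratio"`,
#'   `"correlation_difference"`, `"abs_salience"`,
#'   `"abs_correlation_difference"`.
#' @param condition_pair optional character vector naming the two cells
#'   a correlation difference contrasts.
#' @return an `edge_change_map`.
#' @export
edge_change_map <- function(values, distances,
                            kind = c("salience", "bootstrap_ratio",
                                     "correlation_difference",
                                     "abs_salience",
                                     "abs_correlation_difference"),
                            condition_pair = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(distances)) distances <- upper_triangle_vector(distances)
  if (length(values) != length(distances)) {
    stop("values and distances must share the canonical edge ordering")
  }
  ne <- length(values)
  n <- (1 + sqrt(1 + 8 * ne)) / 2
  if (abs(n - round(n)) > 1e-9) stop("length is not n*(n-1)/2")
  out <- list(kind = kind, values = as.numeric(values),
              distances = as.numeric(distances),
              condition_pair = condition_pair,
              n_nodes = as.integer(round(n)))
  class(out) <- "edge_change_map"
  out
}

#' Absolute-value version of a change map
#'
#' @param change an `edge_change_map` of kind `"salience"` or
#'   `"correlation_difference"`.
#' @return an `edge_change_map` with `abs()` applied to the values.
#' @export
abs_change_map <- function(change) {
  kind <- switch(change$kind,
                 salience = "abs_salience",
                 correlation_difference = "abs_correlation_difference",
                 stop("absolute value only defined for salience or ",
                      "correlation_difference maps"))
  edge_change_map(abs(change$values), change$distances, kind,
                  change$condition_pair)
}

#' Change map from PLS edge saliences
#'
#' @param model a `pls_model`.
#' @param parcellation the parcellation the model was fit on.
#' @param lv latent variable index (default 1).
#' @return an `edge_change_map` of kind `"salience"`.
#' @export
change_map_salience <- function(model, parcellation, lv = 1) {
  edge_change_map(model$saliences[, lv], distance_matrix(parcellation),
                  "salience")
}

#' Change map from bootstrap ratios
#'
#' @param model a `pls_model` fitted with [task_pls()] (or carrying a
#'   `bootstrap` element).
#' @param parcellation the parcellation.
#' @param lv latent variable index (default 1).
#' @return an `edge_change_map` of kind `"bootstrap_ratio"`.
#' @export
change_map_bsr <- function(model, parcellation, lv = 1) {
  if (is.null(model$bootstrap)) stop("model carries no bootstrap results")
  edge_change_map(model$bootstrap$bootstrap_ratio[, lv],
                  distance_matrix(parcellation), "bootstrap_ratio")
}

#' Difference of two conditions' group-averaged z matrices
#'
#' Subtracts the group-averaged Fisher-z matrix of cell B from that of
#' cell A and vectorizes the result.
#'
#' @param ds a `connectivity_dataset`.
#' @param cell_a,cell_b lists or character vectors `(group, condition)`;
#'   a bare condition name uses all groups.
#' @return an `edge_change_map` of kind `"correlation_difference"`.
#' @export
correlation_difference <- function(ds, cell_a, cell_b) {
  get_cell <- function(cell) {
    if (is.character(cell) && length(cell) == 1) {
      list(group = NULL, condition = cell)
    } else {
      list(group = cell[[1]], condition = cell[[2]])
    }
  }
  a <- get_cell(cell_a); b <- get_cell(cell_b)
  for (cl in list(a, b)) {
    if (!cl$condition %in% ds$conditions) {
      stop("unknown condition: ", cl$condition)
    }
    if (!is.null(cl$group) && !cl$group %in% names(ds$groups)) {
      stop("unknown group: ", cl$group)
    }
  }
  za <- group_average_z(ds, a$group, a$condition)
  zb <- group_average_z(ds, b$group, b$condition)
  edge_change_map(upper_triangle_vector(za - zb),
                  distance_matrix(ds$parcellation),
                  "correlation_difference",
                  condition_pair = c(paste(c(a$group, a$condition), collapse = "/"),
                                     paste(c(b$group, b$condition), collapse = "/")))
}

#' Descriptive all-edges change--distance correlation
#'
#' Correlation over all unique edges. Because edges derived from
#' correlation matrices are not independent observations, this figure
#' is descriptive only; inference belongs to
#' [independent_pairs_correlation()].
#'
#' @param change an `edge_change_map`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `method`, `n_edges`, `note`.
#' @export
change_distance_correlation <- function(change,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(change$values) < 3) stop("need at least 3 edges")
  if (stats::sd(change$values) == 0 || stats::sd(change$distances) == 0) {
    stop("zero variance in change values or distances")
  }
  list(coefficient = stats::cor(change$distances, change$values,
                                method = method),
       method = method, n_edges = length(change$values),
       note = "descriptive (non-independent points)")
}

# Draw one uniform random perfect matching of nodes (Fisher-Yates
# shuffle then consecutive pairing; one node dropped when n is odd) and
# return the canonical edge positions of the matched pairs.
sample_matching_edges <- function(n) {
  ord <- sample.int(n)
  m <- floor(n / 2)
  i <- ord[seq(1, 2 * m, by = 2)]
  j <- ord[seq(2, 2 * m, by = 2)]
  edge_position(i, j, n)
}

#' Independent-pairs null for the change--distance correlation
#'
#' Edges derived from a correlation matrix are non-independent (knowing
#' r(a,b) and r(a,c) constrains r(b,c)), so ordinary inference over all
#' edges is anticonservative. This resampling scheme draws, per sample,
#' a uniform random perfect matching of the nodes — `floor(n/2)` edges
#' sharing no node — and correlates distance with change over just
#' those edges. Repeating builds a sampling distribution of independent
#' correlation coefficients; one-tailed p-values are read off it.
#'
#' @param change an `edge_change_map`.
#' @param n_samples number of resampled matchings (default 1000).
#' @param seed integer seed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param stratum optional logical edge vector; only matched pairs
#'   whose edge lies in the stratum enter the correlation, and samples
#'   retaining fewer than `min_pairs` eligible pairs are redrawn.
#' @param min_pairs minimum eligible pairs per sample when `stratum`
#'   is given (default 10).
#' @param max_redraws redraw attempts per sample before erroring.
#' @return an `independent_pairs_result`: list with `rho_samples`,
#'   `mean_rho`, `se` (sd of the sampling distribution), `se_of_mean`
#'   (`se / sqrt(n_samples)`), `p_greater`, `p_less` (ties at zero
#'   counted half toward each), `n_pairs_per_sample`, `n_samples`,
#'   `method`.
#' @export
independent_pairs_correlation <- function(change, n_samples = 1000, seed = 1,
                                          method = c("spearman", "pearson"),
                                          stratum = NULL, min_pairs = 10,
                                          max_redraws = 100) {
  method <- match.arg(method)
  n <- change$n_nodes
  if (n < 4) stop("need at least 4 nodes")
  if (!is.null(stratum) && length(stratum) != length(change$values)) {
    stop("stratum must be a logical edge vector")
  }
  rho <- numeric(n_samples)
  npair <- floor(n / 2)
  with_seed(seed, {
    for (b in seq_len(n_samples)) {
      ok <- FALSE
      for (attempt in seq_len(max_redraws)) {
        pos <- sample_matching_edges(n)
        if (!is.null(stratum)) {
          pos <- pos[stratum[pos]]
          if (length(pos) < min_pairs) next
        }
        dv <- change$distances[pos]
        cv <- change$values[pos]
        if (stats::sd(dv) == 0 || stats::sd(cv) == 0) next
        rho[b] <- stats::cor(dv, cv, method = method)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not draw a valid matching in ", max_redraws, " attempts")
      }
    }
  })
  p_greater <- mean(rho > 0) + 0.5 * mean(rho == 0)
  out <- list(
    rho_samples = rho,
    mean_rho = mean(rho),
    se = stats::sd(rho),
    se_of_mean = stats::sd(rho) / sqrt(n_samples),
    p_greater = p_greater,
    p_less = 1 - p_greater,
    n_pairs_per_sample = as.integer(npair),
    n_samples = as.integer(n_samples),
    method = method
  )
  class(out) <- "independent_pairs_result"
  out
}

#' @export
print.independent_pairs_result <- function(x, ...) {
  cat(sprintf(
    "Independent-pairs null (%s, %d samples of %d pairs):\n", x$method,
    x$n_samples, x$n_pairs_per_sample))
  cat(sprintf("  rho = %.4f, SE = %.4f, P(rho>0) = %.3f, P(rho<0) = %.3f\n",
              x$mean_rho, x$se, x$p_greater, x$p_less))
  invisible(x)
}

#' PCA outlier diagnostic for the change--distance cloud
#'
#' Standardizes distance and change, finds the principal axis of their
#' 2x2 covariance, computes each point's signed orthogonal displacement
#' from that axis, and flags the `ceil(tail_fraction * N)` most
#' positive and most negative displacements. Reports the
#' change--distance correlation within the flagged set, to check
#' whether outlying edges behave differently from the bulk.
#'
#' @param change an `edge_change_map` with >= 20 edges.
#' @param tail_fraction fraction flagged in each tail (default 0.05).
#' @return list with `principal_axis` (unit 2-vector in standardized
#'   (distance, change) coordinates), `displacement` (per edge),
#'   `flagged_upper`, `flagged_lower` (edge indices), the
#'   `outlier_correlation` within the flagged set (`NA` when
#'   degenerate), and `degenerate` flag.
#' @export
pca_outlier_diagnostic <- function(change, tail_fraction = 0.05) {
  nn <- length(change$values)
  if (nn < 20) stop("need at least 20 edges")
  xs <- cbind(d = change$distances, v = change$values)
  sds <- apply(xs, 2, stats::sd)
  degenerate <- any(sds == 0)
  if (!degenerate) {
    xs <- scale(xs)
    e <- eigen(stats::cov(xs), symmetric = TRUE)
    axis <- e$vectors[, 1]
    if (axis[which.max(abs(axis))] < 0) axis <- -axis
    ortho <- c(-axis[2], axis[1])
    disp <- as.numeric(xs %*% ortho)
    disp[abs(disp) < 1e-10] <- 0   # snap numerically-collinear points
    if (all(disp == 0)) degenerate <- TRUE
  } else {
    axis <- c(NA_real_, NA_real_)
    disp <- rep(0, nn)
  }
  if (degenerate && all(is.na(axis))) disp <- rep(0, nn)

  k <- ceiling(tail_fraction * nn)
  ord <- order(disp)                       # ties broken by index order
  flagged_lower <- ord[seq_len(k)]
  flagged_upper <- ord[seq(nn - k + 1, nn)]
  flagged <- c(flagged_lower, flagged_upper)
  dv <- change$distances[flagged]; cv <- change$values[flagged]
  outlier_cor <- if (degenerate || stats::sd(dv) == 0 || stats::sd(cv) == 0) {
    NA_real_
  } else {
    stats::cor(dv, cv)
  }
  list(principal_axis = axis, displacement = disp,
       flagged_upper = flagged_upper, flagged_lower = flagged_lower,
       outlier_correlation = outlier_cor,
       tail_fraction = tail_fraction, degenerate = degenerate)
}

#' 2-D density histogram of change versus distance
#'
#' Bins the (distance, change) points on a rectangular grid spanning
#' the observed ranges; the data behind a density-coloured summary
#' plot of a dense edge cloud.
#'
#' @param change an `edge_change_map`.
#' @param bins_x,bins_y bin counts per axis (>= 2 each).
#' @return list with `counts` (`bins_x x bins_y` matrix),
#'   `breaks_x`, `breaks_y`.
#' @export
density_histogram_2d <- function(change, bins_x = 25, bins_y = 25) {
  if (bins_x < 2 || bins_y < 2) stop("need at least 2 bins per axis")
  dv <- change$distances; cv <- change$values
  bx <- seq(min(dv), max(dv), length.out = bins_x + 1)
  by <- seq(min(cv), max(cv), length.out = bins_y + 1)
  # guard zero-width ranges so every point lands in one bin
  if (bx[1] == bx[length(bx)]) bx <- bx + seq(-0.5, 0.5, length.out = bins_x + 1)
  if (by[1] == by[length(by)]) by <- by + seq(-0.5, 0.5, length.out = bins_y + 1)
  ix <- findInterval(dv, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(cv, by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins_x, bins_y)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(counts = counts, breaks_x = bx, breaks_y = by)
}
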
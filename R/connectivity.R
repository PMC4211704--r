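# Fisher-z connectivity matrices and the within-condition
# distance--connectivity relationship.

#' Pearson correlation matrix of a multivariate time series
#'
#' @param timeseries `T x n` matrix, one column per node. `T >= 3` and
#'   no column may have zero variance.
#' @return symmetric `n x n` correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(timeseries) {
  stopifnot(is.matrix(timeseries))
  if (nrow(timeseries) < 3) stop("need at least 3 time points")
  v <- apply(timeseries, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- colnames(timeseries)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance time series for node(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(timeseries)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform
#'
#' `atanh(r)` after clamping `|r|` to `1 - 1e-7` so that perfect
#' correlations map to a large finite value instead of overflowing.
#' Applied to a matrix, the diagonal is set to 0 (self-connections are
#' excluded throughout the package).
#'
#' @param r correlation value(s) in `[-1, 1]`, scalar, vector or matrix.
#' @return z value(s) of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  clamp <- 1 - 1e-7
  z <- atanh(pmax(pmin(r, clamp), -clamp))
  if (is.matrix(r) && nrow(r) == ncol(r)) diag(z) <- 0
  z
}

#' Euclidean distance matrix between parcellation centroids
#'
#' @param parcellation a parcellation.
#' @return symmetric `n x n` matrix of centroid distances (mm).
#' @export
distance_matrix <- function(parcellation) {
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("centroids must be finite")
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  d
}

#' Assemble a connectivity dataset of Fisher-z matrices
#'
#' Converts a [sample_dataset()] result into per subject x cell
#' symmetric Fisher-z matrices with zero diagonal, stored per group as
#' a 4-D array ordered conditions x participants x regions x regions
#' (the layout connectivity matrices are commonly shipped in).
#'
#' @param x a `synthetic_dataset`, or a named list of such 4-D z arrays
#'   (one per group) together with `parcellation=`.
#' @param parcellation required when `x` is a list of arrays.
#' @return a `connectivity_dataset`: list with `parcellation`,
#'   `conditions`, and `groups` (named list of 4-D arrays).
#' @export
connectivity_dataset <- function(x, parcellation = NULL) {
  if (inherits(x, "synthetic_dataset")) {
    parcellation <- x$parcellation
    n <- nrow(parcellation)
    conditions <- sort(unique(x$design$condition))
    groups <- lapply(x$timeseries, function(subjects) {
      arr <- array(NA_real_,
                   dim = c(length(conditions), length(subjects), n, n),
                   dimnames = list(conditions, names(subjects), NULL, NULL))
      for (s in seq_along(subjects)) {
        for (cc in seq_along(conditions)) {
          arr[cc, s, , ] <- fisher_z(correlation_matrix(
            subjects[[s]][[conditions[cc]]]))
        }
      }
      arr
    })
  } else if (is.list(x) && all(vapply(x, is.array, logical(1)))) {
    if (is.null(parcellation)) stop("parcellation is required with array input")
    n <- nrow(parcellation)
    groups <- x
    conditions <- dimnames(groups[[1]])[[1]]
    if (is.null(conditions)) conditions <- sprintf("C%d", seq_len(dim(groups[[1]])[1]))
    for (g in seq_along(groups)) {
      dd <- dim(groups[[g]])
      if (length(dd) != 4 || dd[3] != n || dd[4] != n) {
        stop("each group array must be conditions x participants x n x n")
      }
      if (is.null(dimnames(groups[[g]]))) {
        dimnames(groups[[g]]) <- list(conditions,
                                      sprintf("S%02d", seq_len(dd[2])), NULL, NULL)
      }
    }
    if (is.null(names(groups))) names(groups) <- sprintf("G%d", seq_along(groups))
  } else {
    stop("cannot build a connectivity dataset from this input")
  }
  out <- list(parcellation = parcellation, conditions = conditions,
              groups = groups)
  class(out) <- "connectivity_dataset"
  validate_connectivity_dataset(out)
}

validate_connectivity_dataset <- function(ds, tol = 1e-6) {
  n <- nrow(ds$parcellation)
  for (g in names(ds$groups)) {
    arr <- ds$groups[[g]]
    if (!all(is.finite(arr))) stop("non-finite entries in group ", g)
    for (cc in seq_len(dim(arr)[1])) {
      for (s in seq_len(dim(arr)[2])) {
        m <- arr[cc, s, , ]
        if (max(abs(m - t(m))) > tol) {
          stop("asymmetric matrix in group ", g, " beyond tolerance ", tol)
        }
        if (max(abs(diag(m))) > tol) {
          stop("diagonal must be zero in z-space (group ", g, ")")
        }
      }
    }
  }
  invisible(ds)
}

#' Design cells of a connectivity dataset
#'
#' @param ds a `connectivity_dataset`.
#' @return data frame with columns `group`, `condition`, `n_subjects`,
#'   one row per cell in the canonical (group-major) cell order used by
#'   the PLS model.
#' @export
design_cells <- function(ds) {
  do.call(rbind, lapply(names(ds$groups), function(g) {
    data.frame(group = g, condition = ds$conditions,
               n_subjects = dim(ds$groups[[g]])[2],
               stringsAsFactors = FALSE)
  }))
}

#' Group-averaged Fisher-z matrix
#'
#' @param ds a `connectivity_dataset`.
#' @param group group name; `NULL` averages over all groups.
#' @param condition condition name; `NULL` averages over all conditions.
#' @return `n x n` averaged z matrix.
#' @export
group_average_z <- function(ds, group = NULL, condition = NULL) {
  gsel <- if (is.null(group)) names(ds$groups) else group
  csel <- if (is.null(condition)) ds$conditions else condition
  n <- nrow(ds$parcellation)
  acc <- matrix(0, n, n); k <- 0L
  for (g in gsel) {
    arr <- ds$groups[[g]]
    for (cc in csel) {
      ci <- match(cc, dimnames(arr)[[1]])
      if (is.na(ci)) stop("unknown condition: ", cc)
      for (s in seq_len(dim(arr)[2])) {
        acc <- acc + arr[ci, s, , ]
        k <- k + 1L
      }
    }
  }
  acc / k
}

#' Within-condition distance--connectivity correlation
#'
#' Correlates the unique-edge Fisher-z values of a connectivity matrix
#' with the corresponding inter-centroid Euclidean distances; negative
#' values mean closer regions are more strongly connected.
#'
#' @param z_matrix `n x n` symmetric Fisher-z matrix.
#' @param d `n x n` distance matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `method`, `n_edges`.
#' @export
distance_fc_correlation <- function(z_matrix, d,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(dim(z_matrix) == dim(d)))
  zv <- upper_triangle_vector(z_matrix)
  dv <- upper_triangle_vector(d)
  if (stats::sd(zv) == 0 || stats::sd(dv) == 0) {
    stop("zero variance in edge values or distances")
  }
  list(coefficient = stats::cor(dv, zv, method = method),
       method = method, n_edges = length(zv))
}

#' Distance--connectivity correlations for every design cell
#'
#' The per-condition, per-group summary of how strongly baseline
#' connectivity decays with distance, computed on each cell's
#' group-averaged z matrix.
#'
#' @param ds a `connectivity_dataset`.
#' @param method correlation method.
#' @return data frame `group`, `condition`, `coefficient`, `n_edges`.
#' @export
distance_fc_by_cell <- function(ds, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d <- distance_matrix(ds$parcellation)
  cells <- design_cells(ds)
  cells$coefficient <- NA_real_
  cells$n_edges <- NA_integer_
  for (k in seq_len(nrow(cells))) {
    zz <- group_average_z(ds, cells$group[k], cells$condition[k])
    res <- distance_fc_correlation(zz, d, method)
    cells$coefficient[k] <- res$coefficient
    cells$n_edges[k] <- res$n_edges
  }
  cells
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cells <- design_cells(x)
  cat("Connectivity dataset:", nrow(x$parcellation), "nodes,",
      length(x$groups), "group(s),", length(x$conditions), "condition(s),",
      sum(cells$n_subjects[!duplicated(cells$group)]), "subjects\n")
  invisible(x)
}
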
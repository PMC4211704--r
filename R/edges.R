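# Canonical edge ordering: upper triangle (i < j), row-major, i.e.
# (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). Every module in the
# package vectorizes symmetric matrices through these helpers so that
# edge-level quantities (saliences, distances, strata labels) align.

#' Number of unique edges among n nodes
#'
#' @param n number of nodes.
#' @return `n * (n - 1) / 2`.
#' @export
n_edges <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  as.integer(n * (n - 1) / 2)
}

#' Edge index table for the canonical edge ordering
#'
#' @param n number of nodes.
#' @return integer matrix with columns `i`, `j` (`i < j`), one row per
#'   edge, in the canonical row-major upper-triangle order.
#' @export
edge_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# Position of edge (i, j), i < j, in the canonical ordering.
edge_position <- function(i, j, n) {
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  as.integer((i - 1L) * n - i * (i - 1L) / 2 + (j - i))
}

#' Vectorize a symmetric matrix over its unique edges
#'
#' Extracts the upper triangle in the canonical row-major order. The
#' matrix must be symmetric; the diagonal is ignored.
#'
#' @param m symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @seealso [from_edge_vector()] for the inverse.
#' @export
upper_triangle_vector <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is not symmetric within tolerance ", tol)
  }
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [upper_triangle_vector()]; the diagonal is set to zero.
#'
#' @param v edge vector in the canonical ordering.
#' @param diag value placed on the diagonal (default 0).
#' @return symmetric `n x n` matrix.
#' @export
from_edge_vector <- function(v, diag = 0) {
  ne <- length(v)
  n <- (1 + sqrt(1 + 8 * ne)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("edge vector length ", ne, " is not n*(n-1)/2 for integer n")
  }
  n <- as.integer(round(n))
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- v
  m <- t(tm) + tm
  base::diag(m) <- diag
  m
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package
# route through this so that explicit seeds never clobber the session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministically spawn `n` child seeds from one master seed, so each
# pipeline stage gets an independent stream controlled by a single knob.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
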
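# Synthetic multi-subject, multi-condition ROI datasets with known
# ground truth: distance-decaying baseline connectivity, controllable
# condition effects over distance (flat / increasing / decreasing), and
# elevated, stable homotopic (mirror-pair) edges. Every downstream
# stage of the package has a parameter-recovery test built on these.

#' Generate a spatially embedded parcellation with mirror pairs
#'
#' Creates `2 * n_pairs + n_medial` nodes with 3-D centroids (mm).
#' Paired nodes are mirror images in the x = 0 plane and are each
#' other's homotope; medial nodes sit on x = 0 and have no homotope.
#'
#' @param n_pairs number of left/right homotopic pairs (>= 1).
#' @param n_medial number of unpaired midline nodes.
#' @param extent side (mm) of the bounding box for coordinates.
#' @param seed integer seed; the same seed reproduces the parcellation.
#' @return a `parcellation`: data frame with columns `node_id`, `x`,
#'   `y`, `z`, `hemisphere` (`"left"`, `"right"`, `"medial"`) and
#'   `homotope_of` (partner `node_id` or `NA`).
#' @examples
#' p <- make_parcellation(n_pairs = 3, n_medial = 1, extent = 140, seed = 1)
#' @export
make_parcellation <- function(n_pairs, n_medial = 0, extent = 140, seed = 1) {
  if (!is.numeric(n_pairs) || n_pairs < 1) stop("n_pairs must be >= 1")
  if (!is.numeric(n_medial) || n_medial < 0) stop("n_medial must be >= 0")
  if (!is.numeric(extent) || extent <= 0) stop("extent must be positive")
  n_pairs <- as.integer(n_pairs); n_medial <- as.integer(n_medial)

  with_seed(seed, {
    # left-hemisphere x in (-extent/2, 0); y, z anywhere in the box
    lx <- stats::runif(n_pairs, -extent / 2, 0)
    ly <- stats::runif(n_pairs, -extent / 2, extent / 2)
    lz <- stats::runif(n_pairs, -extent / 2, extent / 2)
    mx <- rep(0, n_medial)
    my <- stats::runif(n_medial, -extent / 2, extent / 2)
    mz <- stats::runif(n_medial, -extent / 2, extent / 2)

    left_id  <- sprintf("L%02d", seq_len(n_pairs))
    right_id <- sprintf("R%02d", seq_len(n_pairs))
    med_id   <- if (n_medial > 0) sprintf("M%02d", seq_len(n_medial)) else character()

    p <- data.frame(
      node_id = c(left_id, right_id, med_id),
      x = c(lx, -lx, mx),
      y = c(ly, ly, my),
      z = c(lz, lz, mz),
      hemisphere = c(rep("left", n_pairs), rep("right", n_pairs),
                     rep("medial", n_medial)),
      homotope_of = c(right_id, left_id, rep(NA_character_, n_medial)),
      stringsAsFactors = FALSE
    )
    class(p) <- c("parcellation", "data.frame")
    validate_parcellation(p)
    p
  })
}

validate_parcellation <- function(p) {
  req <- c("node_id", "x", "y", "z", "hemisphere", "homotope_of")
  if (!all(req %in% names(p))) {
    stop("parcellation must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(p$node_id)) stop("node_ids must be unique")
  if (!all(is.finite(as.matrix(p[, c("x", "y", "z")])))) {
    stop("centroids must be finite")
  }
  paired <- !is.na(p$homotope_of)
  idx <- match(p$homotope_of[paired], p$node_id)
  if (anyNA(idx)) stop("homotope_of refers to unknown node_id")
  back <- p$homotope_of[idx]
  if (!identical(back, p$node_id[paired])) {
    stop("homotope relation must be symmetric and involutive")
  }
  if (any(p$hemisphere[paired] == p$hemisphere[idx])) {
    stop("homotopic partners must lie in opposite hemispheres")
  }
  invisible(p)
}

#' Ground-truth generative parameters for a synthetic dataset
#'
#' Encodes the hypotheses the pipeline is built to distinguish: a
#' distance-decaying baseline (`r0 * exp(-d / decay_length)`), an
#' additive correlation boost on homotopic edges, and a per-edge
#' condition effect (in Fisher-z units) whose magnitude profile over
#' distance is `"flat"` (drawn independently of distance),
#' `"increasing"` or `"decreasing"` (proportional to the distance
#' z-score with the stated sign). On homotopic edges the effect is
#' multiplied by `homotopic_stability` (0 = perfectly stable, 1 = as
#' labile as any other edge). Condition `k` of `n_conditions` applies
#' the effect with a centered weight running evenly from -0.5 to +0.5.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param n_conditions number of task conditions (>= 1).
#' @param decay_length e-folding length (mm) of the baseline falloff.
#' @param r0 baseline correlation at zero distance.
#' @param homotopic_boost additive correlation increment on homotopic
#'   edges (applied before the 0.95 cap).
#' @param effect_size scale (z units) of the condition effect.
#' @param effect_profile `"flat"`, `"increasing"` or `"decreasing"`.
#' @param homotopic_stability multiplier in `[0, 1]` on homotopic edges.
#' @param group_weights optional per-group multiplier on the effect
#'   (defaults to 1 for every group).
#' @param seed seed for the flat-profile effect draw.
#' @return a `ground_truth` list with the fields above plus
#'   `effect_map`, the per-edge effect magnitudes in canonical edge
#'   order (before condition weighting and homotopic scaling).
#' @export
make_ground_truth <- function(parcellation,
                              n_conditions = 2,
                              decay_length = 50,
                              r0 = 0.5,
                              homotopic_boost = 0.15,
                              effect_size = 0.1,
                              effect_profile = c("flat", "increasing", "decreasing"),
                              homotopic_stability = 0,
                              group_weights = NULL,
                              seed = 1) {
  effect_profile <- match.arg(effect_profile)
  if (decay_length <= 0) stop("decay_length must be positive")
  if (homotopic_stability < 0 || homotopic_stability > 1) {
    stop("homotopic_stability must lie in [0, 1]")
  }
  if (n_conditions < 1) stop("n_conditions must be >= 1")
  validate_parcellation(parcellation)

  n <- nrow(parcellation)
  d <- upper_triangle_vector(distance_matrix(parcellation))
  effect_map <- switch(effect_profile,
    flat = with_seed(seed, stats::rnorm(length(d), 0, effect_size)),
    increasing =  effect_size * as.numeric(scale(d)),
    decreasing = -effect_size * as.numeric(scale(d))
  )
  # centered condition weights; a single condition carries no effect
  w <- if (n_conditions == 1) 0 else {
    seq(-0.5, 0.5, length.out = n_conditions)
  }

  truth <- list(
    n_nodes = n,
    n_conditions = as.integer(n_conditions),
    decay_length = decay_length,
    r0 = r0,
    homotopic_boost = homotopic_boost,
    effect_size = effect_size,
    effect_profile = effect_profile,
    effect_map = effect_map,
    condition_weights = w,
    group_weights = group_weights,
    homotopic_stability = homotopic_stability,
    seed = as.integer(seed)
  )
  class(truth) <- "ground_truth"
  truth
}

# Logical edge vector: TRUE where the edge joins a node and its homotope.
homotopic_edges <- function(parcellation) {
  n <- nrow(parcellation)
  idx <- edge_index(n)
  partner <- match(parcellation$homotope_of, parcellation$node_id)
  !is.na(partner[idx[, "i"]]) & partner[idx[, "i"]] == idx[, "j"]
}

#' Effective per-edge condition effect after homotopic scaling
#'
#' The planted effect map with homotopic edges multiplied by
#' `homotopic_stability`; this is the quantity edge-level analyses are
#' expected to recover (up to the condition contrast weight).
#'
#' @param parcellation,truth as in [make_population_covariance()].
#' @return numeric edge vector in canonical order.
#' @export
effective_effect_map <- function(parcellation, truth) {
  eff <- truth$effect_map
  hom <- homotopic_edges(parcellation)
  eff[hom] <- eff[hom] * truth$homotopic_stability
  eff
}

#' Population correlation matrix for one design cell
#'
#' Builds the baseline `r0 * exp(-d/decay_length)` matrix, adds the
#' homotopic boost, caps entries at 0.95, applies the condition effect
#' in Fisher-z space (`r = tanh(atanh(r) + w * effect)`), and repairs
#' the result to the nearest positive semi-definite correlation matrix
#' by eigenvalue clipping followed by diagonal renormalization.
#'
#' @param parcellation a parcellation.
#' @param truth a [make_ground_truth()] object.
#' @param condition condition index in `1..truth$n_conditions`.
#' @param group group index (only used when `truth$group_weights` is
#'   set; otherwise all groups share the same population).
#' @return symmetric positive semi-definite correlation matrix with
#'   unit diagonal.
#' @export
make_population_covariance <- function(parcellation, truth, condition = 1,
                                       group = 1) {
  validate_parcellation(parcellation)
  n <- nrow(parcellation)
  if (n != truth$n_nodes) stop("truth was built for a different parcellation size")
  if (condition < 1 || condition > truth$n_conditions) {
    stop("condition out of range")
  }
  d <- distance_matrix(parcellation)
  r <- truth$r0 * exp(-d / truth$decay_length)

  hom <- from_edge_vector(as.numeric(homotopic_edges(parcellation)))
  r <- r + truth$homotopic_boost * hom
  r <- pmin(r, 0.95)

  gw <- if (is.null(truth$group_weights)) 1 else truth$group_weights[group]
  w <- gw * truth$condition_weights[condition]
  if (w != 0) {
    eff <- from_edge_vector(effective_effect_map(parcellation, truth))
    z <- atanh(pmax(pmin(r, 0.95), -0.95)) + w * eff
    r <- tanh(z)
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  repair_psd(r)
}

# Nearest-PSD repair: clip negative eigenvalues at zero, then rescale to
# unit diagonal (a congruence, so positive semi-definiteness is kept).
repair_psd <- function(r, tol = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    return(r)
  }
  v <- pmax(e$values, 0)
  a <- e$vectors %*% (v * t(e$vectors))
  dg <- diag(a)
  if (any(dg <= 1e-12)) {
    stop("degenerate parameters: matrix not repairable to a correlation matrix")
  }
  s <- 1 / sqrt(dg)
  a <- a * tcrossprod(s)
  diag(a) <- 1
  (a + t(a)) / 2
}

#' Sample a synthetic multi-subject dataset
#'
#' Each subject x condition time series is `n_timepoints` independent
#' draws from a zero-mean multivariate normal with that cell's
#' population covariance (from [make_population_covariance()]). All
#' groups share the condition set; subjects are nested in groups.
#'
#' @param parcellation a parcellation.
#' @param truth a ground truth object.
#' @param n_subjects_per_group subjects per group (recycled over groups).
#' @param n_timepoints samples per series; at least 30 (estimability).
#' @param n_groups number of groups.
#' @param seed integer seed; one RNG stream drives the whole dataset.
#' @return a `synthetic_dataset`: list with `parcellation`, `design`
#'   (data frame `group`, `subject`, `condition`), `timeseries` (list
#'   keyed `group/subject/condition` of `T x n` matrices), `truth`,
#'   `seed`.
#' @export
sample_dataset <- function(parcellation, truth, n_subjects_per_group = 20,
                           n_timepoints = 200, n_groups = 1, seed = 1) {
  if (n_timepoints < 30) stop("n_timepoints must be >= 30")
  if (any(n_subjects_per_group < 1) || n_groups < 1) {
    stop("counts must be positive")
  }
  n_sub <- rep_len(as.integer(n_subjects_per_group), n_groups)
  n <- nrow(parcellation)

  # eigen square roots of each condition x group population matrix
  roots <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    roots[[g]] <- lapply(seq_len(truth$n_conditions), function(cc) {
      sig <- make_population_covariance(parcellation, truth, cc, g)
      e <- eigen(sig, symmetric = TRUE)
      e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    })
  }

  groups <- sprintf("G%d", seq_len(n_groups))
  conditions <- sprintf("C%d", seq_len(truth$n_conditions))
  ts <- list()
  design <- NULL
  with_seed(seed, {
    for (g in seq_len(n_groups)) {
      ts[[groups[g]]] <- list()
      for (s in seq_len(n_sub[g])) {
        sid <- sprintf("%s_S%02d", groups[g], s)
        ts[[groups[g]]][[sid]] <- list()
        for (cc in seq_len(truth$n_conditions)) {
          zmat <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
          ts[[groups[g]]][[sid]][[conditions[cc]]] <- zmat %*% roots[[g]][[cc]]
          design <- rbind(design, data.frame(
            group = groups[g], subject = sid, condition = conditions[cc],
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  })
  out <- list(
    parcellation = parcellation,
    design = design,
    timeseries = ts,
    truth = truth,
    seed = as.integer(seed)
  )
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic ROI dataset:", nrow(x$parcellation), "nodes,",
      length(x$timeseries), "group(s),",
      x$truth$n_conditions, "condition(s),",
      nrow(x$design), "subject-condition series\n")
  cat("  effect profile:", x$truth$effect_profile,
      "| effect size:", x$truth$effect_size,
      "| homotopic stability:", x$truth$homotopic_stability, "\n")
  invisible(x)
}
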
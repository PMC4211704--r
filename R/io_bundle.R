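# Dataset I/O: the plain-text dataset bundle (nodes.csv, design.csv,
# one matrix file per subject x cell, truth.json) and the MAT-v5
# loader for archives of Fisher-z / correlation matrices stored as
# conditions x participants x regions x regions arrays per group.

#' Write a synthetic dataset as a plain-text bundle
#'
#' Creates a directory with `nodes.csv` (node_id,x,y,z,hemisphere,
#' homotope_of), `design.csv` (group,condition,subject), one CSV matrix
#' per subject x cell (`ts_<subject>_<condition>.csv`) and
#' `truth.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(dataset$parcellation),
                   file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(dataset$design[, c("group", "condition", "subject")],
                   file.path(dir, "design.csv"), row.names = FALSE)
  for (g in names(dataset$timeseries)) {
    for (s in names(dataset$timeseries[[g]])) {
      for (cc in names(dataset$timeseries[[g]][[s]])) {
        utils::write.table(
          dataset$timeseries[[g]][[s]][[cc]],
          file.path(dir, sprintf("ts_%s_%s.csv", s, cc)),
          sep = ",", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  truth <- dataset$truth
  class(truth) <- NULL
  jsonlite::write_json(c(truth, list(dataset_seed = dataset$seed)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a plain-text dataset bundle
#'
#' @param dir directory written by [write_dataset_bundle()].
#' @return a `synthetic_dataset`.
#' @export
read_dataset_bundle <- function(dir) {
  nodes_path <- file.path(dir, "nodes.csv")
  if (!file.exists(nodes_path)) stop("not a dataset bundle (no nodes.csv): ", dir)
  p <- read_node_table(nodes_path)
  design <- utils::read.csv(file.path(dir, "design.csv"),
                            stringsAsFactors = FALSE)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  seed <- tj$dataset_seed
  tj$dataset_seed <- NULL
  truth <- tj
  class(truth) <- "ground_truth"

  ts <- list()
  for (k in seq_len(nrow(design))) {
    g <- design$group[k]; s <- design$subject[k]; cc <- design$condition[k]
    f <- file.path(dir, sprintf("ts_%s_%s.csv", s, cc))
    if (!file.exists(f)) stop("missing time-series file: ", f)
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    ts[[g]][[s]][[cc]] <- m
  }
  out <- list(parcellation = p, design = design, timeseries = ts,
              truth = truth, seed = seed)
  class(out) <- "synthetic_dataset"
  out
}

#' Read a node coordinate table
#'
#' CSV with columns `node_id`, `x`, `y`, `z`, `hemisphere`,
#' `homotope_of` (empty/NA for unpaired nodes).
#'
#' @param path CSV path.
#' @return a `parcellation`.
#' @export
read_node_table <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  p$node_id <- as.character(p$node_id)
  p$homotope_of <- as.character(p$homotope_of)
  p$homotope_of[p$homotope_of %in% c("", "NA")] <- NA_character_
  class(p) <- c("parcellation", "data.frame")
  validate_parcellation(p)
  p
}

#' Load a connectivity dataset from a MAT-v5 archive
#'
#' Expects the archive layout used for shipped connectivity matrices:
#' one cell per experimental group, each a 4-D numeric array ordered
#' conditions x participants x regions x regions (a bare 4-D array is
#' treated as a single group). Matrices are validated for symmetry and
#' finiteness; matrices with a unit diagonal are taken to be Pearson r
#' and passed through [fisher_z()], matrices with a zero diagonal are
#' taken to be Fisher-z already.
#'
#' @param path MAT-v5 file.
#' @param node_table_path CSV of node coordinates ([read_node_table()]);
#'   required, since distances cannot be computed without centroids.
#' @param var variable name inside the MAT file; defaults to the first
#'   variable.
#' @return a `connectivity_dataset`.
#' @export
load_matfile_dataset <- function(path, node_table_path, var = NULL) {
  if (missing(node_table_path) || is.null(node_table_path)) {
    stop("a node coordinate table is required: distances cannot be ",
         "computed without ROI centroids")
  }
  p <- read_node_table(node_table_path)
  n <- nrow(p)
  vars <- read_mat5(path)
  if (length(vars) == 0) stop("no variables in MAT file: ", path)
  v <- if (is.null(var)) vars[[1]] else vars[[var]]
  if (is.null(v)) stop("variable not found in MAT file: ", var)

  groups <- if (is.list(v)) v else list(v)
  names(groups) <- sprintf("G%d", seq_along(groups))
  for (g in names(groups)) {
    arr <- groups[[g]]
    if (!(is.array(arr) && length(dim(arr)) == 4)) {
      stop("group ", g, ": expected a 4-D array ",
           "(conditions x participants x regions x regions)")
    }
    dd <- dim(arr)
    if (dd[3] != n || dd[4] != n) {
      stop("group ", g, ": ", dd[3], "x", dd[4], " matrices do not match ",
           "the ", n, "-row node table")
    }
    if (!all(is.finite(arr))) stop("group ", g, ": non-finite entries")
    # convert r-matrices (unit diagonal) to z; validate z (zero diagonal)
    for (cc in seq_len(dd[1])) {
      for (s in seq_len(dd[2])) {
        m <- arr[cc, s, , ]
        if (max(abs(m - t(m))) > 1e-6) {
          stop("group ", g, ", condition ", cc, ", participant ", s,
               ": asymmetric matrix")
        }
        dg <- diag(m)
        if (max(abs(dg - 1)) < 1e-6) {
          m <- fisher_z(m)
        } else if (max(abs(dg)) < 1e-6) {
          diag(m) <- 0
        } else {
          stop("group ", g, ": diagonal is neither 0 (z) nor 1 (r)")
        }
        arr[cc, s, , ] <- (m + t(m)) / 2
      }
    }
    dimnames(arr) <- list(sprintf("C%d", seq_len(dd[1])),
                          sprintf("S%02d", seq_len(dd[2])), NULL, NULL)
    groups[[g]] <- arr
  }
  connectivity_dataset(groups, parcellation = p)
}

#' Export a connectivity dataset to MAT-v5
#'
#' Writes the group arrays as a cell array of 4-D matrices (the same
#' layout [load_matfile_dataset()] reads); used mainly for round-trip
#' validation.
#'
#' @param ds a `connectivity_dataset`.
#' @param path output MAT path.
#' @return `path`, invisibly.
#' @export
write_matfile_dataset <- function(ds, path) {
  cellv <- lapply(ds$groups, function(a) { dimnames(a) <- NULL; a })
  names(cellv) <- NULL
  write_mat5(list(connectivity = cellv), path)
}
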
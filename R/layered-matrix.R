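#' Layered single-cell expression container
#'
#' A `LayeredMatrix` holds one or more cells x genes count matrices
#' ("layers") that share cell and gene axes, together with per-cell
#' metabolic-labeling metadata. Recognised layer names are `u` (unspliced),
#' `s` (spliced), `l` (labeled/new) and `r` (total); `o` (old) is always
#' derived as `o = r - l` and never stored. All matrices are oriented cells x
#' genes throughout the package.
#'
#' @param layers named list of non-negative numeric matrices (dense or
#'   `Matrix` sparse), all cells x genes with identical dimensions. Names
#'   must be drawn from `c("u", "s", "l", "r")`.
#' @param cell_ids,gene_ids character vectors naming the rows/columns.
#' @param label_time per-cell labeling duration in hours, or `NULL` for
#'   conventional (unlabeled) experiments.
#' @param experiment_type one of `"conventional"`, `"one_shot"`,
#'   `"kinetics"`, `"degradation"`.
#' @param group optional per-cell categorical label (cluster / cell type).
#' @return an object of class `LayeredMatrix`.
#' @export
layered_matrix <- function(layers, cell_ids = NULL, gene_ids = NULL,
                           label_time = NULL,
                           experiment_type = c("conventional", "one_shot",
                                               "kinetics", "degradation"),
                           group = NULL) {
  experiment_type <- match.arg(experiment_type)
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)))
    stop("`layers` must be a non-empty named list of matrices")
  known <- c("u", "s", "l", "r")
  bad <- setdiff(names(layers), known)
  if (length(bad))
    stop("unknown layer name(s): ", paste(bad, collapse = ", "),
         " (schema allows u, s, l, r)")
  layers <- lapply(layers, as_dense_matrix)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same cells x genes dimensions")
  n_cells <- dims[1, 1]
  n_genes <- dims[2, 1]
  for (nm in names(layers)) {
    if (any(layers[[nm]] < 0))
      stop("layer '", nm, "' contains negative entries")
  }
  if (all(c("l", "r") %in% names(layers)) &&
      any(layers$r - layers$l < -1e-8))
    stop("total layer 'r' must be >= labeled layer 'l' elementwise")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n_cells))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(n_genes))
  stopifnot(length(cell_ids) == n_cells, length(gene_ids) == n_genes)
  for (nm in names(layers)) dimnames(layers[[nm]]) <- list(cell_ids, gene_ids)
  if (!is.null(label_time)) {
    if (length(label_time) == 1L) label_time <- rep(label_time, n_cells)
    stopifnot(length(label_time) == n_cells, all(label_time >= 0))
  }
  if (experiment_type == "one_shot") {
    if (is.null(label_time) || length(unique(label_time)) != 1L)
      stop("one_shot experiments need a single labeling time shared by all cells")
  }
  if (experiment_type %in% c("kinetics", "degradation")) {
    if (is.null(label_time) || length(unique(label_time)) < 2L)
      stop(experiment_type, " experiments need >= 2 distinct label times")
  }
  if (!is.null(group)) {
    if (length(group) == 1L) group <- rep(group, n_cells)
    stopifnot(length(group) == n_cells)
    group <- as.factor(group)
  }
  structure(
    list(layers = layers, cell_ids = cell_ids, gene_ids = gene_ids,
         label_time = label_time, experiment_type = experiment_type,
         group = group, size_factors = NULL),
    class = "LayeredMatrix")
}

as_dense_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' @exportS3Method print LayeredMatrix
print.LayeredMatrix <- function(x, ...) {
  cat(sprintf("LayeredMatrix: %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  experiment:", x$experiment_type, "\n")
  if (!is.null(x$label_time))
    cat("  label times (h):",
        paste(sort(unique(x$label_time)), collapse = ", "), "\n")
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method dim LayeredMatrix
dim.LayeredMatrix <- function(x) {
  c(length(x$cell_ids), length(x$gene_ids))
}

#' Extract a layer as a dense matrix
#' @param lm a [layered_matrix()].
#' @param layer layer name; `"o"` returns `o = r - l`.
#' @export
get_layer <- function(lm, layer) {
  stopifnot(inherits(lm, "LayeredMatrix"))
  if (layer == "o") {
    if (!all(c("l", "r") %in% names(lm$layers)))
      stop("old RNA 'o' needs both 'l' and 'r' layers")
    return(lm$layers$r - lm$layers$l)
  }
  if (!layer %in% names(lm$layers)) stop("layer '", layer, "' not present")
  lm$layers[[layer]]
}

#' Read layered matrices plus cell metadata from disk
#'
#' Each layer is either a MatrixMarket `.mtx` file (coordinate format,
#' 1-based per the standard, oriented cells x genes) or a dense `.csv`
#' with header-free numeric values. Cell and gene identifier files are
#' one-id-per-line text. The metadata table (CSV with header) is keyed by a
#' `cell_id` column and may carry `label_time`, `experiment_type` and
#' `group` columns. Layers whose cell order differs from `cells_path` are
#' realigned by identifier.
#'
#' @param matrix_paths named character vector/list mapping layer name to file.
#' @param cells_path,genes_path id files (one per line). For per-layer
#'   permuted fixtures, `matrix_paths` entries may instead be a list with
#'   elements `path` and `cells` (an id file giving that layer's row order).
#' @param meta_path optional metadata CSV.
#' @return a [layered_matrix()].
#' @export
read_layers <- function(matrix_paths, cells_path, genes_path,
                        meta_path = NULL) {
  cell_ids <- readLines(cells_path)
  gene_ids <- readLines(genes_path)
  layers <- list()
  for (nm in names(matrix_paths)) {
    entry <- matrix_paths[[nm]]
    if (is.list(entry)) {
      m <- read_one_matrix(entry$path)
      row_ids <- readLines(entry$cells)
      if (nrow(m) != length(row_ids))
        stop("layer '", nm, "': rows do not match its id file")
      idx <- match(cell_ids, row_ids)
      if (anyNA(idx))
        stop("layer '", nm, "': cell ids do not cover the master id list")
      m <- m[idx, , drop = FALSE]
    } else {
      m <- read_one_matrix(entry)
    }
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids))
      stop("layer '", nm, "': dimensions ", nrow(m), "x", ncol(m),
           " do not match ids (", length(cell_ids), "x", length(gene_ids), ")")
    layers[[nm]] <- m
  }
  label_time <- NULL; experiment_type <- "conventional"; group <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(meta)) stop("meta table needs a cell_id column")
    idx <- match(cell_ids, meta$cell_id)
    if (anyNA(idx)) stop("meta table does not cover all cells")
    meta <- meta[idx, , drop = FALSE]
    if ("label_time" %in% names(meta)) label_time <- meta$label_time
    if ("experiment_type" %in% names(meta))
      experiment_type <- meta$experiment_type[1]
    if ("group" %in% names(meta)) group <- meta$group
  }
  layered_matrix(layers, cell_ids, gene_ids, label_time = label_time,
                 experiment_type = experiment_type, group = group)
}

read_one_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    as_dense_matrix(Matrix::readMM(path))
  } else {
    as_dense_matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Write a LayeredMatrix to disk (MTX layers + id files + metadata CSV)
#'
#' @param lm a [layered_matrix()].
#' @param dir output directory (created if missing).
#' @param format `"mtx"` (sparse MatrixMarket) or `"csv"` (dense).
#' @return invisibly, the list of file paths written.
#' @export
write_layers <- function(lm, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(lm, "LayeredMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(lm$layers)) {
    if (format == "mtx") {
      p <- file.path(dir, paste0(nm, ".mtx"))
      Matrix::writeMM(methods::as(Matrix::Matrix(lm$layers[[nm]],
                                                 sparse = TRUE),
                                  "generalMatrix"), p)
    } else {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.table(lm$layers[[nm]], p, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    }
    paths[[nm]] <- p
  }
  writeLines(lm$cell_ids, file.path(dir, "cells.txt"))
  writeLines(lm$gene_ids, file.path(dir, "genes.txt"))
  meta <- data.frame(cell_id = lm$cell_ids,
                     experiment_type = lm$experiment_type)
  if (!is.null(lm$label_time)) meta$label_time <- lm$label_time
  if (!is.null(lm$group)) meta$group <- as.character(lm$group)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  paths$cells <- file.path(dir, "cells.txt")
  paths$genes <- file.path(dir, "genes.txt")
  paths$meta <- file.path(dir, "meta.csv")
  invisible(paths)
}

#' Size-factor normalization and log1p transform
#'
#' Total counts per cell are computed from the total layer `r` when present,
#' else from `s + u`, else from the single available layer; every layer is
#' scaled by the same per-cell factor `target_total / total` (so the count
#' composition within a cell is preserved) and then `log1p`-transformed.
#' Cells with zero total are dropped with a warning.
#'
#' @param lm a [layered_matrix()].
#' @param target_total target molecule count per cell (default 1e4).
#' @param log whether to apply `log1p` after scaling.
#' @return a normalized `LayeredMatrix` with `size_factors` filled in.
#' @export
normalize_and_log <- function(lm, target_total = 1e4, log = TRUE) {
  stopifnot(inherits(lm, "LayeredMatrix"))
  nms <- names(lm$layers)
  totals <- if ("r" %in% nms) {
    rowSums(lm$layers$r)
  } else if (all(c("s", "u") %in% nms)) {
    rowSums(lm$layers$s) + rowSums(lm$layers$u)
  } else {
    rowSums(lm$layers[[1]])
  }
  keep <- totals > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero total counts excluded")
    lm$layers <- lapply(lm$layers, function(m) m[keep, , drop = FALSE])
    lm$cell_ids <- lm$cell_ids[keep]
    if (!is.null(lm$label_time)) lm$label_time <- lm$label_time[keep]
    if (!is.null(lm$group)) lm$group <- droplevels(lm$group[keep])
    totals <- totals[keep]
  }
  factors <- target_total / totals
  lm$layers <- lapply(lm$layers, function(m) {
    m <- m * factors
    if (log) m <- log1p(m)
    m
  })
  lm$size_factors <- factors
  lm$normalized <- TRUE
  lm
}
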
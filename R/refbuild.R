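# Reference construction: pseudo-bulk profiles from clustered single-cell
# data (mean over member cells) and median merging of bulk replicates.

#' Build pseudo-bulk cell-type profiles from clustered single cells
#'
#' For each cluster, the expression values of all member cells are
#' mean-averaged gene by gene to form one reference column. No library-size
#' normalization is applied before averaging by default; set
#' `normalize_cells` to scale each cell to a fixed total count first.
#'
#' @param cells genes x cells expression matrix.
#' @param clusters cluster label per cell: named character vector or a
#'   2-column data frame (cell_id, cluster). Every cell used must have
#'   exactly one label.
#' @param normalize_cells if `TRUE`, rescale each cell's column to
#'   `target_total` before averaging.
#' @param target_total per-cell total used when `normalize_cells` is `TRUE`.
#' @return expression matrix with one column per cluster, gene order
#'   preserved.
#' @export
pseudobulk_from_clusters <- function(cells, clusters, normalize_cells = FALSE,
                                     target_total = 1e4) {
  validate_expression_matrix(cells, "single-cell matrix")
  if (is.matrix(clusters)) clusters <- as.data.frame(clusters)
  if (is.data.frame(clusters)) {
    if (ncol(clusters) < 2L) stop("cluster table needs 2 columns", call. = FALSE)
    clusters <- stats::setNames(as.character(clusters[[2L]]),
                                as.character(clusters[[1L]]))
  }
  if (is.null(names(clusters))) {
    if (length(clusters) != ncol(cells)) {
      stop("unnamed cluster vector must have one label per cell", call. = FALSE)
    }
    names(clusters) <- colnames(cells)
  }
  missing <- setdiff(colnames(cells), names(clusters))
  if (length(missing)) {
    stop("cells without a cluster label: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lab <- clusters[colnames(cells)]
  if (anyNA(lab)) stop("NA cluster labels", call. = FALSE)
  empty <- setdiff(unique(clusters), lab)
  if (length(empty)) {
    stop("cluster(s) with no cells in the matrix: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (normalize_cells) {
    totals <- colSums(cells)
    if (any(totals == 0)) stop("cell with zero total counts", call. = FALSE)
    cells <- sweep(cells, 2L, totals / target_total, "/")
  }
  groups <- sort(unique(lab))
  out <- vapply(groups,
                function(g) rowMeans(cells[, lab == g, drop = FALSE]),
                numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells),
                dimnames = list(rownames(cells), groups))
  validate_expression_matrix(out, "pseudo-bulk matrix")
  out
}

#' Merge replicate profiles by the per-gene median
#'
#' Columns sharing a group label (replicates of the same cell type) are
#' collapsed into a single column holding the median value of each gene.
#' Even-sized groups use the midpoint of the two central values.
#'
#' @param profiles genes x columns expression matrix.
#' @param groups group label per column (character vector, recycled names
#'   not allowed; length must equal `ncol(profiles)`).
#' @return expression matrix with one column per group.
#' @export
merge_replicates <- function(profiles, groups) {
  validate_expression_matrix(profiles, "profile matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(profiles)) {
    stop("one group label per column required", call. = FALSE)
  }
  out_groups <- unique(groups)
  out <- vapply(out_groups, function(g) {
    sub <- profiles[, groups == g, drop = FALSE]
    apply(sub, 1L, stats::median)
  }, numeric(nrow(profiles)))
  out <- matrix(out, nrow = nrow(profiles),
                dimnames = list(rownames(profiles), out_groups))
  validate_expression_matrix(out, "merged matrix")
  out
}

#' Read a clustered single-cell table from TSV files
#'
#' Accepts a dense cell x gene TSV (cells in rows, genes in columns, in the
#' package's usual dialect with cells as the row identifiers) plus a
#' two-column cluster-assignment TSV (`cell_id`, `cluster`), and returns the
#' genes x cells matrix and label vector expected by
#' [pseudobulk_from_clusters()].
#'
#' @param expr_path path to the cell x gene expression TSV.
#' @param cluster_path path to the cluster-assignment TSV (with header).
#' @return list with `cells` (genes x cells matrix) and `clusters` (named
#'   character vector).
#' @export
read_clustered_cells <- function(expr_path, cluster_path) {
  cells_by_gene <- read_expression_table(expr_path, collapse = "error")
  cells <- t(cells_by_gene)
  assign <- utils::read.delim(cluster_path, header = TRUE,
                              stringsAsFactors = FALSE)
  if (ncol(assign) < 2L) stop("cluster table needs 2 columns", call. = FALSE)
  clusters <- stats::setNames(as.character(assign[[2L]]),
                              trimws(as.character(assign[[1L]])))
  list(cells = cells, clusters = clusters)
}
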
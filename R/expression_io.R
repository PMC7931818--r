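# Expression matrices are plain numeric matrices: rows = genes (rownames),
# columns = cell types or samples (colnames). A "fraction table" is a numeric
# matrix with rows = samples and columns = cell types, each row summing to 1.

#' Validate an expression matrix
#'
#' Checks the invariants every expression matrix in this package must satisfy:
#' a numeric matrix with unique, non-empty gene rownames and column names, and
#' all values finite and non-negative.
#'
#' @param m numeric matrix, genes in rows, samples or cell types in columns.
#' @param what label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop(what, " must have at least one gene row and one column", call. = FALSE)
  }
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == "")) {
    stop(what, " must have non-empty gene rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(what, " has duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop(what, " must have unique column labels", call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  if (any(m < 0)) {
    stop(what, " contains negative expression values", call. = FALSE)
  }
  invisible(m)
}

#' Read a tab-separated expression table
#'
#' Parses the fixed dialect used throughout the package: UTF-8,
#' tab-separated, a header line holding one label per data column (no label
#' over the gene column), then one line per gene whose first field is the
#' gene symbol and remaining fields are non-negative expression values.
#' Gene symbols are whitespace-stripped and matched case-sensitively.
#'
#' Duplicate gene symbols are resolved by `collapse`:
#' \describe{
#'   \item{max_mean}{keep the duplicate row with the highest row mean
#'     (appropriate for transcript-level tables where one transcript
#'     dominates).}
#'   \item{sum}{add duplicate rows (appropriate for count-like data where
#'     a gene's transcripts should pool).}
#'   \item{error}{abort on any duplicate.}
#' }
#'
#' @param path path to the file.
#' @param collapse duplicate-gene policy, one of `"max_mean"`, `"sum"`,
#'   `"error"`. Default `"max_mean"`.
#' @param label free-text provenance tag attached as the `"label"` attribute.
#' @return a validated expression matrix (genes x columns).
#' @export
read_expression_table <- function(path, collapse = c("max_mean", "sum", "error"),
                                  label = basename(path)) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression table needs a header and at least one gene row: ", path,
         call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  # tolerate a stray label over the gene column if the data rows disagree
  ncols <- length(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]) - 1L
  if (length(header) == ncols + 1L) header <- header[-1L]
  if (length(header) != ncols) {
    stop("header has ", length(header), " labels but data rows have ",
         ncols, " value columns", call. = FALSE)
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != ncols + 1L)
  if (length(bad)) {
    stop("line ", bad[1L] + 1L, " has ", nfield[bad[1L]],
         " fields, expected ", ncols + 1L, call. = FALSE)
  }
  genes <- trimws(vapply(body, `[[`, "", 1L))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncols))
  )
  vals <- if (ncols == 1L) matrix(vals, nrow = 1L) else vals
  if (anyNA(vals)) {
    bad_line <- which(colSums(is.na(vals)) > 0)[1L]
    stop("malformed number on line ", bad_line + 1L, " of ", path,
         call. = FALSE)
  }
  m <- t(vals)
  dimnames(m) <- list(genes, header)
  if (any(m < 0)) {
    stop("negative expression value in ", path, call. = FALSE)
  }
  m <- collapse_duplicate_genes(m, collapse)
  attr(m, "label") <- label
  validate_expression_matrix(m)
  m
}

# Resolve duplicate gene rows; order-independent for all strategies.
collapse_duplicate_genes <- function(m, collapse) {
  genes <- rownames(m)
  if (!anyDuplicated(genes)) return(m)
  if (collapse == "error") {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  keep_order <- unique(genes)
  if (collapse == "sum") {
    out <- rowsum(m, group = genes, reorder = FALSE)
    out <- out[keep_order, , drop = FALSE]
  } else { # max_mean
    means <- rowMeans(m)
    # within each symbol keep the row with the highest mean; ties go to the
    # first occurrence in gene-sorted row order so input order cannot matter
    ord <- order(genes, -means)
    first <- !duplicated(genes[ord])
    out <- m[ord[first], , drop = FALSE]
    out <- out[keep_order, , drop = FALSE]
  }
  out
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: writes the matrix in the package's
#' tab-separated dialect with at least 10 significant digits, so a
#' write-then-read round trip reproduces the matrix to numeric tolerance.
#'
#' @param m validated expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  validate_expression_matrix(m)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- apply(m, 1L, function(x)
    paste(sprintf("%.10g", x), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Validate a fraction table
#'
#' @param f numeric matrix, samples in rows, cell types in columns.
#' @param tol tolerance on each row sum's deviation from 1.
#' @return `f`, invisibly, if valid.
#' @export
validate_fraction_table <- function(f, tol = 1e-9) {
  if (!is.matrix(f) || !is.numeric(f)) {
    stop("fraction table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(f)) || is.null(colnames(f))) {
    stop("fraction table must have sample rownames and cell-type colnames",
         call. = FALSE)
  }
  if (anyNA(f) || any(f < -tol) || any(f > 1 + tol)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  dev <- abs(rowSums(f) - 1)
  if (any(dev > tol)) {
    stop("fraction rows must sum to 1 (max deviation ",
         format(max(dev)), ")", call. = FALSE)
  }
  invisible(f)
}

#' Write a fraction table
#'
#' Header of cell-type labels, then one row per sample. Refuses tables whose
#' rows do not sum to 1.
#'
#' @inheritParams validate_fraction_table
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(f, path, tol = 1e-9) {
  validate_fraction_table(f, tol = tol)
  write_expression_table_raw(f, path)
}

# shared writer that skips expression-specific validation
write_expression_table_raw <- function(m, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- apply(m, 1L, function(x)
    paste(sprintf("%.10g", x), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a fraction table
#'
#' @param path path to a fraction TSV written by [write_fraction_table()].
#' @param tol row-sum tolerance.
#' @return samples x cell types fraction matrix.
#' @export
read_fraction_table <- function(path, tol = 1e-9) {
  m <- read_expression_table(path, collapse = "error")
  attr(m, "label") <- NULL
  validate_fraction_table(m, tol = tol)
  m
}
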
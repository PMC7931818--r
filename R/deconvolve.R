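# Core estimation: row scaling of signature-gene rows, per-sample
# non-negative least squares, fraction normalization, subtype aggregation and
# multi-reference combination.

#' Row scaling of signature-gene rows
#'
#' Each gene's values across the combined reference and mixture columns are
#' rescaled as `X_new = (X_old - Min) / (Max - Min) * Max^p`, where `Min` and
#' `Max` are taken per gene over the columns of BOTH matrices jointly (so a
#' sample's transform depends on the whole submitted batch). With `p = 0`
#' every gene row spans exactly \[0, 1\], equalizing the influence of genes
#' with very different expression magnitudes on the regression; with `p = 1`
#' and `Min = 0` the transform is the identity.
#'
#' Constant rows (`Max = Min`) cannot be rescaled; they are mapped to
#' all-zeros with a warning, preserving gene alignment (a constant row
#' contributes nothing to the fit either way).
#'
#' @param ref,mix gene-aligned expression matrices (signature genes only).
#' @param p scaling exponent in \[0, 1\].
#' @return list with scaled `ref`, `mix`, and `params`, a data frame of the
#'   per-gene `min_val`, `max_val` and whether the row was `constant`.
#' @export
row_scale <- function(ref, mix, p = 0) {
  stopifnot(identical(rownames(ref), rownames(mix)))
  if (p < 0 || p > 1) stop("row-scale exponent p must be in [0, 1]", call. = FALSE)
  combined <- cbind(ref, mix)
  mins <- apply(combined, 1L, min)
  maxs <- apply(combined, 1L, max)
  constant <- maxs == mins
  if (any(constant)) {
    warning(sum(constant), " constant gene row(s) mapped to zero: ",
            paste(utils::head(rownames(ref)[constant], 5L), collapse = ", "),
            call. = FALSE)
  }
  span <- ifelse(constant, 1, maxs - mins)
  scale_fac <- ifelse(constant, 0, maxs^p / span)
  scale_mat <- function(m) (m - mins) * scale_fac
  list(ref = scale_mat(ref), mix = scale_mat(mix),
       params = data.frame(gene = rownames(ref), min_val = mins,
                           max_val = maxs, constant = constant,
                           row.names = NULL))
}

#' Non-negative least squares fit of one mixture against the reference
#'
#' Solves `argmin_x ||A x - b||^2` subject to `x >= 0`, with no intercept and
#' no regularization, via the Lawson-Hanson active-set algorithm. This is the
#' exact solution of the constrained regression (equivalently, glmnet with
#' `lower.limits = 0`, `alpha = 0`, `lambda = 0`, `intercept = FALSE`).
#'
#' @param A genes x cell types matrix (row-scaled reference).
#' @param b numeric vector, one mixture column in the same gene order.
#' @return list with `coefficients` (named, >= 0), `rss`, and
#'   `rank_deficient` (TRUE when A has numerically deficient column rank, in
#'   which case the minimizer may be non-unique).
#' @export
nnls_fit <- function(A, b) {
  if (!is.matrix(A) || nrow(A) < 1L) stop("A must have at least 1 gene row", call. = FALSE)
  if (length(b) != nrow(A)) stop("b must match the gene rows of A", call. = FALSE)
  if (all(b == 0)) {
    x <- rep(0, ncol(A))
  } else {
    x <- pracma::lsqnonneg(A, b)$x
  }
  names(x) <- colnames(A)
  resid <- b - A %*% x
  rank_def <- qr(A)$rank < ncol(A)
  list(coefficients = x, rss = sum(resid^2), rank_deficient = rank_def)
}

#' Normalize non-negative coefficients to fractions summing to one
#'
#' @param x non-negative coefficient vector.
#' @return fractions `x / sum(x)`; when all coefficients are zero the sample
#'   is degenerate and uniform fractions `1/K` are returned with attribute
#'   `degenerate = TRUE`.
#' @export
normalize_fractions <- function(x) {
  if (any(x < 0)) stop("coefficients must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s > 0) {
    out <- x / s
    attr(out, "degenerate") <- FALSE
  } else {
    out <- rep(1 / length(x), length(x))
    names(out) <- names(x)
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Deconvolve bulk mixtures against a reference of purified cell types
#'
#' Runs the full pipeline: gene intersection, removal of never-expressed
#' reference genes, quantile normalization of both matrices to the
#' reference's starting distribution, signature-gene selection on the
#' normalized reference (majority-zero filter, zero imputation, specificity
#' scoring, NumSigs/MinSigs selection), restriction of both matrices to the
#' signature genes, row scaling, then one non-negative least-squares fit per
#' mixture column, normalized to fractions.
#'
#' The returned fractions are mRNA fractions (the share of transcripts each
#' cell type contributes), not cell-count proportions.
#'
#' @param ref reference matrix, genes x cell types.
#' @param mix mixture matrix, genes x samples.
#' @param config a [deconv_config()].
#' @return fraction table: samples x cell types matrix whose rows sum to 1,
#'   with attributes `stage_log` (gene counts surviving each stage),
#'   `signatures` (the `signature_set` used), `rss` (per-sample residual sum
#'   of squares) and `degenerate` (per-sample all-zero-fit flag).
#' @export
deconvolve <- function(ref, mix, config = deconv_config()) {
  stopifnot(inherits(config, "deconv_config"))
  pp <- preprocess_pair(ref, mix)
  if (length(pp$target) < 20L) {
    warning("only ", length(pp$target),
            " genes shared between reference and mixture; ",
            "estimates may be unstable", call. = FALSE)
  }
  ref_f <- filter_majority_zero_genes(pp$ref)
  ref_i <- impute_zero_expression(ref_f)
  scores <- score_genes(ref_i, config$sig_method)
  sigs <- select_signatures(scores, colnames(ref_i),
                            config$num_sigs, config$min_sigs)
  if (length(sigs$all_genes) == 0L) stop("empty signature set", call. = FALSE)
  ref_sig <- pp$ref[sigs$all_genes, , drop = FALSE]
  mix_sig <- pp$mix[sigs$all_genes, , drop = FALSE]
  rs <- suppressWarnings(row_scale(ref_sig, mix_sig, config$row_scale_p))

  K <- ncol(ref)
  fractions <- matrix(0, nrow = ncol(mix), ncol = K,
                      dimnames = list(colnames(mix), colnames(ref)))
  rss <- numeric(ncol(mix))
  degenerate <- logical(ncol(mix))
  for (j in seq_len(ncol(mix))) {
    fit <- nnls_fit(rs$ref, rs$mix[, j])
    fr <- normalize_fractions(fit$coefficients)
    degenerate[j] <- attr(fr, "degenerate")
    fractions[j, ] <- fr
    rss[j] <- fit$rss
  }
  stage_log <- c(pp$n_genes,
                 filtered = nrow(ref_f),
                 signature = length(sigs$all_genes))
  structure(fractions, stage_log = stage_log, signatures = sigs,
            rss = stats::setNames(rss, colnames(mix)),
            degenerate = stats::setNames(degenerate, colnames(mix)))
}

#' Aggregate fine-grained subtype fractions into parent cell types
#'
#' The predicted fractions of all subtypes mapping to one parent (for
#' example naive and memory B cells into B cells) are summed; labels absent
#' from the map pass through unchanged. Row sums are preserved.
#'
#' @param f fraction table (samples x cell types).
#' @param map data frame (or 2-column matrix) with columns `fine` and
#'   `parent`; every fine label maps to exactly one parent.
#' @return aggregated fraction table.
#' @export
aggregate_subtypes <- function(f, map) {
  map <- as.data.frame(map)
  if (!all(c("fine", "parent") %in% names(map))) {
    names(map)[1:2] <- c("fine", "parent")
  }
  if (anyDuplicated(map$fine)) {
    stop("each fine cell type must map to exactly one parent", call. = FALSE)
  }
  idx <- match(colnames(f), map$fine)
  parent <- ifelse(is.na(idx), colnames(f), map$parent[idx])
  out <- t(rowsum(t(f), group = parent, reorder = FALSE))
  rownames(out) <- rownames(f)
  out
}

#' Combine fraction predictions from several references by the median
#'
#' For each sample and cell type, takes the median across the tables that
#' contain that cell type (fewer tables when a cell type is missing from
#' some references), then renormalizes each sample's vector to sum to one.
#'
#' @param tables list of >= 2 fraction tables over the same samples;
#'   cell-type sets may differ.
#' @return combined fraction table over the union of cell types.
#' @export
combine_reference_predictions <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  samples <- Reduce(intersect, lapply(tables, rownames))
  if (length(samples) == 0L) {
    stop("fraction tables share no samples", call. = FALSE)
  }
  types <- unique(unlist(lapply(tables, colnames)))
  out <- matrix(NA_real_, length(samples), length(types),
                dimnames = list(samples, types))
  for (ct in types) {
    have <- Filter(function(t) ct %in% colnames(t), tables)
    vals <- vapply(have, function(t) t[samples, ct], numeric(length(samples)))
    vals <- matrix(vals, nrow = length(samples))
    out[, ct] <- apply(vals, 1L, stats::median)
  }
  sw <- rowSums(out)
  out <- out / sw
  out[sw == 0, ] <- 1 / length(types)
  out
}

#' Heatmap of a fraction table
#'
#' Thin wrapper around `pheatmap` (rows = samples, columns = cell types,
#' values in \[0, 1\], no scaling or clustering of fractions by default).
#'
#' @param f fraction table.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_fraction_heatmap <- function(f, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_fraction_heatmap requires the pheatmap package", call. = FALSE)
  }
  pheatmap::pheatmap(f, cluster_cols = FALSE, ...)
}
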
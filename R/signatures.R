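# Signature-gene selection: score every reference gene for cell-type
# specificity, then pick a budget of num_sigs * K genes, guaranteeing each
# cell type at least min_sigs of its own best markers.

#' Deconvolution configuration
#'
#' Bundles the four tunable parameters of the pipeline plus the seed.
#'
#' @param sig_method scoring method for signature-gene selection. `"Entropy"`
#'   (default) ranks genes by Shannon entropy of their expression distribution
#'   across cell types (lower = more specific). The alternatives are
#'   conventional specificity scores where higher = more specific:
#'   `"MeanRat"` (max / mean of the other cell types), `"MeanDiff"`
#'   (max - mean of others), `"ZScore"` ((max - mean) / sd over all types),
#'   `"fsRat"` (highest / second highest), `"fsDiff"` (highest - second
#'   highest).
#' @param num_sigs mean number of signature genes per cell type, in
#'   \[1, 10000\]. Default 50.
#' @param min_sigs minimum number of signature genes guaranteed to each cell
#'   type, in \[1, num_sigs\]. Defaults to `num_sigs`, in which case selection
#'   is exactly per-type top-`num_sigs` and no global fill occurs.
#' @param row_scale_p row-scaling exponent in \[0, 1\]: 0 (default) maps every
#'   signature-gene row to \[0, 1\]; 1 preserves each row's magnitude.
#' @param seed integer seed recorded for reproducibility of any stochastic
#'   step (the core pipeline itself is deterministic).
#' @return an object of class `deconv_config`.
#' @export
deconv_config <- function(sig_method = "Entropy", num_sigs = 50L,
                          min_sigs = num_sigs, row_scale_p = 0,
                          seed = 1L) {
  methods <- c("Entropy", "MeanRat", "MeanDiff", "ZScore", "fsRat", "fsDiff")
  sig_method <- match.arg(sig_method, methods)
  num_sigs <- as.integer(num_sigs)
  min_sigs <- as.integer(min_sigs)
  if (is.na(num_sigs) || num_sigs < 1L || num_sigs > 10000L) {
    stop("num_sigs must be in [1, 10000]", call. = FALSE)
  }
  if (is.na(min_sigs) || min_sigs < 1L || min_sigs > num_sigs) {
    stop("min_sigs must be in [1, num_sigs]", call. = FALSE)
  }
  if (!is.numeric(row_scale_p) || row_scale_p < 0 || row_scale_p > 1) {
    stop("row_scale_p must be in [0, 1]", call. = FALSE)
  }
  structure(list(sig_method = sig_method, num_sigs = num_sigs,
                 min_sigs = min_sigs, row_scale_p = row_scale_p,
                 seed = as.integer(seed)),
            class = "deconv_config")
}

#' @export
print.deconv_config <- function(x, ...) {
  cat("deconvolution config: sig_method=", x$sig_method,
      ", num_sigs=", x$num_sigs, ", min_sigs=", x$min_sigs,
      ", row_scale_p=", x$row_scale_p, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Remove genes with zero expression in half or more of the cell types
#'
#' Zeros in purified profiles usually reflect detection limits rather than
#' true absence; genes zero in at least half the cell types make unstable
#' signatures and are excluded before scoring. The boundary is inclusive:
#' with K cell types, a gene with zero in >= K/2 columns is removed.
#'
#' @param ref reference expression matrix with K >= 2 cell types.
#' @return the filtered reference matrix (possibly with fewer genes).
#' @export
filter_majority_zero_genes <- function(ref) {
  validate_expression_matrix(ref, "reference")
  if (ncol(ref) < 2L) stop("need at least 2 cell types", call. = FALSE)
  n_zero <- rowSums(ref == 0)
  ref[n_zero < ncol(ref) / 2, , drop = FALSE]
}

#' Replace remaining zeros by the smallest observed nonzero value
#'
#' After the majority-zero filter, any residual zero is treated as expression
#' below the detection limit and imputed with the global minimum nonzero
#' value of the matrix, so entropy and ratio scores stay finite.
#'
#' @param ref reference expression matrix with at least one nonzero value.
#' @return matrix with every zero replaced; nonzero values untouched.
#' @export
impute_zero_expression <- function(ref) {
  nz <- ref[ref > 0]
  if (length(nz) == 0L) {
    stop("cannot impute: matrix is all zeros", call. = FALSE)
  }
  floor_val <- min(nz)
  ref[ref == 0] <- floor_val
  ref
}

#' Shannon entropy of an expression vector across cell types
#'
#' The vector is converted to probabilities `p_i = x_i / sum(x)`; the
#' `i`-th probability is the fraction of transcripts a hypothetical equal
#' mixture of the cell types would draw from type `i`. The score is
#' `H = -sum(p_i * log2(p_i))` in bits: 0 when all mass sits on one type,
#' `log2(K)` when expression is uniform. Low entropy marks a cell-type
#' specific gene.
#'
#' @param x strictly positive expression vector over K >= 2 cell types.
#' @return entropy in bits.
#' @export
entropy_score <- function(x) {
  if (length(x) < 2L) stop("entropy needs at least 2 cell types", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("entropy_score requires strictly positive values (impute zeros first)",
         call. = FALSE)
  }
  p <- x / sum(x)
  -sum(p * log2(p))
}

# Vectorized per-row scores; ref must be filtered + imputed (all > 0).
score_matrix <- function(ref, method) {
  K <- ncol(ref)
  switch(method,
    Entropy = {
      p <- ref / rowSums(ref)
      -rowSums(p * log2(p))
    },
    MeanRat = {
      mx <- apply(ref, 1L, max)
      others <- (rowSums(ref) - mx) / (K - 1L)
      mx / others
    },
    MeanDiff = {
      mx <- apply(ref, 1L, max)
      mx - (rowSums(ref) - mx) / (K - 1L)
    },
    ZScore = {
      mx <- apply(ref, 1L, max)
      (mx - rowMeans(ref)) / apply(ref, 1L, stats::sd)
    },
    fsRat = {
      srt <- apply(ref, 1L, function(x) sort(x, decreasing = TRUE)[1:2])
      srt[1L, ] / srt[2L, ]
    },
    fsDiff = {
      srt <- apply(ref, 1L, function(x) sort(x, decreasing = TRUE)[1:2])
      srt[1L, ] - srt[2L, ]
    },
    stop("unknown scoring method: ", method, call. = FALSE)
  )
}

#' Score all reference genes for cell-type specificity
#'
#' Each gene's expression vector across the K reference cell types is turned
#' into a specificity score (see [deconv_config()] for the method menu) and
#' assigned to the cell type in which it is maximally expressed. Argmax ties
#' go to the first tied column in column order and the gene is flagged.
#'
#' @param ref filtered, imputed reference matrix (all values > 0).
#' @param method scoring method name.
#' @return data frame with columns `gene`, `score`, `best_cell_type`,
#'   `tied`, `method`, plus a `desirability` column on which lower rank
#'   index = better signature (entropy ascending, all other methods
#'   descending via negation).
#' @export
score_genes <- function(ref, method = "Entropy") {
  validate_expression_matrix(ref, "reference")
  if (any(ref <= 0)) {
    stop("score_genes expects a filtered and imputed reference (all values > 0)",
         call. = FALSE)
  }
  score <- score_matrix(ref, method)
  best_idx <- max.col(ref, ties.method = "first")
  n_at_max <- rowSums(ref == apply(ref, 1L, max))
  data.frame(
    gene = rownames(ref),
    score = unname(score),
    best_cell_type = colnames(ref)[best_idx],
    tied = n_at_max > 1L,
    method = method,
    desirability = if (method == "Entropy") unname(score) else -unname(score),
    stringsAsFactors = FALSE
  )
}

#' Select signature genes under the NumSigs/MinSigs budget
#'
#' The total budget is `B = num_sigs * K`. First each cell type contributes
#' its `min_sigs` best genes (by the active method's desirability) among the
#' genes maximally expressed in that type; types with fewer candidates
#' contribute what they have, with a warning. If `min_sigs < num_sigs`, the
#' remaining slots are filled with the globally best-ranked unselected genes
#' regardless of which cell type they mark; those fill genes are flagged.
#' With `min_sigs = num_sigs` there is no fill step and selection is exactly
#' per-type top-N.
#'
#' Ties in desirability at a selection boundary are broken by gene symbol,
#' so the selected set never depends on input row order.
#'
#' @param scores score table from [score_genes()].
#' @param cell_types character vector of all K reference cell-type labels
#'   (types with zero candidate genes trigger a warning).
#' @param num_sigs,min_sigs see [deconv_config()].
#' @return an object of class `signature_set`: list with
#'   `genes_by_cell_type` (named list of ordered gene vectors),
#'   `all_genes` (de-duplicated union), and `fill_genes` (genes added by the
#'   global fill whose best type may already be saturated).
#' @export
select_signatures <- function(scores, cell_types, num_sigs, min_sigs = num_sigs) {
  stopifnot(nrow(scores) > 0L, length(cell_types) >= 1L)
  K <- length(cell_types)
  budget <- num_sigs * K
  if (budget < K) stop("budget smaller than number of cell types", call. = FALSE)
  ord <- order(scores$desirability, scores$gene)
  scores <- scores[ord, , drop = FALSE]

  by_type <- split(scores$gene, factor(scores$best_cell_type, levels = cell_types))
  empty <- names(by_type)[lengths(by_type) == 0L]
  if (length(empty)) {
    warning("no candidate signature genes for cell type(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  short <- names(by_type)[lengths(by_type) < min_sigs & lengths(by_type) > 0L]
  if (length(short)) {
    warning("fewer than min_sigs candidates for cell type(s): ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  picked <- lapply(by_type, function(g) g[seq_len(min(min_sigs, length(g)))])
  fill_genes <- character(0)
  if (min_sigs < num_sigs) {
    taken <- unlist(picked, use.names = FALSE)
    remaining <- budget - length(taken)
    if (remaining > 0L) {
      pool <- scores[!(scores$gene %in% taken), , drop = FALSE]
      fill <- pool[seq_len(min(remaining, nrow(pool))), , drop = FALSE]
      fill_genes <- fill$gene
      add <- split(fill$gene, factor(fill$best_cell_type, levels = cell_types))
      picked <- Map(c, picked, add)
    }
  }
  all_genes <- unique(unlist(picked, use.names = FALSE))
  structure(list(genes_by_cell_type = picked, all_genes = all_genes,
                 fill_genes = fill_genes),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature set:", length(x$all_genes), "genes over",
      length(x$genes_by_cell_type), "cell types\n")
  counts <- lengths(x$genes_by_cell_type)
  print(counts)
  invisible(x)
}

#' Export a signature set as a two-column TSV (gene, cell type)
#'
#' @param sigs a `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_set <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  df <- data.frame(
    gene = unlist(sigs$genes_by_cell_type, use.names = FALSE),
    cell_type = rep(names(sigs$genes_by_cell_type),
                    lengths(sigs$genes_by_cell_type))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
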
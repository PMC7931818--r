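# Preprocessing: make a reference matrix (purified cell-type profiles) and a
# mixture matrix (bulk samples) comparable before signature selection and
# regression. Order is fixed: intersect genes -> drop never-expressed
# reference genes -> quantile normalize both to the reference's starting
# distribution.

#' Restrict two expression matrices to their shared genes
#'
#' @param ref reference expression matrix (genes x cell types).
#' @param mix mixture expression matrix (genes x samples).
#' @return list with elements `ref` and `mix`, both containing exactly the
#'   shared genes in the same row order (reference order).
#' @export
intersect_genes <- function(ref, mix) {
  validate_expression_matrix(ref, "reference")
  validate_expression_matrix(mix, "mixture")
  shared <- intersect(rownames(ref), rownames(mix))
  if (length(shared) == 0L) {
    stop("reference and mixture share zero genes", call. = FALSE)
  }
  list(ref = ref[shared, , drop = FALSE], mix = mix[shared, , drop = FALSE])
}

#' Drop genes with no detected expression in any reference cell type
#'
#' A gene whose reference row is all zeros carries no information about
#' cell-type composition, so it is removed from both matrices.
#'
#' @param ref,mix gene-aligned expression matrices.
#' @return list with elements `ref` and `mix`.
#' @export
drop_unexpressed_reference_genes <- function(ref, mix) {
  stopifnot(identical(rownames(ref), rownames(mix)))
  keep <- rowSums(ref > 0) > 0L
  if (!any(keep)) {
    stop("all genes have zero expression in every reference cell type",
         call. = FALSE)
  }
  list(ref = ref[keep, , drop = FALSE], mix = mix[keep, , drop = FALSE])
}

# Quantile-normalize one column to a sorted target vector. Ties receive the
# mean of the target values at the tied rank positions, which keeps the
# transform deterministic and permutation-invariant.
qn_column <- function(x, target) {
  if (!anyDuplicated(x)) {
    out <- numeric(length(x))
    out[order(x)] <- target
    return(out)
  }
  rk_min <- rank(x, ties.method = "min")
  rk_max <- rank(x, ties.method = "max")
  cs <- c(0, cumsum(target))
  (cs[rk_max + 1L] - cs[rk_min]) / (rk_max - rk_min + 1L)
}

#' Quantile normalize a reference/mixture pair to the reference distribution
#'
#' The target distribution is the mean of the sorted columns of the
#' reference matrix before normalization (its "starting distribution").
#' Every column of both matrices is then mapped onto that target: after the
#' transform each column, when sorted, equals the target, and the rank order
#' within each column is preserved. Ties are assigned the average of the
#' target values at the tied ranks.
#'
#' @param ref,mix gene-aligned expression matrices with at least 2 genes.
#' @return list with elements `ref`, `mix` (normalized matrices) and
#'   `target` (the sorted target vector, length = number of genes).
#' @export
quantile_normalize_pair <- function(ref, mix) {
  stopifnot(identical(rownames(ref), rownames(mix)))
  if (nrow(ref) < 2L) {
    stop("quantile normalization needs at least 2 genes", call. = FALSE)
  }
  target <- unname(rowMeans(apply(ref, 2L, sort, method = "radix")))
  ref_qn <- apply(ref, 2L, qn_column, target = target)
  mix_qn <- apply(mix, 2L, qn_column, target = target)
  dimnames(ref_qn) <- dimnames(ref)
  dimnames(mix_qn) <- dimnames(mix)
  list(ref = ref_qn, mix = mix_qn, target = target)
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper running [intersect_genes()],
#' [drop_unexpressed_reference_genes()] and [quantile_normalize_pair()] in
#' the pipeline's fixed order.
#'
#' @inheritParams intersect_genes
#' @return list with `ref`, `mix`, `target` and `n_genes`, the gene count
#'   surviving each stage (named vector).
#' @export
preprocess_pair <- function(ref, mix) {
  n0 <- c(ref = nrow(ref), mix = nrow(mix))
  s1 <- intersect_genes(ref, mix)
  s2 <- drop_unexpressed_reference_genes(s1$ref, s1$mix)
  s3 <- quantile_normalize_pair(s2$ref, s2$mix)
  s3$n_genes <- c(reference = unname(n0["ref"]), mixture = unname(n0["mix"]),
                  shared = nrow(s1$ref), expressed = nrow(s2$ref))
  s3
}
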
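# Benchmarking harness: synthetic references, in-silico mixtures of known
# proportions, accuracy metrics, and parameter sweeps.

#' Generate a synthetic reference matrix of well-separated cell types
#'
#' Emulates a purified-profile reference: every gene draws a log-normal
#' baseline expression level shared across cell types, and a random subset of
#' genes per cell type is upregulated in that type by a fold change of
#' 2^U(2, 6), giving each type a distinct marker program. Values are linear
#' scale, non-negative.
#'
#' @param n_genes number of genes (default 1200).
#' @param n_celltypes number of cell types K (default 10).
#' @param marker_frac fraction of genes recruited as markers of each cell
#'   type (default 0.08).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters
#'   (defaults 4 and 1.2, giving a realistic right-skewed bulk-like
#'   distribution).
#' @param seed integer seed; the same seed reproduces the same reference.
#' @return expression matrix, `n_genes` x `n_celltypes`.
#' @export
simulate_reference <- function(n_genes = 1200L, n_celltypes = 10L,
                               marker_frac = 0.08,
                               baseline_meanlog = 4, baseline_sdlog = 1.2,
                               seed = 1L) {
  stopifnot(n_genes >= 10L, n_celltypes >= 2L)
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    m <- matrix(rep(base, n_celltypes), nrow = n_genes)
    n_markers <- max(1L, round(marker_frac * n_genes))
    for (k in seq_len(n_celltypes)) {
      idx <- sample.int(n_genes, n_markers)
      fold <- 2^stats::runif(n_markers, 2, 6)
      m[idx, k] <- m[idx, k] * fold
    }
    dimnames(m) <- list(sprintf("GENE%04d", seq_len(n_genes)),
                        sprintf("CellType%02d", seq_len(n_celltypes)))
    m
  })
}

#' Perturb a reference with per-gene multiplicative log-normal biases
#'
#' Emulates cross-platform / cross-laboratory differences: each gene row is
#' multiplied by an independent log-normal factor with log-sd `sigma`
#' (median 1). Deconvolving mixtures generated from the original reference
#' with the perturbed copy mimics using a separate expression matrix from
#' another source.
#'
#' @param ref expression matrix.
#' @param sigma log-scale standard deviation of the per-gene bias.
#' @param seed integer seed.
#' @return perturbed expression matrix of the same shape.
#' @export
perturb_reference <- function(ref, sigma = 0.3, seed = 1L) {
  validate_expression_matrix(ref, "reference")
  with_seed(seed, {
    bias <- stats::rlnorm(nrow(ref), meanlog = 0, sdlog = sigma)
    ref * bias
  })
}

#' Simulate bulk mixtures of known cell-type proportions
#'
#' Each synthetic sample mixes `n_celltypes` distinct reference columns,
#' drawn uniformly; mixing proportions are drawn from a flat Dirichlet
#' (uniform on the simplex). Gene values are the proportion-weighted sum of
#' the chosen reference columns; with `noise_cv > 0`, each value is further
#' multiplied by an independent log-normal factor with unit mean and
#' coefficient of variation `noise_cv`.
#'
#' @param ref generating reference matrix (genes x K cell types).
#' @param n_mixtures number of synthetic samples.
#' @param n_celltypes number of distinct cell types per mixture (<= K).
#' @param seed integer seed; identical seeds give identical mixtures and truth.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise; 0 (default) gives exact convex combinations.
#' @return list with `mixtures` (genes x samples matrix) and `truth`
#'   (samples x K matrix of true proportions, rows summing to 1; attributes
#'   `reference_label`, `n_celltypes`, `seed`).
#' @export
simulate_mixtures <- function(ref, n_mixtures, n_celltypes, seed = 1L,
                              noise_cv = 0) {
  validate_expression_matrix(ref, "reference")
  K <- ncol(ref)
  if (n_celltypes > K) stop("n_celltypes exceeds reference cell types", call. = FALSE)
  stopifnot(n_mixtures >= 1L, n_celltypes >= 1L, noise_cv >= 0)
  with_seed(seed, {
    truth <- matrix(0, n_mixtures, K,
                    dimnames = list(sprintf("mix%04d", seq_len(n_mixtures)),
                                    colnames(ref)))
    mixtures <- matrix(0, nrow(ref), n_mixtures,
                       dimnames = list(rownames(ref), rownames(truth)))
    for (i in seq_len(n_mixtures)) {
      chosen <- sample.int(K, n_celltypes)
      w <- stats::rgamma(n_celltypes, shape = 1)   # flat Dirichlet
      w <- w / sum(w)
      truth[i, chosen] <- w
      mixtures[, i] <- ref[, chosen, drop = FALSE] %*% w
    }
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      fac <- matrix(stats::rlnorm(length(mixtures), -sdlog^2 / 2, sdlog),
                    nrow = nrow(mixtures))
      mixtures <- mixtures * fac
    }
    attr(truth, "reference_label") <- attr(ref, "label")
    attr(truth, "n_celltypes") <- n_celltypes
    attr(truth, "seed") <- seed
    list(mixtures = mixtures, truth = truth)
  })
}

# align a prediction table to the truth's samples and cell types;
# cell types absent from the prediction score as 0
align_pred_truth <- function(pred, truth) {
  if (!all(rownames(truth) %in% rownames(pred))) {
    stop("prediction is missing samples present in the truth", call. = FALSE)
  }
  out <- matrix(0, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  common <- intersect(colnames(truth), colnames(pred))
  out[, common] <- pred[rownames(truth), common]
  out
}

#' Mean absolute error between predicted and true fractions
#'
#' @param pred fraction table (samples x cell types).
#' @param truth true-proportion matrix from [simulate_mixtures()]; cell types
#'   absent from `pred` are scored as predicted 0.
#' @return list with `overall` (mean |predicted - true| over all
#'   (sample, cell type) pairs) and `per_sample` (named vector of per-sample
#'   means).
#' @export
mean_abs_error <- function(pred, truth) {
  p <- align_pred_truth(pred, truth)
  err <- abs(p - truth)
  list(overall = mean(err), per_sample = rowMeans(err))
}

#' Pearson correlation between predicted and true fractions
#'
#' Computed per cell type across samples and pooled over all
#' (sample, cell type) pairs. Correlations with fewer than 3 samples or a
#' constant vector are undefined and reported as `NA` with a reason.
#'
#' @inheritParams mean_abs_error
#' @return list with `per_celltype` (named vector, `NA` where undefined),
#'   `pooled` (single r over all pairs) and `undefined` (named character
#'   vector of reasons for `NA`s).
#' @export
correlation_by_celltype <- function(pred, truth) {
  p <- align_pred_truth(pred, truth)
  undefined <- character(0)
  per_ct <- vapply(colnames(truth), function(ct) {
    x <- truth[, ct]; y <- p[, ct]
    if (length(x) < 3L) {
      undefined[[ct]] <<- "fewer than 3 samples"
      return(NA_real_)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      undefined[[ct]] <<- "constant vector"
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  pooled <- if (stats::sd(truth) == 0 || stats::sd(p) == 0) NA_real_
            else stats::cor(as.vector(truth), as.vector(p))
  list(per_celltype = per_ct, pooled = pooled, undefined = undefined)
}

#' Sweep deconvolution parameters over simulated mixtures
#'
#' Simulates one batch of mixtures from `ref_gen` and deconvolves it with
#' `ref_dec` under every configuration in the grid (a paired design: all
#' configurations see the same mixtures, which sharpens comparisons between
#' settings). `ref_gen` and `ref_dec` may be the same matrix
#' (same-reference evaluation) or a perturbed copy (cross-reference
#' evaluation, see [perturb_reference()]).
#'
#' @param ref_gen reference used to generate mixtures.
#' @param ref_dec reference handed to [deconvolve()].
#' @param grid data frame whose columns are a subset of `sig_method`,
#'   `num_sigs`, `min_sigs`, `row_scale_p`; one row per configuration
#'   (missing columns take the [deconv_config()] defaults).
#' @param n_mixtures,n_celltypes,noise_cv,seed passed to
#'   [simulate_mixtures()].
#' @return long-format data frame: one row per configuration with the config
#'   columns plus `n_mixtures`, `mean_error`, `median_sample_error`,
#'   `pooled_r`.
#' @export
parameter_sweep <- function(ref_gen, ref_dec, grid, n_mixtures = 50L,
                            n_celltypes = min(4L, ncol(ref_gen)),
                            noise_cv = 0, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  sim <- simulate_mixtures(ref_gen, n_mixtures, n_celltypes,
                           seed = seed, noise_cv = noise_cv)
  defaults <- deconv_config()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, , drop = FALSE])
    cfg <- deconv_config(
      sig_method = if (!is.null(g$sig_method)) as.character(g$sig_method) else defaults$sig_method,
      num_sigs = if (!is.null(g$num_sigs)) g$num_sigs else defaults$num_sigs,
      min_sigs = if (!is.null(g$min_sigs)) g$min_sigs
                 else if (!is.null(g$num_sigs)) g$num_sigs else defaults$min_sigs,
      row_scale_p = if (!is.null(g$row_scale_p)) g$row_scale_p else defaults$row_scale_p,
      seed = seed)
    pred <- deconvolve(ref_dec, sim$mixtures, cfg)
    err <- mean_abs_error(pred, sim$truth)
    r <- correlation_by_celltype(pred, sim$truth)
    data.frame(sig_method = cfg$sig_method, num_sigs = cfg$num_sigs,
               min_sigs = cfg$min_sigs, row_scale_p = cfg$row_scale_p,
               n_mixtures = n_mixtures, mean_error = err$overall,
               median_sample_error = stats::median(err$per_sample),
               pooled_r = r$pooled)
  })
  do.call(rbind, rows)
}

# run code with a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
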
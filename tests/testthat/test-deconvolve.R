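test_that("row scaling matches its closed forms", {
  genes <- c("g1")
  as_mat <- function(x, cols) matrix(x, 1, length(x),
                                     dimnames = list(genes, cols))
  # values {0, 5, 10}: ref holds {0, 5}, mix holds {10}
  ref <- as_mat(c(0, 5), c("A", "B")); mix <- as_mat(10, "s1")
  p0 <- row_scale(ref, mix, p = 0)
  expect_equal(unname(cbind(p0$ref, p0$mix)[1, ]), c(0, 0.5, 1))
  p1 <- row_scale(ref, mix, p = 1)
  expect_equal(unname(cbind(p1$ref, p1$mix)[1, ]), c(0, 5, 10)) # identity
  # worked value: {2, 4, 6}, p = 0.5 -> {0, 0.5*sqrt(6), sqrt(6)}
  ref2 <- as_mat(c(2, 4), c("A", "B")); mix2 <- as_mat(6, "s1")
  ph <- row_scale(ref2, mix2, p = 0.5)
  expect_equal(unname(cbind(ph$ref, ph$mix)[1, ]),
               c(0, 0.5 * sqrt(6), sqrt(6)), tolerance = 1e-4)
})

test_that("row scaling spans [0,1] at p=0 and flags constant rows", {
  set.seed(9)
  ref <- matrix(rlnorm(40), 10, 4,
                dimnames = list(sprintf("g%02d", 1:10), LETTERS[1:4]))
  mix <- matrix(rlnorm(30), 10, 3,
                dimnames = list(rownames(ref), paste0("s", 1:3)))
  out <- row_scale(ref, mix, p = 0)
  joint <- cbind(out$ref, out$mix)
  expect_equal(unname(apply(joint, 1, min)), rep(0, 10))
  expect_equal(unname(apply(joint, 1, max)), rep(1, 10))

  ref_c <- ref; ref_c[1, ] <- 2
  mix_c <- mix; mix_c[1, ] <- 2
  expect_warning(out_c <- row_scale(ref_c, mix_c, 0), "constant")
  expect_equal(unname(out_c$ref[1, ]), rep(0, 4))
  expect_true(out_c$params$constant[1])
})

test_that("nnls recovers exact and blended columns", {
  set.seed(2)
  A <- matrix(rlnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  fit <- nnls_fit(A, A[, 2])
  expect_equal(unname(fit$coefficients), c(0, 1, 0), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)

  b <- 0.3 * A[, 1] + 0.7 * A[, 2]
  fit2 <- nnls_fit(A, b)
  expect_equal(unname(fit2$coefficients), c(0.3, 0.7, 0), tolerance = 1e-6)

  fit0 <- nnls_fit(A, rep(0, 20))
  expect_equal(unname(fit0$coefficients), c(0, 0, 0))

  # rank deficiency is flagged but still yields a solution
  A_def <- cbind(A[, 1], A[, 1], deparse.level = 0)
  colnames(A_def) <- c("A", "B")
  fit_def <- nnls_fit(A_def, A[, 1])
  expect_true(fit_def$rank_deficient)
  expect_lt(fit_def$rss, 1e-12)
})

test_that("nnls agrees with glmnet under the unpenalized non-negative settings", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  A <- matrix(rlnorm(120), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  b <- as.vector(A %*% c(0.2, 0.5, 0.3)) + rnorm(40, sd = 0.05)
  ours <- nnls_fit(A, b)$coefficients
  gl <- glmnet::glmnet(A, b, lower.limits = 0, alpha = 0, lambda = 0,
                       intercept = FALSE, standardize = FALSE,
                       thresh = 1e-14)
  theirs <- as.numeric(stats::coef(gl))[-1]
  expect_equal(unname(ours), theirs, tolerance = 1e-3)
})

test_that("nnls matches the simplex grid-search oracle on random instances", {
  set.seed(13)
  for (i in 1:10) {
    K <- sample(2:3, 1)
    A <- matrix(rlnorm(20 * K), 20, K,
                dimnames = list(NULL, LETTERS[seq_len(K)]))
    w_true <- rexp(K); w_true <- w_true / sum(w_true)
    b <- as.vector(A %*% w_true) * runif(1, 0.5, 2)
    ours <- normalize_fractions(nnls_fit(A, b)$coefficients)
    oracle <- grid_search_nnls(A, b, step = 0.01)
    expect_lt(max(abs(ours - oracle$weights)), 0.02)
  }
})

test_that("fraction normalization handles ordinary and degenerate input", {
  expect_equal(unname(normalize_fractions(c(2, 2))), c(0.5, 0.5),
               ignore_attr = TRUE)
  out <- normalize_fractions(c(0.3, 0.7))
  expect_equal(unname(out), c(0.3, 0.7), ignore_attr = TRUE)
  expect_false(attr(out, "degenerate"))
  deg <- normalize_fractions(c(0, 0, 0))
  expect_equal(unname(deg), rep(1 / 3, 3), ignore_attr = TRUE)
  expect_true(attr(deg, "degenerate"))
  expect_error(normalize_fractions(c(-1, 2)), "non-negative")
})

test_that("deconvolution recovers pure columns and simple blends", {
  ref <- default_study_reference()
  # noiseless pure columns: the true type dominates
  self <- deconvolve(ref, ref)
  expect_gte(min(diag(self)), 0.99)
  expect_equal(unname(rowSums(self)), rep(1, ncol(ref)), tolerance = 1e-9)

  # 50/50 blend of two reference columns
  blend <- matrix(0.5 * ref[, 1] + 0.5 * ref[, 2], ncol = 1,
                  dimnames = list(rownames(ref), "blend"))
  fr <- deconvolve(ref, blend)
  expect_lt(abs(fr["blend", 1] - 0.5), 0.05)
  expect_lt(abs(fr["blend", 2] - 0.5), 0.05)

  # stage log records the surviving gene counts
  log <- attr(fr, "stage_log")
  expect_named(log, c("reference", "mixture", "shared", "expressed",
                      "filtered", "signature"))
  expect_lte(log[["signature"]], 50 * ncol(ref))
})

test_that("fractions are invariant to uniform rescaling of a mixture column", {
  ref <- default_study_reference()
  sim <- simulate_mixtures(ref, 3, 4, seed = 21)
  scaled <- sim$mixtures * 37.5
  fr1 <- deconvolve(ref, sim$mixtures)
  fr2 <- deconvolve(ref, scaled)
  expect_equal(fr1, fr2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("low shared-gene counts run with a warning", {
  ref <- default_study_reference()[1:10, ]
  mix <- matrix(ref[, 1], ncol = 1, dimnames = list(rownames(ref), "s1"))
  warns <- character(0)
  fr <- withCallingHandlers(
    deconvolve(ref, mix, deconv_config(num_sigs = 2)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(warns, "genes shared", all = FALSE)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("subtype aggregation sums members and preserves row sums", {
  f <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"),
                              c("naive B", "memory B", "CD4 T", "NK")))
  map <- data.frame(fine = c("naive B", "memory B"),
                    parent = c("B cells", "B cells"))
  out <- aggregate_subtypes(f, map)
  expect_equal(out["s1", "B cells"], 0.3)
  expect_equal(out["s2", "B cells"], 0.5)
  expect_equal(unname(rowSums(out)), c(1, 1))
  # unmapped labels pass through
  expect_true(all(c("CD4 T", "NK") %in% colnames(out)))

  # identity map changes nothing
  idmap <- data.frame(fine = colnames(f), parent = colnames(f))
  expect_equal(aggregate_subtypes(f, idmap), f)

  # collapsing everything conserves the total
  allmap <- data.frame(fine = colnames(f), parent = "cells")
  expect_equal(unname(aggregate_subtypes(f, allmap)[, "cells"]), c(1, 1))
})

test_that("multi-reference combination takes medians then renormalizes", {
  mk <- function(vals, types) {
    matrix(vals, 1, length(types), dimnames = list("s1", types))
  }
  t1 <- mk(c(0.1, 0.9), c("T", "B"))
  t2 <- mk(c(0.2, 0.8), c("T", "B"))
  t3 <- mk(c(0.6, 0.4), c("T", "B"))
  out <- combine_reference_predictions(list(t1, t2, t3))
  # medians 0.2 and 0.8 already sum to 1
  expect_equal(out["s1", "T"], 0.2)
  expect_equal(out["s1", "B"], 0.8)

  # a type present in only one table uses that value as its median
  t4 <- mk(c(0.5, 0.3, 0.2), c("T", "B", "NK"))
  out2 <- combine_reference_predictions(list(t1, t2, t4))
  med <- c(T = 0.2, B = 0.8, NK = 0.2)
  expect_equal(out2["s1", ], med / sum(med))

  # equal predictions stay equal
  out3 <- combine_reference_predictions(list(t1, t1, t1))
  expect_equal(out3["s1", ], t1["s1", ])

  bad <- t1; rownames(bad) <- "other_sample"
  expect_error(combine_reference_predictions(list(t1, bad)), "no samples")
})
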
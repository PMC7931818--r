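# Small in-code fixtures shared across tests.

# tiny hand-checkable reference: 4 genes x 3 cell types
tiny_ref <- function() {
  m <- matrix(c(10, 1, 1,
                1, 12, 1,
                1, 1, 9,
                5, 5, 5), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(c("G1", "G2", "G3", "G4"), c("A", "B", "C"))
  m
}

# write an expression table from raw lines (to exercise the parser itself)
write_raw_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# exhaustive simplex grid-search oracle for NNLS: enumerate mixing weights w
# on the unit simplex at the given step, fit the optimal non-negative scale s
# for each direction in closed form, and return the normalized weights with
# the smallest residual. Independent of the active-set solver under test.
grid_search_nnls <- function(A, b, step = 0.01) {
  K <- ncol(A)
  ticks <- seq(0, 1, by = step)
  grid <- switch(as.character(K),
    "1" = matrix(1, 1, 1),
    "2" = {
      w1 <- ticks
      cbind(w1, 1 - w1)
    },
    "3" = {
      g <- expand.grid(w1 = ticks, w2 = ticks)
      g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
      cbind(g$w1, g$w2, 1 - g$w1 - g$w2)
    },
    stop("oracle supports K <= 3")
  )
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    d <- A %*% w
    dd <- sum(d * d)
    s <- if (dd > 0) max(0, sum(d * b) / dd) else 0
    rss <- sum((b - s * d)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- w
    }
  }
  list(weights = best, rss = best_rss)
}

# simulated study conditions used by several tests
default_study_reference <- function(seed = 7) simulate_reference(seed = seed)
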
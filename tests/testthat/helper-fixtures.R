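# Shared fixtures for the test suite.

# Quick signal_matrix from a bare matrix, auto-naming rows/columns.
sm <- function(values, scale = "log2", row_prefix = "g", col_prefix = "s") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("%s%03d", row_prefix, seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s%03d", col_prefix, seq_len(ncol(values)))
  }
  signal_matrix(values, scale = scale)
}

# A small exactly-realizable training problem: Y = a + B X with no noise
# and no clipping (baselines high enough that all values stay positive).
# Used for oracle tests of the regression pipeline with quantile
# normalization off and locus-only models.
make_exact_problem <- function(n_genes = 12, n_loci = 6, n_samples = 20,
                               K_true = 2, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n_genes * n_samples, mean = 8, sd = 1.5),
                n_genes, n_samples)
    drivers <- t(vapply(seq_len(n_loci), function(l) {
      sample.int(n_genes, K_true)
    }, integer(K_true)))
    B <- matrix(stats::runif(n_loci * K_true, 0.3, 0.7), n_loci, K_true)
    a <- stats::runif(n_loci, 4, 6)
    Y <- matrix(0, n_loci, n_samples)
    for (l in seq_len(n_loci)) {
      Y[l, ] <- a[l] + colSums(B[l, ] * X[drivers[l, ], , drop = FALSE])
    }
    list(
      X = sm(X), Y = sm(Y, row_prefix = "l"),
      drivers = drivers, B = B, a = a
    )
  })
}

# Tiny synthetic world for end-to-end tests that must stay fast.
small_truth <- function(seed = 7) {
  synthetic_truth(n_genes = 120, n_loci = 100, n_cell_types = 5,
                  replicates = 2, drivers_per_block = 3, block_size = 10,
                  n_modules = 10, seed = seed)
}

# Config that keeps small worlds cheap and deterministic.
small_config <- function(...) {
  train_config(cluster_sizes = c(4L, 10L), ...)
}

# Ridge regression oracle via an augmented least-squares system:
# rows sqrt(lambda) * I appended to X (intercept column unpenalized).
ridge_oracle <- function(X, y, lambda) {
  K <- ncol(X)
  Za <- rbind(cbind(1, X), cbind(0, sqrt(lambda) * diag(K)))
  ya <- c(y, rep(0, K))
  as.numeric(stats::lm.fit(Za, ya)$coefficients)
}
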
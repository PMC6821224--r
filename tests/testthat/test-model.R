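test_that("pearson correlation matches the textbook formula and the zero-variance convention", {
  withr::with_seed(21, {
    x <- stats::rnorm(15)
    y <- stats::rnorm(15)
  })
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), manual, tolerance = 1e-12)
  expect_identical(pearson_cor(rep(2, 5), y[1:5]), 0)
  expect_identical(pearson_cor(x[1:5], rep(-1, 5)), 0)
  expect_error(pearson_cor(1:3, 1:4), "equal length")
  expect_error(pearson_cor(1, 2), "at least 2")
})

test_that("predictor screening matches an exhaustive |correlation| sort", {
  withr::with_seed(22, {
    for (i in 1:10) {
      G <- sample(10:40, 1)
      M <- sample(5:15, 1)
      X <- matrix(stats::rnorm(G * M), G, M,
                  dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:M)))
      y <- stats::rnorm(M)
      K <- sample(1:5, 1)
      sel <- select_predictors(signal_matrix(X, "log2"), y, K)
      r <- abs(apply(X, 1, function(row) stats::cor(row, y)))
      oracle <- order(-r, seq_len(G))[seq_len(K)]
      expect_identical(sel, oracle)
    }
  })
})

test_that("screening ties break by ascending gene index and constants rank last", {
  y <- c(1, 2, 3, 4)
  X <- rbind(g1 = c(4, 3, 2, 1),   # r = -1
             g2 = c(1, 2, 3, 4),   # r = +1, same |r|: index order decides
             g3 = c(5, 5, 5, 5),   # constant -> r = 0
             g4 = c(1, 2, 2, 3))   # 0 < |r| < 1
  colnames(X) <- sprintf("s%d", 1:4)
  sel <- select_predictors(signal_matrix(X, "log2"), y, 4)
  expect_identical(sel[1:2], c(1L, 2L))
  expect_identical(sel[4], 3L)  # the constant gene comes last
})

test_that("unpenalized fits recover planted coefficients exactly", {
  withr::with_seed(23, {
    X <- matrix(stats::rnorm(40), 10, 4)
    b_true <- c(2.5, -1, 0.5, 3, 1.25)
    y <- b_true[1] + X %*% b_true[-1]
  })
  expect_equal(fit_linear_model(X, as.numeric(y)), b_true, tolerance = 1e-10)
})

test_that("a constant response yields a pure-intercept fit", {
  withr::with_seed(24, X <- matrix(stats::rnorm(24), 8, 3))
  b <- fit_linear_model(X, rep(4.2, 8))
  expect_equal(b, c(4.2, 0, 0, 0), tolerance = 1e-10)
})

test_that("ridge fits match an augmented least-squares oracle", {
  withr::with_seed(25, {
    for (i in 1:5) {
      n <- sample(8:20, 1); K <- sample(2:5, 1)
      X <- matrix(stats::rnorm(n * K), n, K)
      y <- stats::rnorm(n)
      lambda <- stats::runif(1, 0.01, 2)
      expect_equal(fit_linear_model(X, y, lambda), ridge_oracle(X, y, lambda),
                   tolerance = 1e-8)
    }
  })
})

test_that("singular unpenalized systems error but a ridge penalty resolves them", {
  X <- cbind(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))  # collinear
  y <- c(1, 2, 3, 4, 5)
  expect_error(fit_linear_model(X, y), "ridge")
  b <- fit_linear_model(X, y, ridge_lambda = 1e-6)
  expect_equal(drop(b[1] + X %*% b[-1]), y, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(fit_linear_model(matrix(1:4, 2, 2), 1:2), "K \\+ 1 samples")
})

test_that("locus clustering is deterministic, complete, and isolates constant loci", {
  withr::with_seed(26, {
    Y <- matrix(stats::rnorm(200, 4, 1), 20, 10)
  })
  Y[5, ] <- 3  # constant profile
  dimnames(Y) <- list(sprintf("l%02d", 1:20), sprintf("s%02d", 1:10))
  m <- signal_matrix(Y, "log2")
  a1 <- cluster_loci(m, 4, seed = 99)
  a2 <- cluster_loci(m, 4, seed = 99)
  expect_identical(a1, a2)
  expect_identical(names(a1), rownames(Y))
  expect_identical(a1[["l05"]], 5L)  # constant locus -> extra cluster
  expect_true(all(a1[-5] %in% 1:4))
  expect_error(cluster_loci(m, 0), ">= 1")
  expect_error(cluster_loci(m, 21), "exceeds")
})

test_that("clustering is invariant to per-locus affine scaling of profiles", {
  withr::with_seed(27, Y <- matrix(stats::rnorm(120, 5, 1), 12, 10))
  dimnames(Y) <- list(sprintf("l%02d", 1:12), sprintf("s%02d", 1:10))
  scaled <- Y * stats::runif(12, 0.5, 3) + stats::runif(12, -2, 2)
  dimnames(scaled) <- dimnames(Y)
  expect_identical(cluster_loci(signal_matrix(Y, "log2"), 3, seed = 1),
                   cluster_loci(signal_matrix(scaled, "log2"), 3, seed = 1))
})

test_that("a locus-only model recovers an exactly linear world perfectly", {
  prob <- make_exact_problem()
  cfg <- train_config(n_predictors = 4, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- train_accessibility_model(prob$X, prob$Y, cfg)
  pred <- predict_accessibility(model, prob$X)
  expect_equal(sm_values(pred), sm_values(prob$Y), tolerance = 1e-8)
})

test_that("locus-only training equals independent per-locus least squares", {
  withr::with_seed(28, {
    G <- 30; M <- 25; L <- 8
    X <- matrix(stats::rnorm(G * M, 6, 1), G, M)
    Y <- matrix(stats::rnorm(L * M, 4, 1), L, M)
  })
  dimnames(X) <- list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:M))
  dimnames(Y) <- list(sprintf("l%02d", 1:L), sprintf("s%02d", 1:M))
  K <- 5
  cfg <- train_config(n_predictors = K, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- train_accessibility_model(signal_matrix(X, "log2"),
                                     signal_matrix(Y, "log2"), cfg)
  for (l in seq_len(L)) {
    sel <- select_predictors(signal_matrix(X, "log2"), Y[l, ], K)
    expect_identical(model$locus_models$sel[l, ], sel)
    b <- fit_linear_model(t(X[sel, , drop = FALSE]), Y[l, ])
    expect_equal(model$locus_models$coefs[l, ], b, tolerance = 1e-8)
  }
  # with a single level the averaging weight must be exactly 1 everywhere
  expect_true(all(model$weights == 1))
})

test_that("model-averaging weights are a proper convex combination", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  model <- train_accessibility_model(bulk$X, bulk$Y, small_config())
  w <- model$weights
  expect_true(all(w >= 0))
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
  expect_identical(ncol(w), 1L + length(model$clusterings))
})

test_that("retraining with the same inputs is bit-identical", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  m1 <- train_accessibility_model(bulk$X, bulk$Y, small_config())
  m2 <- train_accessibility_model(bulk$X, bulk$Y, small_config())
  expect_identical(m1, m2)
  p1 <- predict_accessibility(m1, bulk$X)
  p2 <- predict_accessibility(m2, bulk$X)
  expect_identical(sm_values(p1), sm_values(p2))
})

test_that("prediction applies stored coefficients, weights and the zero floor", {
  # hand-built model: 2 loci, 3 genes, K = 1, no cluster levels
  cfg <- train_config(n_predictors = 1, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- structure(list(
    gene_ids = c("gA", "gB", "gC"),
    quantile_reference = c(0, 1, 2),
    locus_ids = c("l1", "l2"),
    locus_set = NULL,
    locus_keep = c(TRUE, TRUE),
    mean_profile = c(l1 = 3, l2 = 1),
    locus_models = list(sel = matrix(c(2L, 3L), 2, 1),
                        coefs = matrix(c(1, -4, 2, 0.5), 2, 2)),
    clusterings = list(),
    weights = matrix(1, 2, 1),
    train_sample_ids = c("t1", "t2", "t3"),
    config = cfg, schema_version = 1L
  ), class = "accessibility_model")
  Xn <- matrix(c(5, 3, 2), 3, 1, dimnames = list(c("gA", "gB", "gC"), "new"))
  pred <- sm_values(predict_accessibility(model, signal_matrix(Xn, "log2")))
  expect_equal(pred["l1", "new"], 1 + 2 * 3)       # intercept + coef * gB
  expect_equal(pred["l2", "new"], 0)               # -4 + 0.5 * 2 = -3 -> floored
})

test_that("prediction matches genes by identifier, not by row position", {
  prob <- make_exact_problem()
  cfg <- train_config(n_predictors = 4, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- train_accessibility_model(prob$X, prob$Y, cfg)
  shuffled <- sm_values(prob$X)[rev(seq_len(nrow(sm_values(prob$X)))), ]
  pred <- predict_accessibility(model, signal_matrix(shuffled, "log2"))
  expect_equal(sm_values(pred), sm_values(prob$Y), tolerance = 1e-8)
})

test_that("missing model genes and wrong scale flags raise clear errors", {
  prob <- make_exact_problem()
  cfg <- train_config(n_predictors = 2, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- train_accessibility_model(prob$X, prob$Y, cfg)
  v <- sm_values(prob$X)
  expect_error(predict_accessibility(model,
                                     signal_matrix(v[-1, , drop = FALSE], "log2")),
               "missing")
  expect_error(predict_accessibility(model, prob$X, already_log2 = FALSE),
               "tagged log2")
})

test_that("raw-scale input is log2(x + 1)-transformed before prediction", {
  prob <- make_exact_problem()
  cfg <- train_config(n_predictors = 4, cluster_sizes = integer(0),
                      quantile_normalize = FALSE, min_signal = 0)
  model <- train_accessibility_model(prob$X, prob$Y, cfg)
  raw <- signal_matrix(2^sm_values(prob$X) - 1, "raw")
  pred <- predict_accessibility(model, raw, already_log2 = FALSE)
  expect_equal(sm_values(pred), sm_values(prob$Y), tolerance = 1e-6)
})

test_that("training validates sample alignment and sizes", {
  prob <- make_exact_problem()
  Xv <- sm_values(prob$X)
  colnames(Xv) <- rev(colnames(Xv))
  expect_error(train_accessibility_model(signal_matrix(Xv, "log2"), prob$Y),
               "identical sample ids")
  expect_error(train_accessibility_model(
    signal_matrix(sm_values(prob$X)[, 1:2], "log2"),
    signal_matrix(sm_values(prob$Y)[, 1:2], "log2")), "at least 3")
  expect_error(train_accessibility_model(prob$X, prob$Y,
                                         train_config(n_predictors = 999,
                                                      min_signal = 0)),
               "exceeds")
})

test_that("the identity permutation control reproduces the standard model", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  cfg <- small_config()
  m_id <- train_permuted_model(bulk$X, bulk$Y, cfg,
                               permutation = seq_len(ncol(sm_values(bulk$X))))
  m_std <- train_accessibility_model(bulk$X, bulk$Y, cfg)
  expect_identical(m_id$locus_models, m_std$locus_models)
  expect_identical(m_id$weights, m_std$weights)
})

test_that("permutation controls preserve each locus's value multiset", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  Yv <- sm_values(bulk$Y)
  perm <- withr::with_seed(5, sample.int(ncol(Yv)))
  # the shuffled training target seen by the permuted model keeps the same
  # per-locus values; its mean profile must therefore match the standard one
  cfg <- small_config()
  m_perm <- train_permuted_model(bulk$X, bulk$Y, cfg, permutation = perm)
  m_std <- train_accessibility_model(bulk$X, bulk$Y, cfg)
  expect_identical(m_perm$locus_ids, m_std$locus_ids)
  expect_equal(m_perm$mean_profile, m_std$mean_profile, tolerance = 1e-12)
})

test_that("the mean-profile baseline repeats the training mean verbatim", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  model <- train_accessibility_model(bulk$X, bulk$Y, small_config())
  mp <- mean_profile_predict(model, n_samples = 3, sample_ids = c("a", "b", "c"))
  v <- sm_values(mp)
  expect_identical(colnames(v), c("a", "b", "c"))
  for (j in 1:3) expect_equal(unname(v[, j]), unname(model$mean_profile))
  Yk <- sm_values(bulk$Y)[model$locus_ids, ]
  expect_equal(unname(model$mean_profile), unname(rowMeans(Yk)))
})

test_that("tidy and glance summarize a model's structure", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  model <- train_accessibility_model(bulk$X, bulk$Y, small_config())
  td <- generics::tidy(model)
  expect_identical(nrow(td), length(model$locus_ids))
  expect_true(all(c("locus_id", "mean_signal", "w_locus") %in% names(td)))
  gl <- generics::glance(model)
  expect_identical(gl$n_cluster_resolutions, 2L)
  expect_identical(gl$n_predictors, 7L)
})

test_that("models survive a JSON round trip and predict identically", {
  truth <- small_truth()
  bulk <- generate_bulk(truth)
  model <- train_accessibility_model(bulk$X, bulk$Y, small_config(),
                                     loci = bulk$loci)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  p1 <- predict_accessibility(model, bulk$X)
  p2 <- predict_accessibility(back, bulk$X)
  expect_equal(sm_values(p1), sm_values(p2), tolerance = 1e-12)
  expect_identical(back$locus_ids, model$locus_ids)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_identical(back$locus_set$locus_id, model$locus_set$locus_id)
})
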
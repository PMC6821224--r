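#' Training configuration for an accessibility model
#'
#' @param n_predictors Number of predictor genes per regression (default 7).
#' @param cluster_sizes Integer vector of cluster counts, one per cluster
#'   resolution. `NULL` (the default) uses `round(L / c(500, 100, 20))`
#'   clipped to `[1, L]` at training time, giving three resolutions from
#'   coarse to fine.
#' @param ridge_lambda Ridge penalty (intercept unpenalized). The default 0
#'   fits ordinary least squares, falling back to `1e-6` on a singular
#'   system.
#' @param seed Integer seed controlling locus clustering.
#' @param min_signal Log2 threshold for the training locus pre-filter: loci
#'   whose maximum training signal is below it are dropped before model
#'   fitting. The default of 2 restricts training to loci that are clearly
#'   hypersensitive in at least one training sample, matching
#'   [filter_training_loci()]; set to 0 to keep every locus.
#' @param quantile_normalize Whether expression columns are quantile
#'   normalized to the training reference, both at training time and for
#'   new samples at prediction time (default `TRUE`).
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_predictors = 7L, cluster_sizes = NULL,
                         ridge_lambda = 0, seed = 1L, min_signal = 2,
                         quantile_normalize = TRUE) {
  n_predictors <- as.integer(n_predictors)
  if (n_predictors < 1) stop("`n_predictors` must be >= 1", call. = FALSE)
  if (!is.null(cluster_sizes)) {
    cluster_sizes <- as.integer(cluster_sizes)
    if (length(cluster_sizes) > 0 && any(cluster_sizes < 1)) {
      stop("all `cluster_sizes` must be >= 1", call. = FALSE)
    }
  }
  if (ridge_lambda < 0) stop("`ridge_lambda` must be >= 0", call. = FALSE)
  structure(list(n_predictors = n_predictors, cluster_sizes = cluster_sizes,
                 ridge_lambda = ridge_lambda, seed = as.integer(seed),
                 min_signal = min_signal,
                 quantile_normalize = isTRUE(quantile_normalize)),
            class = "train_config")
}

#' Pearson correlation with the zero-variance convention
#'
#' Standard Pearson correlation, except that a zero-variance (constant)
#' vector yields exactly 0 rather than NA. The convention is forced by the
#' mean-profile baseline: its predictions are constant across samples at
#' every locus, and its cross-sample correlation is reported as 0.
#'
#' @param u,v Numeric vectors of equal length >= 2.
#' @return A single correlation in \[-1, 1\], or 0 under the convention.
#' @export
pearson_cor <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  if (length(u) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

# row-wise pearson between two matrices with zero-variance rows -> 0
.rowwise_pearson <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Select the genes most correlated with a target profile
#'
#' Screens predictors for one regression: returns the indices of the `K`
#' genes with the largest absolute Pearson correlation to the target across
#' samples. Constant gene rows get correlation 0; ties break by ascending
#' gene index.
#'
#' @param X A log2-scale `signal_matrix`, genes x samples.
#' @param y_target Numeric vector, one value per sample.
#' @param K Number of genes to select.
#' @return Integer vector of `K` gene (row) indices.
#' @export
select_predictors <- function(X, y_target, K) {
  v <- if (inherits(X, "signal_matrix")) sm_values(X) else X
  if (ncol(v) != length(y_target)) stop("sample count mismatch", call. = FALSE)
  if (ncol(v) < 3) stop("need at least 3 samples for screening", call. = FALSE)
  if (K > nrow(v)) stop("K exceeds the number of genes", call. = FALSE)
  r <- .rowwise_pearson(v, matrix(y_target, nrow = nrow(v), ncol = ncol(v),
                                  byrow = TRUE))
  order(-abs(r), seq_along(r))[seq_len(K)]
}

#' Fit a linear model with an unpenalized intercept
#'
#' Minimizes `||y - b0 - X b||^2 + lambda ||b||^2`. With `lambda = 0` this
#' is ordinary least squares; a singular system then raises an error
#' advising a ridge penalty.
#'
#' @param X_sel Numeric matrix, samples x K selected predictors.
#' @param y Response vector.
#' @param ridge_lambda Penalty on the slope coefficients.
#' @return Numeric vector of K + 1 coefficients, intercept first.
#' @export
fit_linear_model <- function(X_sel, y, ridge_lambda = 0) {
  X_sel <- as.matrix(X_sel)
  n <- nrow(X_sel)
  K <- ncol(X_sel)
  if (length(y) != n) stop("length(y) must match nrow(X_sel)", call. = FALSE)
  if (ridge_lambda == 0 && n < K + 1) {
    stop("need at least K + 1 samples for an unpenalized fit", call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = 1, X_sel)
  A <- crossprod(Z) + ridge_lambda * diag(c(0, rep(1, K)), nrow = K + 1)
  b <- tryCatch(solve(A, crossprod(Z, y)),
                error = function(e) {
                  if (ridge_lambda == 0) {
                    stop("singular system with ridge_lambda = 0; ",
                         "set a small ridge penalty (e.g. 1e-6)", call. = FALSE)
                  }
                  stop(e)
                })
  as.numeric(b)
}

# OLS with automatic tiny-ridge fallback used inside train()
.fit_with_fallback <- function(X_sel, y, ridge_lambda) {
  tryCatch(fit_linear_model(X_sel, y, ridge_lambda),
           error = function(e) fit_linear_model(X_sel, y, 1e-6))
}

#' Partition loci by their standardized cross-sample profiles
#'
#' k-means clustering of loci on per-locus standardized (mean 0, sd 1)
#' accessibility profiles. Constant-profile loci cannot be standardized and
#' are assigned to a dedicated extra cluster.
#'
#' @param Y_train A log2-scale `signal_matrix`, loci x samples.
#' @param n_clusters Number of clusters for the variable-profile loci.
#' @param seed Integer seed making the partition deterministic.
#' @return Integer assignment vector named by locus id. Values are in
#'   `1..n_clusters`, with constant loci (if any) in cluster
#'   `n_clusters + 1`.
#' @export
cluster_loci <- function(Y_train, n_clusters, seed = 1L) {
  v <- if (inherits(Y_train, "signal_matrix")) sm_values(Y_train) else Y_train
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1) stop("`n_clusters` must be >= 1", call. = FALSE)
  if (n_clusters > nrow(v)) stop("`n_clusters` exceeds the number of loci", call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  variable <- sds > 0
  assign <- integer(nrow(v))
  names(assign) <- rownames(v)
  if (any(variable)) {
    Z <- (v[variable, , drop = FALSE] - rowMeans(v[variable, , drop = FALSE])) /
      sds[variable]
    k <- min(n_clusters, nrow(unique(Z)))
    cl <- NULL
    for (try in 0:4) {  # rare empty-cluster starts: retry with a shifted seed
      cl <- tryCatch(
        withr::with_seed(seed + try * 1000L,
                         stats::kmeans(Z, centers = k, iter.max = 50, nstart = 1)),
        error = function(e) NULL)
      if (!is.null(cl)) break
    }
    if (is.null(cl)) stop("k-means failed to find a valid partition", call. = FALSE)
    assign[variable] <- cl$cluster
  }
  if (any(!variable)) assign[!variable] <- n_clusters + 1L
  assign
}

#' Train an accessibility prediction model
#'
#' Learns to predict log2 accessibility at every locus from a log2
#' expression profile. The model combines, per locus, a locus-level
#' regression on that locus's own best-correlated genes with cluster-level
#' regressions fitted to the mean profile of co-varying locus clusters at
#' several resolutions. Level predictions are averaged with per-locus
#' weights proportional to each level's within-training squared correlation
#' between fitted and observed signal.
#'
#' @param X A log2-scale `signal_matrix` of training expression, genes x
#'   samples.
#' @param Y A log2-scale `signal_matrix` of training accessibility, loci x
#'   samples, with identical sample ids in identical order as `X`.
#' @param cfg A [train_config()].
#' @param loci Optional `locus_set` giving genomic coordinates for Y's rows.
#' @return An object of class `accessibility_model`.
#' @export
train_accessibility_model <- function(X, Y, cfg = train_config(), loci = NULL) {
  stopifnot(inherits(X, "signal_matrix"), inherits(Y, "signal_matrix"),
            inherits(cfg, "train_config"))
  Xv <- sm_values(X)
  Yv <- sm_values(Y)
  if (!identical(colnames(Xv), colnames(Yv))) {
    stop("X and Y must share identical sample ids in identical order", call. = FALSE)
  }
  M <- ncol(Xv)
  if (M < 3) stop("need at least 3 training samples", call. = FALSE)

  # training-average expression distribution (sorted): the quantile reference
  qref <- rowMeans(apply(Xv, 2, sort))

  if (cfg$quantile_normalize) {
    Xn <- sm_values(quantile_normalize_to_reference(X, qref))
  } else {
    Xn <- Xv
  }

  keep <- apply(Yv, 1, max) >= cfg$min_signal
  Yk <- Yv[keep, , drop = FALSE]
  L <- nrow(Yk)
  if (L < 1) stop("no loci pass the training signal filter", call. = FALSE)

  K <- cfg$n_predictors
  if (K > nrow(Xn)) stop("n_predictors exceeds the number of genes", call. = FALSE)

  cluster_sizes <- cfg$cluster_sizes
  if (is.null(cluster_sizes)) {
    cluster_sizes <- unique(pmin(pmax(round(L / c(500, 100, 20)), 1L), L))
  }

  # gene-locus screening correlations, computed once
  gene_sd <- apply(Xn, 1, stats::sd)
  Xs <- (Xn - rowMeans(Xn))
  Xs <- ifelse(gene_sd > 0, 1 / gene_sd, 0) * Xs / sqrt(M - 1)

  fit_level <- function(targets) {
    # targets: profiles x samples; returns list(sel idx matrix, coef matrix, fitted)
    n <- nrow(targets)
    t_sd <- apply(targets, 1, stats::sd)
    Ts <- targets - rowMeans(targets)
    Ts <- ifelse(t_sd > 0, 1 / t_sd, 0) * Ts / sqrt(M - 1)
    R <- Xs %*% t(Ts)  # genes x profiles correlation matrix
    sel <- matrix(0L, n, K)
    coefs <- matrix(0, n, K + 1)
    fitted <- matrix(0, n, M)
    for (i in seq_len(n)) {
      s <- order(-abs(R[, i]), seq_len(nrow(R)))[seq_len(K)]
      b <- .fit_with_fallback(t(Xn[s, , drop = FALSE]), targets[i, ],
                              cfg$ridge_lambda)
      sel[i, ] <- s
      coefs[i, ] <- b
      fitted[i, ] <- b[1] + colSums(Xn[s, , drop = FALSE] * b[-1])
    }
    list(sel = sel, coefs = coefs, fitted = fitted)
  }

  locus_level <- fit_level(Yk)

  clusterings <- vector("list", length(cluster_sizes))
  level_fitted <- vector("list", 1 + length(cluster_sizes))
  level_fitted[[1]] <- locus_level$fitted
  for (h in seq_along(cluster_sizes)) {
    assign <- cluster_loci(signal_matrix(Yk, "log2"), cluster_sizes[h],
                           seed = cfg$seed + h)
    ids <- sort(unique(assign))
    centers <- t(vapply(ids, function(cid) {
      colMeans(Yk[assign == cid, , drop = FALSE])
    }, numeric(M)))
    cl_fit <- fit_level(centers)
    pos <- match(assign, ids)
    clusterings[[h]] <- list(n_clusters = cluster_sizes[h], assignment = assign,
                             cluster_ids = ids, sel = cl_fit$sel,
                             coefs = cl_fit$coefs)
    level_fitted[[1 + h]] <- cl_fit$fitted[pos, , drop = FALSE]
  }

  # model-averaging weights: within-training squared correlation per level
  H <- length(level_fitted)
  w <- matrix(0, L, H)
  for (h in seq_len(H)) {
    w[, h] <- .rowwise_pearson(level_fitted[[h]], Yk)^2
  }
  zero_rows <- rowSums(w) == 0
  w[zero_rows, ] <- 1 / H
  w <- w / rowSums(w)

  if (!is.null(loci)) {
    loci <- loci[match(rownames(Yk), loci$locus_id), , drop = FALSE]
  }

  structure(list(
    gene_ids = rownames(Xv),
    quantile_reference = qref,
    locus_ids = rownames(Yk),
    locus_set = loci,
    locus_keep = keep,
    mean_profile = rowMeans(Yk),
    locus_models = list(sel = locus_level$sel, coefs = locus_level$coefs),
    clusterings = clusterings,
    weights = w,
    train_sample_ids = colnames(Xv),
    config = cfg,
    schema_version = 1L
  ), class = "accessibility_model")
}

#' @export
print.accessibility_model <- function(x, ...) {
  cat(sprintf(paste0("<accessibility_model> %d loci, %d genes, %d training ",
                     "samples\n  cluster resolutions: %s; K = %d predictors; ",
                     "quantile normalization: %s\n"),
              length(x$locus_ids), length(x$gene_ids),
              length(x$train_sample_ids),
              paste(vapply(x$clusterings, function(cl) cl$n_clusters, 1L),
                    collapse = ", "),
              x$config$n_predictors,
              x$config$quantile_normalize))
  invisible(x)
}

#' Predict accessibility for new expression profiles
#'
#' Per sample: (optional log2 transform of raw input) -> quantile
#' normalization to the model's training reference (if the model was
#' trained with it) -> locus-level and cluster-level linear predictions ->
#' per-locus weighted average. Predictions are floored at 0 since log2
#' accessibility (log2(signal + 1)) is non-negative.
#'
#' @param model An `accessibility_model`.
#' @param X_new A `signal_matrix` of expression, genes x new samples. Row
#'   ids are matched to the model's genes by exact identifier; missing
#'   genes raise an error listing them.
#' @param already_log2 If `FALSE`, the input is raw-scale and is
#'   log2(x + 1)-transformed first.
#' @return A log2-scale `signal_matrix` of predictions, loci x samples, in
#'   the model's locus order.
#' @export
predict_accessibility <- function(model, X_new, already_log2 = TRUE) {
  stopifnot(inherits(model, "accessibility_model"),
            inherits(X_new, "signal_matrix"))
  miss <- setdiff(model$gene_ids, row_ids(X_new))
  if (length(miss) > 0) {
    stop("genes required by the model are missing from the input: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" ... (%d total)", length(miss)) else "",
         call. = FALSE)
  }
  v <- sm_values(X_new)[model$gene_ids, , drop = FALSE]
  if (!already_log2) {
    if (sm_scale(X_new) == "log2") {
      stop("input is tagged log2 but `already_log2 = FALSE`", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative values in input declared raw-scale; wrong scale flag?",
           call. = FALSE)
    }
    v <- log2(v + 1)
  }
  if (model$config$quantile_normalize) {
    v <- sm_values(quantile_normalize_to_reference(
      signal_matrix(v, "log2"), model$quantile_reference))
  }

  L <- length(model$locus_ids)
  M <- ncol(v)
  predict_level <- function(sel, coefs) {
    out <- matrix(0, nrow(sel), M)
    for (i in seq_len(nrow(sel))) {
      out[i, ] <- coefs[i, 1] +
        colSums(v[sel[i, ], , drop = FALSE] * coefs[i, -1])
    }
    out
  }
  pred <- model$weights[, 1] * predict_level(model$locus_models$sel,
                                             model$locus_models$coefs)
  for (h in seq_along(model$clusterings)) {
    cl <- model$clusterings[[h]]
    cl_pred <- predict_level(cl$sel, cl$coefs)
    pos <- match(cl$assignment, cl$cluster_ids)
    pred <- pred + model$weights[, 1 + h] * cl_pred[pos, , drop = FALSE]
  }
  pred <- pmax(pred, 0)
  dimnames(pred) <- list(model$locus_ids, colnames(v))
  signal_matrix(pred, scale = "log2")
}

#' Train a permutation-control model
#'
#' Shuffles the accessibility sample columns before training, breaking the
#' pairing between expression and accessibility while preserving the locus
#' effects (each locus keeps its own set of values). The resulting model is
#' the random-prediction control: its cross-sample accuracy should be near
#' zero while its cross-locus accuracy reflects locus effects only.
#'
#' @inheritParams train_accessibility_model
#' @param perm_seed Seed for the uniform random permutation.
#' @param permutation Optional explicit permutation of `1..M` overriding
#'   the random draw (e.g. the identity, for testing).
#' @return An `accessibility_model`.
#' @export
train_permuted_model <- function(X, Y, cfg = train_config(), perm_seed = 1L,
                                 permutation = NULL, loci = NULL) {
  Yv <- sm_values(Y)
  M <- ncol(Yv)
  if (is.null(permutation)) {
    permutation <- withr::with_seed(as.integer(perm_seed), sample.int(M))
  }
  stopifnot(length(permutation) == M, all(sort(permutation) == seq_len(M)))
  Yp <- Yv[, permutation, drop = FALSE]
  colnames(Yp) <- colnames(Yv)  # re-pair shuffled columns with X's samples
  train_accessibility_model(X, signal_matrix(Yp, sm_scale(Y)), cfg, loci = loci)
}

#' Predict with the training mean profile
#'
#' The trivial baseline: every output column is the model's mean training
#' accessibility profile. It captures locus effects (so its cross-locus
#' correlation is well above zero) but is constant across samples, so its
#' cross-sample correlation is 0 at every locus by the zero-variance
#' convention.
#'
#' @param model An `accessibility_model`.
#' @param n_samples Number of identical output columns.
#' @param sample_ids Optional column names (default `mean_1..mean_n`).
#' @return A log2-scale `signal_matrix`.
#' @export
mean_profile_predict <- function(model, n_samples = 1L,
                                 sample_ids = NULL) {
  stopifnot(inherits(model, "accessibility_model"), n_samples >= 1)
  if (is.null(sample_ids)) sample_ids <- sprintf("mean_%d", seq_len(n_samples))
  v <- matrix(model$mean_profile, nrow = length(model$locus_ids),
              ncol = n_samples, dimnames = list(model$locus_ids, sample_ids))
  signal_matrix(v, scale = "log2")
}

#' Tidy an accessibility model
#'
#' @param x An `accessibility_model`.
#' @param ... Unused.
#' @return A tibble with one row per locus: locus id, mean training signal,
#'   and the model-averaging weight of each level (`w_locus`,
#'   `w_cluster_<n>`).
#' @method tidy accessibility_model
#' @export
tidy.accessibility_model <- function(x, ...) {
  w <- x$weights
  colnames(w) <- c("w_locus", vapply(x$clusterings, function(cl) {
    sprintf("w_cluster_%d", cl$n_clusters)
  }, character(1)))
  dplyr::bind_cols(
    tibble::tibble(locus_id = x$locus_ids, mean_signal = unname(x$mean_profile)),
    tibble::as_tibble(w)
  )
}

#' Summarize an accessibility model in one row
#'
#' @param x An `accessibility_model`.
#' @param ... Unused.
#' @return A one-row tibble: counts of loci, genes and training samples,
#'   number of cluster resolutions, predictors per regression, and the
#'   mean locus-level weight.
#' @method glance accessibility_model
#' @export
glance.accessibility_model <- function(x, ...) {
  tibble::tibble(
    n_loci = length(x$locus_ids),
    n_genes = length(x$gene_ids),
    n_train_samples = length(x$train_sample_ids),
    n_cluster_resolutions = length(x$clusterings),
    n_predictors = x$config$n_predictors,
    mean_locus_weight = mean(x$weights[, 1])
  )
}
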
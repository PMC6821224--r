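#' Plan for pooling single cells into pseudo-bulk profiles
#'
#' @param k Cells per pool (1..number of cells).
#' @param R Number of replicate pools (default 10). When `k` equals the
#'   number of available cells there is only one possible pool, so `R`
#'   collapses to 1.
#' @param seed Integer seed for the random draws.
#' @param exhaustive If `TRUE` with `k = 1`, every cell is returned once in
#'   order instead of sampling (the single-cell analysis is performed for
#'   every cell).
#' @return A list of class `pooling_plan`.
#' @export
pooling_plan <- function(k, R = 10L, seed = 1L, exhaustive = FALSE) {
  k <- as.integer(k)
  R <- as.integer(R)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  structure(list(k = k, R = R, seed = as.integer(seed),
                 exhaustive = isTRUE(exhaustive)),
            class = "pooling_plan")
}

#' Pool single cells into pseudo-bulk expression profiles
#'
#' Each replicate draws `k` distinct cells without replacement (draws are
#' independent across replicates) and averages their expression per gene;
#' the average profile is what gets fed to the accessibility predictor.
#'
#' @param sc_expr A `signal_matrix` with cells as columns.
#' @param plan A [pooling_plan()].
#' @return A `signal_matrix` (genes x replicates) of pooled profiles, with
#'   the cells used per replicate attached as attribute `"cells"`.
#' @export
pool_cells <- function(sc_expr, plan) {
  stopifnot(inherits(sc_expr, "signal_matrix"), inherits(plan, "pooling_plan"))
  v <- sm_values(sc_expr)
  n <- ncol(v)
  if (plan$k > n) stop("`k` exceeds the number of cells", call. = FALSE)
  if (plan$exhaustive && plan$k == 1) {
    pools <- as.list(seq_len(n))
  } else if (plan$k == n) {
    pools <- list(seq_len(n))
  } else {
    pools <- withr::with_seed(plan$seed, lapply(seq_len(plan$R), function(r) {
      sort(sample.int(n, plan$k))
    }))
  }
  out <- vapply(pools, function(idx) rowMeans(v[, idx, drop = FALSE]),
                numeric(nrow(v)))
  dimnames(out) <- list(rownames(v), sprintf("pool_%d", seq_along(pools)))
  res <- signal_matrix(out, scale = sm_scale(sc_expr))
  attr(res, "cells") <- lapply(pools, function(idx) colnames(v)[idx])
  res
}

#' Mix two expression profiles in given cell proportions
#'
#' Emulates a heterogeneous sample: the pooled profile of `cells_a` cells
#' of type A and `cells_b` cells of type B is the cell-count-weighted mean
#' of the two type profiles.
#'
#' @param expr_a,expr_b Numeric vectors (aligned genes).
#' @param cells_a,cells_b Non-negative cell counts, not both zero.
#' @return The mixed profile vector.
#' @export
mix_proportions <- function(expr_a, expr_b, cells_a, cells_b) {
  if (length(expr_a) != length(expr_b)) stop("profiles must be aligned",
                                             call. = FALSE)
  if (cells_a < 0 || cells_b < 0 || cells_a + cells_b == 0) {
    stop("cell counts must be non-negative and not both zero", call. = FALSE)
  }
  w <- cells_a / (cells_a + cells_b)
  w * expr_a + (1 - w) * expr_b
}

#' Combine predicted accessibility with measured ATAC-seq signal
#'
#' The hybrid signal is the unweighted elementwise mean of a predicted
#' log2 accessibility profile and a measured (sc)ATAC-seq log2 profile on
#' the same locus grid; measuring some cells by ATAC-seq and predicting
#' from the RNA-seq of the rest yields a better profile than either alone.
#'
#' @param bird_pred,atac_signal Numeric vectors (or one-column
#'   `signal_matrix`) on the model's locus grid, both log2 scale.
#' @param weight Weight on the predicted profile (default 0.5, the plain
#'   average).
#' @return The combined profile vector.
#' @export
hybrid_combine <- function(bird_pred, atac_signal, weight = 0.5) {
  as_vec <- function(x) if (inherits(x, "signal_matrix")) drop(sm_values(x)) else x
  p <- as_vec(bird_pred)
  a <- as_vec(atac_signal)
  if (length(p) != length(a)) stop("profiles must be on the same locus grid",
                                   call. = FALSE)
  if (weight < 0 || weight > 1) stop("`weight` must be in [0, 1]", call. = FALSE)
  weight * p + (1 - weight) * a
}

#' Distance between a new expression profile and the training space
#'
#' Computes `1 - max_j cor(x_new, training sample j)` over the model's
#' genes, after quantile-normalizing the new profile to the training
#' reference (when the model uses normalization). Advisory bands follow
#' the observed relationship between this distance and prediction
#' accuracy: accuracy is high and stable below 0.5, starts dropping
#' between 0.5 and 0.8, and beyond 0.8 the model is extrapolating.
#'
#' @param model An `accessibility_model` carrying `train_expression`
#'   (stored by [run_cli()] workflows) or an explicit `train_expr`.
#' @param x_new Numeric vector of log2 expression named by gene, or a
#'   one-column `signal_matrix`.
#' @param train_expr A `signal_matrix` of the training expression
#'   (genes x samples) if not stored on the model.
#' @param method `"nearest"` (1 - max correlation, default) or `"mean"`
#'   (1 - mean correlation).
#' @return A list of class `distance_report`: `distance`,
#'   `nearest_sample`, `band` (`"stable"`, `"caution"` or
#'   `"extrapolating"`), and the per-training-sample correlations.
#' @export
training_test_distance <- function(model, x_new, train_expr = NULL,
                                   method = c("nearest", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "accessibility_model"))
  if (is.null(train_expr)) train_expr <- model$train_expression
  if (is.null(train_expr)) {
    stop("training expression is required (pass `train_expr`)", call. = FALSE)
  }
  tv <- sm_values(train_expr)[model$gene_ids, , drop = FALSE]
  if (inherits(x_new, "signal_matrix")) x_new <- drop(sm_values(x_new))
  miss <- setdiff(model$gene_ids, names(x_new))
  if (length(miss) > 0) {
    stop("genes missing from the new profile: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  x <- x_new[model$gene_ids]
  if (model$config$quantile_normalize) {
    x <- drop(sm_values(quantile_normalize_to_reference(
      signal_matrix(matrix(x, ncol = 1,
                           dimnames = list(model$gene_ids, "new")), "log2"),
      model$quantile_reference)))
    tv <- sm_values(quantile_normalize_to_reference(
      signal_matrix(tv, "log2"), model$quantile_reference))
  }
  cors <- apply(tv, 2, function(col) pearson_cor(x, col))
  d <- if (method == "nearest") 1 - max(cors) else 1 - mean(cors)
  band <- if (d < 0.5) "stable" else if (d <= 0.8) "caution" else "extrapolating"
  structure(list(distance = d,
                 nearest_sample = colnames(tv)[which.max(cors)],
                 band = band,
                 correlations = tibble::tibble(sample_id = colnames(tv),
                                               cor = unname(cors))),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> distance = %.3f (%s), nearest: %s\n",
              x$distance, x$band, x$nearest_sample))
  invisible(x)
}

#' Validate an externally imputed single-cell expression matrix
#'
#' Sparse droplet-based single-cell data are imputed by an external method
#' before prediction; this checks the imputed matrix against the raw one
#' (same ids, finite, non-negative, no cell zeroed out entirely) and
#' passes it through. A deliberately simple fallback imputer — replacing
#' zeros with the gene's mean over non-zero cells — is available for
#' testing pipelines without an external tool.
#'
#' @param raw_sc,imputed_sc `signal_matrix` objects with identical gene and
#'   cell ids. With `fallback = TRUE`, `imputed_sc` may be omitted and is
#'   computed from `raw_sc`.
#' @param fallback If `TRUE`, run the mean-of-nonzero fallback imputer on
#'   `raw_sc` instead of validating an external result.
#' @return The checked (or fallback-imputed) `signal_matrix`.
#' @export
validate_imputed <- function(raw_sc, imputed_sc = NULL, fallback = FALSE) {
  stopifnot(inherits(raw_sc, "signal_matrix"))
  rv <- sm_values(raw_sc)
  if (fallback) {
    gene_means <- apply(rv, 1, function(r) {
      nz <- r[r > 0]
      if (length(nz) == 0) 0 else mean(nz)
    })
    iv <- rv
    zero <- iv == 0
    iv[zero] <- matrix(gene_means, nrow(iv), ncol(iv))[zero]
    return(signal_matrix(iv, scale = sm_scale(raw_sc)))
  }
  stopifnot(inherits(imputed_sc, "signal_matrix"))
  iv <- sm_values(imputed_sc)
  if (!identical(rownames(rv), rownames(iv)) ||
      !identical(colnames(rv), colnames(iv))) {
    stop("raw and imputed matrices must share gene and cell ids", call. = FALSE)
  }
  if (any(!is.finite(iv))) stop("imputed values must be finite", call. = FALSE)
  if (any(iv < 0)) stop("imputed values must be non-negative", call. = FALSE)
  dead <- colSums(iv) == 0 & colSums(rv) > 0
  if (any(dead)) {
    stop("imputation zeroed out cell(s) entirely: ",
         paste(colnames(iv)[dead], collapse = ", "), call. = FALSE)
  }
  imputed_sc
}

#' Motif binding activity per cell, along pseudotime
#'
#' A transcription factor's binding activity in a cell is inferred as the
#' mean predicted accessibility over all loci containing its motif. When a
#' pseudotime ordering is supplied, activities are joined to it so the
#' activity trend can be followed along each lineage.
#'
#' @param pred_cells A `signal_matrix` of predictions over cells
#'   (loci x cells).
#' @param motif_mask Logical vector (one entry per locus) marking the
#'   motif-containing loci; at least one must be `TRUE`.
#' @param pseudotime Optional tibble with columns `cell_id`, `lineage`,
#'   `pseudotime_rank` covering a subset of the cells.
#' @return A tibble with columns `cell_id`, `activity`, plus `lineage` and
#'   `pseudotime_rank` (ordered within lineage) when pseudotime is given.
#' @export
motif_activity <- function(pred_cells, motif_mask, pseudotime = NULL) {
  v <- sm_values(pred_cells)
  if (length(motif_mask) != nrow(v)) {
    stop("`motif_mask` must have one entry per locus", call. = FALSE)
  }
  if (!any(motif_mask)) stop("`motif_mask` selects no loci", call. = FALSE)
  act <- colMeans(v[motif_mask, , drop = FALSE])
  out <- tibble::tibble(cell_id = colnames(v), activity = unname(act))
  if (!is.null(pseudotime)) {
    out <- dplyr::inner_join(pseudotime, out, by = "cell_id") |>
      dplyr::arrange(.data$lineage, .data$pseudotime_rank)
  }
  out
}

#' Read a pseudotime ordering table
#'
#' @param path TSV with columns `cell_id`, `lineage`, `pseudotime_rank`.
#' @return A tibble.
#' @export
read_pseudotime <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell_id = readr::col_character(),
    lineage = readr::col_character(),
    pseudotime_rank = readr::col_double()
  ), progress = FALSE)
}
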
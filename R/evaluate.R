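#' Cross-locus correlation within each sample
#'
#' For every sample, the Pearson correlation between predicted and true
#' accessibility across all loci (the r_L statistic). Large values can
#' reflect locus effects alone; see [cross_sample_cor()] for the statistic
#' that cannot.
#'
#' @param pred,truth Log2-scale `signal_matrix` objects with aligned loci
#'   (same row ids in the same order) and the same samples.
#' @return A tibble with columns `sample_id`, `r_l`.
#' @export
cross_locus_cor <- function(pred, truth) {
  p <- sm_values(pred)
  t_ <- sm_values(truth)
  .check_aligned(p, t_)
  tibble::tibble(
    sample_id = colnames(p),
    r_l = unname(.rowwise_pearson(t(p), t(t_)))
  )
}

#' Cross-sample correlation at each locus
#'
#' For every locus, the Pearson correlation between predicted and true
#' accessibility across samples (the r_C statistic). Baseline locus effects
#' cancel within a locus, so r_C isolates the ability to predict how
#' accessibility changes between samples; a predictor that is constant
#' across samples scores exactly 0 by the zero-variance convention.
#'
#' @inheritParams cross_locus_cor
#' @return A tibble with columns `locus_id`, `r_c`.
#' @export
cross_sample_cor <- function(pred, truth) {
  p <- sm_values(pred)
  t_ <- sm_values(truth)
  .check_aligned(p, t_)
  if (ncol(p) < 2) stop("need at least 2 samples for cross-sample correlation",
                        call. = FALSE)
  tibble::tibble(
    locus_id = rownames(p),
    r_c = unname(.rowwise_pearson(p, t_))
  )
}

.check_aligned <- function(p, t_) {
  if (!identical(dim(p), dim(t_)) ||
      !identical(rownames(p), rownames(t_)) ||
      !identical(colnames(p), colnames(t_))) {
    stop("prediction and truth must share identical loci and samples",
         call. = FALSE)
  }
}

#' Evaluate predictions against true accessibility
#'
#' @inheritParams cross_locus_cor
#' @param activity_threshold Log2 threshold used for the specificity
#'   category (see [locus_categories()]).
#' @return A list of class `accessibility_eval` with tibbles `r_l` (per
#'   sample) and `r_c` (per locus, including category labels computed on
#'   the predicted signal), plus `summary` (one row of means).
#' @export
evaluate_predictions <- function(pred, truth, activity_threshold = 2.0) {
  r_l <- cross_locus_cor(pred, truth)
  r_c <- cross_sample_cor(pred, truth)
  cats <- locus_categories(pred, activity_threshold = activity_threshold)
  r_c <- dplyr::left_join(r_c, cats, by = "locus_id")
  structure(list(
    r_l = r_l,
    r_c = r_c,
    summary = tibble::tibble(mean_r_l = mean(r_l$r_l), mean_r_c = mean(r_c$r_c))
  ), class = "accessibility_eval")
}

#' @export
print.accessibility_eval <- function(x, ...) {
  cat(sprintf("<accessibility_eval> %d samples, %d loci\n",
              nrow(x$r_l), nrow(x$r_c)))
  cat(sprintf("  mean r_L = %.3f, mean r_C = %.3f\n",
              x$summary$mean_r_l, x$summary$mean_r_c))
  invisible(x)
}

#' @method tidy accessibility_eval
#' @export
tidy.accessibility_eval <- function(x, ...) x$r_c

#' @method glance accessibility_eval
#' @export
glance.accessibility_eval <- function(x, ...) x$summary

#' Leave-one-cell-type-out cross-validation
#'
#' Partitions the samples by cell type; in each fold all samples of one
#' cell type are held out and a model is trained on the remaining types
#' only (the quantile reference, locus filter, clustering and all
#' regressions are recomputed within the fold, so no held-out information
#' leaks into training). Predictions are concatenated across folds before
#' computing cross-sample correlations.
#'
#' @param X,Y Log2-scale training expression and accessibility matrices
#'   with identical sample ids.
#' @param cell_type_of_sample Character vector of cell-type labels, one per
#'   sample; replicates of a type share the label. At least 3 distinct
#'   types are required.
#' @param cfg A [train_config()].
#' @param permute If `TRUE`, each fold trains the permutation-control model
#'   instead ([train_permuted_model()]).
#' @param perm_seed Base seed for fold-wise permutations.
#' @param predictor One of `"model"` (default) or `"mean_profile"`; the
#'   latter evaluates the trivial mean-profile baseline under the same
#'   folds.
#' @return An `accessibility_eval` whose `r_l` tibble gains `cell_type` and
#'   `fold` columns. `r_c` is computed over loci retained by the training
#'   filter in every fold.
#' @export
loocv_evaluate <- function(X, Y, cell_type_of_sample, cfg = train_config(),
                           permute = FALSE, perm_seed = 1L,
                           predictor = c("model", "mean_profile")) {
  predictor <- match.arg(predictor)
  Xv <- sm_values(X)
  Yv <- sm_values(Y)
  if (length(cell_type_of_sample) != ncol(Xv)) {
    stop("one cell-type label per sample is required", call. = FALSE)
  }
  types <- unique(cell_type_of_sample)
  if (length(types) < 3) stop("need at least 3 distinct cell types", call. = FALSE)
  if (length(types) == length(cell_type_of_sample) &&
      length(types) == 1) {
    stop("degenerate fold: a single cell type holds all samples", call. = FALSE)
  }

  pred_cols <- vector("list", length(types))
  rl_rows <- vector("list", length(types))
  kept_loci <- vector("list", length(types))

  for (f in seq_along(types)) {
    held <- cell_type_of_sample == types[f]
    if (all(held)) stop("degenerate fold: one cell type holds all samples",
                        call. = FALSE)
    Xtr <- signal_matrix(Xv[, !held, drop = FALSE], sm_scale(X))
    Ytr <- signal_matrix(Yv[, !held, drop = FALSE], sm_scale(Y))
    model <- if (permute) {
      train_permuted_model(Xtr, Ytr, cfg, perm_seed = as.integer(perm_seed) + f)
    } else {
      train_accessibility_model(Xtr, Ytr, cfg)
    }
    Xte <- signal_matrix(Xv[, held, drop = FALSE], sm_scale(X))
    pred <- if (predictor == "mean_profile") {
      mean_profile_predict(model, sum(held), sample_ids = colnames(Xv)[held])
    } else {
      predict_accessibility(model, Xte)
    }
    truth_f <- signal_matrix(Yv[model$locus_ids, held, drop = FALSE], "log2")
    rl <- cross_locus_cor(pred, truth_f)
    rl$cell_type <- types[f]
    rl$fold <- f
    rl_rows[[f]] <- rl
    pred_cols[[f]] <- pred
    kept_loci[[f]] <- model$locus_ids
  }

  common <- Reduce(intersect, kept_loci)
  pred_all <- do.call(cbind, lapply(pred_cols, function(p) {
    sm_values(p)[common, , drop = FALSE]
  }))
  pred_all <- pred_all[, colnames(Yv), drop = FALSE]
  truth_all <- Yv[common, , drop = FALSE]
  r_c <- cross_sample_cor(signal_matrix(pred_all, "log2"),
                          signal_matrix(truth_all, "log2"))
  r_l <- dplyr::bind_rows(rl_rows)
  cats <- locus_categories(signal_matrix(pred_all, "log2"))
  r_c <- dplyr::left_join(r_c, cats, by = "locus_id")
  structure(list(
    r_l = r_l,
    r_c = r_c,
    predictions = signal_matrix(pred_all, "log2"),
    summary = tibble::tibble(mean_r_l = mean(r_l$r_l), mean_r_c = mean(r_c$r_c))
  ), class = "accessibility_eval")
}

#' Two-sided Wilcoxon signed-rank test on paired statistics
#'
#' Used to compare the per-sample (r_L) or per-locus (r_C) accuracy of two
#' methods. Zero differences are dropped; the exact distribution is used
#' for n <= 25 untied differences, the normal approximation beyond.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return The two-sided p-value.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length",
                                   call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(1)
  }
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = use_exact,
                                             correct = !use_exact))
  unname(res$p.value)
}

#' Categorize loci by spread, variability and specificity
#'
#' Per locus, three statistics over samples: spread = max - min; CV =
#' sd / mean (mean floored at machine epsilon); specificity count =
#' min(number of samples with value >= `activity_threshold`, number
#' below). Each is split low/high at its median over loci; a small
#' specificity count means the locus is active (or inactive) in only a few
#' samples, i.e. highly cell-type specific.
#'
#' @param signal A `signal_matrix` with >= 2 samples (typically the
#'   predicted signal of the test samples).
#' @param activity_threshold Log2 value above which a locus counts as
#'   active in a sample (default 2.0).
#' @return A tibble with columns `locus_id`, `spread`, `cv`,
#'   `specificity_count`, and the labels `spread_high`, `cv_high`,
#'   `specificity_high` (logical).
#' @export
locus_categories <- function(signal, activity_threshold = 2.0) {
  v <- sm_values(signal)
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  spread <- apply(v, 1, max) - apply(v, 1, min)
  mu <- pmax(rowMeans(v), .Machine$double.eps)
  cv <- apply(v, 1, stats::sd) / mu
  n_active <- rowSums(v >= activity_threshold)
  spec <- pmin(n_active, ncol(v) - n_active)
  tibble::tibble(
    locus_id = rownames(v),
    spread = unname(spread),
    cv = unname(cv),
    specificity_count = unname(spec),
    spread_high = spread >= stats::median(spread),
    cv_high = cv >= stats::median(cv),
    specificity_high = spec <= stats::median(spec)
  )
}

#' Mean cross-sample correlation after filtering unpredictable loci
#'
#' Drops loci labelled low spread, low CV, or high specificity (categories
#' computed on the predicted signal, as evaluation must not peek at the
#' truth) and reports the mean r_C over the survivors.
#'
#' @param report An `accessibility_eval` whose `r_c` tibble carries
#'   category labels.
#' @param drop Character subset of
#'   `c("low_spread", "low_cv", "high_specificity")`; loci matching any
#'   selected label are removed.
#' @return A list with `mean_r_c` (over surviving loci), `n_kept`, and
#'   `mask` (logical keep vector named by locus id).
#' @export
filtered_mean_rc <- function(report,
                             drop = c("low_spread", "low_cv", "high_specificity")) {
  drop <- match.arg(drop, several.ok = TRUE)
  rc <- report$r_c
  keep <- rep(TRUE, nrow(rc))
  if ("low_spread" %in% drop) keep <- keep & rc$spread_high
  if ("low_cv" %in% drop) keep <- keep & rc$cv_high
  if ("high_specificity" %in% drop) keep <- keep & !rc$specificity_high
  if (!any(keep)) stop("no loci survive the filters", call. = FALSE)
  names(keep) <- rc$locus_id
  list(mean_r_c = mean(rc$r_c[keep]), n_kept = sum(keep), mask = keep)
}

#' Benchmark differential-accessibility prediction between two cell types
#'
#' The differential signal is the per-locus log2 difference A - B.
#' Differential loci are those with |true difference| > 1 after excluding
#' loci whose true log2 level is below 1 in both cell types. Performance is
#' the Pearson correlation between predicted and true differences over all
#' loci and over the differential loci.
#'
#' @param pred_a,pred_b Predicted log2 profiles (numeric vectors or
#'   one-column `signal_matrix`), aligned by locus.
#' @param truth_a,truth_b True log2 profiles, same alignment.
#' @return A list of class `differential_result`: tibble `per_locus`
#'   (predicted and true delta, `differential` mask), `cor_all`,
#'   `cor_differential` (NA with a warning when no locus is differential),
#'   and `n_differential`.
#' @export
differential_benchmark <- function(pred_a, pred_b, truth_a, truth_b) {
  as_vec <- function(x) if (inherits(x, "signal_matrix")) drop(sm_values(x)) else x
  pa <- as_vec(pred_a); pb <- as_vec(pred_b)
  ta <- as_vec(truth_a); tb <- as_vec(truth_b)
  n <- length(pa)
  if (length(pb) != n || length(ta) != n || length(tb) != n) {
    stop("all four locus vectors must be aligned and of equal length",
         call. = FALSE)
  }
  delta_pred <- pa - pb
  delta_true <- ta - tb
  expressed <- ta >= 1 | tb >= 1
  mask <- expressed & abs(delta_true) > 1
  cor_all <- pearson_cor(delta_pred, delta_true)
  if (any(mask)) {
    cor_diff <- if (sum(mask) >= 2) {
      pearson_cor(delta_pred[mask], delta_true[mask])
    } else NA_real_
  } else {
    warning("no differential loci after filtering; correlation undefined",
            call. = FALSE)
    cor_diff <- NA_real_
  }
  ids <- names(pa)
  if (is.null(ids)) ids <- sprintf("locus_%d", seq_len(n))
  structure(list(
    per_locus = tibble::tibble(locus_id = ids,
                               delta_pred = unname(delta_pred),
                               delta_true = unname(delta_true),
                               differential = unname(mask)),
    cor_all = cor_all,
    cor_differential = cor_diff,
    n_differential = sum(mask)
  ), class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> %d loci, %d differential\n",
              nrow(x$per_locus), x$n_differential))
  cat(sprintf("  r(all) = %.3f, r(differential) = %s\n", x$cor_all,
              ifelse(is.na(x$cor_differential), "undefined",
                     sprintf("%.3f", x$cor_differential))))
  invisible(x)
}

#' @method tidy differential_result
#' @export
tidy.differential_result <- function(x, ...) x$per_locus

#' @method glance differential_result
#' @export
glance.differential_result <- function(x, ...) {
  tibble::tibble(cor_all = x$cor_all, cor_differential = x$cor_differential,
                 n_differential = x$n_differential)
}
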
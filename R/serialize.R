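#' Save a trained model to a JSON archive
#'
#' The archive is a single self-describing JSON file holding the
#' configuration, quantile reference, mean profile, per-locus and
#' per-cluster regressions, cluster assignments and averaging weights,
#' under a versioned schema field.
#'
#' @param model An `accessibility_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "accessibility_model"))
  obj <- list(
    schema_version = model$schema_version,
    config = unclass(model$config),
    gene_ids = model$gene_ids,
    quantile_reference = model$quantile_reference,
    locus_ids = model$locus_ids,
    locus_set = if (!is.null(model$locus_set)) {
      list(chrom = model$locus_set$chrom, start = model$locus_set$start,
           end = model$locus_set$end, locus_id = model$locus_set$locus_id)
    },
    locus_keep = unname(model$locus_keep),
    mean_profile = unname(model$mean_profile),
    locus_models = list(sel = model$locus_models$sel,
                        coefs = model$locus_models$coefs),
    clusterings = lapply(model$clusterings, function(cl) {
      list(n_clusters = cl$n_clusters, assignment = unname(cl$assignment),
           cluster_ids = cl$cluster_ids, sel = cl$sel, coefs = cl$coefs)
    }),
    weights = model$weights,
    train_sample_ids = model$train_sample_ids
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model saved by [write_model()]
#'
#' @param path JSON archive path.
#' @return An `accessibility_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported model schema version", call. = FALSE)
  }
  cfg <- train_config(
    n_predictors = obj$config$n_predictors,
    cluster_sizes = obj$config$cluster_sizes,
    ridge_lambda = obj$config$ridge_lambda,
    seed = obj$config$seed,
    min_signal = obj$config$min_signal,
    quantile_normalize = obj$config$quantile_normalize
  )
  loci <- NULL
  if (!is.null(obj$locus_set)) {
    ls_df <- obj$locus_set
    loci <- locus_set(ls_df$chrom, ls_df$start, ls_df$end, ls_df$locus_id,
                      width = unique(ls_df$end - ls_df$start))
  }
  keep <- as.logical(obj$locus_keep)
  structure(list(
    gene_ids = obj$gene_ids,
    quantile_reference = as.numeric(obj$quantile_reference),
    locus_ids = obj$locus_ids,
    locus_set = loci,
    locus_keep = keep,
    mean_profile = stats::setNames(as.numeric(obj$mean_profile), obj$locus_ids),
    locus_models = list(sel = matrix(as.integer(obj$locus_models$sel),
                                     nrow = length(obj$locus_ids)),
                        coefs = matrix(as.numeric(obj$locus_models$coefs),
                                       nrow = length(obj$locus_ids))),
    clusterings = lapply(obj$clusterings, function(cl) {
      list(n_clusters = as.integer(cl$n_clusters),
           assignment = stats::setNames(as.integer(cl$assignment), obj$locus_ids),
           cluster_ids = as.integer(cl$cluster_ids),
           sel = matrix(as.integer(cl$sel), nrow = length(cl$cluster_ids)),
           coefs = matrix(as.numeric(cl$coefs), nrow = length(cl$cluster_ids)))
    }),
    weights = matrix(as.numeric(obj$weights), nrow = length(obj$locus_ids)),
    train_sample_ids = obj$train_sample_ids,
    config = cfg,
    schema_version = 1L
  ), class = "accessibility_model")
}
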
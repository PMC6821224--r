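#' Construct a set of motif sites
#'
#' @param chrom,start,end Site intervals, 0-based half-open.
#' @param strand `"+"`, `"-"` or `"."` per site (default `"."`).
#' @param motif_score Numeric motif match score per site.
#' @return A tibble of class `motif_site_set`, sorted by (chrom, start)
#'   with a `site_id` column.
#' @export
motif_site_set <- function(chrom, start, end, strand = ".", motif_score = 0) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("every site must satisfy start < end", call. = FALSE)
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                        strand = rep_len(as.character(strand), length(start)),
                        motif_score = rep_len(as.numeric(motif_score),
                                              length(start)))
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  out$site_id <- sprintf("site_%05d", seq_len(nrow(out)))
  class(out) <- c("motif_site_set", class(out))
  out
}

#' Read motif sites from a BED6 file
#'
#' Columns: chrom, start, end, name, score, strand. The score column is
#' used as the motif score.
#'
#' @param path BED file path.
#' @return A `motif_site_set`.
#' @export
read_motif_bed <- function(path) {
  df <- .read_bedlike(path)
  motif_site_set(df[[1]], df[[2]], df[[3]],
                 strand = if (ncol(df) >= 6) df[[6]] else ".",
                 motif_score = if (ncol(df) >= 5) df[[5]] else 0)
}

#' Read gold-standard peaks from a narrowPeak or BED file
#'
#' Only the interval columns are used.
#'
#' @param path narrowPeak/BED file path.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_peaks_bed <- function(path) {
  df <- .read_bedlike(path)
  tibble::tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                 end = as.integer(df[[3]]))
}

.sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  )
}

#' Score motif sites by predicted accessibility
#'
#' Each site's score is the maximum predicted accessibility over the loci
#' overlapping it (a motif site can be wider than one bin). Sites
#' overlapping no locus get `-Inf` and rank last. Ties in predicted
#' accessibility break by motif score descending, then coordinate.
#'
#' @param sites A `motif_site_set`.
#' @param loci A `locus_set` aligned with the prediction rows.
#' @param pred A `signal_matrix` of predictions (loci x samples).
#' @param sample Sample id or column index selecting one prediction column.
#' @return The sites tibble with an added `dh_score` column, ordered from
#'   best to worst.
#' @export
score_sites <- function(sites, loci, pred, sample = 1L) {
  stopifnot(inherits(sites, "motif_site_set"), inherits(loci, "locus_set"))
  v <- sm_values(pred)
  if (nrow(v) != nrow(loci)) stop("prediction rows must align with loci",
                                  call. = FALSE)
  col <- v[, sample]
  hits <- GenomicRanges::findOverlaps(.sites_granges(sites), .as_granges(loci))
  score <- rep(-Inf, nrow(sites))
  if (length(hits) > 0) {
    agg <- tapply(col[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    score[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- sites
  out$dh_score <- score
  dplyr::arrange(out, dplyr::desc(.data$dh_score),
                 dplyr::desc(.data$motif_score), .data$chrom, .data$start)
}

#' Label motif sites by overlap with gold-standard peaks
#'
#' A site is a true binding site iff it overlaps any gold-standard peak by
#' at least 1 bp (half-open intervals).
#'
#' @param sites A tibble of sites (any order; `chrom`, `start`, `end`).
#' @param gold_peaks A tibble of peak intervals (`chrom`, `start`, `end`).
#' @return The sites tibble with a logical `gold` column.
#' @export
label_gold <- function(sites, gold_peaks) {
  if (nrow(gold_peaks) == 0) {
    stop("empty gold-standard peak set: sensitivity is undefined", call. = FALSE)
  }
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end))
  gr_gold <- GenomicRanges::GRanges(
    seqnames = gold_peaks$chrom,
    ranges = IRanges::IRanges(start = gold_peaks$start + 1L,
                              end = gold_peaks$end))
  out <- sites
  out$gold <- GenomicRanges::countOverlaps(gr_sites, gr_gold) > 0
  out
}

#' Sensitivity-rank curve for a site ranking
#'
#' `curve[N]` is the fraction of all gold-standard sites found among the
#' top N ranked sites, for N = 1..max_rank.
#'
#' @param ranking A tibble of sites already ordered from best to worst,
#'   with a logical `gold` column (see [score_sites()] and [label_gold()]).
#' @param max_rank Largest rank to report (default: all sites). Truncated
#'   with a warning when it exceeds the number of sites.
#' @return A tibble of class `sensitivity_curve` with columns `rank`,
#'   `sensitivity`.
#' @export
sensitivity_rank_curve <- function(ranking, max_rank = nrow(ranking)) {
  n_gold <- sum(ranking$gold)
  if (n_gold < 1) stop("need at least one gold-standard site", call. = FALSE)
  if (max_rank > nrow(ranking)) {
    warning("max_rank exceeds the number of sites; truncating", call. = FALSE)
    max_rank <- nrow(ranking)
  }
  hits <- cumsum(ranking$gold)[seq_len(max_rank)]
  out <- tibble::tibble(rank = seq_len(max_rank), sensitivity = hits / n_gold)
  class(out) <- c("sensitivity_curve", class(out))
  out
}

#' Scaled area under a sensitivity-rank curve
#'
#' Trapezoidal AUC of a method's curve divided by the AUC of a reference
#' curve (by construction the gold-standard scorer scales to 1). Curves
#' must share the rank grid.
#'
#' @param curve_method,curve_reference Tibbles with `rank` and
#'   `sensitivity` columns on identical grids.
#' @return A single scaled AUC value.
#' @export
scaled_auc <- function(curve_method, curve_reference) {
  if (!identical(curve_method$rank, curve_reference$rank)) {
    stop("curves must share an identical rank grid", call. = FALSE)
  }
  auc_ref <- pracma::trapz(curve_reference$rank, curve_reference$sensitivity)
  if (auc_ref == 0) stop("reference curve has zero AUC", call. = FALSE)
  pracma::trapz(curve_method$rank, curve_method$sensitivity) / auc_ref
}

#' Average rank of each method across factors
#'
#' Within each transcription factor, methods are ranked by AUC (1 = best,
#' ties get the average rank); the output is each method's mean rank over
#' all factors.
#'
#' @param aucs A tibble with columns `tf`, `method`, `auc`, complete over
#'   the tf x method grid.
#' @return A tibble with columns `method`, `average_rank`, sorted best
#'   first.
#' @export
rank_methods <- function(aucs) {
  counts <- dplyr::count(aucs, .data$tf)
  n_methods <- length(unique(aucs$method))
  if (any(counts$n != n_methods) || anyNA(aucs$auc)) {
    stop("the AUC table must be complete over the tf x method grid",
         call. = FALSE)
  }
  aucs |>
    dplyr::group_by(.data$tf) |>
    dplyr::mutate(rank = rank(-.data$auc, ties.method = "average")) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(average_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$average_rank)
}

#' Empirical q-values for predicted accessibility against a permutation null
#'
#' The null distribution is pooled over all loci and all columns of the
#' permutation-control predictions. The empirical p-value of locus l is
#' `(1 + #null >= observed_l) / (1 + #null)`; q-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param pred_sample Numeric vector of predicted values, one per locus.
#' @param null_preds A `signal_matrix` (or matrix) of predictions from one
#'   or more permutation-control models.
#' @return A tibble with columns `locus_id`, `p`, `q`.
#' @export
empirical_qvalues <- function(pred_sample, null_preds) {
  nulls <- if (inherits(null_preds, "signal_matrix")) {
    as.vector(sm_values(null_preds))
  } else {
    as.vector(null_preds)
  }
  if (length(nulls) < 1) stop("need at least one null prediction column",
                              call. = FALSE)
  sorted <- sort(nulls)
  n_ge <- length(sorted) - findInterval(pred_sample, sorted, left.open = TRUE)
  p <- (1 + n_ge) / (1 + length(sorted))
  ids <- names(pred_sample)
  if (is.null(ids)) ids <- sprintf("locus_%d", seq_along(pred_sample))
  tibble::tibble(locus_id = ids, p = p, q = stats::p.adjust(p, method = "BH"))
}
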
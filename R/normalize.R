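#' Log2-transform raw signal after adding a pseudocount
#'
#' Each value v becomes log2(v + pseudocount); the default pseudocount of 1
#' maps zero coverage to exactly 0 on the log2 scale.
#'
#' @param m A raw- or normalized-scale `signal_matrix` with non-negative
#'   values.
#' @param pseudocount Positive constant added before the log (default 1).
#' @return A log2-scale `signal_matrix`.
#' @export
log2_pseudocount <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "signal_matrix"))
  if (sm_scale(m) == "log2") stop("input is already on the log2 scale", call. = FALSE)
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  v <- sm_values(m)
  if (any(v < 0)) stop("log2 transform requires non-negative input values", call. = FALSE)
  signal_matrix(log2(v + pseudocount), scale = "log2")
}

#' Quantile normalize each sample to a reference distribution
#'
#' Within each sample (column) independently, the value of rank i is
#' replaced by the i-th smallest reference value, so every normalized
#' sample's sorted values equal the reference. Tied values receive the mean
#' of the reference values over their tied rank range, and within-sample
#' rank order is preserved.
#'
#' This is how new expression profiles are mapped onto the distribution of
#' the training expression data before prediction.
#'
#' @param m A `signal_matrix` (rows must match the reference length).
#' @param reference Numeric vector sorted ascending, one value per row of
#'   `m`.
#' @return A `signal_matrix` with the same scale tag as the reference is
#'   assumed to be on (`scale` argument, default `"log2"`).
#' @param scale Scale tag for the output.
#' @export
quantile_normalize_to_reference <- function(m, reference, scale = "log2") {
  stopifnot(inherits(m, "signal_matrix"))
  v <- sm_values(m)
  if (length(reference) != nrow(v)) {
    stop(sprintf("reference length (%d) must equal number of rows (%d)",
                 length(reference), nrow(v)), call. = FALSE)
  }
  if (is.unsorted(reference)) stop("`reference` must be sorted ascending", call. = FALSE)
  out <- apply(v, 2, .qn_column, reference = reference)
  dimnames(out) <- dimnames(v)
  signal_matrix(out, scale = scale)
}

# map one column onto the reference distribution with tie-averaging
.qn_column <- function(x, reference) {
  o <- order(x)
  xs <- x[o]
  # runs of tied values in sorted order share the mean reference value
  grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
  assigned <- stats::ave(reference, grp, FUN = mean)
  out <- numeric(length(x))
  out[o] <- assigned
  out
}

#' Scale each sample to a constant library size
#'
#' Rescales every column so its sum equals `target_total`, preserving
#' within-sample proportions between loci. The default target of 1e7
#' matches a fixed-total coverage normalization; the constant is
#' immaterial for correlation-based evaluation.
#'
#' @param m A raw-scale `signal_matrix` with positive column sums.
#' @param target_total Desired column sum (default `1e7`).
#' @return A normalized-scale `signal_matrix`.
#' @export
scale_coverage <- function(m, target_total = 1e7) {
  stopifnot(inherits(m, "signal_matrix"))
  v <- sm_values(m)
  cs <- colSums(v)
  if (any(cs <= 0)) {
    stop("all-zero sample(s): ", paste(colnames(v)[cs <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- sweep(v, 2, target_total / cs, `*`)
  signal_matrix(out, scale = "normalized")
}

#' Drop cells with too few non-zero-coverage loci
#'
#' Retains exactly the cells (columns) with strictly more than
#' `min_nonzero` loci of non-zero coverage; the default threshold of 500
#' keeps cells with more than 500 non-zero-coverage loci.
#'
#' @param cells A raw-scale `signal_matrix`, loci x cells.
#' @param min_nonzero Strict lower bound on the number of non-zero loci.
#' @return A `signal_matrix` with the retained cells (possibly zero
#'   columns, with a message).
#' @export
filter_cells_by_coverage <- function(cells, min_nonzero = 500L) {
  stopifnot(inherits(cells, "signal_matrix"))
  v <- sm_values(cells)
  keep <- colSums(v > 0) > min_nonzero
  if (!any(keep)) {
    message("filter_cells_by_coverage: no cells pass the threshold of > ",
            min_nonzero, " non-zero loci")
  }
  signal_matrix(v[, keep, drop = FALSE], scale = sm_scale(cells))
}

#' Mask loci with no strong accessibility signal in any training sample
#'
#' Most genomic bins are background rather than regulatory elements; loci
#' whose maximum log2 signal across all training samples falls below
#' `min_signal` are excluded from model training.
#'
#' @param dh A log2-scale `signal_matrix` of training accessibility,
#'   loci x samples.
#' @param min_signal Inclusive log2 threshold on the per-locus maximum
#'   (default 2.0).
#' @return A named logical vector (TRUE = keep), one entry per locus.
#' @export
filter_training_loci <- function(dh, min_signal = 2.0) {
  stopifnot(inherits(dh, "signal_matrix"))
  v <- sm_values(dh)
  keep <- apply(v, 1, max) >= min_signal
  names(keep) <- rownames(v)
  keep
}
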
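#' Write predicted accessibility as genome-browser tracks
#'
#' Writes one track file per sample. bedGraph lines are
#' `chrom<TAB>start<TAB>end<TAB>value` in 0-based half-open coordinates;
#' WIG output uses 1-based `variableStep` records (converted at write
#' time).
#'
#' @param pred A `signal_matrix` whose rows align with `loci` (same order
#'   and count).
#' @param loci A `locus_set`.
#' @param path Output path. With more than one sample, the sample id is
#'   inserted before the file extension.
#' @param format `"bedGraph"` or `"WIG"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_track <- function(pred, loci, path, format = c("bedGraph", "WIG")) {
  format <- match.arg(format)
  stopifnot(inherits(pred, "signal_matrix"), inherits(loci, "locus_set"))
  v <- sm_values(pred)
  if (nrow(v) != nrow(loci)) {
    stop(sprintf("prediction has %d rows but locus set has %d loci",
                 nrow(v), nrow(loci)), call. = FALSE)
  }
  samples <- colnames(v)
  paths <- if (ncol(v) == 1) {
    path
  } else {
    sub("(\\.[^.]+)$", "", path) |>
      paste0(".", samples, sub("^.*(\\.[^.]+)$", "\\1", path))
  }
  for (j in seq_along(samples)) {
    if (format == "bedGraph") {
      lines <- sprintf("%s\t%d\t%d\t%s", loci$chrom, loci$start, loci$end,
                       format(v[, j], trim = TRUE, scientific = FALSE, digits = 15))
      readr::write_lines(lines, paths[j])
    } else {
      # variableStep WIG: one block per chromosome, 1-based start positions
      span <- unique(loci$end - loci$start)
      out <- character(0)
      for (chr in unique(loci$chrom)) {
        idx <- which(loci$chrom == chr)
        out <- c(out,
                 sprintf("variableStep chrom=%s span=%d", chr, span),
                 sprintf("%d\t%s", loci$start[idx] + 1L,
                         format(v[idx, j], trim = TRUE, scientific = FALSE,
                                digits = 15)))
      }
      readr::write_lines(out, paths[j])
    }
  }
  invisible(paths)
}

#' Read a bedGraph track back into a one-sample signal matrix
#'
#' @param path bedGraph file path.
#' @param sample_id Column name for the resulting matrix.
#' @param width Expected bin width.
#' @return A list with elements `loci` (a `locus_set`) and `signal`
#'   (a one-column log2-scale `signal_matrix`).
#' @export
read_bedgraph <- function(path, sample_id = "sample_1", width = 200L) {
  df <- .read_bedlike(path)
  loci <- locus_set(df[[1]], df[[2]], df[[3]], width = width)
  key <- sprintf("%s:%d-%d", as.character(df[[1]]), as.integer(df[[2]]),
                 as.integer(df[[3]]))
  vals <- as.numeric(df[[4]])[match(loci$locus_id, key)]
  v <- matrix(vals, ncol = 1, dimnames = list(loci$locus_id, sample_id))
  list(loci = loci, signal = signal_matrix(v, scale = "log2"))
}
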
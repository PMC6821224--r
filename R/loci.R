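#' Define an ordered set of fixed-width genomic loci
#'
#' Loci are the 200-bp genomic bins at which chromatin accessibility is
#' measured and predicted. Coordinates are 0-based half-open (BED
#' convention) throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors, 0-based half-open.
#' @param locus_id Optional unique ids; defaults to `chrom:start-end`.
#' @param width Expected common width of all loci (default 200 bp).
#' @return A tibble of class `locus_set` with columns `chrom`, `start`,
#'   `end`, `locus_id`, sorted by (chrom, start).
#' @export
locus_set <- function(chrom, start, end, locus_id = NULL, width = 200L) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("every locus must satisfy start < end", call. = FALSE)
  if (any(end - start != width)) {
    stop("all loci must share width ", width, " bp", call. = FALSE)
  }
  if (is.null(locus_id)) locus_id <- sprintf("%s:%d-%d", chrom, start, end)
  if (anyDuplicated(locus_id)) stop("locus ids must be unique", call. = FALSE)
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                        locus_id = as.character(locus_id))
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  class(out) <- c("locus_set", class(out))
  out
}

#' Tile a chromosome into consecutive fixed-width loci
#'
#' Convenience constructor used by the synthetic-data generator and
#' examples: `n` adjacent bins starting at position 0.
#'
#' @param n Number of loci.
#' @param chrom Chromosome name.
#' @param width Bin width in bp.
#' @return A `locus_set`.
#' @export
tile_loci <- function(n, chrom = "chr1", width = 200L) {
  start <- (seq_len(n) - 1L) * as.integer(width)
  locus_set(rep(chrom, n), start, start + as.integer(width),
            locus_id = sprintf("locus_%05d", seq_len(n)), width = width)
}

#' Construct a set of sequenced fragments
#'
#' @param chrom,start,end Fragment intervals, 0-based half-open. Input may
#'   be unsorted; the result is sorted by (chrom, start).
#' @return A tibble of class `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("every fragment must satisfy start < end", call. = FALSE)
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  class(out) <- c("fragment_set", class(out))
  out
}

# 0-based half-open intervals -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Read a BED3+ file of loci
#'
#' @param path BED file path (uncompressed, no track lines required).
#' @param width Expected locus width.
#' @return A `locus_set`. Uses the 4th BED column as locus id when present.
#' @export
read_loci_bed <- function(path, width = 200L) {
  df <- .read_bedlike(path)
  id <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  locus_set(df[[1]], df[[2]], df[[3]], locus_id = id, width = width)
}

#' Read a BED file of fragments
#'
#' @param path BED file path.
#' @return A `fragment_set`.
#' @export
read_fragments_bed <- function(path) {
  df <- .read_bedlike(path)
  fragment_set(df[[1]], df[[2]], df[[3]])
}

.read_bedlike <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no interval records in ", path, call. = FALSE)
  utils::read.table(text = lines, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
}

#' Count fragments overlapping each locus
#'
#' Computes bin-level fragment coverage: for one sample, the number of
#' fragments whose half-open interval overlaps each locus. A fragment
#' spanning a bin boundary increments every bin it touches.
#'
#' @param frags A `fragment_set`.
#' @param loci A `locus_set`.
#' @param sample_id Column name for the resulting one-sample matrix.
#' @return A one-column raw-scale `signal_matrix` (loci x 1).
#' @export
bin_fragment_coverage <- function(frags, loci, sample_id = "sample_1") {
  stopifnot(inherits(frags, "fragment_set"), inherits(loci, "locus_set"))
  missing_chr <- setdiff(unique(frags$chrom), unique(loci$chrom))
  if (length(missing_chr) > 0) {
    warning("fragments on chromosome(s) absent from loci (counted as zero): ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  counts <- GenomicRanges::countOverlaps(.as_granges(loci), .as_granges(frags))
  v <- matrix(as.numeric(counts), ncol = 1,
              dimnames = list(loci$locus_id, sample_id))
  signal_matrix(v, scale = "raw")
}
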
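#' Construct a signal matrix
#'
#' A signal matrix is the package's container for any row-feature by sample
#' real matrix: gene expression (genes x samples or genes x cells) and
#' chromatin accessibility (loci x samples) both live in it. It carries a
#' `scale` tag recording which stage of the processing pipeline the values
#' are on:
#'
#' * `"raw"` — non-negative counts or FPKM/TPM-like values;
#' * `"normalized"` — library-size-scaled coverage, still linear scale;
#' * `"log2"` — log2(signal + pseudocount) values.
#'
#' @param values Numeric matrix. Row names are gene or locus identifiers,
#'   column names are sample (or cell) identifiers; both are required and
#'   must be unique. All values must be finite; `scale = "raw"` additionally
#'   requires non-negative values.
#' @param scale One of `"raw"`, `"normalized"`, `"log2"`.
#' @return An object of class `signal_matrix`.
#' @examples
#' m <- signal_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), scale = "raw")
#' sm_values(m)
#' @export
signal_matrix <- function(values, scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  rid <- rownames(values)
  cid <- colnames(values)
  if (is.null(rid) || (is.null(cid) && ncol(values) > 0)) {
    stop("`values` must have row names (feature ids) and column names (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(rid)) {
    stop("duplicate row ids: ", paste(unique(rid[duplicated(rid)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cid)) {
    stop("duplicate sample ids: ", paste(unique(cid[duplicated(cid)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("signal matrix values must all be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (scale == "raw" && any(values < 0)) {
    stop("scale = \"raw\" requires non-negative values", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "signal_matrix")
}

#' @rdname signal_matrix
#' @param m A `signal_matrix`.
#' @export
sm_values <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  m$values
}

#' @rdname signal_matrix
#' @export
sm_scale <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  m$scale
}

#' @rdname signal_matrix
#' @export
row_ids <- function(m) rownames(sm_values(m))

#' @rdname signal_matrix
#' @export
sample_ids <- function(m) colnames(sm_values(m))

#' @export
print.signal_matrix <- function(x, ...) {
  v <- sm_values(x)
  cat(sprintf("<signal_matrix> %d features x %d samples, scale = %s\n",
              nrow(v), ncol(v), sm_scale(x)))
  nshow <- min(5L, nrow(v))
  mshow <- min(5L, ncol(v))
  print(v[seq_len(nshow), seq_len(mshow), drop = FALSE])
  if (nrow(v) > nshow || ncol(v) > mshow) cat("...\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(sm_values(x))

#' Convert a signal matrix to a long tibble
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `row_id`, `sample_id`, `value`.
#' @method as_tibble signal_matrix
#' @export
as_tibble.signal_matrix <- function(x, ...) {
  v <- sm_values(x)
  tibble::tibble(
    row_id = rep(rownames(v), times = ncol(v)),
    sample_id = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
}

#' Read a signal matrix from a delimited file
#'
#' The file must have a header row of sample ids and a first column of row
#' (gene or locus) ids. The delimiter is inferred from the extension
#' (`.csv` is comma; anything else tab).
#'
#' @param path Path to a TSV or CSV file.
#' @param scale_hint Scale tag to attach to the values (see
#'   [signal_matrix()]).
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(path, scale_hint = c("raw", "normalized", "log2")) {
  scale_hint <- match.arg(scale_hint)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          col_types = readr::cols(
                            .default = readr::col_character()
                          ), progress = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus >= 1 sample column",
                         call. = FALSE)
  rid <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(rid, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("malformed numeric cell at row '%s', column '%s' in %s",
                 rid[bad[1, 1]], colnames(num)[bad[1, 2]], path), call. = FALSE)
  }
  if (anyNA(num)) {
    stop("missing values are not allowed in signal matrices: ", path, call. = FALSE)
  }
  signal_matrix(num, scale = scale_hint)
}

#' Write a signal matrix to a delimited file
#'
#' @param m A `signal_matrix`.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @param id_column Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(m, path, id_column = "id") {
  v <- sm_values(m)
  df <- tibble::as_tibble(v)
  df <- dplyr::bind_cols(tibble::tibble(!!id_column := rownames(v)), df)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}
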
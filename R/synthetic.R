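#' Ground-truth parameters for synthetic paired expression/accessibility data
#'
#' The generator plants the statistical structure the predictor assumes:
#' each locus has a baseline accessibility (its locus effect) plus a linear
#' dependence on a small set of driver genes whose expression varies across
#' cell types. Loci come in blocks that share drivers and coefficients —
#' the co-regulated clusters the cluster-level models exploit — while
#' keeping their own baselines and noise.
#'
#' Gene expression itself has co-expression structure: genes belong to
#' modules whose module-level activity varies across cell types, and each
#' gene tracks its module's activity (plus an idiosyncratic cross-type
#' effect and replicate noise). A block's driver genes all come from one
#' module. This mirrors the regulatory-module structure that makes
#' accessibility predictable from expression in real compendia: with few
#' training cell types, marginal gene screening can only find driver
#' signal if co-expressed genes share the cross-cell-type variation that
#' drives accessibility.
#'
#' Defaults are a desk-scale emulation of a multi-cell-type compendium:
#' 2000 genes in 50 co-expression modules, 2000 loci, 8 cell types with 2
#' replicates each, 3 driver genes per block of 20 loci, log2-scale
#' Gaussian noise, and 60% dropout for single cells.
#'
#' @param n_genes,n_loci,n_cell_types,replicates Problem dimensions.
#' @param drivers_per_block Number of driver genes shared by each locus
#'   block.
#' @param block_size Loci per co-regulated block.
#' @param n_modules Number of gene co-expression modules. Genes are split
#'   evenly (randomly) across modules; every module must end up with at
#'   least `drivers_per_block` genes.
#' @param gene_baseline_mean,gene_baseline_sd Log2 expression baselines.
#' @param type_effect_sd SD of the module activity scores across cell
#'   types (the signal the predictor learns from).
#' @param loading_range Absolute range of gene-on-module loadings (sign
#'   random).
#' @param idio_effect_sd SD of each gene's idiosyncratic cross-type
#'   effect, on top of its module activity.
#' @param expr_noise_sd Replicate-level expression noise SD.
#' @param locus_baseline_mean,locus_baseline_sd Log2 accessibility locus
#'   effects.
#' @param coef_range Absolute range of driver coefficients. Each block
#'   responds to its module with one random sign (chromatin opening or
#'   closing); a driver's coefficient sign is that block sign times the
#'   driver's loading sign, so driver contributions reinforce.
#' @param dh_noise_sd Accessibility noise SD.
#' @param sc_noise_sd Per-cell expression noise SD.
#' @param dropout Probability that a single-cell gene measurement is zeroed.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `synthetic_truth` holding the drawn parameters
#'   (locus effects `a_l`, driver index matrix, coefficient matrix, block
#'   membership, module assignments and factor scores) and the
#'   configuration.
#' @export
synthetic_truth <- function(n_genes = 2000L, n_loci = 2000L,
                            n_cell_types = 8L, replicates = 2L,
                            drivers_per_block = 3L, block_size = 20L,
                            n_modules = 50L,
                            gene_baseline_mean = 6, gene_baseline_sd = 2,
                            type_effect_sd = 1, loading_range = c(0.8, 1.2),
                            idio_effect_sd = 0.2, expr_noise_sd = 0.2,
                            locus_baseline_mean = 3, locus_baseline_sd = 1.2,
                            coef_range = c(0.4, 0.8), dh_noise_sd = 0.3,
                            sc_noise_sd = 0.5, dropout = 0.6, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  stopifnot(dh_noise_sd >= 0, expr_noise_sd >= 0, sc_noise_sd >= 0,
            idio_effect_sd >= 0)
  if (n_genes < n_modules * drivers_per_block) {
    stop("need at least `n_modules * drivers_per_block` genes so every module ",
         "can supply a block's drivers", call. = FALSE)
  }
  n_blocks <- ceiling(n_loci / block_size)
  params <- withr::with_seed(as.integer(seed), {
    gene_baseline <- stats::rnorm(n_genes, gene_baseline_mean, gene_baseline_sd)
    gene_baseline <- pmax(gene_baseline, 0)
    module_of_gene <- sample(rep_len(seq_len(n_modules), n_genes))
    factor_scores <- matrix(stats::rnorm(n_modules * n_cell_types, 0, type_effect_sd),
                            n_modules, n_cell_types)
    loadings <- stats::runif(n_genes, loading_range[1], loading_range[2]) *
      sample(c(-1, 1), n_genes, replace = TRUE)
    type_effects <- loadings * factor_scores[module_of_gene, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_cell_types, 0, idio_effect_sd),
             n_genes, n_cell_types)
    block_of_locus <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_loci)]
    module_of_block <- rep_len(seq_len(n_modules), n_blocks)
    drivers <- t(vapply(seq_len(n_blocks), function(b) {
      pool <- which(module_of_gene == module_of_block[b])
      sort(sample(pool, drivers_per_block))
    }, integer(drivers_per_block)))
    # A block responds to its module with one sign (opening or closing);
    # each driver's coefficient sign is its loading sign times that block
    # sign, so driver contributions to the shared factor reinforce rather
    # than cancel.
    block_sign <- sample(c(-1, 1), n_blocks, replace = TRUE)
    driver_loading_sign <- matrix(sign(loadings[drivers]),
                                  n_blocks, drivers_per_block)
    coefs <- matrix(stats::runif(n_blocks * drivers_per_block,
                                 coef_range[1], coef_range[2]),
                    n_blocks, drivers_per_block) *
      block_sign * driver_loading_sign
    a_raw <- stats::rnorm(n_loci, locus_baseline_mean, locus_baseline_sd)
    list(gene_baseline = gene_baseline, module_of_gene = module_of_gene,
         factor_scores = factor_scores, loadings = loadings,
         type_effects = type_effects,
         block_of_locus = block_of_locus, module_of_block = module_of_block,
         drivers = drivers, coefs = coefs,
         a_raw = a_raw)
  })
  # fold driver baselines into the intercept so Y = a_l + sum_g B[l,g] X[g,m]
  a_l <- params$a_raw - vapply(seq_len(n_loci), function(l) {
    b <- params$block_of_locus[l]
    sum(params$coefs[b, ] * params$gene_baseline[params$drivers[b, ]])
  }, numeric(1))
  structure(list(
    n_genes = as.integer(n_genes), n_loci = as.integer(n_loci),
    n_cell_types = as.integer(n_cell_types), replicates = as.integer(replicates),
    drivers_per_block = as.integer(drivers_per_block),
    block_size = as.integer(block_size),
    n_modules = as.integer(n_modules),
    gene_baseline = params$gene_baseline,
    module_of_gene = params$module_of_gene,
    factor_scores = params$factor_scores,
    loadings = params$loadings,
    type_effects = params$type_effects,
    block_of_locus = params$block_of_locus,
    module_of_block = params$module_of_block,
    drivers = params$drivers,
    coefs = params$coefs,
    a_l = a_l,
    expr_noise_sd = expr_noise_sd, dh_noise_sd = dh_noise_sd,
    sc_noise_sd = sc_noise_sd, dropout = dropout,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# type-mean log2 expression matrix (genes x types)
.type_mean_expression <- function(truth) {
  truth$gene_baseline + truth$type_effects
}

# noiseless accessibility implied by an expression matrix, before clipping
.implied_dh <- function(truth, X) {
  Y <- matrix(truth$a_l, truth$n_loci, ncol(X))
  for (b in seq_len(nrow(truth$drivers))) {
    rows <- which(truth$block_of_locus == b)
    contrib <- crossprod(X[truth$drivers[b, ], , drop = FALSE], truth$coefs[b, ])
    Y[rows, ] <- Y[rows, ] + matrix(contrib, length(rows), ncol(X), byrow = TRUE)
  }
  Y
}

#' Generate paired bulk expression and accessibility matrices
#'
#' Per cell type a mean expression profile is drawn (baseline + type
#' effect); replicates add Gaussian noise. Accessibility is
#' `Y[l, m] = a_l + sum_g B[l, g] X[g, m] + noise`, clipped at 0 (log2
#' accessibility is non-negative). Deterministic given the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with `X` (log2 `signal_matrix`, genes x samples), `Y`
#'   (log2 `signal_matrix`, loci x samples), `labels` (cell type per
#'   sample) and `loci` (a `locus_set` tiling for Y's rows).
#' @export
generate_bulk <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  T_ <- truth$n_cell_types
  reps <- truth$replicates
  M <- T_ * reps
  type_of_sample <- rep(seq_len(T_), each = reps)
  out <- withr::with_seed(truth$seed + 1L, {
    mu <- .type_mean_expression(truth)
    X <- mu[, type_of_sample, drop = FALSE] +
      matrix(stats::rnorm(truth$n_genes * M, 0, truth$expr_noise_sd),
             truth$n_genes, M)
    X <- pmax(X, 0)
    Y <- .implied_dh(truth, X) +
      matrix(stats::rnorm(truth$n_loci * M, 0, truth$dh_noise_sd),
             truth$n_loci, M)
    Y <- pmax(Y, 0)
    list(X = X, Y = Y)
  })
  labels <- sprintf("type_%02d", type_of_sample)
  sample_ids <- sprintf("%s_rep%d", labels, rep(seq_len(reps), times = T_))
  gene_ids <- sprintf("gene_%05d", seq_len(truth$n_genes))
  loci <- tile_loci(truth$n_loci)
  dimnames(out$X) <- list(gene_ids, sample_ids)
  dimnames(out$Y) <- list(loci$locus_id, sample_ids)
  list(X = signal_matrix(out$X, "log2"), Y = signal_matrix(out$Y, "log2"),
       labels = labels, loci = loci)
}

#' Generate single-cell expression with dropout
#'
#' Per cell: type mean expression plus cell-level noise, then each gene is
#' independently zeroed with probability `dropout`. The true cell type of
#' every cell is recorded.
#'
#' @param truth A [synthetic_truth()].
#' @param cells_per_type Number of cells per cell type.
#' @param dropout Dropout probability (default: the truth's).
#' @param cell_types Integer vector of type indices to simulate (default
#'   all).
#' @return A list with `expression` (log2 `signal_matrix`, genes x cells)
#'   and `cell_info` (tibble: `cell_id`, `cell_type`).
#' @export
generate_single_cells <- function(truth, cells_per_type = 30L,
                                  dropout = truth$dropout,
                                  cell_types = seq_len(truth$n_cell_types)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  type_of_cell <- rep(cell_types, each = cells_per_type)
  n_cells <- length(type_of_cell)
  E <- withr::with_seed(truth$seed + 2L, {
    mu <- .type_mean_expression(truth)
    E <- mu[, type_of_cell, drop = FALSE] +
      matrix(stats::rnorm(truth$n_genes * n_cells, 0, truth$sc_noise_sd),
             truth$n_genes, n_cells)
    E <- pmax(E, 0)
    if (dropout > 0) {
      keep <- matrix(stats::runif(truth$n_genes * n_cells) >= dropout,
                     truth$n_genes, n_cells)
      E <- E * keep
    }
    E
  })
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  dimnames(E) <- list(sprintf("gene_%05d", seq_len(truth$n_genes)), cell_ids)
  list(expression = signal_matrix(E, "log2"),
       cell_info = tibble::tibble(cell_id = cell_ids,
                                  cell_type = sprintf("type_%02d", type_of_cell)))
}

#' Generate sequencing fragments from an accessibility profile
#'
#' Fragment midpoints are drawn per locus with probability proportional to
#' the linear-scale signal `2^Y - 1`; each fragment is 100 bp long. Used to
#' exercise the coverage-binning input path end to end.
#'
#' @param truth A [synthetic_truth()] (provides the locus grid).
#' @param y_sample Numeric vector of log2 accessibility, one per locus.
#' @param frags_total Number of fragments to draw.
#' @param seed Integer seed.
#' @param frag_len Fragment length in bp (default 100).
#' @return A `fragment_set`.
#' @export
generate_fragments <- function(truth, y_sample, frags_total = 1e4L, seed = 1L,
                               frag_len = 100L) {
  stopifnot(inherits(truth, "synthetic_truth"), frags_total >= 1)
  if (length(y_sample) != truth$n_loci) {
    stop("`y_sample` must have one value per locus", call. = FALSE)
  }
  loci <- tile_loci(truth$n_loci)
  w <- pmax(2^y_sample - 1, 0)
  if (sum(w) == 0) stop("accessibility profile has no signal", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    locus_idx <- sample.int(truth$n_loci, frags_total, replace = TRUE,
                            prob = w / sum(w))
    offset <- sample.int(200L, frags_total, replace = TRUE) - 1L
    mid <- loci$start[locus_idx] + offset
    start <- pmax(mid - frag_len %/% 2L, 0L)
    fragment_set(loci$chrom[locus_idx], start, start + frag_len)
  })
}
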
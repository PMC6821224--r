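# chromcast

Predict genome-wide chromatin accessibility from gene expression.

Chromatin accessibility assays (DNase-seq, ATAC-seq) are available for far
fewer samples than RNA-seq. Because regulatory-element activity is tightly
coupled to the expression of co-regulated genes, a regression model trained on
samples profiled by both assays can predict accessibility wherever only
expression exists. chromcast trains such models — log2 DNase I
hypersensitivity (DH) in fixed 200-bp genomic bins, each bin predicted from
its 7 most correlated genes, averaged with cluster-level regressions at
several resolutions — and evaluates them with the statistics that matter:

* **r_L** (cross-locus): correlation of predicted vs. true DH across loci
  within one sample.
* **r_C** (cross-sample): correlation across samples at one locus — immune to
  baseline "locus effects", so it measures whether cell-type *differences*
  are actually predicted.
* Leave-one-cell-type-out cross-validation with per-fold retraining, a
  permutation control (retains locus effects only), and a mean-profile
  baseline (r_C is exactly 0 by the zero-variance convention).

Also included: TFBS prediction by ranking motif sites on predicted
accessibility (sensitivity-rank curves, scaled AUC), pseudo-bulk pooling of
single cells, hybrid integration of predicted and measured (sc)ATAC-seq
profiles, differential-accessibility benchmarking, a training-test distance
diagnostic, motif activity along pseudotime, and a synthetic paired
expression/accessibility generator with known linear ground truth.

## Worked example

Simulate a ground-truth world, train, and cross-validate against the
permutation control (runs in a few seconds):

```r
library(chromcast)

truth <- synthetic_truth(n_genes = 800, n_loci = 600, n_cell_types = 6,
                         n_modules = 30, seed = 7)
bulk <- generate_bulk(truth)
cfg <- train_config(cluster_sizes = c(6L, 30L))

model <- train_accessibility_model(bulk$X, bulk$Y, cfg)
model
#> <accessibility_model> 594 loci, 800 genes, 12 training samples
#>   cluster resolutions: 6, 30; K = 7 predictors; quantile normalization: TRUE

cv <- loocv_evaluate(bulk$X, bulk$Y, bulk$labels, cfg)
cv_perm <- loocv_evaluate(bulk$X, bulk$Y, bulk$labels, cfg, permute = TRUE)
cv$summary
#> # A tibble: 1 × 2
#>   mean_r_l mean_r_c
#>      <dbl>    <dbl>
#> 1    0.689    0.573
cv_perm$summary
#> # A tibble: 1 × 2
#>   mean_r_l mean_r_c
#>      <dbl>    <dbl>
#> 1  -0.0687   -0.132

shared <- intersect(cv$r_c$locus_id, cv_perm$r_c$locus_id)
paired_wilcoxon(cv$r_c$r_c[match(shared, cv$r_c$locus_id)],
                cv_perm$r_c$r_c[match(shared, cv_perm$r_c$locus_id)])
#> [1] 1.740421e-71
```

Held-out cell types are predicted with mean r_C = 0.57 while the permuted
control sits near zero. At the generator's full default scale (2000 genes,
2000 loci, 8 cell types x 2 replicates) the same pipeline reaches mean
r_C = 0.83 and mean r_L = 0.87, against −0.09 / 0.12 for the permutation
control and 0.50 mean r_L for the mean-profile baseline.

`tidy()`, `glance()` and `autoplot()` work on models and evaluation reports;
see `vignette("predicting-accessibility")` for the methods description,
parameter rationale and downstream analyses (TFBS, pooling, hybrid,
differential, distance).

## Command line

Every step is scriptable:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "chromcast.R", package = "chromcast"))')
Rscript "$CLI" simulate --out-dir sim --seed 1
Rscript "$CLI" train    --expr sim/X.tsv --dh sim/Y.tsv --model model.json --seed 1
Rscript "$CLI" predict  --model model.json --expr sim/X.tsv --out pred.tsv
Rscript "$CLI" evaluate --pred pred.tsv --truth sim/Y.tsv --labels sim/labels.tsv --report rep
```

Subcommands: `simulate`, `train`, `predict`, `permute`, `evaluate`, `tfbs`,
`pool`, `hybrid`, `distance`, `activity`. Flags may come from a YAML config
(`--config`, explicit flags win). Every output begins with a provenance
comment (version, seed, options hash); identical flags give byte-identical
outputs.

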
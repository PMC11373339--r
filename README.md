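# pepimpute

Peptide-level missing-value imputation for label-free bottom-up proteomics,
with per-value uncertainty estimates.

Intensity tables from label-free LC–MS experiments miss large fractions of
their peptide-level entries — stochastically (MCAR) and below the detection
limit (MNAR) — and those holes propagate into protein quantification and
differential-expression analysis. `pepimpute` fills them **directly at the
peptide level** with a graph attention network that exploits three sources of
information at once:

* the peptide's own abundance profile across samples,
* the abundances of peptides from the same protein — every protein induces a
  clique in a peptide–peptide graph, and shared peptides merge cliques into
  connected components,
* an amino-acid sequence embedding carrying the peptide's biophysical
  properties.

For each entry the network predicts a Gaussian mean and variance (two output
heads, trained in two self-supervised rounds: MSE on the mean head, then a
Gaussian negative log-likelihood on both heads), so every imputed value comes
with a predicted standard deviation `sigma` on the standardized log scale.
Uncertain imputations can be filtered out of downstream analyses.

The package also ships eleven classical comparison imputers (MinDet, MinProb,
Median, KNN, MICE-style Bayesian ridge, random forest, iterative SVD,
Bayesian PCA, denoising and variational autoencoders, collaborative
filtering), an evaluation framework (sample-wise RMSE with bootstrap CIs,
paired Wilcoxon signed-rank method tournaments, Welch/Benjamini–Hochberg
differential-expression ROC analysis, uncertainty diagnostics) and a fully
seeded synthetic-data generator, so the complete benchmark runs without any
external download.

## Worked example

```r
library(pepimpute)

fix  <- make_benchmark_fixture("small")   # 200 peptides x 8 samples, seeded
ds   <- fix$dataset
plan <- fix$plan                          # 10% test / 10% validation split

cfg <- model_config(attention_heads = 8, epoch_size = 50,
                    max_epochs = 8, patience = 3, seed = 7)
fit <- train_gnn_imputer(ds, plan, embeddings = fix$embeddings, cfg = cfg)
res <- impute_gnn(ds, fit, embeddings = fix$embeddings, plan = plan)
res
#> imputation_result: 200 x 8, 630 imputed entries
#>   sigma (std-log scale): median 0.248, max 0.572

# paired comparison against a classical baseline on the same mask plan
trainZ <- apply_mask_plan(log_standardize(ds)$matrix, plan)
med    <- impute_matrix(trainZ, "Median")
sqrt(mean((res$mu[plan$test_idx] - plan$truth_test)^2))  # GNN
#> [1] 0.4442
sqrt(mean((med[plan$test_idx]   - plan$truth_test)^2))   # Median
#> [1] 0.4425
```

The test RMSEs are on the standardized log scale (1.0 = one standard
deviation of all observed log-intensities). On the larger `"medium"` preset
(2000 peptides × 12 samples, 30% missing), where each protein contributes
eight correlated peptides, the trained network clearly separates from the
baseline (RMSE ≈ 0.29 vs ≈ 0.38 with the same budget); at the `"small"`
scale above the margin is within noise — a 200-peptide table is at the edge
of what network training can exploit.

`res$completed` is the completed table on the raw intensity scale (observed
entries untouched), `res$uncertainty` the per-imputation sigma. A full
multi-method comparison on one shared mask plan, with report files:

```r
report <- run_benchmark(list(
  dataset = list(preset = "small"),
  methods = c("GNN", "Median", "KNN", "BPCA"),
  model   = list(attention_heads = 8, epoch_size = 50, max_epochs = 8,
                 patience = 3),
  out_dir = "bench_small", seed = 1))
unlist(report$rmse)
```

There is also a thin command-line interface (installed under `exec/`):
`pepimpute simulate|impute|benchmark|evaluate`, driven by YAML configs.

See the methods vignette
(`vignettes/peptide-imputation-methods.Rmd`) for the model, the generator's
assumptions, numerical choices and known limitations.

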
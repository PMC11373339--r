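---
title: "Methods: graph-attention imputation of peptide abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-attention imputation of peptide abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pepimpute)
```

## The problem

Label-free bottom-up proteomics quantifies peptides, not proteins, and
peptide-level intensity tables routinely miss 20–70% of their entries, partly
at random (MCAR: stochastic fluctuations of the measurement process) and
partly as a function of abundance (MNAR: values below the detection limit).
`pepimpute` imputes the missing entries directly at the peptide level and
attaches a per-value uncertainty to every imputation.

Three structural facts about peptide data drive the model:

1. peptides cleaved from the same protein have strongly correlated abundance
   profiles across samples;
2. shared (non-unique) peptides link proteins into larger connected groups;
3. a peptide's amino-acid sequence determines biophysical properties
   (ionization efficiency among them) that shift its intensity level and its
   noise behaviour, and sequence embeddings carry that information.

## Model

All modelling happens on the standardized natural-log scale: intensities are
logged and scaled by one global mean and standard deviation computed over the
observed entries (`log_standardize()`), so that 0 is "the average observed
log-intensity". Imputed values are mapped back through
`inverse_transform()`.

Let `A` be the `n x s` standardized abundance matrix, `S` an `n x d`
sequence-embedding matrix, and `G` the peptide–peptide graph in which two
peptides are adjacent when they share a parent protein (`build_peptide_graph()`
makes every protein a clique and deduplicates edges; self-loops are added by
the attention layer, not stored). The network (`model_config()`,
`gnn_forward()`) computes:

1. a projection of the sequence embedding to 16 dimensions (affine + ReLU);
2. a latent peptide representation `h in R^128` from the concatenation of the
   abundance vector, an observed-value indicator channel, and the projected
   embedding (two affine layers with a ReLU between them);
3. one multi-head dynamic-attention layer over `G`: per head, scores
   `a' LeakyReLU(W_l h_i + W_r h_j)` (slope 0.2) are softmax-normalized over
   each node's neighbourhood including itself, and the attention-weighted
   messages `W_r h_j` are averaged; each head outputs `floor(s/2)` values and
   the heads' outputs are concatenated;
4. a final representation `f in R^128` from the concatenation of the
   attention output and a skip connection carrying `h` past the graph layer;
5. two affine output heads: a mean `mu in R^{n x s}` and a variance
   `sigma^2 = softplus(.) + 1e-6`, so every entry gets a full Gaussian
   predictive distribution.

Missing and held-out inputs are encoded as 0 (the standardized global mean);
the indicator channel (`use_mask_channel`, on by default) lets the network
distinguish "missing" from "average abundance". Switching it off reproduces
the bare abundance-vector input.

### Training

Training is self-supervised (`train_gnn_imputer()`). A 10% test and 10%
validation split of the observed entries is hidden up front
(`make_masked_split()`; for paired DDA/DIA acquisitions
`make_dda_dia_split()` instead uses rescaled DIA values as orthogonal truth
for entries genuinely missing in DDA). At each step a fraction
`gamma ~ U[0.05, 0.15)` of the remaining observed entries is masked and the
network is trained to reconstruct them — round 1 trains the mean head alone
with MSE, round 2 continues from the round-1 best weights and trains both
heads with the Gaussian negative log-likelihood
`0.5 (log sigma^2 + (y - mu)^2 / sigma^2)` (variances floored at `1e-6`).
Both rounds evaluate the validation MSE of the mean head after each epoch
(an epoch is `epoch_size` masked datasets), stop after `patience` epochs
without improvement, and restore the best post-epoch checkpoint. Optimization
is full-graph Adam at `learning_rate = 1e-3`. All randomness flows from
`model_config(seed = )`; a fixed seed reproduces the parameter trajectory
bit for bit.

### Numerical choices

* Attention scores are clipped to `[-30, 30]` before the neighbourhood
  softmax. Scores are bounded and small in practice; clipping guards the
  `exp()` without a per-node max-subtraction pass, and its gradient is zero
  only in the (unobserved) saturated regime.
* The backward pass is derived analytically for the exact pipeline above and
  is verified in the test suite against central finite differences to a
  relative error below `1e-4`, for both losses and for every ablation wiring.
* With `use_gnn = FALSE`, the attention block's output is replaced by zeros
  of the same width, so the final block keeps its shape and ablation
  comparisons hold the parameter count of the non-graph path fixed.
* With `use_embeddings = FALSE` the projected embedding is a zero vector.

## Comparison imputers

Eleven standard imputers share one contract (`impute_matrix()`): input the
standardized matrix with missing entries, never change observed values,
return a complete matrix, be deterministic given a seed. MinDet/MinProb use
per-sample 0.01-quantiles (linear-interpolation convention — fills are
sensitive to it, so it is pinned and tested); Median is peptide-wise with a
global-median fallback for empty rows; KNN uses Euclidean distances over
co-observed columns rescaled by `sqrt(s / #co-observed)`; MICE is a
single-imputation chained-equations pass with evidence-approximation Bayesian
ridge regressions; RF is a missForest-style loop over `ranger` forests;
ISVD alternates truncated-SVD reconstruction and refill; BPCA is EM
probabilistic PCA with missing data and automatic-relevance-determination
precisions on the loading columns (rows sharing a missingness pattern share
their posterior computations); DAE/VAE are compact peptide-row autoencoders;
CF is biased matrix factorization fitted by alternating ridge least squares.
The deep baselines are deliberately compact reference versions, not
replications of any specific published architecture.

## Synthetic data: what it emulates, and what it does not

`synthetic_spec()` / `generate_dataset()` draw peptide tables from a
hierarchical log-normal model: protein base levels `N(14, 1.5^2)` on the
natural-log scale (raw intensities around `e^14`, a typical LC–MS magnitude),
per-sample protein effects (`protein_sd = 0.5`), peptide ionization offsets
(`peptide_offset_sd = 0.8` by default), and heteroscedastic peptide noise
with `sd ~ U(0.1, 0.5)` — log-scale coefficients of variation of roughly
10–50%, spanning well-behaved to noisy peptides. A configurable fraction of
peptides is shared between two proteins (signal = mean of the parents, the
simplest coupling that creates cross-clique information flow). Missingness is
the union of i.i.d. MCAR and logistic abundance-dependent MNAR; entries hit
by both are attributed to MCAR in the cause table. Embeddings are noisy
linear images of the latent peptide properties (offset and noise sd), so
sequence features carry genuine but imperfect signal, as language-model
embeddings do. The within-protein correlation has the closed form
implemented in `expected_clique_correlation()` and the generator is tested
against it.

Three presets fix the study conditions used throughout the tests:
`small` (200 peptides × 8 samples), `medium` (2000 × 12, 30% MCAR,
within-protein correlation ≈ 0.84) and `de_spikein` (two conditions of 6
samples, 10% differential proteins at log-effect 1.2, MNAR-dominated
missingness). These sizes keep a full benchmark, including network training,
in CPU minutes; they are the package's declared desk-scale conditions, and
the test-suite training budgets (8 attention heads, 50-step epochs, patience
3) are scaled to them. The defaults in `model_config()` (64 heads, 500-step
epochs, patience 5) are the full-scale settings.

What passing tests on this generator do **not** show: real peptide tables
have non-Gaussian tails, batch effects, correlated missingness across
samples, and embeddings whose information content is not a clean linear
image of the generative parameters. Results on synthetic presets demonstrate
that the implementation exploits the structure it is designed for, not that
it will match any particular real-data benchmark value.

## Evaluation framework

* **Abundance error**: per-sample RMSE (the replicate unit for bootstrap
  confidence intervals), dataset MAE, RMSE stratified by each peptide's
  missingness fraction, and RMSE over predicted-uncertainty quantiles.
* **Paired method comparison**: one-sided paired Wilcoxon signed-rank tests
  on absolute errors over the shared test positions, Bonferroni-corrected
  over all ordered method pairs; tournament win counts give 1 to a
  significant winner and 0.5 to each method of an insignificant pair. Zero
  differences are dropped before ranking; an all-zero comparison is p = 1 by
  convention.
* **Differential expression**: per-peptide Welch t-tests (vectorized, with
  Welch–Satterthwaite degrees of freedom) with Benjamini–Hochberg
  adjustment; ROC/PR curves sweep the adjusted q-values (peptides with fewer
  than two observations in a group are excluded from scoring — they have no
  q-value — with an optional flag to score them at q = 1). The q-value sweep
  was chosen over raw p because the q scale is what a practitioner
  thresholds; both orderings are identical up to monotone transformation, so
  the AUC is unchanged.
* **Uncertainty filtering**: imputations with predicted sigma above a
  threshold (standardized-log scale) are reverted to missing before the DE
  analysis, trading coverage for reliability.

One mask plan is shared by every method in `run_benchmark()` — the paired
tests require it — and is serialized next to the report.

## Known limitations

* **Uncertainty informativeness under MCAR-only conditions.** On the
  `medium` preset the trained model's errors are close to homoscedastic: with
  uniform random missingness and eight informative clique mates per peptide,
  estimation error varies little from entry to entry, and the rank
  correlation between predicted sigma and realized error is near zero — an
  upper bound well below what abundance-dependent (MNAR) missingness and
  heterogeneous peptide coverage produce on real data, where low-uncertainty
  subsets are visibly more accurate. The uncertainty machinery is therefore
  best exercised on the `de_spikein` preset (MNAR-dominated), where
  filtering by predicted sigma preserves or improves DE detection.
* BPCA here is an EM/ARD formulation, not a line-by-line port of any
  published implementation; its convergence warning at tight tolerances is
  informational.
* The per-dataset DIA-to-DDA mean matching is an additive shift on the log
  scale (multiplicative on the raw scale); per-sample and per-peptide
  variants are deliberately not the default, since the global variant is the
  only one that never leaks sample-specific information into the truth set.
* Full-clique graphs grow quadratically in peptides per protein; an optional
  seeded per-protein edge cap exists for memory safety but is off by
  default, because subsampling changes the attention neighbourhood.

## Reproducing a benchmark

```{r}
config <- list(
  dataset = list(preset = "small"),
  methods = c("GNN", "Median", "KNN", "BPCA"),
  model = list(attention_heads = 8, epoch_size = 50, max_epochs = 8,
               patience = 3),
  out_dir = "bench_small",
  seed = 1)
report <- run_benchmark(config)
report$rmse
```

The same run is available from a shell via the installed CLI:

```sh
pepimpute benchmark --config run.yaml --out bench_small --seed 1
```
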
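# helpers shared by the network tests -----------------------------------------

tiny_net_setup <- function(s = 4, n_prot = 3, pep_per = 2, d = 6, heads = 2,
                           seed = 5, use_gnn = TRUE, use_embeddings = TRUE,
                           use_mask_channel = TRUE) {
  ds <- random_dataset(n_prot = n_prot, pep_per = pep_per, s = s,
                       miss = 0.15, seed = seed)
  g <- build_peptide_graph(ds)
  cfg <- model_config(attention_heads = heads, latent_dim = 8L,
                      final_dim = 8L, embed_proj_dim = 4L,
                      use_gnn = use_gnn, use_embeddings = use_embeddings,
                      use_mask_channel = use_mask_channel, seed = seed)
  set.seed(seed)
  emb <- matrix(rnorm(nrow(ds$abundance) * d), ncol = d)
  Z <- log_standardize(ds)$matrix
  enc_A <- ifelse(is.na(Z), 0, Z)
  obs_ind <- 1 - is.na(Z)
  gt <- pepimpute:::graph_tensors(g)
  params <- pepimpute:::init_gnn_params(cfg, s, d)
  list(ds = ds, g = g, gt = gt, cfg = cfg, emb = emb, Z = Z,
       enc_A = enc_A, obs_ind = obs_ind, params = params)
}

test_that("forward pass has the architecture's exact widths", {
  for (s in c(4, 5)) {
    st <- tiny_net_setup(s = s, heads = 3)
    fw <- gnn_forward(st$params, st$enc_A, st$obs_ind, st$emb, st$gt, st$cfg,
                      keep_cache = TRUE)
    Dh <- max(1, s %/% 2)
    expect_equal(dim(fw$mu), dim(st$Z))
    expect_equal(dim(fw$sigma2), dim(st$Z))
    expect_true(all(fw$sigma2 > 0))
    # attention output width: heads * floor(s/2); final input adds latent skip
    expect_equal(ncol(fw$cache$C), 3 * Dh + st$cfg$latent_dim)
    expect_equal(dim(st$params$Wl), c(st$cfg$latent_dim, 3 * Dh))
  }
})

test_that("isolated nodes self-attend and stay finite", {
  ds <- membership_dataset(list("P1", "P2", "P3", "P3"), s = 4)
  g <- build_peptide_graph(ds)
  cfg <- model_config(attention_heads = 2L, latent_dim = 8L, final_dim = 8L,
                      embed_proj_dim = 4L, seed = 1L)
  set.seed(1)
  emb <- matrix(rnorm(4 * 6), 4, 6)
  Z <- log_standardize(ds)$matrix
  fw <- gnn_forward(pepimpute:::init_gnn_params(cfg, 4, 6),
                    ifelse(is.na(Z), 0, Z), 1 - is.na(Z), emb,
                    pepimpute:::graph_tensors(g), cfg)
  expect_true(all(is.finite(fw$mu)))
  expect_true(all(is.finite(fw$sigma2)))
})

# central finite differences against the analytic gradient ---------------------

numeric_grad_check <- function(st, round, n_checks = 60) {
  set.seed(99)
  mask <- sample(which(!is.na(st$Z)), 5)
  truth <- st$Z[mask]
  loss_of <- function(params) {
    fw <- gnn_forward(params, st$enc_A, st$obs_ind, st$emb, st$gt, st$cfg)
    if (round == 1) loss_round1(fw$mu, truth, mask)
    else loss_round2(fw$mu, fw$sigma2, truth, mask)
  }
  fw <- gnn_forward(st$params, st$enc_A, st$obs_ind, st$emb, st$gt, st$cfg,
                    keep_cache = TRUE)
  m <- length(mask)
  n <- nrow(st$Z)
  dmu <- matrix(0, n, ncol(st$Z))
  if (round == 1) {
    dmu[mask] <- 2 * (fw$mu[mask] - truth) / m
    grads <- pepimpute:::gnn_backward(st$params, fw$cache, st$gt, st$cfg, dmu)
  } else {
    s2 <- pmax(fw$sigma2[mask], 1e-6)
    dmu[mask] <- (fw$mu[mask] - truth) / s2 / m
    ds2 <- matrix(0, n, ncol(st$Z))
    ds2[mask] <- 0.5 * (1 / s2 - (truth - fw$mu[mask])^2 / s2^2) / m
    grads <- pepimpute:::gnn_backward(st$params, fw$cache, st$gt, st$cfg,
                                      dmu, ds2)
  }
  eps <- 1e-6
  set.seed(7)
  worst <- 0
  for (chk in seq_len(n_checks)) {
    nm <- sample(names(grads), 1)
    pos <- sample(length(st$params[[nm]]), 1)
    pp <- st$params
    pp[[nm]][pos] <- pp[[nm]][pos] + eps
    up <- loss_of(pp)
    pp[[nm]][pos] <- pp[[nm]][pos] - 2 * eps
    dn <- loss_of(pp)
    num <- (up - dn) / (2 * eps)
    ana <- grads[[nm]][pos]
    denom <- max(abs(num), abs(ana), 1e-4)
    worst <- max(worst, abs(num - ana) / denom)
  }
  worst
}

test_that("analytic gradients match finite differences (MSE round)", {
  st <- tiny_net_setup(seed = 21)
  expect_lt(numeric_grad_check(st, round = 1), 1e-4)
})

test_that("analytic gradients match finite differences (NLL round)", {
  st <- tiny_net_setup(seed = 22)
  expect_lt(numeric_grad_check(st, round = 2), 1e-4)
})

test_that("gradients stay correct with ablation switches off", {
  st <- tiny_net_setup(seed = 23, use_gnn = FALSE)
  expect_lt(numeric_grad_check(st, round = 1, n_checks = 40), 1e-4)
  st <- tiny_net_setup(seed = 24, use_embeddings = FALSE,
                       use_mask_channel = FALSE)
  expect_lt(numeric_grad_check(st, round = 1, n_checks = 40), 1e-4)
})

# training-mask sampling -------------------------------------------------------

test_that("training mask sizes follow the gamma interval", {
  obs <- seq_len(1000)
  sizes <- vapply(1:50, function(s)
    length(sample_training_mask(obs, c(0.05, 0.15), seed = s)), integer(1))
  expect_true(all(sizes >= 50 & sizes < 150))
  expect_identical(sample_training_mask(obs, seed = 3),
                   sample_training_mask(obs, seed = 3))
  expect_error(sample_training_mask(integer(0)), "empty")
})

test_that("mean masked fraction matches the uniform-interval mean", {
  obs <- seq_len(1000)
  set.seed(123)
  fracs <- vapply(seq_len(10000), function(i)
    length(sample_training_mask(obs)) / 1000, numeric(1))
  expect_lt(abs(mean(fracs) - 0.10), 0.003)
})

# losses ------------------------------------------------------------------------

test_that("round-1 loss is the masked MSE", {
  mu <- matrix(1:6 / 2, 2, 3)
  expect_equal(loss_round1(mu, mu[c(1, 4)], c(1, 4)), 0)
  expect_equal(loss_round1(mu, mu[c(1, 4)] + c(1, -1), c(1, 4)), 1)
  set.seed(8)
  idx <- sample(6, 4)
  truth <- rnorm(4)
  expect_equal(loss_round1(mu, truth, idx), sum((mu[idx] - truth)^2) / 4)
  expect_error(loss_round1(mu, numeric(0), integer(0)), "empty")
})

test_that("round-2 loss matches the Gaussian NLL closed form", {
  mu <- matrix(0, 1, 2)
  s2 <- matrix(1, 1, 2)
  expect_equal(loss_round2(mu, s2, c(0, 0), 1:2), 0)
  expect_equal(loss_round2(mu, s2, c(1, -1), 1:2), 0.5)
  # for fixed mu, the NLL at sigma^2 = (y - mu)^2 equals its analytic minimum
  y <- 1.7
  s2opt <- matrix((y - 0)^2, 1, 1)
  expect_equal(loss_round2(matrix(0, 1, 1), s2opt, y, 1),
               0.5 * (log(y^2) + 1))
})

# training behaviour ------------------------------------------------------------

test_that("a short training run reduces validation MSE on a tiny dataset", {
  ds <- random_dataset(n_prot = 5, pep_per = 4, s = 4, miss = 0.1, seed = 31)
  plan <- make_masked_split(ds, 0.1, 0.1, seed = 32)
  cfg <- model_config(attention_heads = 2L, latent_dim = 16L, final_dim = 16L,
                      embed_proj_dim = 4L, epoch_size = 100L, max_epochs = 3L,
                      patience = 2L, seed = 33L)
  fit <- train_gnn_imputer(ds, plan, cfg = cfg)
  expect_lte(fit$history$best_mse["round1"], fit$history$initial_mse["round1"])
})

test_that("training is deterministic and round 2 warm-starts from round 1", {
  ds <- random_dataset(n_prot = 4, pep_per = 3, s = 4, miss = 0.1, seed = 41)
  plan <- make_masked_split(ds, 0.1, 0.1, seed = 42)
  cfg <- model_config(attention_heads = 2L, latent_dim = 8L, final_dim = 8L,
                      embed_proj_dim = 4L, epoch_size = 10L, max_epochs = 2L,
                      patience = 1L, seed = 43L)
  fit1 <- train_gnn_imputer(ds, plan, cfg = cfg)
  fit2 <- train_gnn_imputer(ds, plan, cfg = cfg)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history, fit2$history)
  # round 2 starts from round-1 best weights
  expect_equal(unname(fit1$history$initial_mse["round2"]),
               unname(fit1$history$best_mse["round1"]), tolerance = 1e-6)
})

test_that("imputation preserves observed values and flags provenance", {
  ds <- random_dataset(n_prot = 4, pep_per = 3, s = 4, miss = 0.15, seed = 51)
  plan <- make_masked_split(ds, 0.1, 0.1, seed = 52)
  cfg <- model_config(attention_heads = 2L, latent_dim = 8L, final_dim = 8L,
                      embed_proj_dim = 4L, epoch_size = 5L, max_epochs = 1L,
                      seed = 53L)
  fit <- train_gnn_imputer(ds, plan, cfg = cfg)
  res <- impute_gnn(ds, fit)
  obs <- !is.na(ds$abundance)
  expect_identical(res$completed[obs], ds$abundance[obs])
  expect_false(anyNA(res$completed))
  expect_true(all(res$provenance[obs] == "observed"))
  expect_true(all(res$provenance[!obs] == "imputed"))
  expect_true(all(res$sigma2 > 0))
  expect_true(all(res$uncertainty[!obs] > 0))
  expect_true(all(is.na(res$uncertainty[obs])))
  # imputed entries equal the back-transformed predicted means
  expect_equal(res$completed[!obs],
               inverse_transform(res$mu, res$state)[!obs])
  # imputing a complete dataset changes nothing
  ds_full <- peptide_dataset(res$completed, ds$peptide_ids,
                             ds$protein_groups, ds$sample_ids)
  fit$graph <- build_peptide_graph(ds_full)
  res2 <- impute_gnn(ds_full, fit)
  expect_identical(res2$completed, res$completed)
  expect_true(all(res2$provenance == "observed"))
})

test_that("checkpoints round-trip a trained model", {
  ds <- random_dataset(n_prot = 3, pep_per = 3, s = 4, miss = 0.1, seed = 61)
  plan <- make_masked_split(ds, 0.1, 0.1, seed = 62)
  cfg <- model_config(attention_heads = 2L, latent_dim = 8L, final_dim = 8L,
                      embed_proj_dim = 4L, epoch_size = 5L, max_epochs = 1L,
                      seed = 63L)
  fit <- train_gnn_imputer(ds, plan, cfg = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_identical(fit2$params, fit$params)
  expect_identical(impute_gnn(ds, fit2)$completed,
                   impute_gnn(ds, fit)$completed)
})

# hash embedder ----------------------------------------------------------------

test_that("hash embeddings are deterministic, unit-norm and equivariant", {
  seqs <- c("PEPTIDEK", "ACDEFGHIK", "PEPTIDEK", "WYVR")
  E <- hash_embedder(seqs, d = 16)
  expect_equal(dim(E), c(4L, 16L))
  expect_identical(E[1, ], E[3, ])
  expect_equal(unname(apply(E, 1, function(v) sqrt(sum(v^2)))),
               rep(1, 4), tolerance = 1e-8)
  # permuting the input permutes the rows correspondingly
  perm <- c(2, 4, 1, 3)
  expect_identical(hash_embedder(seqs[perm], d = 16), E[perm, ])
  expect_error(hash_embedder(c("PEPTIDEK", "")), "empty")
  expect_error(hash_embedder("NOT4SEQ!"), "alphabet")
})

test_that("embedding tables round-trip and validate alignment", {
  set.seed(9)
  ids <- c("AAAK", "CCCR", "DDDK")
  E <- matrix(rnorm(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_table(E, ids, path)
  E2 <- load_embedding_table(path, ids)
  expect_equal(unname(E2), E, tolerance = 1e-12)
  # reordering is honoured, unknown ids rejected
  E3 <- load_embedding_table(path, rev(ids))
  expect_equal(unname(E3), E[3:1, ], tolerance = 1e-12)
  expect_error(load_embedding_table(path, c(ids, "MISSINGK")), "misaligned")
})
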
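#' Configuration of the graph attention imputer
#'
#' Architecture and training hyperparameters of the peptide-level GNN
#' imputer. The network projects a `d`-dimensional sequence embedding down to
#' `embed_proj_dim`, concatenates it with the peptide's abundance vector (and,
#' by default, a binary observed-value indicator channel), maps the result to
#' a `latent_dim` representation, runs one multi-head dynamic-attention layer
#' over the peptide-peptide graph (each head emitting `floor(s/2)` values),
#' concatenates the attention output with a skip connection around it, and
#' finally predicts per-(peptide, sample) Gaussian means and variances with
#' two separate output heads.
#'
#' @param embed_proj_dim width of the projected sequence embedding (16).
#' @param latent_dim width of the latent peptide representation (128).
#' @param attention_heads number of attention heads (64).
#' @param final_dim width of the post-attention representation (128).
#' @param gamma_interval half-open interval from which the self-supervised
#'   masking fraction is drawn uniformly at each training step.
#' @param epoch_size number of randomly masked datasets (gradient steps) that
#'   constitute one epoch.
#' @param learning_rate Adam learning rate.
#' @param max_epochs,patience early-stopping protocol per training round:
#'   training stops after `patience` epochs without improvement of the
#'   validation MSE and the best-validation weights are restored.
#' @param use_embeddings if `FALSE`, the sequence-embedding input is replaced
#'   by zeros (ablation switch).
#' @param use_gnn if `FALSE`, the attention output is replaced by zeros of
#'   the same width so the final block keeps its shape (ablation switch).
#' @param use_mask_channel if `TRUE` (default) an s-dimensional binary
#'   observed-value indicator is appended to the abundance vector, removing
#'   the ambiguity between a missing value and an abundance at the global
#'   mean (missing inputs are encoded as 0 on the standardized scale).
#' @param seed integer seed governing initialization and all training
#'   randomness; fixed seed gives identical parameter trajectories.
#' @return list of class `model_config`.
#' @export
model_config <- function(embed_proj_dim = 16L, latent_dim = 128L,
                         attention_heads = 64L, final_dim = 128L,
                         gamma_interval = c(0.05, 0.15), epoch_size = 500L,
                         learning_rate = 1e-3, max_epochs = 100L,
                         patience = 5L, use_embeddings = TRUE,
                         use_gnn = TRUE, use_mask_channel = TRUE,
                         seed = 1L) {
  stopifnot(embed_proj_dim >= 1L, latent_dim >= 1L, attention_heads >= 1L,
            final_dim >= 1L, length(gamma_interval) == 2L,
            gamma_interval[1L] > 0, gamma_interval[2L] < 1,
            gamma_interval[1L] < gamma_interval[2L],
            epoch_size >= 1L, max_epochs >= 1L, patience >= 1L)
  structure(list(embed_proj_dim = as.integer(embed_proj_dim),
                 latent_dim = as.integer(latent_dim),
                 attention_heads = as.integer(attention_heads),
                 final_dim = as.integer(final_dim),
                 gamma_interval = gamma_interval,
                 epoch_size = as.integer(epoch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 use_embeddings = isTRUE(use_embeddings),
                 use_gnn = isTRUE(use_gnn),
                 use_mask_channel = isTRUE(use_mask_channel),
                 seed = as.integer(seed)),
            class = "model_config")
}

# head output width: floor(s/2), at least 1 (requires s >= 2)
head_out_dim <- function(s) max(1L, s %/% 2L)

# directed edge tensors for message passing: both directions of every
# undirected edge plus one self-loop per node (self-attention)
graph_tensors <- function(g) {
  e <- g$edges
  n <- g$n
  dst <- c(e[, 1L], e[, 2L], seq_len(n))
  src <- c(e[, 2L], e[, 1L], seq_len(n))
  list(dst = as.integer(dst), src = as.integer(src), n = n)
}

# 0/1 matrix summing Dh-wide head blocks: (K*Dh) x K
block_sum_mat <- function(K, Dh) {
  M <- matrix(0, K * Dh, K)
  M[cbind(seq_len(K * Dh), rep(seq_len(K), each = Dh))] <- 1
  M
}

init_gnn_params <- function(cfg, s, d_embed) {
  Dh <- head_out_dim(s)
  K <- cfg$attention_heads
  KD <- K * Dh
  x_width <- s * (1L + cfg$use_mask_channel) + cfg$embed_proj_dim
  params <- list(
    We = glorot(d_embed, cfg$embed_proj_dim),
    be = numeric(cfg$embed_proj_dim),
    W1 = glorot(x_width, cfg$latent_dim),
    b1 = numeric(cfg$latent_dim),
    W2 = glorot(cfg$latent_dim, cfg$latent_dim),
    b2 = numeric(cfg$latent_dim),
    Wl = glorot(cfg$latent_dim, KD),
    Wr = glorot(cfg$latent_dim, KD),
    att = runif(KD, -sqrt(6 / (Dh + 1)), sqrt(6 / (Dh + 1))),
    W3 = glorot(KD + cfg$latent_dim, cfg$final_dim),
    b3 = numeric(cfg$final_dim),
    W4 = glorot(cfg$final_dim, cfg$final_dim),
    b4 = numeric(cfg$final_dim),
    Wm = glorot(cfg$final_dim, s),
    bm = numeric(s),
    Ws = glorot(cfg$final_dim, s),
    bs = numeric(s))
  params
}

SCORE_CLIP <- 30

#' Forward pass of the graph attention imputer
#'
#' Computes per-entry Gaussian means and variances from an encoded abundance
#' matrix, sequence embeddings and the peptide graph. Exposed mainly for
#' inspection and testing; training and imputation wrap it.
#'
#' @param params parameter list from a trained or initialized model.
#' @param a_enc `n x s` standardized abundance matrix with missing entries
#'   encoded as 0 (the standardized global mean).
#' @param obs_ind `n x s` binary observed-value indicator (1 = observed in
#'   the input), or `NULL` when `use_mask_channel` is off.
#' @param s_embed `n x d` sequence embedding matrix (ignored when
#'   `use_embeddings` is off, but a matrix of the right shape is still
#'   required to fix dimensions).
#' @param gt graph tensors from the peptide graph (internal; pass the graph
#'   through [train_gnn_imputer()] in normal use).
#' @param cfg a [model_config()].
#' @param keep_cache keep intermediates for backpropagation?
#' @return list with `mu`, `sigma2` (both `n x s`; `sigma2 > 0`) and,
#'   if requested, `cache`.
#' @export
gnn_forward <- function(params, a_enc, obs_ind, s_embed, gt, cfg,
                        keep_cache = FALSE) {
  n <- nrow(a_enc)
  s <- ncol(a_enc)
  Dh <- head_out_dim(s)
  K <- cfg$attention_heads
  KD <- K * Dh
  if (cfg$use_embeddings) {
    E0pre <- sweep(s_embed %*% params$We, 2, params$be, "+")
    E0 <- relu(E0pre)
  } else {
    E0pre <- NULL
    E0 <- matrix(0, n, cfg$embed_proj_dim)
  }
  X <- if (cfg$use_mask_channel) cbind(a_enc, obs_ind, E0) else cbind(a_enc, E0)
  H1pre <- sweep(X %*% params$W1, 2, params$b1, "+")
  H1 <- relu(H1pre)
  H <- sweep(H1 %*% params$W2, 2, params$b2, "+")
  if (cfg$use_gnn) {
    Hl <- H %*% params$Wl
    Hr <- H %*% params$Wr
    G <- Hl[gt$dst, , drop = FALSE] + Hr[gt$src, , drop = FALSE]
    Gact <- lrelu(G)
    BS <- block_sum_mat(K, Dh)
    score_raw <- sweep(Gact, 2, params$att, "*") %*% BS
    score <- pmin(pmax(score_raw, -SCORE_CLIP), SCORE_CLIP)
    expsc <- exp(score)
    den <- rowsum(expsc, gt$dst, reorder = TRUE)
    alpha <- expsc / den[gt$dst, , drop = FALSE]
    rep_idx <- rep(seq_len(K), each = Dh)
    alpharep <- alpha[, rep_idx, drop = FALSE]
    Msg <- Hr[gt$src, , drop = FALSE]
    Z <- rowsum(alpharep * Msg, gt$dst, reorder = TRUE)
  } else {
    Z <- matrix(0, n, KD)
  }
  C <- cbind(Z, H)
  F1pre <- sweep(C %*% params$W3, 2, params$b3, "+")
  F1 <- relu(F1pre)
  Ff <- sweep(F1 %*% params$W4, 2, params$b4, "+")
  mu <- sweep(Ff %*% params$Wm, 2, params$bm, "+")
  s2pre <- sweep(Ff %*% params$Ws, 2, params$bs, "+")
  sigma2 <- softplus(s2pre) + 1e-6
  if (any(!is.finite(mu)) || any(!is.finite(sigma2)))
    stop("numeric error: non-finite network output")
  out <- list(mu = mu, sigma2 = sigma2)
  if (keep_cache) {
    out$cache <- list(E0pre = E0pre, E0 = E0, X = X, H1pre = H1pre, H1 = H1,
                      H = H, C = C, F1pre = F1pre, F1 = F1, Ff = Ff,
                      s2pre = s2pre, s_embed = s_embed, n = n, s = s,
                      K = K, Dh = Dh)
    if (cfg$use_gnn)
      out$cache <- c(out$cache,
                     list(Hl = Hl, Hr = Hr, G = G, Gact = Gact,
                          score_raw = score_raw, alpha = alpha, Msg = Msg,
                          rep_idx = rep_idx))
  }
  out
}

# Backward pass: dmu, ds2 are gradients of the scalar loss w.r.t. mu and
# sigma2 (ds2 may be NULL in round 1). Returns gradients for all parameters.
gnn_backward <- function(params, cache, gt, cfg, dmu, ds2 = NULL) {
  K <- cache$K; Dh <- cache$Dh; KD <- K * Dh
  ds2pre <- if (is.null(ds2)) NULL else ds2 * sigmoid(cache$s2pre)
  dF <- tcrossprod(dmu, params$Wm)
  if (!is.null(ds2pre)) dF <- dF + tcrossprod(ds2pre, params$Ws)
  grads <- list(
    Wm = crossprod(cache$Ff, dmu), bm = colSums(dmu))
  if (!is.null(ds2pre)) {
    grads$Ws <- crossprod(cache$Ff, ds2pre)
    grads$bs <- colSums(ds2pre)
  }
  dF1 <- tcrossprod(dF, params$W4)
  grads$W4 <- crossprod(cache$F1, dF)
  grads$b4 <- colSums(dF)
  dF1pre <- dF1 * (cache$F1pre > 0)
  dC <- tcrossprod(dF1pre, params$W3)
  grads$W3 <- crossprod(cache$C, dF1pre)
  grads$b3 <- colSums(dF1pre)
  dZ <- dC[, seq_len(KD), drop = FALSE]
  dH <- dC[, KD + seq_len(cfg$latent_dim), drop = FALSE]
  if (cfg$use_gnn) {
    BS <- block_sum_mat(K, Dh)
    dWeighted <- dZ[gt$dst, , drop = FALSE]
    alpharep <- cache$alpha[, cache$rep_idx, drop = FALSE]
    dMsg <- dWeighted * alpharep
    dHr <- rowsum(dMsg, gt$src, reorder = TRUE)
    dalpha <- (dWeighted * cache$Msg) %*% BS
    ssum <- rowsum(cache$alpha * dalpha, gt$dst, reorder = TRUE)
    dscore <- cache$alpha * (dalpha - ssum[gt$dst, , drop = FALSE])
    dscore[abs(cache$score_raw) > SCORE_CLIP] <- 0
    dscore_rep <- dscore[, cache$rep_idx, drop = FALSE]
    dGact <- sweep(dscore_rep, 2, params$att, "*")
    grads$att <- colSums(dscore_rep * cache$Gact)
    dG <- dGact * ifelse(cache$G > 0, 1, 0.2)
    dHl <- rowsum(dG, gt$dst, reorder = TRUE)
    dHr <- dHr + rowsum(dG, gt$src, reorder = TRUE)
    grads$Wl <- crossprod(cache$H, dHl)
    grads$Wr <- crossprod(cache$H, dHr)
    dH <- dH + tcrossprod(dHl, params$Wl) + tcrossprod(dHr, params$Wr)
  }
  dH1 <- tcrossprod(dH, params$W2)
  grads$W2 <- crossprod(cache$H1, dH)
  grads$b2 <- colSums(dH)
  dH1pre <- dH1 * (cache$H1pre > 0)
  dX <- tcrossprod(dH1pre, params$W1)
  grads$W1 <- crossprod(cache$X, dH1pre)
  grads$b1 <- colSums(dH1pre)
  if (cfg$use_embeddings) {
    xw <- ncol(cache$X)
    dE0 <- dX[, (xw - cfg$embed_proj_dim + 1L):xw, drop = FALSE]
    dE0pre <- dE0 * (cache$E0pre > 0)
    grads$We <- crossprod(cache$s_embed, dE0pre)
    grads$be <- colSums(dE0pre)
  }
  grads
}

#' Draw a self-supervised training mask
#'
#' Samples a masking fraction gamma uniformly from the configured half-open
#' interval and then selects `floor(gamma * n_observed)` observed positions
#' uniformly without replacement. Held-out test/validation positions are
#' already missing in the training view and therefore can never be masked.
#'
#' @param observed linear indices (or positions) of observed entries in the
#'   training view.
#' @param gamma_interval numeric length-2 half-open interval, e.g.
#'   `c(0.05, 0.15)`.
#' @param seed optional seed; if `NULL` the current RNG stream is used (as
#'   during training).
#' @return Integer vector of masked linear indices.
#' @export
sample_training_mask <- function(observed, gamma_interval = c(0.05, 0.15),
                                 seed = NULL) {
  if (!length(observed)) stop("observed set is empty")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  gamma <- runif(1, gamma_interval[1L], gamma_interval[2L])
  m <- max(1L, as.integer(floor(gamma * length(observed))))
  sample(observed, m)
}

#' Round-1 training loss: mean squared error over masked positions
#' @param mu predicted mean matrix.
#' @param truth true (standardized) values at the masked positions.
#' @param idx linear indices of the masked positions.
#' @return scalar MSE.
#' @export
loss_round1 <- function(mu, truth, idx) {
  if (!length(idx)) stop("empty mask")
  mean((mu[idx] - truth)^2)
}

#' Round-2 training loss: Gaussian negative log-likelihood
#'
#' Mean over masked positions of `0.5 * (log(sigma2) + (y - mu)^2 / sigma2)`
#' (the additive constant is dropped); variances are floored at `1e-6`.
#'
#' @param mu,sigma2 predicted mean / variance matrices.
#' @param truth true values at the masked positions.
#' @param idx linear indices of the masked positions.
#' @return scalar loss.
#' @export
loss_round2 <- function(mu, sigma2, truth, idx) {
  if (!length(idx)) stop("empty mask")
  s2 <- pmax(sigma2[idx], 1e-6)
  mean(0.5 * (log(s2) + (mu[idx] - truth)^2 / s2))
}

encode_input <- function(trainZ, extra_mask = NULL) {
  A <- trainZ
  if (!is.null(extra_mask)) A[extra_mask] <- NA
  ind <- 1 - is.na(A)
  A[is.na(A)] <- 0
  list(a_enc = A, obs_ind = ind)
}

val_mse <- function(params, enc, s_embed, gt, cfg, plan) {
  fw <- gnn_forward(params, enc$a_enc, enc$obs_ind, s_embed, gt, cfg)
  mean((fw$mu[plan$val_idx] - plan$truth_val)^2)
}

run_training_round <- function(round, params, trainZ, observed, s_embed, gt,
                               cfg, plan, verbose) {
  adam <- adam_init(params)
  enc_val <- encode_input(trainZ)
  initial_mse <- val_mse(params, enc_val, s_embed, gt, cfg, plan)
  # best weights are chosen among the post-epoch checkpoints; the incoming
  # weights only serve as the pre-training baseline
  best <- NULL
  history <- numeric(0)
  stall <- 0L
  n <- nrow(trainZ)
  for (epoch in seq_len(cfg$max_epochs)) {
    for (step in seq_len(cfg$epoch_size)) {
      mask <- sample_training_mask(observed, cfg$gamma_interval)
      enc <- encode_input(trainZ, extra_mask = mask)
      fw <- gnn_forward(params, enc$a_enc, enc$obs_ind, s_embed, gt, cfg,
                        keep_cache = TRUE)
      truth <- trainZ[mask]
      m <- length(mask)
      dmu <- matrix(0, n, ncol(trainZ))
      if (round == 1L) {
        dmu[mask] <- 2 * (fw$mu[mask] - truth) / m
        grads <- gnn_backward(params, fw$cache, gt, cfg, dmu)
      } else {
        s2 <- pmax(fw$sigma2[mask], 1e-6)
        dmu[mask] <- (fw$mu[mask] - truth) / s2 / m
        ds2 <- matrix(0, n, ncol(trainZ))
        ds2[mask] <- 0.5 * (1 / s2 - (truth - fw$mu[mask])^2 / s2^2) / m
        ds2[mask][fw$sigma2[mask] < 1e-6] <- 0
        grads <- gnn_backward(params, fw$cache, gt, cfg, dmu, ds2)
      }
      upd <- adam_step(params, grads, adam, lr = cfg$learning_rate)
      params <- upd$params
      adam <- upd$state
    }
    mse <- val_mse(params, enc_val, s_embed, gt, cfg, plan)
    history <- c(history, mse)
    if (verbose)
      message(sprintf("round %d epoch %d: validation MSE %.5f", round, epoch, mse))
    if (is.null(best) || mse < best$mse - 1e-12) {
      best <- list(params = params, mse = mse)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  list(params = best$params, best_mse = best$mse,
       initial_mse = initial_mse, history = history)
}

#' Train the graph attention imputer
#'
#' Two-round self-supervised training. In each step an additional fraction of
#' the observed training entries is masked and the network is asked to
#' reconstruct them. Round 1 trains the mean head alone with MSE loss; round
#' 2 continues from the round-1 best weights and trains both heads jointly
#' with the Gaussian negative log-likelihood. Both rounds early-stop on the
#' validation-set MSE of the mean head and restore the best weights.
#'
#' @param ds a [peptide_dataset()].
#' @param plan a [mask_plan]; its test and validation positions are hidden
#'   from training.
#' @param embeddings optional `n x d` sequence embedding matrix (rows in
#'   dataset order). When `NULL`, deterministic k-mer hash embeddings are
#'   computed from the peptide ids via [hash_embedder()].
#' @param graph optional [build_peptide_graph()] result; built from the
#'   dataset when `NULL`.
#' @param cfg a [model_config()].
#' @param verbose print per-epoch validation MSE?
#' @return list of class `gnn_imputer` with `params`, `cfg`, `state`
#'   (transform), `history` (per-round validation curves) and `graph`.
#' @export
train_gnn_imputer <- function(ds, plan, embeddings = NULL, graph = NULL,
                              cfg = model_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "peptide_dataset"), inherits(plan, "mask_plan"))
  std <- log_standardize(ds)
  Z <- std$matrix
  if (ncol(Z) < 2L) stop("need at least two samples")
  trainZ <- apply_mask_plan(Z, plan)
  observed <- which(!is.na(trainZ))
  if (!length(observed)) stop("no observed entries left for training")
  if (is.null(graph)) graph <- build_peptide_graph(ds)
  if (is.null(embeddings)) embeddings <- hash_embedder(ds$peptide_ids)
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != nrow(Z))
    stop("embedding row count must match peptide count")
  if (anyNA(embeddings) || any(!is.finite(embeddings)))
    stop("embeddings must be finite with no missing entries")
  gt <- graph_tensors(graph)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  params <- init_gnn_params(cfg, ncol(Z), ncol(embeddings))
  r1 <- run_training_round(1L, params, trainZ, observed, embeddings, gt, cfg,
                           plan, verbose)
  r2 <- run_training_round(2L, r1$params, trainZ, observed, embeddings, gt,
                           cfg, plan, verbose)
  structure(list(params = r2$params, cfg = cfg, state = std$state,
                 history = list(round1 = r1$history, round2 = r2$history,
                                initial_mse = c(round1 = r1$initial_mse,
                                                round2 = r2$initial_mse),
                                best_mse = c(round1 = r1$best_mse,
                                             round2 = r2$best_mse)),
                 graph = graph, d_embed = ncol(embeddings)),
            class = "gnn_imputer")
}

#' @export
print.gnn_imputer <- function(x, ...) {
  cat(sprintf(paste0("gnn_imputer: %d attention heads, latent %d; best ",
                     "validation MSE %.4f (round 1) / %.4f (round 2)\n"),
              x$cfg$attention_heads, x$cfg$latent_dim,
              x$history$best_mse["round1"], x$history$best_mse["round2"]))
  invisible(x)
}

#' Impute a dataset with a trained graph attention imputer
#'
#' Observed entries are kept exactly; every missing entry is filled with the
#' predicted Gaussian mean mapped back to the raw measurement scale, and
#' carries a predicted standard deviation on the standardized log scale.
#'
#' @param ds the [peptide_dataset()] to complete.
#' @param fit a trained `gnn_imputer`.
#' @param embeddings embedding matrix as in [train_gnn_imputer()].
#' @param plan optional [mask_plan]; when given, its test/validation
#'   positions are hidden from the network input (benchmark mode) and appear
#'   as imputed entries in the result.
#' @return Object of class `imputation_result` with `completed` (raw scale,
#'   no missing entries), `mu` and `sigma2` (standardized log scale),
#'   `provenance` (`"observed"`/`"imputed"` per entry) and `uncertainty`
#'   (predicted sigma at imputed entries, `NA` elsewhere).
#' @export
impute_gnn <- function(ds, fit, embeddings = NULL, plan = NULL) {
  stopifnot(inherits(fit, "gnn_imputer"))
  std <- log_standardize(ds)
  Z <- std$matrix
  view <- if (is.null(plan)) Z else apply_mask_plan(Z, plan)
  if (is.null(embeddings)) embeddings <- hash_embedder(ds$peptide_ids)
  embeddings <- as.matrix(embeddings)
  gt <- graph_tensors(fit$graph)
  enc <- encode_input(view)
  fw <- gnn_forward(fit$params, enc$a_enc, enc$obs_ind, embeddings, gt,
                    fit$cfg)
  observed <- !is.na(view)
  completed <- inverse_transform(fw$mu, std$state)
  completed[observed] <- ds$abundance[observed]
  provenance <- matrix(ifelse(observed, "observed", "imputed"),
                       nrow(Z), ncol(Z), dimnames = dimnames(Z))
  uncertainty <- matrix(NA_real_, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  uncertainty[!observed] <- sqrt(fw$sigma2[!observed])
  structure(list(completed = completed, mu = fw$mu, sigma2 = fw$sigma2,
                 provenance = provenance, uncertainty = uncertainty,
                 state = std$state),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  n_imp <- sum(x$provenance == "imputed")
  cat(sprintf("imputation_result: %d x %d, %d imputed entries\n",
              nrow(x$completed), ncol(x$completed), n_imp))
  if (n_imp)
    cat(sprintf("  sigma (std-log scale): median %.3f, max %.3f\n",
                median(x$uncertainty[x$provenance == "imputed"]),
                max(x$uncertainty[x$provenance == "imputed"])))
  invisible(x)
}

#' Deterministic k-mer hash embeddings for peptide sequences
#'
#' A lightweight, fully deterministic stand-in for pretrained
#' protein-language-model embeddings: signed k-mer counts are hashed into `d`
#' buckets and the resulting vector is normalized to unit length. Identical
#' sequences always map to identical rows; the mapping depends only on the
#' sequence, `d`, `k` and `seed` (not on the R RNG).
#'
#' @param sequences character vector of amino-acid sequences.
#' @param d embedding dimension (default 64).
#' @param k k-mer length (sequences shorter than `k` contribute one k-mer,
#'   the whole sequence).
#' @param seed integer mixed into the hash.
#' @return `length(sequences) x d` matrix with unit-norm rows.
#' @export
hash_embedder <- function(sequences, d = 64L, k = 3L, seed = 1L) {
  if (!length(sequences)) stop("no sequences given")
  if (any(!nzchar(sequences))) stop("empty sequence")
  aa <- "^[ACDEFGHIKLMNPQRSTVWYXBZU]+$"
  if (any(!grepl(aa, sequences)))
    stop("sequences must use the amino-acid alphabet")
  p <- 2147483647
  E <- matrix(0, length(sequences), d)
  for (i in seq_along(sequences)) {
    codes <- utf8ToInt(sequences[i])
    L <- length(codes)
    kk <- min(k, L)
    v <- numeric(d)
    for (start in seq_len(L - kk + 1L)) {
      h <- (seed %% p)
      for (cc in codes[start:(start + kk - 1L)]) h <- (h * 131 + cc) %% p
      bucket <- (h %% d) + 1L
      sgn <- if ((h %/% d) %% 2 == 0) 1 else -1
      v[bucket] <- v[bucket] + sgn
    }
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) v[1L] <- 1 else v <- v / nrm
    E[i, ] <- v
  }
  rownames(E) <- names(sequences)
  E
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint records parameters, configuration (including the seed) and
#' the transform state, so imputation can be reproduced later.
#'
#' @param fit a `gnn_imputer`.
#' @param path checkpoint path (RDS).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gnn_imputer"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "gnn_imputer")) stop("not a gnn_imputer checkpoint")
  fit
}

#' Read / write a sequence-embedding table
#'
#' Plain-text embedding container: a TSV whose first column (`peptide_id`)
#' indexes the rows and whose remaining `d` columns hold the embedding
#' coordinates. On reading, rows are aligned to the supplied peptide ids and
#' a mismatch is an error.
#'
#' @param path TSV path.
#' @param peptide_ids ids to align against (dataset row order).
#' @return `n x d` numeric matrix in `peptide_ids` order.
#' @export
load_embedding_table <- function(path, peptide_ids) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  pos <- match(peptide_ids, ids)
  if (anyNA(pos))
    stop("embedding index misaligned: missing ids, e.g. ",
         peptide_ids[is.na(pos)][1L])
  E <- as.matrix(df[pos, -1L, drop = FALSE])
  storage.mode(E) <- "double"
  rownames(E) <- peptide_ids
  E
}

#' @rdname load_embedding_table
#' @param embeddings `n x d` matrix to write.
#' @export
write_embedding_table <- function(embeddings, peptide_ids, path) {
  df <- data.frame(peptide_id = peptide_ids, embeddings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
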
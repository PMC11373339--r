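# Comparison imputers. All operate on the standardized log-scale matrix with
# NA missing values (the same scale the GNN imputer trains on, so the
# benchmark is fair), never alter observed entries, return a matrix with no
# missing values, and are deterministic given their seed.

check_input_matrix <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (!any(!is.na(A))) stop("all entries missing")
  A
}

# restore observed entries bit-identically and verify totality
finalize_imputation <- function(A, filled) {
  obs <- !is.na(A)
  filled[obs] <- A[obs]
  if (anyNA(filled)) stop("imputer left missing values")
  dimnames(filled) <- dimnames(A)
  filled
}

col_quantiles <- function(A, q) {
  apply(A, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) stop("all-missing sample column")
    quantile(v, q, names = FALSE, type = 7)
  })
}

#' Minimum-value imputation (MinDet)
#'
#' Replaces every missing entry of a sample column with that column's
#' `q`-quantile of observed values (linear-interpolation quantiles). A
#' classical left-censoring imputer for abundance-dependent missingness.
#'
#' @param A standardized log-scale matrix with `NA` missing values.
#' @param q quantile (default 0.01).
#' @return Completed matrix.
#' @export
impute_mindet <- function(A, q = 0.01) {
  A <- check_input_matrix(A)
  fills <- col_quantiles(A, q)
  filled <- A
  for (j in seq_len(ncol(A))) filled[is.na(A[, j]), j] <- fills[j]
  finalize_imputation(A, filled)
}

#' Stochastic minimum-value imputation (MinProb)
#'
#' Draws each missing entry of sample column `j` from
#' `Normal(quantile_q(column j), (sd_scale * sd_j)^2)` where `sd_j` is the
#' standard deviation of the column's observed values. With `sd_scale = 0`
#' (or a constant column) this reduces to [impute_mindet()].
#'
#' @inheritParams impute_mindet
#' @param sd_scale multiplier on the observed column sd (default 0.01).
#' @param seed integer seed.
#' @export
impute_minprob <- function(A, q = 0.01, sd_scale = 0.01, seed = 1L) {
  A <- check_input_matrix(A)
  fills <- col_quantiles(A, q)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  filled <- A
  for (j in seq_len(ncol(A))) {
    mis <- which(is.na(A[, j]))
    if (!length(mis)) next
    sdj <- sd(A[, j], na.rm = TRUE)
    if (!is.finite(sdj)) sdj <- 0
    if (sd_scale * sdj > 0) {
      filled[mis, j] <- rnorm(length(mis), fills[j], sd_scale * sdj)
    } else {
      filled[mis, j] <- fills[j]
    }
  }
  finalize_imputation(A, filled)
}

#' Peptide-wise median imputation
#'
#' Missing entries of a peptide row are filled with the median of the row's
#' observed values; rows with no observed value fall back to the global
#' median of all observed entries.
#'
#' @inheritParams impute_mindet
#' @export
impute_median <- function(A) {
  A <- check_input_matrix(A)
  global <- median(A[!is.na(A)])
  row_med <- apply(A, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) median(v) else global
  })
  filled <- A
  mis <- which(is.na(A), arr.ind = TRUE)
  filled[mis] <- row_med[mis[, 1L]]
  finalize_imputation(A, filled)
}

# pairwise squared Euclidean distances over co-observed columns, scaled by
# s / #co-observed; Inf where no column is co-observed
knn_distances <- function(A) {
  s <- ncol(A)
  M <- (!is.na(A)) * 1
  Af <- A; Af[is.na(A)] <- 0
  A2 <- Af^2
  co <- tcrossprod(M)
  D2 <- tcrossprod(A2, M) + tcrossprod(M, A2) - 2 * tcrossprod(Af)
  D2 <- pmax(D2, 0) * s / co
  D2[co == 0] <- Inf
  diag(D2) <- Inf
  D2
}

#' K-nearest-neighbour imputation
#'
#' For each peptide row with missing values, the `k` nearest rows (Euclidean
#' distance over co-observed columns, rescaled by `sqrt(s / #co-observed)`)
#' are found; each missing cell is filled with the mean of the neighbours'
#' observed values in that column. Cells no neighbour can resolve fall back
#' to the row median (global median for all-missing rows).
#'
#' @inheritParams impute_mindet
#' @param k number of neighbours (default 10); requires `nrow(A) > k`.
#' @export
impute_knn <- function(A, k = 10L) {
  A <- check_input_matrix(A)
  if (k < 1L) stop("k must be at least 1")
  n <- nrow(A)
  if (n <= k) stop("need more rows than neighbours")
  D2 <- knn_distances(A)
  global <- median(A[!is.na(A)])
  filled <- A
  for (i in which(rowSums(is.na(A)) > 0)) {
    ord <- order(D2[i, ])[seq_len(k)]
    ord <- ord[is.finite(D2[i, ord])]
    row_med <- if (any(!is.na(A[i, ]))) median(A[i, ], na.rm = TRUE) else global
    for (j in which(is.na(A[i, ]))) {
      vals <- A[ord, j]
      vals <- vals[!is.na(vals)]
      filled[i, j] <- if (length(vals)) mean(vals) else row_med
    }
  }
  finalize_imputation(A, filled)
}

# Bayesian ridge regression (evidence approximation): returns a predictor
# closure. X may have as few as 1 column; intercept handled by centering.
bayes_ridge_fit <- function(X, y, max_iter = 100, tol = 1e-6) {
  X <- as.matrix(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  N <- nrow(X)
  alpha <- 1 / max(var(y), 1e-8)
  lambda <- 1
  w <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    Sinv <- lambda * diag(ncol(X)) + alpha * XtX
    w_new <- alpha * solve(Sinv, Xty)
    gam <- sum(alpha * ev / (lambda + alpha * ev))
    lambda <- (gam + 1e-8) / (sum(w_new^2) + 1e-8)
    rss <- sum((yc - Xc %*% w_new)^2)
    alpha <- max(N - gam, 1e-8) / max(rss, 1e-10)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  function(Xnew) drop(sweep(as.matrix(Xnew), 2, xbar) %*% w) + ybar
}

#' Chained-equations imputation with Bayesian ridge regression
#'
#' Single-imputation variant of multivariate imputation by chained equations:
#' missing entries are initialized with column means, then sample columns are
#' visited round-robin; each column with missingness is regressed on all
#' other columns (Bayesian ridge, evidence-approximation hyperparameters)
#' over the rows where it is observed, and its missing entries are replaced
#' by the posterior predictive mean.
#'
#' @inheritParams impute_mindet
#' @param iters number of round-robin sweeps (default 10).
#' @param seed kept for interface uniformity; the procedure is deterministic.
#' @export
impute_mice_ridge <- function(A, iters = 10L, seed = 1L) {
  A <- check_input_matrix(A)
  if (ncol(A) < 3L) stop("need at least 3 sample columns")
  filled <- A
  for (j in seq_len(ncol(A))) {
    cm <- mean(A[, j], na.rm = TRUE)
    if (!is.finite(cm)) cm <- mean(A[!is.na(A)])
    filled[is.na(A[, j]), j] <- cm
  }
  for (sweep_i in seq_len(iters)) {
    for (j in seq_len(ncol(A))) {
      mis <- which(is.na(A[, j]))
      if (!length(mis) || length(mis) == nrow(A)) next
      obs <- which(!is.na(A[, j]))
      pred <- bayes_ridge_fit(filled[obs, -j, drop = FALSE], A[obs, j])
      filled[mis, j] <- pred(filled[mis, -j, drop = FALSE])
    }
  }
  finalize_imputation(A, filled)
}

#' Random-forest imputation
#'
#' Iterative random-forest imputation in the style of missForest: missing
#' entries are initialized with column means; columns are visited in order of
#' increasing missingness, each fitted with a random forest (via
#' \pkg{ranger}) on the rows where the column is observed and predicted at
#' its missing rows; sweeps repeat until the change between completed
#' matrices stops decreasing or `max_iter` is reached.
#'
#' @inheritParams impute_mindet
#' @param num_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed (forests and sweep order are deterministic).
#' @export
impute_rf <- function(A, num_trees = 100L, max_iter = 10L, seed = 1L) {
  A <- check_input_matrix(A)
  filled <- A
  for (j in seq_len(ncol(A))) {
    cm <- mean(A[, j], na.rm = TRUE)
    if (!is.finite(cm)) cm <- mean(A[!is.na(A)])
    filled[is.na(A[, j]), j] <- cm
  }
  miss_count <- colSums(is.na(A))
  visit <- order(miss_count)
  visit <- visit[miss_count[visit] > 0 & miss_count[visit] < nrow(A)]
  if (!length(visit)) return(finalize_imputation(A, filled))
  prev_change <- Inf
  best <- filled
  for (it in seq_len(max_iter)) {
    old_filled <- filled
    for (j in visit) {
      obs <- which(!is.na(A[, j]))
      mis <- which(is.na(A[, j]))
      df <- as.data.frame(filled[, -j, drop = FALSE])
      names(df) <- paste0("V", seq_len(ncol(df)))
      fit <- ranger::ranger(x = df[obs, , drop = FALSE], y = A[obs, j],
                            num.trees = num_trees, seed = seed + it,
                            num.threads = 1L)
      filled[mis, j] <- predict(fit, df[mis, , drop = FALSE],
                                num.threads = 1L)$predictions
    }
    change <- sum((filled - old_filled)^2) / max(sum(filled^2), 1e-12)
    if (change > prev_change) { filled <- best; break }
    best <- filled
    prev_change <- change
  }
  finalize_imputation(A, filled)
}

#' Iterative SVD imputation
#'
#' Missing entries are initialized with row means (global mean for empty
#' rows); the matrix is then repeatedly approximated by its rank-`rank`
#' truncated SVD and missing entries refilled from the reconstruction until
#' the relative Frobenius change falls below `tol`.
#'
#' @inheritParams impute_mindet
#' @param rank SVD rank (default 2); must be at most `min(n, s) - 1`.
#' @param tol relative Frobenius convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @export
impute_isvd <- function(A, rank = 2L, tol = 1e-4, max_iter = 100L) {
  A <- check_input_matrix(A)
  if (rank > min(dim(A)) - 1L) stop("rank must be at most min(n, s) - 1")
  global <- mean(A[!is.na(A)])
  row_mean <- apply(A, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else global
  })
  filled <- A
  mis <- is.na(A)
  filled[mis] <- row_mean[row(A)[mis]]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sv <- svd(filled, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_filled <- filled
    new_filled[mis] <- recon[mis]
    delta <- sqrt(sum((new_filled - filled)^2)) /
      max(sqrt(sum(filled^2)), 1e-12)
    filled <- new_filled
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("ISVD did not converge; returning last iterate")
  finalize_imputation(A, filled)
}

#' Bayesian PCA imputation
#'
#' Probabilistic PCA with missing data fitted by expectation-maximization,
#' with automatic-relevance-determination precisions on the factor loading
#' columns so that unneeded components are shrunk away. Missing entries are
#' filled with the posterior predictive mean at convergence. Rows with
#' identical missingness patterns share their posterior computations.
#'
#' @inheritParams impute_mindet
#' @param n_components number of latent components (default `ncol(A) - 1`).
#' @param max_iter EM iteration cap (default 200).
#' @param tol relative change in loadings for convergence (default 1e-5).
#' @param seed kept for interface uniformity; initialization is an SVD and
#'   the algorithm is deterministic.
#' @return Completed matrix; attribute `"ard_alpha"` carries the final ARD
#'   precisions (large alpha = pruned component).
#' @export
impute_bpca <- function(A, n_components = ncol(A) - 1L, max_iter = 200L,
                        tol = 1e-5, seed = 1L) {
  A <- check_input_matrix(A)
  s <- ncol(A)
  q <- as.integer(n_components)
  if (q < 1L || q > s - 1L) stop("n_components must lie in [1, s - 1]")
  n <- nrow(A)
  obs <- !is.na(A)
  col_mean <- colMeans(A, na.rm = TRUE)
  col_mean[!is.finite(col_mean)] <- mean(A[obs])
  filled <- A
  filled[!obs] <- col_mean[col(A)[!obs]]
  mu <- colMeans(filled)
  Xc <- sweep(filled, 2, mu)
  sv <- svd(Xc, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  sigma2 <- max(mean(Xc^2) * 0.2, 1e-4)
  alpha <- rep(1, q)
  pat_key <- apply(obs, 1, function(v) paste(as.integer(v), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  for (it in seq_len(max_iter)) {
    Sxx <- matrix(0, q, q)
    Syx <- matrix(0, s, q)
    rss <- 0
    n_obs_total <- sum(obs)
    Xbar <- matrix(0, n, q)
    for (g in groups) {
      o <- obs[g[1L], ]
      if (!any(o)) next
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + sigma2 * diag(q)
      Minv <- solve(M)
      Yo <- sweep(filled[g, o, drop = FALSE], 2, mu[o])
      xb <- Yo %*% Wo %*% Minv
      Xbar[g, ] <- xb
      Sxx <- Sxx + length(g) * sigma2 * Minv + crossprod(xb)
      rss <- rss + sum((Yo - xb %*% t(Wo))^2) +
        length(g) * sigma2 * sum(diag(Wo %*% Minv %*% t(Wo)))
      if (any(!o)) {
        Wm <- W[!o, , drop = FALSE]
        filled[g, !o] <- sweep(xb %*% t(Wm), 2, mu[!o], "+")
      }
    }
    Yc <- sweep(filled, 2, mu)
    Syx <- crossprod(Yc, Xbar)
    W_new <- Syx %*% solve(Sxx + sigma2 * diag(alpha, q, q))
    sigma2 <- max(rss / n_obs_total, 1e-8)
    alpha <- s / (colSums(W_new^2) + 1e-8)
    delta <- sqrt(sum((W_new - W)^2)) / max(sqrt(sum(W^2)), 1e-12)
    W <- W_new
    mu <- colMeans(filled)
    if (delta < tol) break
  }
  if (delta >= tol) warning("BPCA did not fully converge; returning last iterate")
  out <- finalize_imputation(A, filled)
  attr(out, "ard_alpha") <- alpha
  out
}

#' Denoising-autoencoder imputation
#'
#' Compact reference version: each peptide row (abundance across samples,
#' missing as 0) is autoencoded through a small bottleneck network; during
#' training a random subset of observed inputs is zeroed and the network is
#' trained to reconstruct all observed entries. Missing cells are filled from
#' the reconstruction of the uncorrupted input.
#'
#' @inheritParams impute_mindet
#' @param hidden,latent layer widths of the bottleneck (defaults 32 / 8).
#' @param epochs full-batch Adam epochs (default 200).
#' @param lr learning rate.
#' @param corrupt_frac fraction of observed inputs zeroed per epoch.
#' @param seed integer seed.
#' @export
impute_dae <- function(A, hidden = 32L, latent = 8L, epochs = 200L,
                       lr = 1e-2, corrupt_frac = 0.2, seed = 1L) {
  A <- check_input_matrix(A)
  s <- ncol(A)
  obs <- !is.na(A)
  X0 <- A; X0[!obs] <- 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  params <- mlp_init(c(s, hidden, latent, hidden, s))
  adam <- adam_init(params)
  n_obs <- sum(obs)
  obs_lin <- which(obs)
  for (ep in seq_len(epochs)) {
    Xin <- X0
    drop_idx <- sample(obs_lin, max(1L, floor(corrupt_frac * n_obs)))
    Xin[drop_idx] <- 0
    fw <- mlp_forward(params, Xin)
    resid <- (fw$out - X0) * obs
    dout <- 2 * resid / n_obs
    bk <- mlp_backward(params, fw, dout)
    upd <- adam_step(params, bk$grads, adam, lr = lr)
    params <- upd$params; adam <- upd$state
  }
  recon <- mlp_forward(params, X0)$out
  finalize_imputation(A, recon)
}

#' Variational-autoencoder imputation
#'
#' Compact reference version: a Gaussian-latent variational autoencoder over
#' peptide rows (missing inputs as 0), trained on the reconstruction error of
#' observed entries plus a KL regularizer on the latent code. Missing cells
#' are filled from the decoded posterior mean.
#'
#' @inheritParams impute_dae
#' @param kl_weight weight of the KL term (default 0.05).
#' @export
impute_vae <- function(A, hidden = 32L, latent = 8L, epochs = 200L,
                       lr = 1e-2, kl_weight = 0.05, seed = 1L) {
  A <- check_input_matrix(A)
  s <- ncol(A)
  n <- nrow(A)
  obs <- !is.na(A)
  X0 <- A; X0[!obs] <- 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  enc <- mlp_init(c(s, hidden, 2L * latent))
  dec <- mlp_init(c(latent, hidden, s))
  adam_e <- adam_init(enc)
  adam_d <- adam_init(dec)
  n_obs <- sum(obs)
  for (ep in seq_len(epochs)) {
    fe <- mlp_forward(enc, X0)
    zmu <- fe$out[, seq_len(latent), drop = FALSE]
    zlv <- fe$out[, latent + seq_len(latent), drop = FALSE]
    zlv <- pmin(pmax(zlv, -10), 10)
    eps <- matrix(rnorm(n * latent), n, latent)
    z <- zmu + exp(zlv / 2) * eps
    fd <- mlp_forward(dec, z)
    resid <- (fd$out - X0) * obs
    dout <- 2 * resid / n_obs
    bd <- mlp_backward(dec, fd, dout)
    dz <- bd$dx
    dzmu <- dz + kl_weight * zmu / n
    dzlv <- dz * eps * 0.5 * exp(zlv / 2) +
      kl_weight * 0.5 * (exp(zlv) - 1) / n
    be <- mlp_backward(enc, fe, cbind(dzmu, dzlv))
    upd <- adam_step(dec, bd$grads, adam_d, lr = lr)
    dec <- upd$params; adam_d <- upd$state
    upd <- adam_step(enc, be$grads, adam_e, lr = lr)
    enc <- upd$params; adam_e <- upd$state
  }
  fe <- mlp_forward(enc, X0)
  zmu <- fe$out[, seq_len(latent), drop = FALSE]
  recon <- mlp_forward(dec, zmu)$out
  finalize_imputation(A, recon)
}

#' Collaborative-filtering imputation
#'
#' Biased matrix factorization: every observed entry is modelled as
#' `global + row bias + column bias + <peptide factor, sample factor>`,
#' fitted by alternating ridge-regularized least squares over the observed
#' entries only. Missing entries are predicted from the fitted factors.
#'
#' @inheritParams impute_mindet
#' @param dim latent factor dimension (default 8, capped at `s - 1`).
#' @param reg ridge regularization (default 0.1).
#' @param iters alternating sweeps (default 30).
#' @param seed integer seed for factor initialization.
#' @export
impute_cf <- function(A, dim = 8L, reg = 0.1, iters = 30L, seed = 1L) {
  A <- check_input_matrix(A)
  n <- nrow(A); s <- ncol(A)
  d <- min(as.integer(dim), s - 1L)
  obs <- !is.na(A)
  gm <- mean(A[obs])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  U <- matrix(rnorm(n * d, sd = 0.1), n, d)
  V <- matrix(rnorm(s * d, sd = 0.1), s, d)
  bi <- numeric(n); cj <- numeric(s)
  for (it in seq_len(iters)) {
    R <- A - gm
    for (i in seq_len(n)) {
      o <- which(obs[i, ])
      if (!length(o)) { bi[i] <- 0; U[i, ] <- 0; next }
      r <- R[i, o] - cj[o]
      bi[i] <- sum(r - U[i, ] %*% t(V[o, , drop = FALSE])) /
        (length(o) + reg)
      Vo <- V[o, , drop = FALSE]
      U[i, ] <- solve(crossprod(Vo) + reg * diag(d),
                      crossprod(Vo, r - bi[i]))
    }
    for (j in seq_len(s)) {
      o <- which(obs[, j])
      if (!length(o)) { cj[j] <- 0; V[j, ] <- 0; next }
      r <- R[o, j] - bi[o]
      cj[j] <- sum(r - U[o, , drop = FALSE] %*% V[j, ]) / (length(o) + reg)
      Uo <- U[o, , drop = FALSE]
      V[j, ] <- solve(crossprod(Uo) + reg * diag(d),
                      crossprod(Uo, r - cj[j]))
    }
  }
  pred <- gm + outer(bi, cj, "+") + tcrossprod(U, V)
  finalize_imputation(A, pred)
}

#' Registry of baseline imputers
#'
#' Maps method names to imputer functions with the common contract
#' `function(A, seed, params)` on the standardized log-scale matrix.
#'
#' @return Named list of imputer wrapper functions.
#' @export
imputer_registry <- function() {
  list(
    MinDet = function(A, seed, params)
      do.call(impute_mindet, c(list(A = A), params)),
    MinProb = function(A, seed, params)
      do.call(impute_minprob, c(list(A = A, seed = seed), params)),
    Median = function(A, seed, params)
      do.call(impute_median, c(list(A = A), params)),
    KNN = function(A, seed, params)
      do.call(impute_knn, c(list(A = A), params)),
    MICE = function(A, seed, params)
      do.call(impute_mice_ridge, c(list(A = A, seed = seed), params)),
    RF = function(A, seed, params)
      do.call(impute_rf, c(list(A = A, seed = seed), params)),
    ISVD = function(A, seed, params)
      do.call(impute_isvd, c(list(A = A), params)),
    BPCA = function(A, seed, params)
      do.call(impute_bpca, c(list(A = A, seed = seed), params)),
    DAE = function(A, seed, params)
      do.call(impute_dae, c(list(A = A, seed = seed), params)),
    VAE = function(A, seed, params)
      do.call(impute_vae, c(list(A = A, seed = seed), params)),
    CF = function(A, seed, params)
      do.call(impute_cf, c(list(A = A, seed = seed), params)))
}

#' Impute a matrix with a named baseline method
#'
#' @param A standardized log-scale matrix with `NA` missing values.
#' @param method a name from [imputer_registry()].
#' @param seed integer seed passed to stochastic methods.
#' @param params named list of method-specific hyperparameter overrides.
#' @return Completed matrix.
#' @export
impute_matrix <- function(A, method, seed = 1L, params = list()) {
  reg <- imputer_registry()
  if (!method %in% names(reg))
    stop("unknown imputation method '", method, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[method]](A, seed, params)
}
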
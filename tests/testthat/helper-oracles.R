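# Independent brute-force oracles used by unit and acceptance tests.

oracle_median <- function(A) {
  global <- median(A[!is.na(A)])
  out <- A
  for (i in seq_len(nrow(A))) {
    v <- A[i, ][!is.na(A[i, ])]
    fill <- if (length(v)) median(v) else global
    out[i, is.na(A[i, ])] <- fill
  }
  out
}

oracle_mindet <- function(A, q = 0.01) {
  out <- A
  for (j in seq_len(ncol(A))) {
    fill <- quantile(A[, j], q, na.rm = TRUE, names = FALSE, type = 7)
    out[is.na(A[, j]), j] <- fill
  }
  out
}

oracle_knn <- function(A, k) {
  n <- nrow(A); s <- ncol(A)
  global <- median(A[!is.na(A)])
  out <- A
  for (i in seq_len(n)) {
    if (!anyNA(A[i, ])) next
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i) next
      co <- which(!is.na(A[i, ]) & !is.na(A[r, ]))
      if (!length(co)) next
      d[r] <- sqrt(sum((A[i, co] - A[r, co])^2) * s / length(co))
    }
    nbr <- order(d)[seq_len(k)]
    nbr <- nbr[is.finite(d[nbr])]
    row_med <- if (any(!is.na(A[i, ]))) median(A[i, ], na.rm = TRUE) else global
    for (j in which(is.na(A[i, ]))) {
      v <- A[nbr, j]; v <- v[!is.na(v)]
      out[i, j] <- if (length(v)) mean(v) else row_med
    }
  }
  out
}

# exhaustive sign-flip enumeration for the one-sided signed-rank p-value
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d < 0])
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(r[signs == 1]) >= w_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# pairwise-concordance AUC (rank-sum identity); smaller score = positive call
oracle_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b)))
}
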
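# Shared neural-network primitives: activations, Glorot initialization and an
# Adam optimizer over named lists of parameter arrays. Used by the graph
# attention imputer and by the compact autoencoder baselines.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

lrelu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable softplus: log(1 + exp(x))
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Small fully-connected nets for the autoencoder baselines: layer sizes,
# ReLU between layers, linear output. Parameters named W1/b1, W2/b2, ...
mlp_init <- function(sizes) {
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- glorot(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, x) {
  nl <- length(params) / 2L
  acts <- list(x)
  pre <- list()
  h <- x
  for (l in seq_len(nl)) {
    z <- sweep(h %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]], "+")
    pre[[l]] <- z
    h <- if (l < nl) relu(z) else z
    acts[[l + 1L]] <- h
  }
  list(out = h, acts = acts, pre = pre)
}

mlp_backward <- function(params, cache, dout) {
  nl <- length(params) / 2L
  grads <- list()
  d <- dout
  for (l in rev(seq_len(nl))) {
    if (l < nl) d <- d * (cache$pre[[l]] > 0)
    grads[[paste0("W", l)]] <- crossprod(cache$acts[[l]], d)
    grads[[paste0("b", l)]] <- colSums(d)
    if (l > 1L) d <- tcrossprod(d, params[[paste0("W", l)]])
  }
  dx <- tcrossprod(d, params[["W1"]])
  list(grads = grads, dx = dx)
}
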
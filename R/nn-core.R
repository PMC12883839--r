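# Minimal neural-network primitives: dense and 1-D convolutional layers,
# batch normalization, activations, dropout, and SGD-momentum / Adam
# updates. Parameters and gradients are mirrored nested lists of numeric
# arrays; forward functions return the output plus a cache consumed by the
# matching backward function. Batches of spectra are arrays dim c(B, C, L)
# (sample, channel, position) or plain B x n matrices for dense layers.

init_he <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

init_glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), n_in, n_out)
}

## ---- dense ----

dense_init <- function(n_in, n_out, init = c("glorot", "he")) {
  init <- match.arg(init)
  W <- if (init == "glorot") init_glorot(n_in, n_out) else
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  list(W = W, b = numeric(n_out))
}

dense_forward <- function(p, X) {
  Y <- X %*% p$W
  Y <- sweep(Y, 2L, p$b, "+")
  list(Y = Y, cache = X)
}

dense_backward <- function(p, cache, dY) {
  list(grads = list(W = crossprod(cache, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

## ---- 1-D convolution (same padding, odd kernel) ----

conv1d_init <- function(c_in, c_out, k) {
  list(W = init_he(c(c_out, c_in, k), fan_in = c_in * k), b = numeric(c_out))
}

# im2col: X (B, C_in, L) -> matrix (B*L) x (C_in*k), rows ordered sample-
# fastest then position, column blocks ordered by tap then input channel.
# A single upfront aperm to (B, L, C) keeps per-tap slicing copy-cheap.
conv_im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; C <- d[2]; L <- d[3]
  pad <- (k - 1L) %/% 2L
  Xp <- aperm(X, c(1, 3, 2))                   # (B, L, C)
  dim(Xp) <- c(B * L, C)
  out <- matrix(0, B * L, C * k)
  for (t in seq_len(k)) {
    off <- t - 1L - pad
    l0 <- max(1L, 1L - off); l1 <- min(L, L - off)
    if (l0 > l1) next
    lr <- l0:l1
    rows <- c(outer(seq_len(B), (lr - 1L) * B, `+`))
    src <- c(outer(seq_len(B), (lr + off - 1L) * B, `+`))
    out[rows, ((t - 1L) * C + 1L):(t * C)] <- Xp[src, ]
  }
  out
}

conv1d_forward <- function(p, X) {
  d <- dim(X); B <- d[1]; L <- d[3]
  k <- dim(p$W)[3]; c_out <- dim(p$W)[1]
  Xcol <- conv_im2col(X, k)
  Wmat <- t(matrix(p$W, nrow = c_out))         # (C_in*k) x C_out
  Y <- Xcol %*% Wmat
  Y <- sweep(Y, 2L, p$b, "+")
  dim(Y) <- c(B, L, c_out)
  list(Y = aperm(Y, c(1, 3, 2)), cache = list(Xcol = Xcol, dims = d))
}

conv1d_backward <- function(p, cache, dY) {
  d <- cache$dims; B <- d[1]; C_in <- d[2]; L <- d[3]
  k <- dim(p$W)[3]; c_out <- dim(p$W)[1]
  dYmat <- aperm(dY, c(1, 3, 2)); dim(dYmat) <- c(B * L, c_out)
  dWmat <- crossprod(cache$Xcol, dYmat)        # (C_in*k) x C_out
  dW <- array(t(dWmat), dim = c(c_out, C_in, k))
  db <- colSums(dYmat)
  Wmat <- t(matrix(p$W, nrow = c_out))
  dXcol <- tcrossprod(dYmat, Wmat)             # (B*L) x (C_in*k)
  dXp <- matrix(0, B * L, C_in)                # (B, L) rows x C_in
  pad <- (k - 1L) %/% 2L
  for (t in seq_len(k)) {
    off <- t - 1L - pad
    l0 <- max(1L, 1L - off); l1 <- min(L, L - off)
    if (l0 > l1) next
    lr <- l0:l1
    rows <- c(outer(seq_len(B), (lr - 1L) * B, `+`))
    src <- c(outer(seq_len(B), (lr + off - 1L) * B, `+`))
    dXp[src, ] <- dXp[src, ] +
      dXcol[rows, ((t - 1L) * C_in + 1L):(t * C_in), drop = FALSE]
  }
  dim(dXp) <- c(B, L, C_in)
  list(grads = list(W = dW, b = db), dX = aperm(dXp, c(1, 3, 2)))
}

## ---- depthwise 1-D convolution ----

depthwise_init <- function(c_ch, k) {
  list(W = matrix(stats::rnorm(c_ch * k, 0, sqrt(2 / k)), c_ch, k),
       b = numeric(c_ch))
}

depthwise_forward <- function(p, X) {
  d <- dim(X)
  depthwise_forward_cpp(X, p$W, p$b, d[1], d[2], d[3])
}

depthwise_forward_cached <- function(p, X) {
  list(Y = depthwise_forward(p, X), cache = X)
}

depthwise_backward <- function(p, cache, dY) {
  d <- dim(cache)
  r <- depthwise_backward_cpp(cache, dY, p$W, d[1], d[2], d[3])
  list(grads = list(W = r$dW, b = drop(r$db)), dX = r$dX)
}

## ---- batch normalization over input bands ----

# Trainable parameters (gamma, beta) live in the model's parameter tree;
# running statistics are kept in a separate state list so optimizer updates
# and the L2 penalty never touch them.
batchnorm_init <- function(n) list(gamma = rep(1, n), beta = numeric(n))

batchnorm_stats_init <- function(n) list(mean = numeric(n), var = rep(1, n))

batchnorm_forward <- function(p, stats, X, train = TRUE, momentum = 0.1,
                              eps = 1e-5) {
  if (train && nrow(X) > 1L) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean; v <- stats$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(Y = Y, stats = stats, cache = list(xhat = xhat, inv_sd = inv_sd))
}

batchnorm_backward <- function(p, cache, dY) {
  B <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, p$gamma, "*")
  dX <- sweep(dxhat - matrix(colMeans(dxhat), B, ncol(dY), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), B, ncol(dY),
                              byrow = TRUE),
              2L, cache$inv_sd, "*")
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

## ---- activations, dropout, softmax ----

relu <- function(x) {
  x[x < 0] <- 0
  x
}
relu_backward <- function(x_pre, dY) dY * (x_pre > 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_backward <- function(x_pre, dY, slope = 0.2)
  dY * ifelse(x_pre > 0, 1, slope)

dropout_forward <- function(X, rate, train = TRUE) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(Y = X * mask, mask = mask)
}
dropout_backward <- function(mask, dY) if (is.null(mask)) dY else dY * mask

softmax_rows <- function(X) {
  m <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  e <- exp(X - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- nested parameter-list utilities ----

par_map <- function(p, f) {
  if (is.list(p)) lapply(p, par_map, f = f) else f(p)
}

par_map2 <- function(a, b, f) {
  if (is.list(a)) Map(par_map2, a, b, MoreArgs = list(f = f)) else f(a, b)
}

par_zeros <- function(p) par_map(p, function(x) x * 0)

par_sum_sq <- function(p) {
  if (is.list(p)) sum(vapply(p, par_sum_sq, numeric(1))) else sum(p^2)
}

par_count <- function(p) {
  if (is.list(p)) sum(vapply(p, par_count, numeric(1))) else length(p)
}

# SGD with momentum; batch-norm running statistics live inside the param
# list but receive zero "gradients", so they pass through unchanged.
sgd_step <- function(params, grads, vel, lr, momentum = 0.9) {
  vel <- par_map2(vel, grads, function(v, g) momentum * v + g)
  params <- par_map2(params, vel, function(p, v) p - lr * v)
  list(params = params, vel = vel)
}

adam_init <- function(params) list(m = par_zeros(params),
                                   v = par_zeros(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads,
                      function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v,
                  function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- par_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# Add the gradient of an L2 penalty eta * sum(theta^2) in place.
add_l2_grad <- function(grads, params, eta) {
  if (eta == 0) return(grads)
  par_map2(grads, params, function(g, p) g + 2 * eta * p)
}
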
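#' Feature-extractor configuration
#'
#' Hyperparameters of the IRAC extractor: a one-dimensional multi-branch
#' Inception-ResNet stage whose branches can replace plain convolution with
#' an ACmix block (parallel convolution and dot-product self-attention,
#' fused by learnable scalars alpha and beta). Input and output channel
#' counts are equal inside ACmix blocks so the blocks can be stacked freely.
#'
#' @param branch_kernels Odd kernel sizes of the three branches
#'   (default c(3, 5, 7)).
#' @param channels Channel width of the stem and every branch (default 8).
#' @param n_heads Attention heads inside ACmix; channel width must be
#'   divisible by it (default 1; the 176-band sequence is short).
#' @param n_bands Input sequence length L (default 176).
#' @param acmix_enabled Master switch; FALSE yields the plain
#'   Inception-ResNet baseline with identical layout.
#' @param acmix_branches Logical per branch: which branches use ACmix when
#'   enabled. Default: the two largest-kernel branches.
#' @return A list of class \code{irac_config}; \code{feature_dim} is
#'   \code{channels * n_bands} (the flattened final feature map).
#' @export
irac_config <- function(branch_kernels = c(3L, 5L, 7L), channels = 8L,
                        n_heads = 1L, n_bands = 176L, acmix_enabled = TRUE,
                        acmix_branches = c(FALSE, TRUE, TRUE)) {
  stopifnot(all(branch_kernels %% 2 == 1), channels >= 1, n_heads >= 1,
            channels %% n_heads == 0, n_bands >= 1,
            length(acmix_branches) == length(branch_kernels))
  structure(list(branch_kernels = as.integer(branch_kernels),
                 channels = as.integer(channels),
                 n_heads = as.integer(n_heads),
                 n_bands = as.integer(n_bands),
                 acmix_enabled = isTRUE(acmix_enabled),
                 acmix_branches = as.logical(acmix_branches),
                 feature_dim = as.integer(channels * n_bands)),
            class = "irac_config")
}

## ---- ACmix block ----

#' Initialize an ACmix block
#'
#' Parameters of one ACmix block over inputs of shape (batch, channels, L):
#' query/key/value pointwise projections and a learnable positional table
#' for the attention path; a pointwise then depthwise convolution for the
#' convolution path; learnable fusion scalars \code{alpha} (attention) and
#' \code{beta} (convolution), both initialized to 1.
#'
#' @param channels Channel count (input = output).
#' @param L Sequence length.
#' @param k Depthwise kernel size (odd).
#' @param n_heads Number of attention heads (divides \code{channels}).
#' @return Parameter list for \code{acmix_forward}.
#' @export
acmix_init <- function(channels, L, k, n_heads = 1L) {
  stopifnot(channels %% n_heads == 0, k %% 2 == 1)
  list(Wq = init_he(c(channels, channels), channels), bq = numeric(channels),
       Wk = init_he(c(channels, channels), channels), bk = numeric(channels),
       Wv = init_he(c(channels, channels), channels), bv = numeric(channels),
       pos = stats::rnorm(L, 0, 0.1),
       pw = conv1d_init(channels, channels, 1L),
       dw = depthwise_init(channels, k),
       alpha = 1.0, beta = 1.0)
}

#' ACmix block forward pass
#'
#' Computes \code{alpha * attention_path(x) + beta * conv_path(x)}. The
#' attention path projects channels to Q, K, V, scores positions by scaled
#' dot products plus the learnable positional term, softmaxes over key
#' positions and mixes V; the convolution path applies a 1x1 pointwise and
#' then a depthwise convolution.
#'
#' @param p Parameters from \code{\link{acmix_init}}.
#' @param X Array of shape (batch, channels, L).
#' @param n_heads Attention heads.
#' @param want_cache Keep intermediates for the backward pass.
#' @return List with \code{Y} (same shape as \code{X}) and, if requested,
#'   \code{cache}.
#' @export
acmix_forward <- function(p, X, n_heads = 1L, want_cache = FALSE) {
  d <- dim(X)
  # convolution path (batched)
  pwf <- conv1d_forward(p$pw, X)
  dwf <- depthwise_forward_cached(p$dw, pwf$Y)
  conv_out <- dwf$Y
  # attention path (compiled kernel over (C, L, batch) slices)
  Xc <- aperm(X, c(2, 3, 1))
  af <- acmix_att_forward_cpp(Xc, p$Wq, p$bq, p$Wk, p$bk, p$Wv, p$bv,
                              p$pos, as.integer(n_heads), want_cache)
  att_out <- aperm(af$out, c(3, 1, 2))
  Y <- p$alpha * att_out + p$beta * conv_out
  cache <- if (want_cache)
    list(Xc = Xc, pw = pwf$cache, dw = dwf$cache, att_out = att_out,
         conv_out = conv_out, Q = af$Q, K = af$K, V = af$V, A = af$A,
         n_heads = as.integer(n_heads))
  list(Y = Y, cache = cache)
}

acmix_backward <- function(p, cache, dY) {
  dalpha <- sum(dY * cache$att_out)
  dbeta <- sum(dY * cache$conv_out)
  # conv path
  dconv <- p$beta * dY
  dwb <- depthwise_backward(p$dw, cache$dw, dconv)
  pwb <- conv1d_backward(p$pw, cache$pw, dwb$dX)
  # attention path
  dAtt <- aperm(p$alpha * dY, c(2, 3, 1))
  ab <- acmix_att_backward_cpp(cache$Xc, dAtt, cache$Q, cache$K, cache$V,
                               cache$A, p$Wq, p$Wk, p$Wv, cache$n_heads)
  dX <- pwb$dX + aperm(ab$dX, c(3, 1, 2))
  list(grads = list(Wq = ab$dWq, bq = drop(ab$dbq), Wk = ab$dWk,
                    bk = drop(ab$dbk), Wv = ab$dWv, bv = drop(ab$dbv),
                    pos = drop(ab$dpos),
                    pw = pwb$grads, dw = dwb$grads,
                    alpha = dalpha, beta = dbeta),
       dX = dX)
}

## ---- full extractor ----

#' Build an IRAC feature extractor
#'
#' Assembles the extractor: input batch normalization, a stem convolution,
#' three parallel branches with different kernel sizes (ACmix replacing
#' plain convolution where configured), channel concatenation, 1x1 fusion,
#' a residual connection back to the stem output, and flattening to a
#' feature vector of length \code{cfg$feature_dim}. Convolutional weights
#' use He initialization.
#'
#' @param cfg An \code{\link{irac_config}}.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class \code{irac_extractor}.
#' @export
build_irac <- function(cfg = irac_config(), seed = 1L) {
  stopifnot(inherits(cfg, "irac_config"))
  set.seed(seed)
  C <- cfg$channels; L <- cfg$n_bands
  use_acmix <- cfg$acmix_enabled & cfg$acmix_branches
  branches <- vector("list", length(cfg$branch_kernels))
  for (j in seq_along(branches)) {
    k <- cfg$branch_kernels[j]
    branches[[j]] <- if (use_acmix[j]) acmix_init(C, L, k, cfg$n_heads)
                     else conv1d_init(C, C, k)
  }
  params <- list(bn = batchnorm_init(L),
                 stem = conv1d_init(1L, C, 3L),
                 branches = branches,
                 fuse = conv1d_init(length(branches) * C, C, 1L))
  structure(list(cfg = cfg, params = params,
                 bn_stats = batchnorm_stats_init(L),
                 use_acmix = use_acmix, seed = as.integer(seed)),
            class = "irac_extractor")
}

#' @export
print.irac_extractor <- function(x, ...) {
  cat("<irac_extractor> ", x$cfg$n_bands, " bands -> ", x$cfg$feature_dim,
      " features; channels=", x$cfg$channels, "\n", sep = "")
  cat("  branches: kernels", paste(x$cfg$branch_kernels, collapse = "/"),
      "| ACmix:", paste(ifelse(x$use_acmix, "yes", "no"), collapse = "/"),
      "\n")
  cat("  parameters:", par_count(x$params), "\n")
  invisible(x)
}

# Forward pass through the extractor. X is a B x L matrix of normalized
# spectra. Returns features (B x feature_dim), updated batch-norm stats,
# and a cache when training.
irac_forward <- function(params, bn_stats, cfg, use_acmix, X,
                         train = FALSE, want_cache = FALSE) {
  B <- nrow(X); L <- cfg$n_bands; C <- cfg$channels
  if (ncol(X) != L) stop("input has ", ncol(X), " bands; extractor expects ", L)
  bnf <- batchnorm_forward(params$bn, bn_stats, X, train = train)
  X1 <- array(bnf$Y, dim = c(B, 1L, L))
  stemf <- conv1d_forward(params$stem, X1)
  stem_pre <- stemf$Y
  S <- relu(stem_pre)
  nb <- length(params$branches)
  bouts <- vector("list", nb); bcaches <- vector("list", nb)
  for (j in seq_len(nb)) {
    if (use_acmix[j]) {
      f <- acmix_forward(params$branches[[j]], S, n_heads = cfg$n_heads,
                         want_cache = want_cache)
      bouts[[j]] <- f$Y; bcaches[[j]] <- f$cache
    } else {
      f <- conv1d_forward(params$branches[[j]], S)
      bouts[[j]] <- f$Y; bcaches[[j]] <- f$cache
    }
  }
  concat <- array(0, dim = c(B, nb * C, L))
  for (j in seq_len(nb)) concat[, ((j - 1) * C + 1):(j * C), ] <- bouts[[j]]
  fusef <- conv1d_forward(params$fuse, concat)
  res_pre <- fusef$Y + S
  Z <- relu(res_pre)
  feats <- matrix(Z, B, C * L)
  cache <- if (want_cache)
    list(bn = bnf$cache, stem = stemf$cache, stem_pre = stem_pre,
         branch = bcaches, fuse = fusef$cache, res_pre = res_pre,
         dims = c(B, C, L))
  list(features = feats, bn_stats = bnf$stats, cache = cache)
}

irac_backward <- function(params, cfg, use_acmix, cache, dFeat) {
  B <- cache$dims[1]; C <- cache$dims[2]; L <- cache$dims[3]
  nb <- length(params$branches)
  dZ <- array(dFeat, dim = c(B, C, L))
  dres <- relu_backward(cache$res_pre, dZ)
  fuseb <- conv1d_backward(params$fuse, cache$fuse, dres)
  dS_total <- dres                      # residual shortcut
  gbranches <- vector("list", nb)
  for (j in seq_len(nb)) {
    dbranch <- fuseb$dX[, ((j - 1) * C + 1):(j * C), , drop = FALSE]
    if (use_acmix[j]) {
      bb <- acmix_backward(params$branches[[j]], cache$branch[[j]], dbranch)
    } else {
      bb <- conv1d_backward(params$branches[[j]], cache$branch[[j]], dbranch)
    }
    gbranches[[j]] <- bb$grads
    dS_total <- dS_total + bb$dX
  }
  dstem_pre <- relu_backward(cache$stem_pre, dS_total)
  stemb <- conv1d_backward(params$stem, cache$stem, dstem_pre)
  dX1 <- matrix(stemb$dX, B, L)
  bnb <- batchnorm_backward(params$bn, cache$bn, dX1)
  list(grads = list(bn = bnb$grads, stem = stemb$grads,
                    branches = gbranches, fuse = fuseb$grads))
}

#' Extract feature vectors from spectra
#'
#' Runs the extractor in inference mode (batch-norm uses running
#' statistics; deterministic).
#'
#' @param extractor An \code{irac_extractor}.
#' @param x A \code{spectra_set} or numeric matrix (rows = spectra) of
#'   normalized reflectance.
#' @return Matrix of shape n_samples x feature_dim.
#' @export
extract_features <- function(extractor, x) {
  stopifnot(inherits(extractor, "irac_extractor"))
  X <- if (inherits(x, "spectra_set")) x$spectra else as.matrix(x)
  irac_forward(extractor$params, extractor$bn_stats, extractor$cfg,
               extractor$use_acmix, X, train = FALSE)$features
}
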
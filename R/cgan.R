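#' Conditional-GAN configuration
#'
#' Architecture and training settings for the psi-conditioned spectral
#' generator. Generator and discriminator are small fully connected
#' networks over the 176-band vectors; the conditioning water potential is
#' normalized to [-1, 1] using the training-label range and concatenated to
#' the input of both networks (repeated to \code{cond_width} units).
#'
#' @param noise_dim Length of the generator noise vector z (default 64).
#' @param cond_width Width of the condition embedding (default 8).
#' @param gen_hidden,disc_hidden Hidden-layer widths (single hidden layer).
#' @param epochs Adversarial training epochs (default 2000).
#' @param batch_size Minibatch size (default 64).
#' @param lr_g,lr_d Adam learning rates of generator / discriminator.
#' @param out_scale Upper bound of the sigmoid-bounded generator output
#'   (default 1.2, the ceiling of physically plausible reflectance).
#' @param ema_decay Decay of the exponential moving average of generator
#'   weights used for synthesis; adversarial updates oscillate around the
#'   equilibrium and the averaged generator is markedly more faithful
#'   (default 0.999; 0 disables).
#' @param seed Integer seed: training is deterministic given data and config.
#' @param n_synthetic Number of spectra synthesized for augmentation
#'   (default 500).
#' @return A list of class \code{cgan_config}.
#' @export
cgan_config <- function(noise_dim = 64L, cond_width = 8L, gen_hidden = 64L,
                        disc_hidden = 64L, epochs = 2000L, batch_size = 64L,
                        lr_g = 1e-3, lr_d = 1e-3, out_scale = 1.2,
                        ema_decay = 0.999, seed = 1L, n_synthetic = 500L) {
  stopifnot(noise_dim >= 1, cond_width >= 1, gen_hidden >= 1,
            disc_hidden >= 1, epochs >= 0, batch_size >= 1,
            lr_g > 0, lr_d > 0, out_scale > 0, ema_decay >= 0, ema_decay < 1,
            n_synthetic >= 0)
  structure(list(noise_dim = as.integer(noise_dim),
                 cond_width = as.integer(cond_width),
                 gen_hidden = as.integer(gen_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, out_scale = out_scale,
                 ema_decay = ema_decay, seed = as.integer(seed),
                 n_synthetic = as.integer(n_synthetic)),
            class = "cgan_config")
}

# Condition embedding: the psi value normalized to [-1, 1] on the training
# range, expanded in a fixed polynomial/Fourier basis (z, sin k pi z,
# cos k pi z, ...) of the configured width. The richer basis lets both
# networks resolve the conditioning value much faster than a raw scalar.
cond_embed <- function(psi, norm, width) {
  z <- 2 * (psi - norm$lo) / (norm$hi - norm$lo) - 1
  E <- matrix(0, length(psi), width)
  E[, 1] <- z
  j <- 2L; k <- 1L
  while (j <= width) {
    E[, j] <- sin(k * pi * z); j <- j + 1L
    if (j <= width) { E[, j] <- cos(k * pi * z); j <- j + 1L }
    k <- k + 1L
  }
  E
}

# Generator: [z, condition] -> hidden ReLU -> (hidden, condition) ->
# sigmoid output scaled to (0, out_scale), bounding spectra to the
# physically plausible range. The condition re-enters every layer.
gen_forward <- function(p, Z, E, out_scale, want_cache = FALSE) {
  X0 <- cbind(Z, E)
  h <- dense_forward(p$fc1, X0)
  a <- relu(h$Y)
  A2 <- cbind(a, E)
  o <- dense_forward(p$fc2, A2)
  s <- sigmoid(o$Y)
  list(Y = out_scale * s,
       cache = if (want_cache) list(X0 = X0, h_pre = h$Y, A2 = A2, s = s))
}

gen_backward <- function(p, cache, dY, out_scale) {
  dO <- dY * out_scale * cache$s * (1 - cache$s)
  b2 <- dense_backward(p$fc2, cache$A2, dO)
  nh <- ncol(cache$h_pre)
  da <- relu_backward(cache$h_pre, b2$dX[, seq_len(nh), drop = FALSE])
  b1 <- dense_backward(p$fc1, cache$X0, da)
  list(fc1 = b1$grads, fc2 = b2$grads)
}

disc_forward <- function(p, X, E, want_cache = FALSE) {
  X0 <- cbind(X, E)
  h <- dense_forward(p$fc1, X0)
  a <- leaky_relu(h$Y)
  A2 <- cbind(a, E)
  o <- dense_forward(p$fc2, A2)
  list(logit = drop(o$Y),
       cache = if (want_cache) list(X0 = X0, h_pre = h$Y, A2 = A2))
}

# Backward of binary cross-entropy with logits wrt the logit is
# sigmoid(logit) - target; propagate through the discriminator, returning
# both parameter gradients and the gradient wrt the input spectra.
disc_backward <- function(p, cache, dlogit) {
  dY <- matrix(dlogit, ncol = 1L)
  b2 <- dense_backward(p$fc2, cache$A2, dY)
  nh <- ncol(cache$h_pre)
  da <- leaky_relu_backward(cache$h_pre, b2$dX[, seq_len(nh), drop = FALSE])
  b1 <- dense_backward(p$fc1, cache$X0, da)
  list(grads = list(fc1 = b1$grads, fc2 = b2$grads), dX0 = b1$dX)
}

bce_logit_loss <- function(logit, target) {
  # numerically stable binary cross-entropy with logits
  mean(pmax(logit, 0) - logit * target + log1p(exp(-abs(logit))))
}

#' Train a psi-conditioned GAN on labelled spectra
#'
#' Alternating adversarial training: the discriminator learns to tell
#' measured spectra from generated ones given the conditioning water
#' potential, and the generator learns to fool it (non-saturating
#' generator objective, which shares the minimax fixed point). Both
#' networks are updated with Adam. An exponential moving average of the
#' generator weights is maintained and used for synthesis. Training must
#' only ever see training rows; pass the training subset, never validation
#' or test samples.
#'
#' @param train_set A labelled \code{spectra_set} (training rows only).
#' @param cfg A \code{\link{cgan_config}}.
#' @return An object of class \code{cgan_bundle}: generator and
#'   discriminator parameters, per-epoch loss traces of both players, the
#'   condition normalization constants, and the wavelength grid.
#' @export
train_cgan <- function(train_set, cfg = cgan_config()) {
  stopifnot(inherits(train_set, "spectra_set"))
  if (is.null(train_set$psi))
    stop("CGAN training requires a labelled spectra_set")
  X <- train_set$spectra
  n <- nrow(X); L <- ncol(X)
  if (n < cfg$batch_size)
    stop("training set has ", n, " rows but batch_size is ", cfg$batch_size,
         "; use a smaller batch_size")
  norm <- list(lo = min(train_set$psi), hi = max(train_set$psi))
  if (norm$hi - norm$lo <= 0) stop("degenerate psi range in training set")
  set.seed(cfg$seed)
  gen <- list(fc1 = dense_init(cfg$noise_dim + cfg$cond_width,
                               cfg$gen_hidden, "glorot"),
              fc2 = dense_init(cfg$gen_hidden + cfg$cond_width, L, "glorot"))
  disc <- list(fc1 = dense_init(L + cfg$cond_width, cfg$disc_hidden,
                                "glorot"),
               fc2 = dense_init(cfg$disc_hidden + cfg$cond_width, 1L,
                                "glorot"))
  g_state <- adam_init(gen); d_state <- adam_init(disc)
  gen_ema <- gen
  E_all <- cond_embed(train_set$psi, norm, cfg$cond_width)
  g_trace <- numeric(cfg$epochs); d_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    gl <- 0; dl <- 0; nb <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      B <- length(idx)
      Xr <- X[idx, , drop = FALSE]
      Er <- E_all[idx, , drop = FALSE]
      Z <- matrix(stats::rnorm(B * cfg$noise_dim), B)
      gf <- gen_forward(gen, Z, Er, cfg$out_scale, want_cache = TRUE)
      # --- discriminator update ---
      dfr <- disc_forward(disc, Xr, Er, want_cache = TRUE)
      dff <- disc_forward(disc, gf$Y, Er, want_cache = TRUE)
      d_loss <- bce_logit_loss(dfr$logit, 1) + bce_logit_loss(dff$logit, 0)
      gr <- disc_backward(disc, dfr$cache, (sigmoid(dfr$logit) - 1) / B)
      gfk <- disc_backward(disc, dff$cache, sigmoid(dff$logit) / B)
      d_grads <- par_map2(gr$grads, gfk$grads, `+`)
      upd <- adam_step(disc, d_grads, d_state, lr = cfg$lr_d)
      disc <- upd$params; d_state <- upd$state
      # --- generator update (non-saturating: maximize log D(fake)) ---
      dff2 <- disc_forward(disc, gf$Y, Er, want_cache = TRUE)
      g_loss <- bce_logit_loss(dff2$logit, 1)
      db <- disc_backward(disc, dff2$cache, (sigmoid(dff2$logit) - 1) / B)
      dXfake <- db$dX0[, seq_len(L), drop = FALSE]
      g_grads <- gen_backward(gen, gf$cache, dXfake, cfg$out_scale)
      updg <- adam_step(gen, g_grads, g_state, lr = cfg$lr_g)
      gen <- updg$params; g_state <- updg$state
      gen_ema <- par_map2(gen_ema, gen, function(e, g)
        cfg$ema_decay * e + (1 - cfg$ema_decay) * g)
      gl <- gl + g_loss; dl <- dl + d_loss; nb <- nb + 1
    }
    g_trace[ep] <- gl / nb; d_trace[ep] <- dl / nb
  }
  structure(list(gen = gen_ema, gen_last = gen, disc = disc, cfg = cfg,
                 norm = norm, grid = train_set$grid, n_bands = L,
                 loss_trace = list(generator = g_trace,
                                   discriminator = d_trace),
                 trained = cfg$epochs > 0L),
            class = "cgan_bundle")
}

#' @export
print.cgan_bundle <- function(x, ...) {
  cat("<cgan_bundle> ", x$n_bands, " bands; noise_dim=", x$cfg$noise_dim,
      "; epochs=", x$cfg$epochs, "\n", sep = "")
  cat(sprintf("  condition range: [%.3f, %.3f] MPa\n", x$norm$lo, x$norm$hi))
  if (x$cfg$epochs > 0)
    cat(sprintf("  final losses: G=%.4f D=%.4f\n",
                utils::tail(x$loss_trace$generator, 1),
                utils::tail(x$loss_trace$discriminator, 1)))
  invisible(x)
}

#' Evenly spaced water-potential condition grid
#'
#' \code{n} evenly spaced psi values spanning [psi_min, psi_max], endpoints
#' included — the gap-filling resampling used before conditional synthesis.
#' \code{random = TRUE} switches to uniform random draws on the same range.
#'
#' @param n Number of conditions (>= 2); the augmentation default is 500.
#' @param psi_min,psi_max Range in MPa, \code{psi_min < psi_max <= 0}.
#' @param random Draw uniformly at random instead of an even grid.
#' @return Numeric vector of length \code{n}.
#' @export
#' @examples
#' resample_condition_grid(5, -1, 0)  # -1 -0.75 -0.5 -0.25 0
resample_condition_grid <- function(n, psi_min, psi_max, random = FALSE) {
  if (!(psi_min < psi_max) || psi_max > 0)
    stop("need psi_min < psi_max <= 0")
  if (n < 2) stop("n must be >= 2")
  if (random) sort(stats::runif(n, psi_min, psi_max))
  else seq(psi_min, psi_max, length.out = n)
}

#' Generate spectra at given water-potential conditions
#'
#' Feeds fresh seeded noise and the conditioning values through the trained
#' generator; one spectrum per condition, clipped below at 0, labelled with
#' its conditioning psi and flagged \code{"cgan_generated"}.
#'
#' @param bundle A trained \code{cgan_bundle}.
#' @param psi_values Conditioning water potentials (MPa).
#' @param seed Seed for the noise draws.
#' @param allow_untrained Permit sampling from an untrained (epoch-0)
#'   generator, e.g. as a random-initialization reference.
#' @return A \code{spectra_set} of generated spectra.
#' @export
generate_conditioned_spectra <- function(bundle, psi_values, seed = 1L,
                                         allow_untrained = FALSE) {
  stopifnot(inherits(bundle, "cgan_bundle"))
  if (!isTRUE(bundle$trained) && !allow_untrained)
    stop("bundle is untrained (epochs = 0); train the CGAN first")
  n <- length(psi_values)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * bundle$cfg$noise_dim), n)
  E <- cond_embed(psi_values, bundle$norm, bundle$cfg$cond_width)
  Y <- gen_forward(bundle$gen, Z, E, bundle$cfg$out_scale)$Y
  spectra_set(pmax(Y, 0), grid = bundle$grid, psi = psi_values,
              sample_ids = sprintf("g%03d", seq_len(n)),
              provenance = "cgan_generated")
}

#' Spectral-angle fidelity between real and generated sets
#'
#' The spectral angle (radians) between the column-mean spectrum of the
#' real samples and the column-mean spectrum of the generated samples.
#' Values below 0.1 rad indicate high spectral fidelity.
#'
#' @param real,generated \code{spectra_set} objects on the same grid.
#' @return Angle in radians.
#' @export
fidelity_sam <- function(real, generated) {
  stopifnot(inherits(real, "spectra_set"), inherits(generated, "spectra_set"))
  if (nrow(real$spectra) == 0L || nrow(generated$spectra) == 0L)
    stop("empty spectra set")
  if (length(real$grid) != length(generated$grid) ||
      max(abs(real$grid - generated$grid)) > 1e-8)
    stop("wavelength grids differ")
  spectral_angle(colMeans(real$spectra), colMeans(generated$spectra))
}

#' Augment a training set with conditionally generated spectra
#'
#' Generates \code{cfg$n_synthetic} spectra at an evenly spaced condition
#' grid spanning the training psi range and row-binds them to the training
#' set. Pure function: the input set is not modified; validation and test
#' rows must never enter here.
#'
#' @param train A labelled \code{spectra_set} (training rows only).
#' @param bundle A trained \code{cgan_bundle}.
#' @param cfg A \code{\link{cgan_config}} (supplies \code{n_synthetic}).
#' @param seed Seed for the generator noise.
#' @return The augmented \code{spectra_set}; provenance flags distinguish
#'   measured from generated rows.
#' @export
augment_training_set <- function(train, bundle, cfg = bundle$cfg,
                                 seed = 1L) {
  stopifnot(inherits(train, "spectra_set"))
  if (cfg$n_synthetic == 0L) return(train)
  conds <- resample_condition_grid(cfg$n_synthetic, min(train$psi),
                                   max(train$psi))
  gen <- generate_conditioned_spectra(bundle, conds, seed = seed)
  bind_spectra(train, gen)
}
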
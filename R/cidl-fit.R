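#' Optimizer / training-loop configuration
#'
#' Settings of the SGD training loop shared by every model variant:
#' stochastic gradient descent with momentum 0.9, batch size 256, dropout
#' 0.2 on the fully connected head, initial learning rate 0.05 decayed by a
#' factor of 0.1 every 100 epochs with a floor of 1e-9. He initialization
#' is used for convolutional weights and Glorot for fully connected ones.
#'
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size (default 256; when the training set is
#'   smaller, a single full batch is used).
#' @param lr Initial learning rate (default 0.05).
#' @param momentum SGD momentum (default 0.9).
#' @param lr_decay Multiplicative decay factor (default 0.1).
#' @param decay_every Epoch period of the decay (default 100).
#' @param lr_floor Lower clamp of the learning rate (default 1e-9).
#' @param dropout Dropout rate on fully connected layers (default 0.2).
#' @param hidden Width of the fully connected hidden layer (default 64).
#' @param clip_norm Global gradient-norm clip; Inf disables (default 5).
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(epochs = 300L, batch_size = 256L, lr = 0.05,
                         momentum = 0.9, lr_decay = 0.1, decay_every = 100L,
                         lr_floor = 1e-9, dropout = 0.2, hidden = 64L,
                         clip_norm = 5) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, momentum >= 0,
            momentum < 1, lr_decay > 0, decay_every >= 1, lr_floor > 0,
            dropout >= 0, dropout < 1, hidden >= 1, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), lr_floor = lr_floor,
                 dropout = dropout, hidden = as.integer(hidden),
                 clip_norm = clip_norm),
            class = "train_config")
}

# One global seed expands into per-component seeds by fixed offsets, so a
# single integer reproduces the whole pipeline.
derive_seed <- function(seed, component) {
  offs <- c(simulate = 0L, split = 1000L, cgan = 10000L, extractor = 20000L,
            head = 21000L, loop = 30000L, generate = 40000L)
  as.integer(seed) + offs[[component]]
}

model_head_forward <- function(head, feats, rate, train, want_cache = FALSE) {
  h <- dense_forward(head$fc1, feats)
  a <- relu(h$Y)
  dp <- dropout_forward(a, rate, train = train)
  o <- dense_forward(head$fc2, dp$Y)
  list(out = o$Y,
       cache = if (want_cache) list(feats = feats, h_pre = h$Y,
                                    dp_in = dp$Y, mask = dp$mask))
}

model_head_backward <- function(head, cache, dOut) {
  b2 <- dense_backward(head$fc2, cache$dp_in, dOut)
  da <- dropout_backward(cache$mask, b2$dX)
  da <- relu_backward(cache$h_pre, da)
  b1 <- dense_backward(head$fc1, cache$feats, da)
  list(grads = list(fc1 = b1$grads, fc2 = b2$grads), dFeat = b1$dX)
}

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(par_sum_sq(grads))
  if (nrm > max_norm) grads <- par_map(grads, function(g) g * max_norm / nrm)
  grads
}

#' Fit a distribution-aware deep regression of leaf water potential
#'
#' The full pipeline on labelled spectra: per-spectrum max-abs
#' normalization, optional conditional-GAN augmentation of the training
#' rows, the IRAC convolution/attention feature extractor, and either the
#' distribution-aware regression head (Gaussian label encoding, KL +
#' weighted MSE objective, expectation decoding) or a plain fully connected
#' regression head trained with MSE. All three stages can be switched off
#' independently for ablation; with all switches off the model is the plain
#' Inception-ResNet + regression-network baseline.
#'
#' @param x A labelled \code{spectra_set}, or a numeric matrix of spectra
#'   (rows = samples) together with \code{psi}.
#' @param psi Labels in MPa when \code{x} is a matrix.
#' @param train_idx Row indices used for training (default: all rows).
#'   Only these rows ever reach normalization-free training, CGAN fitting
#'   and label-grid construction.
#' @param use_cgan Augment training rows with conditionally generated
#'   spectra.
#' @param use_acmix Use ACmix blocks in the configured branches of the
#'   extractor.
#' @param use_darn Use the distribution-aware head; otherwise a plain
#'   regression head with MSE loss.
#' @param cgan,irac,darn,control Component configurations; see
#'   \code{\link{cgan_config}}, \code{\link{irac_config}},
#'   \code{\link{darn_config}}, \code{\link{train_config}}.
#' @param seed Integer seed; expands deterministically into per-component
#'   seeds (CGAN, initialization, data order, noise draws).
#' @param verbose Print per-epoch losses.
#' @return An object of class \code{cidl} with \code{predict},
#'   \code{print}, \code{summary}, \code{coef}, \code{plot}, \code{fitted}
#'   and \code{residuals} methods.
#' @export
#' @examples
#' \donttest{
#' d <- generate_dataset(sim_config(n_samples = 60, seed = 1))
#' fit <- cidl(d, use_cgan = FALSE,
#'             control = train_config(epochs = 5), seed = 1)
#' head(predict(fit, d))
#' }
cidl <- function(x, psi = NULL, train_idx = NULL,
                 use_cgan = TRUE, use_acmix = TRUE, use_darn = TRUE,
                 cgan = cgan_config(), irac = irac_config(),
                 darn = darn_config(), control = train_config(),
                 seed = 1L, verbose = FALSE) {
  data <- if (inherits(x, "spectra_set")) x else
    spectra_set(as.matrix(x), grid = default_wavelength_grid(ncol(x)),
                psi = psi)
  if (is.null(data$psi)) stop("fitting requires labelled spectra")
  if (is.null(train_idx)) train_idx <- seq_len(nrow(data$spectra))
  train_set <- subset_spectra(data, train_idx)
  train_set$spectra <- max_abs_normalize(train_set$spectra)

  bundle <- NULL
  if (use_cgan) {
    ccfg <- cgan
    ccfg$seed <- derive_seed(seed, "cgan")
    if (nrow(train_set$spectra) < ccfg$batch_size)
      ccfg$batch_size <- nrow(train_set$spectra)
    bundle <- train_cgan(train_set, ccfg)
    train_aug <- augment_training_set(train_set, bundle, ccfg,
                                      seed = derive_seed(seed, "generate"))
  } else {
    train_aug <- train_set
  }

  X <- train_aug$spectra
  y <- train_aug$psi
  n <- nrow(X)

  if (irac$n_bands != ncol(X))
    stop("extractor configured for ", irac$n_bands, " bands, data has ",
         ncol(X))
  ext_cfg <- irac
  ext_cfg$acmix_enabled <- use_acmix
  extractor <- build_irac(ext_cfg, seed = derive_seed(seed, "extractor"))
  use_ac <- extractor$use_acmix

  grid_y <- NULL; P <- NULL; n_out <- 1L
  if (use_darn) {
    pad <- darn$pad_sigmas * darn$sigma
    grid_y <- label_grid(min(train_set$psi) - pad, max(train_set$psi) + pad,
                         darn$l)
    P <- encode_label_distribution(y, grid_y, darn$sigma)
    n_out <- grid_y$k
  }

  set.seed(derive_seed(seed, "head"))
  head_par <- list(fc1 = dense_init(ext_cfg$feature_dim, control$hidden,
                                    "glorot"),
                   fc2 = dense_init(control$hidden, n_out, "glorot"))

  params <- list(ext = extractor$params, head = head_par)
  vel <- par_zeros(params)
  bn_stats <- extractor$bn_stats
  trace <- data.frame(epoch = seq_len(control$epochs), loss = NA_real_,
                      reg = NA_real_, ld = NA_real_)
  set.seed(derive_seed(seed, "loop"))
  for (ep in seq_len(control$epochs)) {
    lr <- max(control$lr * control$lr_decay^((ep - 1) %/% control$decay_every),
              control$lr_floor)
    ord <- sample.int(n)
    ep_loss <- 0; ep_reg <- 0; ep_ld <- 0; nb <- 0
    for (start in seq(1L, n, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1L, n)]
      B <- length(idx)
      fwd <- irac_forward(params$ext, bn_stats, ext_cfg, use_ac,
                          X[idx, , drop = FALSE], train = TRUE,
                          want_cache = TRUE)
      bn_stats <- fwd$bn_stats
      hf <- model_head_forward(params$head, fwd$features, control$dropout,
                               train = TRUE, want_cache = TRUE)
      if (use_darn) {
        phat <- softmax_rows(hf$out)
        yhat <- drop(phat %*% grid_y$centers)
        reg <- regression_loss(y[idx], yhat)
        ld <- kl_loss(P[idx, , drop = FALSE], phat, darn$epsilon)
        loss <- total_loss(reg, ld, params, darn)
        resid <- yhat - y[idx]
        A <- outer(resid, grid_y$centers) - resid * yhat
        dlogits <- ((phat - P[idx, , drop = FALSE]) +
                      2 * darn$C * phat * A) / B
      } else {
        yhat <- drop(hf$out)
        reg <- regression_loss(y[idx], yhat)
        ld <- 0
        loss <- reg + darn$eta * par_sum_sq(params)
        dlogits <- matrix(2 * (yhat - y[idx]) / B, ncol = 1L)
      }
      hb <- model_head_backward(params$head, hf$cache, dlogits)
      eb <- irac_backward(params$ext, ext_cfg, use_ac, fwd$cache, hb$dFeat)
      grads <- list(ext = eb$grads, head = hb$grads)
      grads <- add_l2_grad(grads, params, darn$eta)
      grads <- clip_grads(grads, control$clip_norm)
      upd <- sgd_step(params, grads, vel, lr, control$momentum)
      params <- upd$params; vel <- upd$vel
      ep_loss <- ep_loss + loss; ep_reg <- ep_reg + reg; ep_ld <- ep_ld + ld
      nb <- nb + 1
    }
    trace$loss[ep] <- ep_loss / nb
    trace$reg[ep] <- ep_reg / nb
    trace$ld[ep] <- ep_ld / nb
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  loss %.5f", ep, lr,
                      trace$loss[ep]))
  }

  extractor$params <- params$ext
  # finalize batch-norm statistics exactly over the training inputs, so
  # inference matches the training-mode normalization (running averages
  # decay too slowly from their initialization at few batches per epoch)
  mu <- colMeans(X)
  extractor$bn_stats <- list(mean = mu, var = colMeans(X^2) - mu^2)
  obj <- structure(
    list(extractor = extractor, head = params$head, label_grid = grid_y,
         darn = darn, control = control, flags = c(cgan = use_cgan,
                                                   acmix = use_acmix,
                                                   darn = use_darn),
         cgan_bundle = bundle, wavelength_grid = data$grid,
         normalization = "spectrum", loss_trace = trace,
         train_idx = train_idx, seed = as.integer(seed),
         call = match.call()),
    class = "cidl")
  obj$fitted_values <- predict(obj, train_set)
  obj$train_psi <- train_set$psi
  obj
}

#' Predict leaf water potential from spectra
#'
#' Normalizes the spectra the same way as in training, extracts features in
#' inference mode (deterministic) and decodes the head output. For a
#' distribution-aware model, \code{type = "distribution"} returns the
#' predicted probability matrix over the label grid instead of its
#' expectation.
#'
#' @param object A fitted \code{cidl} model.
#' @param newdata A \code{spectra_set} or numeric matrix of spectra.
#' @param type "response" (psi in MPa) or "distribution".
#' @param ... Unused.
#' @return Numeric vector of psi predictions, or a probability matrix.
#' @export
predict.cidl <- function(object, newdata,
                         type = c("response", "distribution"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_set")) newdata$spectra
       else as.matrix(newdata)
  if (ncol(X) != object$extractor$cfg$n_bands)
    stop("newdata has ", ncol(X), " bands; model expects ",
         object$extractor$cfg$n_bands)
  X <- max_abs_normalize(X, axis = object$normalization)
  feats <- extract_features(object$extractor, X)
  out <- model_head_forward(object$head, feats, 0, train = FALSE)$out
  if (object$flags[["darn"]]) {
    phat <- softmax_rows(out)
    if (type == "distribution") return(phat)
    drop(phat %*% object$label_grid$centers)
  } else {
    if (type == "distribution")
      stop("model was fitted without the distribution head")
    drop(out)
  }
}

#' @export
print.cidl <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("<cidl> leaf water potential regression\n")
  cat("  components:", if (length(on)) paste(on, collapse = " + ")
      else "baseline (none)", "\n")
  if (!is.null(x$label_grid))
    cat(sprintf("  label grid: k=%d bins of l=%g MPa, sigma=%g\n",
                x$label_grid$k, x$label_grid$l, x$darn$sigma))
  cat(sprintf("  trained %d epochs; final loss %.5f\n",
              nrow(x$loss_trace), utils::tail(x$loss_trace$loss, 1)))
  invisible(x)
}

#' @export
summary.cidl <- function(object, ...) {
  m <- compute_metrics(object$train_psi, object$fitted_values)
  structure(list(flags = object$flags,
                 n_train = length(object$train_psi),
                 n_params = par_count(list(object$extractor$params,
                                           object$head)),
                 fusion = coef(object),
                 label_grid = object$label_grid,
                 train_metrics = m,
                 final_loss = utils::tail(object$loss_trace$loss, 1)),
            class = "summary.cidl")
}

#' @export
print.summary.cidl <- function(x, ...) {
  cat("Distribution-aware spectral regression of leaf water potential\n")
  cat("  components:", paste(names(x$flags)[x$flags], collapse = " + "), "\n")
  cat("  training samples:", x$n_train, " | parameters:", x$n_params, "\n")
  if (!is.null(x$label_grid))
    cat(sprintf("  label grid: k=%d bins (l=%g MPa)\n", x$label_grid$k,
                x$label_grid$l))
  if (nrow(x$fusion))
    print(x$fusion, row.names = FALSE)
  cat(sprintf("  train R2 %.4f | RMSEC %.4f MPa | final loss %.5f\n",
              x$train_metrics$r2, x$train_metrics$rmse, x$final_loss))
  invisible(x)
}

#' Fusion coefficients of the ACmix branches
#'
#' The learnable scalars weighting the self-attention (\code{alpha}) and
#' convolution (\code{beta}) paths of each ACmix branch after training.
#'
#' @param object A fitted \code{cidl} model.
#' @param ... Unused.
#' @return Data frame with one row per ACmix branch.
#' @export
coef.cidl <- function(object, ...) {
  br <- object$extractor$params$branches
  use <- object$extractor$use_acmix
  out <- data.frame(branch = integer(), kernel = integer(),
                    alpha = numeric(), beta = numeric())
  for (j in seq_along(br)) {
    if (use[j])
      out <- rbind(out, data.frame(
        branch = j, kernel = object$extractor$cfg$branch_kernels[j],
        alpha = br[[j]]$alpha, beta = br[[j]]$beta))
  }
  out
}

#' @export
fitted.cidl <- function(object, ...) object$fitted_values

#' @export
residuals.cidl <- function(object, ...)
  object$train_psi - object$fitted_values

#' Plot the training loss trace
#'
#' @param x A fitted \code{cidl} model.
#' @param ... Passed to \code{plot}.
#' @export
plot.cidl <- function(x, ...) {
  graphics::plot(x$loss_trace$epoch, x$loss_trace$loss, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "cidl training loss", ...)
  invisible(x)
}
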
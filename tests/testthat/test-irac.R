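test_that("ACmix fusion weights alpha/beta gate the two paths exactly", {
  set.seed(8)
  C <- 4L; L <- 12L; B <- 3L
  p <- acmix_init(C, L, 5L)
  X <- array(rnorm(B * C * L), c(B, C, L))
  p_conv <- p; p_conv$alpha <- 0; p_conv$beta <- 1
  p_att <- p; p_att$alpha <- 1; p_att$beta <- 0
  # conv path alone, built from its two primitive layers
  pw <- cidl:::conv1d_forward(p$pw, X)$Y
  conv_only <- cidl:::depthwise_forward(p$dw, pw)
  expect_equal(acmix_forward(p_conv, X)$Y, conv_only, tolerance = 1e-12)
  att_only <- acmix_forward(p_att, X)$Y
  full <- acmix_forward(p, X)$Y
  expect_equal(full, att_only + conv_only, tolerance = 1e-12)
  # scaled fusion
  p2 <- p; p2$alpha <- 0.3; p2$beta <- 1.7
  expect_equal(acmix_forward(p2, X)$Y, 0.3 * att_only + 1.7 * conv_only,
               tolerance = 1e-12)
})

test_that("single-position ACmix matches the closed-form oracle", {
  # with L = 1 the softmax weight collapses to 1 and the block reduces to
  # alpha * (Wv x + bv) + beta * (w_center * (Wp x + bp) + b_dw)
  C <- 3L
  p <- acmix_init(C, 1L, 3L)
  p$Wq <- matrix(rnorm(9), 3); p$Wk <- matrix(rnorm(9), 3)
  p$Wv <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 3), 3)
  p$bv <- c(0.1, 0.2, 0.3)
  p$pw$W <- array(diag(3), c(3, 3, 1)); p$pw$b <- rep(0.5, 3)
  p$dw$W <- matrix(c(9, 9, 9, 2, 3, 4, 9, 9, 9), 3, 3)  # only centre tap used
  p$dw$b <- c(0, 0, 1)
  p$alpha <- 0.7; p$beta <- 1.3
  x <- c(1, -1, 2)
  X <- array(x, c(1, 3, 1))
  att <- p$Wv %*% x + p$bv
  conv <- c(2, 3, 4) * (x + 0.5) + c(0, 0, 1)
  expected <- 0.7 * drop(att) + 1.3 * conv
  expect_equal(drop(acmix_forward(p, X)$Y), expected, tolerance = 1e-6)
})

test_that("extractor output is deterministic, finite and correctly shaped", {
  cfg <- tiny_irac()
  ext <- build_irac(cfg, seed = 2)
  set.seed(9)
  X <- matrix(runif(6 * 24), 6, 24)
  X[3, ] <- X[1, ]                      # duplicated row in the same batch
  F1 <- extract_features(ext, X)
  expect_equal(dim(F1), c(6L, cfg$feature_dim))
  expect_equal(F1[3, ], F1[1, ])
  expect_true(all(is.finite(extract_features(ext, matrix(0, 2, 24)))))
  # batched evaluation equals per-sample evaluation
  singles <- t(vapply(seq_len(6), function(i)
    drop(extract_features(ext, X[i, , drop = FALSE])), numeric(cfg$feature_dim)))
  expect_equal(F1, singles, tolerance = 1e-10)
  expect_error(extract_features(ext, matrix(0, 2, 25)), "expects")
})

test_that("disabling ACmix yields the plain-convolution baseline extractor", {
  cfg_on <- tiny_irac(acmix_enabled = TRUE)
  cfg_off <- tiny_irac(acmix_enabled = FALSE)
  ext_on <- build_irac(cfg_on, seed = 4)
  ext_off <- build_irac(cfg_off, seed = 4)
  # baseline branches are plain convolutions with the configured kernels
  for (j in 1:3) {
    br <- ext_off$params$branches[[j]]
    expect_named(br, c("W", "b"))
    expect_equal(dim(br$W), c(4L, 4L, cfg_off$branch_kernels[j]))
  }
  expect_false(any(ext_off$use_acmix))
  # parameter count strictly decreases without ACmix
  expect_lt(cidl:::par_count(ext_off$params), cidl:::par_count(ext_on$params))
})

test_that("positional encoding and band positions influence the features", {
  cfg <- tiny_irac()
  ext <- build_irac(cfg, seed = 6)
  base <- 0.1 + 0.4 / (1 + exp(-(seq_len(24) - 12)))
  dip1 <- base; dip1[6:8] <- dip1[6:8] - 0.08
  dip2 <- base; dip2[16:18] <- dip2[16:18] - 0.08
  f1 <- extract_features(ext, matrix(dip1, 1))
  f2 <- extract_features(ext, matrix(dip2, 1))
  expect_gt(max(abs(f1 - f2)), 1e-6)
  # zeroing the positional tables changes the attention output
  ext0 <- ext
  for (j in which(ext0$use_acmix))
    ext0$params$branches[[j]]$pos <- ext0$params$branches[[j]]$pos * 0
  f0 <- extract_features(ext0, matrix(dip1, 1))
  expect_gt(max(abs(f1 - f0)), 1e-8)
})

test_that("gradients reach the fusion weights during training", {
  cfg <- tiny_irac()
  ext <- build_irac(cfg, seed = 10)
  set.seed(11)
  X <- matrix(runif(4 * 24), 4, 24)
  fwd <- cidl:::irac_forward(ext$params, ext$bn_stats, cfg, ext$use_acmix,
                             X, train = TRUE, want_cache = TRUE)
  dFeat <- matrix(rnorm(length(fwd$features)), nrow(fwd$features))
  back <- cidl:::irac_backward(ext$params, cfg, ext$use_acmix, fwd$cache,
                               dFeat)
  for (j in which(ext$use_acmix)) {
    expect_gt(abs(back$grads$branches[[j]]$alpha), 0)
    expect_gt(abs(back$grads$branches[[j]]$beta), 0)
  }
})
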
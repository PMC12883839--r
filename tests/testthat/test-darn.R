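test_that("label grid construction matches direct arithmetic", {
  g <- label_grid(-1, 0, 0.25)
  expect_equal(g$k, 4L)
  expect_equal(g$centers, c(-0.875, -0.625, -0.375, -0.125))
  for (l in c(0.05, 0.1, 0.15, 0.2, 0.25)) {
    g <- label_grid(-2.5, -0.1, l)
    expect_equal(diff(g$centers), rep(l, g$k - 1))
    expect_equal(g$hi - g$lo, g$k * l)
  }
  expect_error(label_grid(0, 0, 0.1), "lo must be")
  expect_error(label_grid(-1, 0, -0.1), "l must be")
})

test_that("label encoding is a normalized Gaussian over bin centers", {
  g <- label_grid(-2, 0, 0.25)
  set.seed(5)
  for (i in 1:20) {
    y <- runif(1, -2, 0); s <- runif(1, 0.05, 0.5)
    p <- encode_label_distribution(y, g, s)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    # brute-force oracle: unnormalized kernel evaluated centre by centre
    ker <- numeric(g$k)
    for (j in seq_len(g$k))
      ker[j] <- exp(-(g$centers[j] - y)^2 / (2 * s^2))
    expect_equal(p, ker / sum(ker), tolerance = 1e-12)
  }
  # y at the middle of a symmetric grid decodes exactly
  gs <- label_grid(-1, 0, 0.2)
  mid <- mean(range(gs$centers))
  p <- encode_label_distribution(mid, gs, 0.3)
  expect_equal(expectation_decode(p, gs), mid, tolerance = 1e-12)
  # tiny sigma concentrates all mass in the labelled bin
  p <- encode_label_distribution(gs$centers[2], gs, 0.01 * gs$l)
  expect_gt(p[2], 0.999)
  expect_error(encode_label_distribution(0, gs, 0), "sigma")
})

test_that("KL loss matches hand-computed values and is non-negative", {
  expect_equal(kl_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(kl_loss(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(kl_loss(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  set.seed(6)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    q <- stats::rgamma(k, 1); q <- q / sum(q)
    expect_gte(kl_loss(p, q), 0)
    expect_equal(kl_loss(p, p), 0, tolerance = 1e-12)
  }
  expect_error(kl_loss(c(1, 0), c(1, 0, 0)), "shapes differ")
})

test_that("expectation decoding is the convex combination of centers", {
  g <- label_grid(-2.5, -0.5, 0.5)
  onehot <- rep(0, g$k); onehot[3] <- 1
  expect_equal(expectation_decode(onehot, g), g$centers[3])
  g2 <- label_grid(-2.5, -0.5, 1)
  expect_equal(expectation_decode(c(0.5, 0.5), g2), mean(g2$centers))
  u <- rep(1 / g$k, g$k)
  expect_equal(expectation_decode(u, g), mean(g$centers))
  set.seed(7)
  for (i in 1:20) {
    p <- stats::rgamma(g$k, 1); p <- p / sum(p)
    d <- expectation_decode(p, g)
    expect_gte(d, min(g$centers)); expect_lte(d, max(g$centers))
  }
  expect_error(expectation_decode(c(0.5, 0.2), g2), "sum to 1")
})

test_that("regression and total losses combine as specified", {
  expect_equal(regression_loss(c(0, 1), c(1, 1)), 0.5)
  expect_equal(regression_loss(1:5, 1:5), 0)
  expect_error(regression_loss(numeric(0), numeric(0)), "empty")
  cfg <- darn_config(C = 1, eta = 0)
  expect_equal(total_loss(0, 0, NULL, cfg), 0)
  expect_equal(total_loss(0.5, 0.1438, NULL, cfg), 0.6438)
  cfg0 <- darn_config(C = 0, eta = 0)
  expect_equal(total_loss(99, 0.25, NULL, cfg0), 0.25)
  # L2 penalty counts every parameter
  pars <- list(a = matrix(1:4, 2), b = list(c = c(2, 2)))
  cfg2 <- darn_config(C = 2, eta = 0.1)
  expect_equal(total_loss(1, 1, pars, cfg2), 2 + 1 + 0.1 * (30 + 8))
  # monotone non-decreasing in each component
  expect_gte(total_loss(2, 1, NULL, cfg), total_loss(1, 1, NULL, cfg))
  expect_gte(total_loss(1, 2, NULL, cfg), total_loss(1, 1, NULL, cfg))
})

test_that("encode/decode round trip stays within half a bin width", {
  for (sigma in c(0.1, 0.3, 0.5)) for (l in c(0.05, 0.15, 0.25)) {
    g <- label_grid(-2.5 - 3 * sigma, -0.1 + 3 * sigma, l)
    ys <- seq(-2.5, -0.1, length.out = 41)
    for (y in ys) {
      p <- encode_label_distribution(y, g, sigma)
      expect_lte(abs(expectation_decode(p, g) - y), l / 2)
    }
  }
})
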
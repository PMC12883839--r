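test_that("repeated hold-out splits partition 229 samples as 160/22/47", {
  plans <- repeated_holdout_split(229, seeds = 1:10)
  expect_length(plans, 10L)
  for (pl in plans) {
    expect_length(pl$train, 160L)
    expect_length(pl$val, 22L)
    expect_length(pl$test, 47L)
    all_idx <- c(pl$train, pl$val, pl$test)
    expect_equal(sort(all_idx), 1:229)
  }
  # identical seed, identical plan; distinct seeds differ
  again <- repeated_holdout_split(229, seeds = 1:10)
  expect_identical(plans, again)
  keys <- vapply(plans, function(p) paste(p$train, collapse = ","),
                 character(1))
  expect_equal(length(unique(keys)), 10L)
  expect_error(repeated_holdout_split(5, 1), "n >= 10")
  expect_error(repeated_holdout_split(229, c(1, 1)), "anyDuplicated")
})

naive_metrics <- function(y, yhat) {
  # independent brute-force oracle written with explicit loops
  n <- length(y)
  ss_res <- 0; ss_tot <- 0; abs_sum <- 0
  my <- sum(y) / n
  for (i in seq_len(n)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - my)^2
    abs_sum <- abs_sum + abs(y[i] - yhat[i])
  }
  rmse <- sqrt(ss_res / n)
  sdy <- sqrt(ss_tot / (n - 1))
  sorted <- sort(y)
  qat <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  list(r2 = 1 - ss_res / ss_tot, rmse = rmse, mae = abs_sum / n,
       rpd = sdy / rmse, rpiq = (qat(0.75) - qat(0.25)) / rmse)
}

test_that("chemometric metrics match the worked example and a naive oracle", {
  m <- compute_metrics(c(0, 1, 2, 3), c(0.5, 1.5, 1.5, 2.5))
  expect_equal(m$rmse, 0.5)
  expect_equal(m$r2, 0.8)
  expect_equal(m$mae, 0.5)
  expect_equal(m$rpiq, 3.0)
  expect_equal(m$rpd, sqrt(5 / 3) / 0.5, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:100, 1)
    y <- rnorm(n); yhat <- y + rnorm(n, 0, 0.5)
    a <- compute_metrics(y, yhat); b <- naive_metrics(y, yhat)
    for (f in names(b)) expect_equal(a[[f]], b[[f]], tolerance = 1e-10)
  }
  # degenerate cases
  p <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$r2, 1); expect_equal(p$rmse, 0)
  expect_true(is.infinite(p$rpd) && is.infinite(p$rpiq))
  cm <- compute_metrics(c(0, 1, 2), c(1, 1, 1))
  expect_equal(cm$r2, 0)
  expect_error(compute_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(compute_metrics(1:3, 1:4), "equal nonzero length")
})

test_that("metric aggregation recomputes exactly from per-split records", {
  set.seed(14)
  recs <- lapply(1:6, function(i) {
    y <- rnorm(30); compute_metrics(y, y + rnorm(30, 0, 0.4))
  })
  rep_df <- metrics_report(recs)
  r2s <- vapply(recs, `[[`, numeric(1), "r2")
  expect_equal(rep_df$mean[rep_df$metric == "r2"], mean(r2s))
  expect_equal(rep_df$sd[rep_df$metric == "r2"], sd(r2s))
  # SDR row is the mean of per-split SD/RMSE ratios
  expect_equal(rep_df$mean[rep_df$metric == "sdr"],
               mean(vapply(recs, `[[`, numeric(1), "rpd")))
  # pooled RPD uses pooled SD over pooled RMSE
  ns <- vapply(recs, `[[`, numeric(1), "n")
  prmse <- sqrt(sum(vapply(recs, `[[`, numeric(1), "rmse")^2 * ns) / sum(ns))
  psd <- sqrt(sum(vapply(recs, `[[`, numeric(1), "sd_y")^2 * (ns - 1)) /
                sum(ns - 1))
  expect_equal(rep_df$mean[rep_df$metric == "rpd_pooled"], psd / prmse)
})

test_that("one split trains end-to-end deterministically without leakage", {
  d <- small_dataset(n = 60, seed = 17)
  plan <- repeated_holdout_split(60, seeds = 5)[[1]]
  ctrl <- train_config(epochs = 3)
  f1 <- train_cidl(d, plan, use_cgan = FALSE, use_acmix = FALSE,
                   use_darn = TRUE, control = ctrl, seed = 5)
  f2 <- train_cidl(d, plan, use_cgan = FALSE, use_acmix = FALSE,
                   use_darn = TRUE, control = ctrl, seed = 5)
  expect_identical(f1$test, f2$test)
  expect_identical(f1$val, f2$val)
  # training loss decreases from the first epoch
  tr <- f1$model$loss_trace
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
  # label grid derives from training labels only
  g <- f1$model$label_grid
  pad <- f1$model$darn$pad_sigmas * f1$model$darn$sigma
  expect_equal(g$lo, min(d$psi[plan$train]) - pad)
  # corrupted (overlapping) split plans are rejected
  bad <- plan; bad$val[1] <- plan$train[1]
  expect_error(train_cidl(d, bad, use_cgan = FALSE, control = ctrl),
               "leakage")
  short <- plan; short$test <- plan$test[-1]
  expect_error(train_cidl(d, short, use_cgan = FALSE, control = ctrl),
               "cover")
})

test_that("baseline ablation variant has no GAN stage, no distribution head", {
  d <- small_dataset(n = 60, seed = 18)
  plan <- repeated_holdout_split(60, seeds = 2)[[1]]
  fit <- train_cidl(d, plan, use_cgan = FALSE, use_acmix = FALSE,
                    use_darn = FALSE, control = train_config(epochs = 2),
                    seed = 2)
  expect_null(fit$model$cgan_bundle)
  expect_null(fit$model$label_grid)
  expect_false(any(fit$model$extractor$use_acmix))
  expect_equal(ncol(fit$model$head$fc2$W), 1L)
})

test_that("hyperparameter searches cover their grids and report optima", {
  d <- small_dataset(n = 40, seed = 19)
  ctrl <- train_config(epochs = 2)
  gs <- grid_search_sigma_l(d, seeds = 3, sigma_grid = c(0.3, 0.4),
                            l_grid = c(0.15), use_cgan = FALSE,
                            use_acmix = FALSE, control = ctrl)
  expect_equal(dim(gs$val_r2), c(1L, 2L))
  expect_true(all(gs$val_r2 <= 1))
  expect_true(gs$best["sigma"] %in% c(0.3, 0.4))
  expect_equal(unname(gs$best["l"]), 0.15)
  sing <- grid_search_sigma_l(d, seeds = 3, sigma_grid = 0.4, l_grid = 0.2,
                              use_cgan = FALSE, use_acmix = FALSE,
                              control = ctrl)
  expect_equal(unname(sing$best), c(0.4, 0.2))
  sw <- sweep_C(d, seeds = 3, C_grid = c(1), use_cgan = FALSE,
                use_acmix = FALSE, control = ctrl)
  expect_equal(sw$best_C, 1)
  expect_equal(nrow(sw$curve), 1L)
  expect_true(all(c("C", "mean_r2", "sd_r2") %in% names(sw$curve)))
})
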
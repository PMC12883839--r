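#' Repeated hold-out split plans
#'
#' For each seed, shuffles the sample indices and partitions them into
#' training (floor of 70\%), validation (floor of 10\%) and test (the
#' remainder) subsets — e.g. 160/22/47 for n = 229. Every plan is a
#' disjoint and complete partition; identical seeds give identical plans.
#'
#' @param n Number of samples (>= 10).
#' @param seeds Integer vector of distinct seeds, one per repetition.
#' @param fractions Train/validation/test fractions (default 0.7/0.1/0.2).
#' @return A list of \code{split_plan} objects with fields \code{seed},
#'   \code{train}, \code{val}, \code{test}, \code{fractions}.
#' @export
#' @examples
#' plans <- repeated_holdout_split(229, seeds = 1:10)
#' lengths(plans[[1]][c("train", "val", "test")])  # 160 22 47
repeated_holdout_split <- function(n, seeds, fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(n >= 10, length(seeds) >= 1, !anyDuplicated(seeds),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  lapply(seeds, function(s) {
    set.seed(s)
    perm <- sample.int(n)
    n_tr <- floor(fractions[1] * n)
    n_val <- floor(fractions[2] * n)
    structure(list(seed = as.integer(s),
                   train = sort(perm[seq_len(n_tr)]),
                   val = sort(perm[n_tr + seq_len(n_val)]),
                   test = sort(perm[(n_tr + n_val + 1L):n]),
                   fractions = fractions),
              class = "split_plan")
  })
}

validate_split <- function(split, n) {
  stopifnot(inherits(split, "split_plan"))
  all_idx <- c(split$train, split$val, split$test)
  if (anyDuplicated(all_idx))
    stop("split plan has overlapping subsets (leakage)")
  if (!setequal(all_idx, seq_len(n)))
    stop("split plan does not cover all ", n, " samples")
  invisible(split)
}

#' Chemometric metrics for one evaluation split
#'
#' Computes the standard chemometric metric set for measured values
#' \code{y} and predictions \code{yhat}: the coefficient of determination
#' R2 = 1 - SS_res/SS_tot, RMSE, MAE, RPD (sample SD of \code{y} divided by
#' RMSE), and RPIQ (interquartile range of \code{y}, linear-interpolation
#' quartiles, divided by RMSE). When predictions are exact the ratio
#' metrics are infinite.
#'
#' @param y Measured values (must not be constant).
#' @param yhat Predictions, same length.
#' @return A list of class \code{split_metrics} with fields \code{n},
#'   \code{r2}, \code{rmse}, \code{mae}, \code{sd_y}, \code{iqr_y},
#'   \code{rpd}, \code{rpiq}.
#' @export
#' @examples
#' m <- compute_metrics(c(0, 1, 2, 3), c(0.5, 1.5, 1.5, 2.5))
#' c(m$rmse, m$r2, m$mae, m$rpiq)  # 0.5 0.8 0.5 3.0
compute_metrics <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    stop("y and yhat must have equal nonzero length")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("zero variance in y: R2 and ratio metrics are undefined")
  ss_res <- sum((y - yhat)^2)
  rmse <- sqrt(ss_res / length(y))
  sd_y <- stats::sd(y)
  iqr_y <- unname(diff(stats::quantile(y, c(0.25, 0.75), type = 7)))
  structure(list(n = length(y),
                 r2 = 1 - ss_res / ss_tot,
                 rmse = rmse,
                 mae = mean(abs(y - yhat)),
                 sd_y = sd_y,
                 iqr_y = iqr_y,
                 rpd = if (rmse == 0) Inf else sd_y / rmse,
                 rpiq = if (rmse == 0) Inf else iqr_y / rmse),
            class = "split_metrics")
}

#' @export
print.split_metrics <- function(x, ...) {
  cat(sprintf(
    "n=%d  R2=%.4f  RMSE=%.4f  MAE=%.4f  RPD=%.3f  RPIQ=%.3f\n",
    x$n, x$r2, x$rmse, x$mae, x$rpd, x$rpiq))
  invisible(x)
}

#' Aggregate per-split metrics into a report
#'
#' Means and standard deviations of each metric across repetitions. Two
#' ratio conventions are reported: SDR is the per-split SD(y)/RMSE averaged
#' over repetitions, while RPD pools over repetitions (pooled SD of the
#' test labels divided by the pooled RMSE).
#'
#' @param records List of \code{split_metrics}.
#' @return A data frame with one row per metric (mean, sd), plus pooled
#'   RPD in the \code{"rpd_pooled"} row.
#' @export
metrics_report <- function(records) {
  stopifnot(length(records) >= 1)
  get <- function(f) vapply(records, `[[`, numeric(1), f)
  base <- c("r2", "rmse", "mae", "rpd", "rpiq")
  out <- data.frame(metric = character(), mean = numeric(), sd = numeric())
  for (m in base)
    out <- rbind(out, data.frame(metric = m, mean = mean(get(m)),
                                 sd = stats::sd(get(m))))
  out <- rbind(out, data.frame(metric = "sdr", mean = mean(get("rpd")),
                               sd = stats::sd(get("rpd"))))
  pooled_rmse <- sqrt(sum(get("rmse")^2 * get("n")) / sum(get("n")))
  pooled_sd <- sqrt(sum(get("sd_y")^2 * (get("n") - 1)) /
                      sum(get("n") - 1))
  out <- rbind(out, data.frame(metric = "rpd_pooled",
                               mean = pooled_sd / pooled_rmse,
                               sd = NA_real_))
  out
}

#' Train and evaluate one pipeline variant on one split
#'
#' Fits the model on the training subset of the split (all augmentation,
#' normalization-dependent statistics and the label grid are derived from
#' those rows only) and evaluates it on the validation and test subsets.
#'
#' @param dataset A labelled \code{spectra_set}.
#' @param split A \code{split_plan} covering the dataset.
#' @param use_cgan,use_acmix,use_darn Component switches (see
#'   \code{\link{cidl}}).
#' @param cgan,irac,darn,control Component configurations.
#' @param seed Seed for the model fit (default: the split seed).
#' @return A list of class \code{cidl_eval}: \code{model}, plus
#'   \code{train}, \code{val} and \code{test} \code{split_metrics}, and
#'   the split.
#' @export
train_cidl <- function(dataset, split, use_cgan = TRUE, use_acmix = TRUE,
                       use_darn = TRUE, cgan = cgan_config(),
                       irac = irac_config(), darn = darn_config(),
                       control = train_config(), seed = split$seed) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (is.null(dataset$psi)) stop("evaluation requires labelled data")
  validate_split(split, nrow(dataset$spectra))
  model <- cidl(dataset, train_idx = split$train, use_cgan = use_cgan,
                use_acmix = use_acmix, use_darn = use_darn, cgan = cgan,
                irac = irac, darn = darn, control = control, seed = seed)
  ev <- function(idx) {
    sub <- subset_spectra(dataset, idx)
    compute_metrics(sub$psi, predict(model, sub))
  }
  structure(list(model = model, train = ev(split$train),
                 val = ev(split$val), test = ev(split$test),
                 split = split),
            class = "cidl_eval")
}

#' @export
print.cidl_eval <- function(x, ...) {
  cat("<cidl_eval> split seed", x$split$seed, "\n  train: ")
  print(x$train)
  cat("  val:   ")
  print(x$val)
  cat("  test:  ")
  print(x$test)
  invisible(x)
}

#' Grid search over label-encoding spread and interval length
#'
#' Trains the full pipeline for every (sigma, l) pair with the regression
#' coefficient fixed at C = 1, averaging validation R2 over the split
#' repetitions, and returns the best pair with the full matrix (for a heat
#' map).
#'
#' @param dataset A labelled \code{spectra_set}.
#' @param seeds Split seeds (one repetition each).
#' @param sigma_grid Candidate sigma values (default 0.1-0.5).
#' @param l_grid Candidate interval lengths (default 0.05-0.25).
#' @param ... Passed on to \code{\link{train_cidl}} (flags, configs).
#' @param darn Base \code{darn_config}; its C is forced to 1.
#' @return List with \code{best} (named vector sigma, l),
#'   \code{val_r2} matrix (rows = l, cols = sigma) and the per-cell
#'   records.
#' @export
grid_search_sigma_l <- function(dataset, seeds,
                                sigma_grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                l_grid = c(0.05, 0.1, 0.15, 0.2, 0.25),
                                darn = darn_config(), ...) {
  stopifnot(length(sigma_grid) >= 1, length(l_grid) >= 1)
  plans <- repeated_holdout_split(nrow(dataset$spectra), seeds)
  M <- matrix(NA_real_, length(l_grid), length(sigma_grid),
              dimnames = list(paste0("l=", l_grid),
                              paste0("sigma=", sigma_grid)))
  records <- list()
  for (i in seq_along(l_grid)) for (j in seq_along(sigma_grid)) {
    dcfg <- darn
    dcfg$sigma <- sigma_grid[j]; dcfg$l <- l_grid[i]; dcfg$C <- 1
    r2 <- vapply(plans, function(pl)
      train_cidl(dataset, pl, darn = dcfg, ...)$val$r2, numeric(1))
    M[i, j] <- mean(r2)
    records[[paste(l_grid[i], sigma_grid[j], sep = "_")]] <- r2
  }
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  list(best = c(sigma = sigma_grid[best[2]], l = l_grid[best[1]]),
       val_r2 = M, records = records)
}

#' Sweep of the regression-loss coefficient
#'
#' With sigma and l fixed (at their grid-search optimum), trains the
#' pipeline for each candidate C and reports mean and SD of validation R2
#' per value.
#'
#' @param dataset A labelled \code{spectra_set}.
#' @param seeds Split seeds.
#' @param C_grid Candidate coefficients (default 0:6).
#' @param darn \code{darn_config} carrying the fixed sigma and l.
#' @param ... Passed on to \code{\link{train_cidl}}.
#' @return List with \code{best_C} and a data frame \code{curve}
#'   (C, mean_r2, sd_r2).
#' @export
sweep_C <- function(dataset, seeds, C_grid = 0:6, darn = darn_config(),
                    ...) {
  stopifnot(length(C_grid) >= 1)
  plans <- repeated_holdout_split(nrow(dataset$spectra), seeds)
  curve <- data.frame(C = C_grid, mean_r2 = NA_real_, sd_r2 = NA_real_)
  for (i in seq_along(C_grid)) {
    dcfg <- darn; dcfg$C <- C_grid[i]
    r2 <- vapply(plans, function(pl)
      train_cidl(dataset, pl, darn = dcfg, ...)$val$r2, numeric(1))
    curve$mean_r2[i] <- mean(r2)
    curve$sd_r2[i] <- stats::sd(r2)
  }
  list(best_C = curve$C[which.max(curve$mean_r2)], curve = curve)
}

#' Component ablation matrix
#'
#' Evaluates the eight on/off combinations of the CGAN, ACmix and DARN
#' components — from the plain Inception-ResNet + regression baseline to
#' the full pipeline — on identical split plans (paired comparison), and
#' reports mean and SD of test R2 per configuration.
#'
#' @param dataset A labelled \code{spectra_set}.
#' @param seeds Split seeds shared by every configuration.
#' @param ... Passed on to \code{\link{train_cidl}} (configs).
#' @return A data frame of 8 rows (configuration, flags, mean and SD of
#'   test R2); per-split records in \code{attr(, "records")}.
#' @export
run_ablation <- function(dataset, seeds, ...) {
  plans <- repeated_holdout_split(nrow(dataset$spectra), seeds)
  combos <- data.frame(
    use_cgan = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    use_acmix = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    use_darn = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  lab <- function(i) {
    parts <- c("CGAN", "ACmix", "DARN")[unlist(combos[i, ])]
    if (!length(parts)) "Baseline"
    else if (all(unlist(combos[i, ])))
      "Baseline + CGAN + ACmix + DARN (CIDL)"
    else paste(c("Baseline", parts), collapse = " + ")
  }
  out <- cbind(data.frame(configuration = vapply(seq_len(8), lab,
                                                 character(1))),
               combos,
               data.frame(mean_test_r2 = NA_real_, sd_test_r2 = NA_real_))
  records <- list()
  for (i in seq_len(8)) {
    r2 <- vapply(plans, function(pl)
      train_cidl(dataset, pl, use_cgan = combos$use_cgan[i],
                 use_acmix = combos$use_acmix[i],
                 use_darn = combos$use_darn[i], ...)$test$r2,
      numeric(1))
    out$mean_test_r2[i] <- mean(r2)
    out$sd_test_r2[i] <- stats::sd(r2)
    records[[out$configuration[i]]] <- r2
  }
  attr(out, "records") <- records
  attr(out, "seeds") <- seeds
  out
}
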
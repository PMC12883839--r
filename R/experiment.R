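# YAML-driven experiment runner: binds the simulator, augmentation,
# training and ablation into seeded, self-describing artifact directories.

experiment_schema <- function() {
  list(
    task = c("simulate", "augment", "train", "evaluate", "ablate"),
    top = c("task", "seed", "seeds", "output_dir", "unit", "data",
            "simulate", "cgan", "irac", "darn", "train", "eval"),
    data = c("path"),
    simulate = names(formals(sim_config)),
    cgan = names(formals(cgan_config)),
    irac = names(formals(irac_config)),
    darn = names(formals(darn_config)),
    train = names(formals(train_config)),
    eval = c("use_cgan", "use_acmix", "use_darn"))
}

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key: ", path, ".", bad[1], call. = FALSE)
}

build_cfg <- function(fn, section) {
  if (is.null(section)) return(fn())
  do.call(fn, section)
}

#' Run a configured experiment
#'
#' Reads a YAML experiment file, validates it against the configuration
#' schema (unknown keys are rejected with the offending key path), executes
#' the requested task and writes a self-describing artifact directory: a
#' copy of the configuration, a run manifest, and the task outputs (spectra
#' CSV, metrics CSV/JSON, model checkpoint). Re-running the stored
#' configuration reproduces the metrics exactly.
#'
#' Tasks: \code{simulate} writes a synthetic labelled spectra CSV;
#' \code{augment} trains the conditional GAN on a spectra CSV and writes
#' the augmented set; \code{train} fits the pipeline on one hold-out split
#' and writes validation/test metrics; \code{evaluate} runs the full
#' repeated hold-out protocol; \code{ablate} runs the 8-row component
#' ablation.
#'
#' @param config_path Path to the YAML experiment file. Required keys:
#'   \code{task}; optional: \code{seed} (default 1), \code{seeds} (for
#'   repeated protocols), \code{output_dir}, \code{unit} ("MPa"/"bar"),
#'   plus the per-component sections \code{data}, \code{simulate},
#'   \code{cgan}, \code{irac}, \code{darn}, \code{train}, \code{eval}.
#' @param output_dir Overrides the config's output directory.
#' @return The artifact directory path, invisibly.
#' @export
run_experiment <- function(config_path, output_dir = NULL) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  sch <- experiment_schema()
  check_keys(cfg, sch$top, "config")
  if (is.null(cfg$task) || !cfg$task %in% sch$task)
    stop("config.task must be one of: ", paste(sch$task, collapse = ", "))
  for (sec in c("data", "simulate", "cgan", "irac", "darn", "train", "eval"))
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], sch[[sec]], sec)
  # a provided darn section must state the three core hyperparameters
  # explicitly, so experiment files are self-describing
  if (!is.null(cfg$darn)) {
    for (key in c("sigma", "l", "C"))
      if (!key %in% names(cfg$darn))
        stop("missing required configuration key: darn.", key,
             call. = FALSE)
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out <- if (!is.null(output_dir)) output_dir
         else if (!is.null(cfg$output_dir)) cfg$output_dir
         else tempfile("cidl_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out, recursive = TRUE), add = TRUE)

  scfg <- build_cfg(sim_config, cfg$simulate)
  ccfg <- build_cfg(cgan_config, cfg$cgan)
  icfg <- build_cfg(irac_config, cfg$irac)
  dcfg <- build_cfg(darn_config, cfg$darn)
  tcfg <- build_cfg(train_config, cfg$train)
  flags <- cfg$eval
  use_cgan <- !isFALSE(flags$use_cgan)
  use_acmix <- !isFALSE(flags$use_acmix)
  use_darn <- !isFALSE(flags$use_darn)

  load_data <- function() {
    if (!is.null(cfg$data$path)) {
      unit <- if (is.null(cfg$unit)) "MPa" else cfg$unit
      read_spectra_csv(cfg$data$path, unit = unit)
    } else {
      scfg$seed <- derive_seed(seed, "simulate")
      generate_dataset(scfg)
    }
  }

  if (cfg$task == "simulate") {
    scfg$seed <- derive_seed(seed, "simulate")
    d <- generate_dataset(scfg)
    write_spectra_csv(d, file.path(out, "spectra.csv"))
  } else if (cfg$task == "augment") {
    d <- load_data()
    d$spectra <- max_abs_normalize(d$spectra)
    ccfg$seed <- derive_seed(seed, "cgan")
    bundle <- train_cgan(d, ccfg)
    aug <- augment_training_set(d, bundle, ccfg,
                                seed = derive_seed(seed, "generate"))
    write_spectra_csv(aug, file.path(out, "augmented.csv"))
    saveRDS(bundle, file.path(out, "cgan_bundle.rds"))
    jsonlite::write_json(
      list(config = unclass(ccfg), condition_normalization = bundle$norm,
           n_bands = bundle$n_bands),
      file.path(out, "cgan_bundle.json"), auto_unbox = TRUE)
  } else if (cfg$task == "train") {
    d <- load_data()
    plan <- repeated_holdout_split(nrow(d$spectra), seeds = seed)[[1]]
    fit <- train_cidl(d, plan, use_cgan = use_cgan, use_acmix = use_acmix,
                      use_darn = use_darn, cgan = ccfg, irac = icfg,
                      darn = dcfg, control = tcfg, seed = seed)
    saveRDS(fit$model, file.path(out, "model.rds"))
    res <- data.frame(subset = c("train", "val", "test"),
                      r2 = c(fit$train$r2, fit$val$r2, fit$test$r2),
                      rmse = c(fit$train$rmse, fit$val$rmse, fit$test$rmse),
                      mae = c(fit$train$mae, fit$val$mae, fit$test$mae))
    utils::write.csv(res, file.path(out, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(res, file.path(out, "metrics.json"),
                         dataframe = "rows", digits = NA)
  } else if (cfg$task == "evaluate") {
    d <- load_data()
    seeds <- if (is.null(cfg$seeds)) seed + 0:9 else as.integer(cfg$seeds)
    plans <- repeated_holdout_split(nrow(d$spectra), seeds)
    recs <- lapply(plans, function(pl)
      train_cidl(d, pl, use_cgan = use_cgan, use_acmix = use_acmix,
                 use_darn = use_darn, cgan = ccfg, irac = icfg,
                 darn = dcfg, control = tcfg)$test)
    rep_df <- metrics_report(recs)
    utils::write.csv(rep_df, file.path(out, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(rep_df, file.path(out, "metrics.json"),
                         dataframe = "rows", digits = NA)
  } else if (cfg$task == "ablate") {
    d <- load_data()
    seeds <- if (is.null(cfg$seeds)) seed + 0:2 else as.integer(cfg$seeds)
    tab <- run_ablation(d, seeds, cgan = ccfg, irac = icfg, darn = dcfg,
                        control = tcfg)
    utils::write.csv(tab, file.path(out, "ablation.csv"), row.names = FALSE)
    jsonlite::write_json(tab, file.path(out, "ablation.json"),
                         dataframe = "rows", digits = NA)
  }

  file.copy(config_path, file.path(out, "config.yaml"), overwrite = TRUE)
  manifest <- list(package = "cidl",
                   version = as.character(utils::packageVersion("cidl")),
                   task = cfg$task, seed = seed,
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  ok <- TRUE
  invisible(out)
}
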
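#' Default end-to-end run configuration
#'
#' A single nested list describing every stage of a run: the synthetic
#' data source, preprocessing parameters (QC threshold 2 SD, 0/99.9
#' rescale percentiles), split fractions (0.9/0.05/0.05 for train /
#' selection / test), the autoencoder configuration, the selection depth
#' and the panel sizes to evaluate (3, 6, 9, 12, 15, 18 where the panel
#' has enough markers).  The global seed deterministically derives every
#' stage's seed.
#'
#' @param synthetic a [synthetic_spec()] (the data source).
#' @param mae a [mae_config()].
#' @param fractions train/selection/test fractions.
#' @param qc_sd core-QC threshold in SD units.
#' @param percentiles lo/hi rescale percentiles.
#' @param max_k selection depth (default `C - 1`).
#' @param eval_sizes panel sizes to evaluate.
#' @param seed global integer seed.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(synthetic = synthetic_spec(),
                       mae = mae_config(),
                       fractions = c(0.9, 0.05, 0.05),
                       qc_sd = 2, percentiles = c(0, 99.9),
                       max_k = NULL,
                       eval_sizes = c(3, 6, 9, 12, 15, 18),
                       seed = 1L) {
  structure(list(synthetic = synthetic, mae = mae, fractions = fractions,
                 qc_sd = qc_sd, percentiles = percentiles, max_k = max_k,
                 eval_sizes = eval_sizes, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a single YAML file with optional `synthetic`, `mae`, and
#' top-level sections whose entries override the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_spec, y$synthetic %||% list())
  mae <- do.call(mae_config, y$mae %||% list())
  rest <- y[setdiff(names(y), c("synthetic", "mae"))]
  do.call(run_config, c(list(synthetic = syn, mae = mae), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = 10)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

pipeline_log <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full pipeline: simulate, split, train, select, evaluate
#'
#' Orchestrates the stages end to end and writes every artifact, stamped
#' with the configuration hash, into `out_dir`: the simulated stack store
#' and `cells.csv`, the per-epoch `loss.csv`, the model checkpoint, the
#' selection `trajectory.csv`, and `report.json` with the per-panel-size
#' evaluation.  Rerunning with the same configuration and seed reproduces
#' every artifact bit for bit.
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if needed).
#' @param verbose log stage progress.
#' @param resume reuse on-disk stage artifacts (the simulated stack and
#'   the model checkpoint) when they carry the same configuration hash,
#'   instead of recomputing them.
#' @return (invisibly) a list with the fitted model, the trajectory and
#'   the evaluation reports.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logf))
  jsonlite::write_json(c(list(config_hash = hash), unclass_deep(config)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 10)

  # a stage artifact is reusable when its sidecar records the same hash
  same_hash <- function(path) {
    resume && file.exists(path) && file.exists(paste0(path, ".hash")) &&
      identical(readLines(paste0(path, ".hash"))[1], unname(hash))
  }
  stamp <- function(path) writeLines(hash, paste0(path, ".hash"))

  # stage seeds derived deterministically from the global seed
  syn <- config$synthetic
  syn$seed <- config$seed
  pipeline_log(logf, "simulate", config_hash = hash, n_cells = syn$n_cells)
  sim <- generate_stack(syn)
  stack_write(sim$stack, file.path(out_dir, "stack"),
              true_means = sim$truth$true_means)
  stamp(file.path(out_dir, "stack"))

  pipeline_log(logf, "split", fractions = config$fractions)
  splits <- split_dataset(sim$stack, config$fractions,
                          seed = config$seed + 1L)

  mcfg <- config$mae
  mcfg$seed <- config$seed + 2L
  ckpt <- file.path(out_dir, "model.ckpt")
  if (same_hash(ckpt)) {
    pipeline_log(logf, "train", resumed = TRUE)
    model <- mae_load(ckpt)
  } else {
    pipeline_log(logf, "train", epochs = mcfg$epochs,
                 mask_ratio = mcfg$train_mask_ratio)
    model <- channel_mae(splits$train, mcfg, verbose = verbose)
    utils::write.csv(data.frame(epoch = seq_along(model$loss),
                                masked_mse = model$loss, config_hash = hash),
                     file.path(out_dir, "loss.csv"), row.names = FALSE)
    mae_save(model, ckpt)
    stamp(ckpt)
  }

  C <- length(sim$stack$markers)
  max_k <- config$max_k %||% (C - 1L)
  pipeline_log(logf, "select_panel", max_k = max_k)
  sel_stack <- splits$val %||% splits$train
  traj <- select_panel(model, sel_stack, max_k = max_k)
  tdf <- as.data.frame(traj)
  tdf$config_hash <- hash
  utils::write.csv(tdf, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)

  sizes <- config$eval_sizes[config$eval_sizes <= length(traj$markers)]
  pipeline_log(logf, "evaluate", sizes = sizes)
  test_stack <- splits$test %||% splits$train
  reports <- lapply(sizes, function(k)
    evaluate_panel(model, test_stack, traj$markers[seq_len(k)],
                   split_id = "test"))
  names(reports) <- paste0("panel_", sizes)
  jsonlite::write_json(
    c(list(config_hash = hash),
      lapply(reports, function(r)
        list(panel = r$panel, mean_rho = r$mean_rho, var_rho = r$var_rho,
             mean_ssim = r$mean_ssim, n_cells = r$n_cells,
             spearman = as.list(r$spearman), ssim = as.list(r$ssim)))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 10)

  invisible(list(model = model, trajectory = traj, reports = reports,
                 splits = splits, config_hash = hash))
}
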
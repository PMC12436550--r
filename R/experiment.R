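#' Multi-seed training experiment
#'
#' The evaluation protocol: train the same configuration `n_seeds` times with
#' different weight initializations (seeds `base, base + 1, ...`) and report
#' the per-seed test metrics together with their mean and standard deviation
#' (sample convention, `n - 1` denominator).
#'
#' @param bundle An `eeg_bundle` with split assignment.
#' @param model_config A [model_config()].
#' @param tc A [train_config()]; its `seed` is the base seed.
#' @param n_seeds Number of runs (default 5, the reporting protocol).
#' @param condition Optional named list describing the experimental condition
#'   (e.g. `rho`, `montage`), copied into the result rows.
#' @return A tibble of class `run_result`: one row per metric with columns
#'   `variant`, `task`, condition fields, `metric`, `mean`, `sd`, `n_seeds`
#'   and one `seed<k>` column per run.
#' @export
multi_seed_experiment <- function(bundle, model_config, tc = train_config(),
                                  n_seeds = 5, condition = list()) {
  if (n_seeds < 2) stop("n_seeds must be >= 2")
  per_seed <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    tcs <- tc
    tcs$seed <- tc$seed + s - 1L
    fit <- train_model(bundle, model_config, tcs)
    m <- evaluate_model(fit$model, bundle, "test")
    per_seed[[s]] <- if (tc$task == "gaze")
      c(RMSE = m$rmse, MAE = m$mae)
    else c(accuracy = m$accuracy, AUC = m$auc)
  }
  vals <- do.call(rbind, per_seed)   # n_seeds x n_metrics
  rows <- lapply(colnames(vals), function(metric) {
    v <- vals[, metric]
    row <- c(list(variant = model_config$variant, task = tc$task),
             condition,
             list(metric = metric, mean = mean(v), sd = stats::sd(v),
                  n_seeds = n_seeds),
             stats::setNames(as.list(v), paste0("seed", seq_len(n_seeds))))
    tibble::as_tibble(row)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("run_result", class(out))
  out
}

#' Cropping-by-montage sweep
#'
#' Runs the full experimental grid: for every model configuration, cropping
#' ratio and channel montage, the bundle is restricted to the montage,
#' cropped, the configuration is re-inferred for the new `(C, L)`, and a
#' [multi_seed_experiment()] is run. Results are returned as one long-format
#' table, one row per (condition, metric).
#'
#' @param bundle An `eeg_bundle` with split assignment.
#' @param model_configs List of [model_config()] objects (one per variant).
#' @param rhos Numeric vector of cropping ratios (the published grid is
#'   `c(0, 0.1, 0.2, 0.3)`).
#' @param montages Named list of `eeg_montage` objects or `NULL` for the full
#'   channel set, e.g. `list(full = NULL, reduced = reduced_montage())`.
#' @param tc A [train_config()].
#' @param n_seeds Runs per condition.
#' @return A long-format `run_result` tibble with `rho` and `montage`
#'   condition columns.
#' @export
sweep_experiment <- function(bundle, model_configs, rhos = c(0, 0.1, 0.2, 0.3),
                             montages = list(full = NULL),
                             tc = train_config(), n_seeds = 5) {
  if (is.null(names(montages)) || any(names(montages) == ""))
    stop("montages must be a named list")
  rows <- list()
  for (cfg in model_configs) for (mname in names(montages)) {
    b_m <- if (is.null(montages[[mname]])) bundle
           else select_channels(bundle, montages[[mname]])
    for (rho in rhos) {
      b <- crop_signal(b_m, rho)
      cfg_rc <- reconfigure(cfg, C = dim(b$signals)[1L],
                            L = dim(b$signals)[2L])
      rows[[length(rows) + 1L]] <- multi_seed_experiment(
        b, cfg_rc, tc, n_seeds,
        condition = list(rho = rho, montage = mname))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("run_result", class(out))
  out
}

#' Write a results table to CSV
#'
#' Long-format CSV with full double precision (17 significant digits), so a
#' written table read back with [read_results_csv()] reproduces the numeric
#' values to within representation accuracy.
#'
#' @param results A `run_result` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_csv()]
#' @param path CSV path.
#' @return A `run_result` tibble.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("run_result", class(out))
  out
}
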
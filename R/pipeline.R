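#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent R list) with:
#' \describe{
#'   \item{seed}{master integer seed; every stochastic stage derives its
#'     own seed from it.}
#'   \item{scenario}{arguments for [edge_scenario_config()] (`n_rows`,
#'     `n_cols`, `shift`), or `"custom"` fields forwarded to
#'     [generate_two_region_scenario()].}
#'   \item{stages}{character subset of `c("simulate", "fit", "transfer",
#'     "evaluate", "map")`; default all.}
#'   \item{fit}{list with `candidates` (variable codes) and `entry_alpha`.}
#'   \item{model_file}{optional coefficient CSV evaluated instead of a
#'     freshly fitted model when the `fit` stage is disabled.}
#'   \item{threshold_policy, prevalence_source}{evaluation settings.}
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "scenario", "stages", "fit", "model_file",
             "threshold_policy", "prevalence_source")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("config key 'seed' is required",
                                 call. = FALSE)
  config$stages <- config$stages %||%
    c("simulate", "fit", "transfer", "evaluate", "map")
  all_stages <- c("simulate", "fit", "transfer", "evaluate", "map")
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  config$scenario <- config$scenario %||% list()
  config$threshold_policy <- config$threshold_policy %||% "default"
  config$prevalence_source <- config$prevalence_source %||% "training"
  config
}

#' Run the full simulate-fit-transfer-evaluate pipeline
#'
#' Orchestrates the end-to-end workflow on a synthetic two-region
#' landscape: simulate training and target regions, fit (stepwise) a model
#' in the training region, transfer it to the target region, evaluate both
#' locally fitted and transferred predictions, and write favourability
#' maps. All artifacts (ASCII rasters, coefficient CSVs, report JSON, log,
#' manifest with md5 checksums) land in `out_dir`; re-running with the
#' same config reproduces the checksums.
#'
#' @param config Path to a YAML config, or a list
#'   (see [read_pipeline_config()]).
#' @param out_dir Output directory (created; must be empty or absent
#'   unless `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the scenario, fitted/loaded model,
#'   transfer result, reports, and the manifest data frame.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0("INFO %s\n", collapse = ""),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  stages <- config$stages
  written <- character(0)
  emit <- function(p) { written <<- c(written, p); p }

  # --- simulate -------------------------------------------------------
  sc_args <- config$scenario
  sc_config <- do.call(edge_scenario_config,
                       c(sc_args, list(seed = config$seed)))
  scenario <- generate_two_region_scenario(sc_config)
  logf("scenario: %dx%d cells/region, seed %d, shift=%s",
       sc_config$n_rows, sc_config$n_cols, config$seed,
       !identical(sc_args$shift, FALSE))
  logf("train prevalence: n1=%d n0=%d", scenario$train$det$n1,
       scenario$train$det$n0)
  logf("target prevalence: n1=%d n0=%d", scenario$target$det$n1,
       scenario$target$det$n0)
  if ("simulate" %in% stages) {
    emit(write_grid_dir(scenario$train$grid,
                        file.path(out_dir, "train_grid")))
    emit(write_grid_dir(scenario$target$grid,
                        file.path(out_dir, "target_grid")))
    emit(write_detections(scenario$train$det, scenario$train$grid,
                          file.path(out_dir, "train_detections.csv")))
    emit(write_detections(scenario$target$det, scenario$target$grid,
                          file.path(out_dir, "target_detections.csv")))
  }

  # --- fit (or load a supplied model) ---------------------------------
  if ("fit" %in% stages) {
    fit_cfg <- config$fit %||% list()
    candidates <- fit_cfg$candidates %||% scenario$train$grid$variables
    model <- forward_stepwise(
      scenario$train$grid, scenario$train$det, candidates,
      entry_alpha = fit_cfg$entry_alpha %||% 0.05,
      label = "locally fitted model")
    logf("fit: selected %d/%d candidates (%s); n1=%d n0=%d; converged in %d iterations",
         length(model$coefficients), length(candidates),
         paste(names(model$coefficients), collapse = ", "),
         model$n1, model$n0, attr(model, "fit")$iter)
  } else {
    if (is.null(config$model_file)) {
      stop("stage 'fit' disabled and no model_file supplied", call. = FALSE)
    }
    if (!file.exists(config$model_file)) {
      stop("model file not found: ", config$model_file, call. = FALSE)
    }
    model <- read_coefficient_set(config$model_file)
    logf("fit: skipped; loaded model '%s' from %s", model$label,
         config$model_file)
  }
  emit(write_coefficient_set(model, file.path(out_dir, "model.csv")))

  # published fixtures carry no n1/n0; anchor on target prevalence then
  prev_src <- config$prevalence_source
  if (identical(prev_src, "training") && is.na(model$n1)) {
    prev_src <- c(scenario$target$det$n1, scenario$target$det$n0)
    logf("prevalence source: model has no training n1/n0, re-anchored on target (n1=%d n0=%d)",
         prev_src[1], prev_src[2])
  } else {
    logf("prevalence source: %s", paste(prev_src, collapse = "/"))
  }

  # --- transfer -------------------------------------------------------
  transfer <- NULL
  if ("transfer" %in% stages) {
    transfer <- transfer_model(model, scenario$target$grid,
                               scenario$target$det,
                               prevalence_source = prev_src,
                               threshold_policy = config$threshold_policy)
    if (!is.null(transfer$coverage_diagnostics)) {
      logf("transfer coverage (fraction outside training range): %s",
           paste(sprintf("%s=%.3f", names(transfer$coverage_diagnostics),
                         transfer$coverage_diagnostics), collapse = ", "))
    }
  }

  # --- evaluate -------------------------------------------------------
  reports <- list()
  if ("evaluate" %in% stages) {
    reports$training <- evaluate_model(
      model, scenario$train$grid, scenario$train$det,
      config$threshold_policy, prev_src)
    logf("training-region evaluation: threshold %.4g, AUC %.4f, TSS %.4f",
         reports$training$confusion$threshold, reports$training$auc,
         reports$training$tss)
    emit(write_report(reports$training,
                      file.path(out_dir, "report_training.json")))
    if (!is.null(transfer) && !is.null(transfer$report)) {
      reports$transferred <- transfer$report
      logf("target-region (transferred) evaluation: AUC %.4f, TSS %.4f",
           transfer$report$auc, transfer$report$tss)
      emit(write_report(transfer$report,
                        file.path(out_dir, "report_transferred.json")))
    }
  }

  # --- map ------------------------------------------------------------
  if ("map" %in% stages) {
    surf <- favourability_surface(model, scenario$train$grid, prev_src)
    emit(write_ascii_grid(surf,
                          path = file.path(out_dir, "favourability_train.asc")))
    if (!is.null(transfer)) {
      emit(write_ascii_grid(transfer$surface,
                            path = file.path(out_dir, "favourability_target.asc")))
    }
  }

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    c("manifest.csv", "pipeline.log")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  logf("wrote %d artifact(s); manifest complete", nrow(manifest))

  invisible(list(scenario = scenario, model = model, transfer = transfer,
                 reports = reports, manifest = manifest))
}
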
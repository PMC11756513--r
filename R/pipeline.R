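#' Configuration for an end-to-end training and evaluation run
#'
#' @param traces,labels Paths to the input trace and label CSVs.
#' @param outdir Output directory for the model bundle, test-set calls and
#'   the evaluation report.
#' @param train_fraction Training share of the 80/20-style split.
#' @param folds CV folds used when `tune = TRUE`.
#' @param seed Integer seed governing the split, tuning and fitting.
#' @param tune Run the cross-validated grid search before fitting; with
#'   `FALSE` (default) the shipped presets [tac_default_params()] are used.
#' @param grid_classifier,grid_regressor Grids for tuning (see [tac_grid()]).
#' @param threshold,flag_interval Decision cutoff and manual-review
#'   interval.
#' @param cycles Expected cycles per reaction.
#' @return A `run_config` list.
#' @export
run_config <- function(traces, labels, outdir,
                       train_fraction = 0.8, folds = 5L, seed = 1L,
                       tune = FALSE,
                       grid_classifier = tac_grid(),
                       grid_regressor = tac_grid(),
                       threshold = 0.5, flag_interval = c(0.1, 0.9),
                       cycles = 40L) {
  stopifnot(train_fraction > 0, train_fraction < 1, folds >= 2L)
  structure(
    list(traces = traces, labels = labels, outdir = outdir,
         train_fraction = train_fraction, folds = as.integer(folds),
         seed = as.integer(seed), tune = isTRUE(tune),
         grid_classifier = grid_classifier, grid_regressor = grid_regressor,
         threshold = threshold, flag_interval = flag_interval,
         cycles = as.integer(cycles)),
    class = "run_config"
  )
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Train and evaluate the pipeline end to end
#'
#' Runs the full post-run analysis workflow: read traces and labels,
#' normalize, assemble the feature matrix, split into train/test, optionally
#' tune, fit the two-stage model, predict the held-out test set and score it
#' against the gold standard. Writes the model bundle (`<outdir>/model/`),
#' the test-set calls (`calls.csv`) and the evaluation report
#' (`report.json`), and logs dataset sizes, selected hyperparameters and
#' flag counts. Reruns with an identical configuration produce identical
#' outputs (single-threaded reproducible mode).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `tac_eval` report, the fitted model
#'   and the output paths.
#' @export
run_train_eval <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traces <- stage("read", read_curves(config$traces, config$cycles))
  labels <- stage("read", read_labels(config$labels, max_ct = config$cycles))
  message(sprintf("read %d traces, %d labels", length(traces), nrow(labels)))

  normalized <- stage("normalize", normalize_batch(traces))
  ds <- stage("assemble", assemble_dataset(normalized, labels))
  parts <- stage("split",
                 split_dataset(ds, config$train_fraction, seed = config$seed))
  message(sprintf("split: %d train / %d test reactions",
                  nrow(parts$train$x), nrow(parts$test$x)))

  if (config$tune) {
    tuned <- stage("tune", tune_tac(
      parts$train, grid_classifier = config$grid_classifier,
      grid_regressor = config$grid_regressor,
      nfolds = config$folds, seed = config$seed))
    cls_params <- tuned$classifier
    reg_params <- tuned$regressor
    message(sprintf("tuned over %d + %d grid points",
                    nrow(config$grid_classifier), nrow(config$grid_regressor)))
  } else {
    cls_params <- tac_default_params()$classifier
    reg_params <- tac_default_params()$regressor
  }
  message("classifier params: ",
          paste(sprintf("%s=%s", names(cls_params),
                        vapply(cls_params, format, "")), collapse = ", "))
  message("regressor params: ",
          paste(sprintf("%s=%s", names(reg_params),
                        vapply(reg_params, format, "")), collapse = ", "))

  model <- stage("fit", tac_fit(
    parts$train, classifier_params = cls_params,
    regressor_params = reg_params, threshold = config$threshold,
    flag_interval = config$flag_interval, seed = config$seed))
  calls <- stage("predict", predict(model, parts$test))
  report <- stage("evaluate", evaluate_calls(calls, data.frame(
    reaction_id = parts$test$reaction_id, amplified = parts$test$amplified,
    ct = parts$test$ct, stringsAsFactors = FALSE)))
  message(sprintf("%d of %d test calls flagged for manual review",
                  sum(calls$flagged), nrow(calls)))

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  model_dir <- file.path(config$outdir, "model")
  stage("write", save_tac_model(model, model_dir))
  calls_path <- file.path(config$outdir, "calls.csv")
  stage("write", write_calls(calls, calls_path))
  report_path <- file.path(config$outdir, "report.json")
  stage("write", jsonlite::write_json(
    unclass_report(report), report_path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE))
  invisible(list(report = report, model = model,
                 paths = list(model = model_dir, calls = calls_path,
                              report = report_path)))
}

#' @noRd
unclass_report <- function(report) {
  out <- unclass(report)
  out$confusion <- unclass(out$confusion)
  out$metrics <- unclass(out$metrics)
  out
}

#' Apply a persisted model to a new trace file
#'
#' Deployment mode: loads a saved model bundle, normalizes the curves in a
#' run file and writes one call record per reaction. Fails if the file's
#' cycle count does not match the model's.
#'
#' @param model_dir Directory of a bundle written by [save_tac_model()].
#' @param traces Path to a traces CSV.
#' @param out Path for the output calls CSV.
#' @return Invisibly, the call data frame.
#' @export
run_predict <- function(model_dir, traces, out) {
  model <- stage("load", load_tac_model(model_dir))
  trs <- stage("read", read_curves(traces, expected_cycles = model$cycles))
  normalized <- stage("normalize", normalize_batch(trs))
  calls <- stage("predict", predict(model, normalized))
  stage("write", write_calls(calls, out))
  message(sprintf("%d calls written; %d flagged for manual review",
                  nrow(calls), sum(calls$flagged)))
  invisible(calls)
}
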
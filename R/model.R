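#' Default hyperparameters for the two-stage model
#'
#' Presets for the amplification classifier and the Ct regressor, as selected
#' by 5-fold cross-validated grid search (see [tac_grid()]) on a large
#' archived TaqMan Array Card dataset. On other data -- including synthetic
#' data -- a fresh [tune_tac()] run may well select different points; the
#' presets are a documented starting point, not a claim of optimality.
#'
#' Boosting-round counts are not part of the searched grid. The presets leave
#' `n_rounds = NULL`, which makes [tac_fit()] select the round count by
#' cross-validated early stopping; running boosting far past that point makes
#' the classifier's probabilities saturate towards 0/1, which costs nothing
#' in accuracy but ruins the probability-based review flags. Set `n_rounds`
#' explicitly to skip the selection.
#'
#' @return List with elements `classifier` and `regressor`, each a named
#'   list of XGBoost hyperparameters plus `n_rounds`.
#' @export
tac_default_params <- function() {
  list(
    classifier = list(eta = 0.5, max_depth = 13, min_child_weight = 1,
                      subsample = 0.7, gamma = 0.1, colsample_bytree = 0.7,
                      n_rounds = NULL),
    regressor = list(eta = 0.1, max_depth = 16, min_child_weight = 10,
                     subsample = 1, gamma = 0.2, colsample_bytree = 1,
                     n_rounds = NULL)
  )
}

#' Hyperparameter grid for tuning
#'
#' Defaults reproduce the full search grid: eta in \{0.1, 0.3, 0.5, 0.7\},
#' max_depth 10..18, min_child_weight in \{1, 5, 10\}, subsample in
#' \{0.5, 0.7, 1\}, gamma in \{0, 0.1, 0.2\} and colsample_bytree in
#' \{0.5, 0.7, 1\} -- 2,916 candidate settings. Pass shorter vectors for a
#' cheaper search.
#'
#' @param eta,max_depth,min_child_weight,subsample,gamma,colsample_bytree
#'   Candidate values for each hyperparameter.
#' @return Data frame with one row per candidate setting.
#' @export
tac_grid <- function(eta = c(0.1, 0.3, 0.5, 0.7),
                     max_depth = 10:18,
                     min_child_weight = c(1, 5, 10),
                     subsample = c(0.5, 0.7, 1),
                     gamma = c(0, 0.1, 0.2),
                     colsample_bytree = c(0.5, 0.7, 1)) {
  expand.grid(eta = eta, max_depth = max_depth,
              min_child_weight = min_child_weight, subsample = subsample,
              gamma = gamma, colsample_bytree = colsample_bytree,
              KEEP.OUT.ATTRS = FALSE)
}

#' @noRd
xgb_param_list <- function(p, objective, nthread, seed) {
  list(objective = objective,
       eta = p$eta, max_depth = as.integer(p$max_depth),
       min_child_weight = p$min_child_weight, subsample = p$subsample,
       gamma = p$gamma, colsample_bytree = p$colsample_bytree,
       nthread = as.integer(nthread), seed = as.integer(seed))
}

#' Tune the two-stage model by cross-validated grid search
#'
#' Evaluates every grid point with k-fold cross-validation on the training
#' set: the amplification classifier by mean validation log-loss on all
#' reactions, the Ct regressor by mean validation MAE on the gold-standard
#' amplified subset only. Boosting rounds are chosen within each CV run by
#' early stopping (patience `patience`, cap `max_rounds`). Deterministic for
#' a given seed and single-threaded setting.
#'
#' @param train A `tac_dataset` (the training partition).
#' @param grid_classifier,grid_regressor Candidate grids from [tac_grid()].
#' @param nfolds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment and subsampling.
#' @param max_rounds,patience Early-stopping cap and patience.
#' @param nthread Threads for XGBoost (default 1 for reproducibility).
#' @param verbose Print per-point progress.
#' @return List with `classifier` and `regressor` hyperparameter lists (each
#'   including the selected `n_rounds`) and a `cv` element holding the full
#'   per-point CV tables.
#' @export
tune_tac <- function(train,
                     grid_classifier = tac_grid(),
                     grid_regressor = tac_grid(),
                     nfolds = 5L, seed = 1L,
                     max_rounds = 500L, patience = 20L,
                     nthread = 1L, verbose = FALSE) {
  stopifnot(inherits(train, "tac_dataset"), nfolds >= 2L,
            nrow(grid_classifier) >= 1L, nrow(grid_regressor) >= 1L)
  if (length(unique(train$amplified)) < 2L) {
    stop("training labels contain a single class; cannot cross-validate the classifier",
         call. = FALSE)
  }
  amp <- suppressWarnings(amplified_subset(train))
  if (nrow(amp$x) < nfolds) {
    stop("too few amplified reactions to cross-validate the regressor",
         call. = FALSE)
  }

  search <- function(grid, x, y, objective, metric) {
    dm <- xgboost::xgb.DMatrix(x, label = y)
    scores <- numeric(nrow(grid))
    rounds <- integer(nrow(grid))
    col <- paste0("test_", metric, "_mean")
    for (i in seq_len(nrow(grid))) {
      params <- xgb_param_list(grid[i, ], objective, nthread, seed)
      cv <- with_seed(seed, xgboost::xgb.cv(
        params = params, data = dm, nrounds = max_rounds, nfold = nfolds,
        metrics = metric, early_stopping_rounds = patience, verbose = 0
      ))
      curve <- cv$evaluation_log[[col]]
      rounds[i] <- which.min(curve)
      scores[i] <- curve[rounds[i]]
      if (verbose) {
        message(sprintf("grid %d/%d: %s=%.5f @ %d rounds",
                        i, nrow(grid), metric, scores[i], rounds[i]))
      }
    }
    best <- which.min(scores)
    params <- as.list(grid[best, ])
    params$n_rounds <- rounds[best]
    list(params = params,
         cv = cbind(grid, score = scores, n_rounds = rounds))
  }

  cls <- search(grid_classifier, train$x, as.numeric(train$amplified),
                "binary:logistic", "logloss")
  reg <- search(grid_regressor, amp$x, amp$ct, "reg:squarederror", "mae")
  list(classifier = cls$params, regressor = reg$params,
       cv = list(classifier = cls$cv, regressor = reg$cv))
}

#' @noRd
select_n_rounds <- function(x, y, objective, metric, p, seed, nthread,
                            nfolds = 5L, cap = 500L, patience = 20L) {
  if (nrow(x) < 2L * nfolds) return(100L)  # too small to fold; bounded fit
  cv <- with_seed(seed, xgboost::xgb.cv(
    params = xgb_param_list(p, objective, nthread, seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = cap, nfold = nfolds, metrics = metric,
    early_stopping_rounds = patience, verbose = 0))
  which.min(cv$evaluation_log[[paste0("test_", metric, "_mean")]])
}

#' Fit the two-stage amplification-calling model
#'
#' Trains two gradient-boosted tree models on normalized fluorescence
#' features: a classifier for whether amplification occurred, on every
#' training reaction, and a Ct regressor on the gold-standard amplified
#' subset only. At prediction time the regressor is applied conditionally on
#' a positive classifier call.
#'
#' When a parameter list carries `n_rounds = NULL` (the default presets do),
#' the boosting-round count is chosen by 5-fold cross-validated early
#' stopping (patience 20, cap 500) on the respective training data before
#' the final fit, keeping the classifier's probabilities calibrated rather
#' than saturated.
#'
#' @param train A `tac_dataset` with labels attached.
#' @param classifier_params,regressor_params Hyperparameter lists, with
#'   `n_rounds` either fixed or `NULL` for early-stopping selection (see
#'   [tac_default_params()], [tune_tac()]).
#' @param threshold Decision cutoff on the classifier probability; a call is
#'   amplified only when the probability strictly exceeds it (default 0.5).
#' @param flag_interval Closed probability interval flagged for manual
#'   review (default `c(0.1, 0.9)`).
#' @param seed Integer seed for XGBoost's subsampling.
#' @param nthread Threads (default 1, the reproducible mode; identical
#'   data, parameters and seed then give identical probabilities).
#' @return A `tac_model` object with `print`, `summary`, `predict` and
#'   `plot` methods.
#' @export
tac_fit <- function(train,
                    classifier_params = tac_default_params()$classifier,
                    regressor_params = tac_default_params()$regressor,
                    threshold = 0.5, flag_interval = c(0.1, 0.9),
                    seed = 1L, nthread = 1L) {
  stopifnot(inherits(train, "tac_dataset"))
  if (nrow(train$x) == 0L) stop("empty training set", call. = FALSE)
  amp <- suppressWarnings(amplified_subset(train))
  if (nrow(amp$x) == 0L) {
    stop("no gold-standard amplified reactions: the Ct regressor cannot be trained",
         call. = FALSE)
  }
  stopifnot(length(flag_interval) == 2L, flag_interval[1] <= flag_interval[2])

  if (is.null(classifier_params$n_rounds)) {
    classifier_params$n_rounds <- select_n_rounds(
      train$x, as.numeric(train$amplified), "binary:logistic", "logloss",
      classifier_params, seed, nthread)
  }
  if (is.null(regressor_params$n_rounds)) {
    regressor_params$n_rounds <- select_n_rounds(
      amp$x, amp$ct, "reg:squarederror", "mae",
      regressor_params, seed, nthread)
  }

  dcls <- xgboost::xgb.DMatrix(train$x, label = as.numeric(train$amplified))
  classifier <- with_seed(seed, xgboost::xgb.train(
    params = xgb_param_list(classifier_params, "binary:logistic", nthread, seed),
    data = dcls, nrounds = as.integer(classifier_params$n_rounds), verbose = 0
  ))
  dreg <- xgboost::xgb.DMatrix(amp$x, label = amp$ct)
  regressor <- with_seed(seed, xgboost::xgb.train(
    params = xgb_param_list(regressor_params, "reg:squarederror", nthread, seed),
    data = dreg, nrounds = as.integer(regressor_params$n_rounds), verbose = 0
  ))

  structure(
    list(classifier = classifier, regressor = regressor,
         cycles = ncol(train$x),
         threshold = threshold, flag_interval = flag_interval,
         meta = list(n_train = nrow(train$x), n_amplified = nrow(amp$x),
                     seed = as.integer(seed),
                     classifier_params = classifier_params,
                     regressor_params = regressor_params,
                     version = as.character(utils::packageVersion("tacall")))),
    class = "tac_model"
  )
}

#' @noRd
as_feature_matrix <- function(newdata, cycles) {
  if (inherits(newdata, "tac_dataset")) {
    x <- newdata$x
  } else if (is.list(newdata) && !is.data.frame(newdata) &&
             length(newdata) && !is.null(newdata[[1L]]$values)) {
    x <- do.call(rbind, lapply(newdata, `[[`, "values"))
    rownames(x) <- vapply(newdata, `[[`, character(1), "reaction_id")
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != cycles) {
    stop(sprintf("model was trained on %d cycles but data have %d",
                 cycles, ncol(x)), call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  x
}

#' Build call records from classifier probabilities
#'
#' Applies the decision rules that turn a probability into a call: a
#' reaction is amplified only when its probability strictly exceeds the
#' threshold (exactly 0.5 is a negative call by default), the Ct is kept
#' only for amplified calls, and a call is flagged when the probability lies
#' in the closed flag interval.
#'
#' @param reaction_id Character vector of reaction ids.
#' @param probability Classifier probabilities in `[0, 1]`.
#' @param ct Candidate Ct values (same length; entries for non-amplified
#'   calls are dropped to `NA`).
#' @param threshold Decision cutoff (default 0.5, strict).
#' @param flag_interval Closed flag interval (default `c(0.1, 0.9)`).
#' @return Data frame of call records: `reaction_id`, `probability`,
#'   `amplified`, `ct`, `flagged`.
#' @export
call_records <- function(reaction_id, probability, ct,
                         threshold = 0.5, flag_interval = c(0.1, 0.9)) {
  stopifnot(length(probability) == length(reaction_id),
            length(ct) == length(reaction_id))
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  amplified <- probability > threshold
  data.frame(reaction_id = as.character(reaction_id),
             probability = probability,
             amplified = amplified,
             ct = ifelse(amplified, ct, NA_real_),
             flagged = probability >= flag_interval[1] &
               probability <= flag_interval[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call amplification and predict Ct for new curves
#'
#' Applies the classifier to every curve; a reaction is called amplified
#' when its probability strictly exceeds the decision threshold (a
#' probability of exactly 0.5 is a negative call under the default). The Ct
#' regressor is applied only to reactions called amplified; all others have
#' `ct = NA`. A call is flagged for manual review when the probability lies
#' inside the closed flag interval.
#'
#' @param object A `tac_model`.
#' @param newdata A `tac_dataset`, a list of normalized traces, or a numeric
#'   matrix with one column per cycle.
#' @param ... Unused.
#' @return Data frame of call records: `reaction_id`, `probability`,
#'   `amplified`, `ct`, `flagged`.
#' @export
predict.tac_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata, object$cycles)
  probability <- stats::predict(object$classifier, xgboost::xgb.DMatrix(x))
  amplified <- probability > object$threshold
  ct <- rep(NA_real_, nrow(x))
  if (any(amplified)) {
    ct[amplified] <- stats::predict(
      object$regressor, xgboost::xgb.DMatrix(x[amplified, , drop = FALSE]))
  }
  call_records(rownames(x), probability, ct,
               threshold = object$threshold,
               flag_interval = object$flag_interval)
}

#' @export
print.tac_model <- function(x, ...) {
  cat("Two-stage amplification-calling model (gradient-boosted trees)\n")
  cat(sprintf("  cycles: %d   trained on %d reactions (%d amplified)\n",
              x$cycles, x$meta$n_train, x$meta$n_amplified))
  cat(sprintf("  decision threshold: p > %s   flag interval: [%s, %s]\n",
              format(x$threshold), format(x$flag_interval[1]),
              format(x$flag_interval[2])))
  invisible(x)
}

#' @export
summary.tac_model <- function(object, ...) {
  print(object)
  fmt <- function(p) paste(sprintf("%s=%s", names(p), vapply(p, format, "")),
                           collapse = ", ")
  cat("  classifier:", fmt(object$meta$classifier_params), "\n")
  cat("  regressor: ", fmt(object$meta$regressor_params), "\n")
  cat(sprintf("  seed: %d   version: %s\n", object$meta$seed,
              object$meta$version))
  invisible(object)
}

#' Plot per-cycle feature importance of a fitted model
#'
#' Shows which cycles each stage leans on: gain-based importance of the 40
#' cycle features for the amplification classifier and the Ct regressor.
#'
#' @param x A `tac_model`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, a list of the two importance tables.
#' @export
plot.tac_model <- function(x, ...) {
  imp_vec <- function(booster) {
    imp <- xgboost::xgb.importance(model = booster)
    v <- numeric(x$cycles)
    idx <- as.integer(sub("cycle_", "", imp$Feature))
    v[idx] <- imp$Gain
    v
  }
  cls <- imp_vec(x$classifier)
  reg <- imp_vec(x$regressor)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(cls, names.arg = seq_len(x$cycles),
                    main = "Classifier: cycle importance (gain)",
                    xlab = "cycle", ylab = "gain", ...)
  graphics::barplot(reg, names.arg = seq_len(x$cycles),
                    main = "Ct regressor: cycle importance (gain)",
                    xlab = "cycle", ylab = "gain", ...)
  invisible(list(classifier = cls, regressor = reg))
}

#' Persist and restore a fitted model bundle
#'
#' The bundle is a directory holding the two boosters in XGBoost's portable
#' JSON format plus a `manifest.json` with the cycle count, decision
#' threshold, flag interval and training metadata.
#'
#' @param model A `tac_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_tac_model()` returns `dir` invisibly; `load_tac_model()`
#'   returns the restored `tac_model`.
#' @export
save_tac_model <- function(model, dir) {
  stopifnot(inherits(model, "tac_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$classifier, file.path(dir, "classifier.json"))
  xgboost::xgb.save(model$regressor, file.path(dir, "regressor.json"))
  manifest <- list(cycles = model$cycles, threshold = model$threshold,
                   flag_interval = model$flag_interval, meta = model$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_tac_model
#' @export
load_tac_model <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a model bundle (no manifest.json): ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  structure(
    list(classifier = xgboost::xgb.load(file.path(dir, "classifier.json")),
         regressor = xgboost::xgb.load(file.path(dir, "regressor.json")),
         cycles = manifest$cycles,
         threshold = manifest$threshold,
         flag_interval = manifest$flag_interval,
         meta = manifest$meta),
    class = "tac_model"
  )
}
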
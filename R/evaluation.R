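#' @noRd
align_labels <- function(calls, labels) {
  if (anyDuplicated(calls$reaction_id) || anyDuplicated(labels$reaction_id)) {
    stop("duplicate reaction_id in calls or labels", call. = FALSE)
  }
  missing_lab <- setdiff(calls$reaction_id, labels$reaction_id)
  missing_call <- setdiff(labels$reaction_id, calls$reaction_id)
  if (length(missing_lab) || length(missing_call)) {
    stop("calls and labels do not align; unmatched ids: ",
         paste(utils::head(c(missing_lab, missing_call), 10), collapse = ", "),
         call. = FALSE)
  }
  labels[match(calls$reaction_id, labels$reaction_id), , drop = FALSE]
}

#' Confusion matrix of automated calls against the gold standard
#'
#' The positive class is amplification: `tp` counts reactions both the model
#' and the gold standard call amplified, `fp` model-only, `fn` gold-only and
#' `tn` neither.
#'
#' @param calls Data frame of call records with `reaction_id` and
#'   `amplified`.
#' @param labels Gold-standard label data frame.
#' @return A `tac_confusion` list with fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(calls, labels) {
  lab <- align_labels(calls, labels)
  pred <- calls$amplified
  gold <- lab$amplified
  structure(
    list(tp = sum(pred & gold), fp = sum(pred & !gold),
         fn = sum(!pred & gold), tn = sum(!pred & !gold)),
    class = "tac_confusion"
  )
}

#' @export
print.tac_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(`model call` = c("no amplification", "amplification"),
                              `manual call` = c("no amplification", "amplification")))
  print(m)
  invisible(x)
}

#' Classification performance metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (Se), specificity (Sp), positive and
#' negative predictive value (PPV, NPV), with amplification as the positive
#' class. A metric whose denominator is zero is reported as `NA` rather than
#' coerced to 0.
#'
#' @param cm A `tac_confusion` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A `tac_metrics` list with fields `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` and the counts `n` and `n_misclassified`.
#' @export
classification_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(accuracy = (cm$tp + cm$tn) / total,
         sensitivity = ratio(cm$tp, cm$tp + cm$fn),
         specificity = ratio(cm$tn, cm$tn + cm$fp),
         ppv = ratio(cm$tp, cm$tp + cm$fp),
         npv = ratio(cm$tn, cm$tn + cm$fn),
         n = total,
         n_misclassified = cm$fp + cm$fn),
    class = "tac_metrics"
  )
}

#' @export
print.tac_metrics <- function(x, ...) {
  f <- function(v) if (is.na(v)) "  --" else sprintf("%.3f", v)
  cat(sprintf("accuracy %s  Se %s  Sp %s  PPV %s  NPV %s  (n=%d, misclassified=%d)\n",
              f(x$accuracy), f(x$sensitivity), f(x$specificity),
              f(x$ppv), f(x$npv), x$n, x$n_misclassified))
  invisible(x)
}

#' Mean absolute Ct error with the Ct-40 false-positive convention
#'
#' The MAE is averaged over reactions the model called amplified. For false
#' positives -- called amplified but negative by the gold standard -- the
#' gold Ct is taken as `no_amp_ct` (default 40, the run length). The
#' "excluding" variant drops those false positives and averages over true
#' positives only. Reactions the model called negative are not in the MAE
#' population by default; set `include_false_negatives = TRUE` for a
#' symmetric variant where missed amplifications enter with a predicted Ct
#' of `no_amp_ct`.
#'
#' @param calls Call records with `reaction_id`, `amplified`, `ct`.
#' @param labels Gold-standard labels.
#' @param no_amp_ct Ct substituted for a non-amplified gold standard
#'   (default 40).
#' @param include_false_negatives Include gold-amplified reactions the model
#'   missed, with predicted Ct `no_amp_ct` (default `FALSE`).
#' @return List with `mae`, `mae_excluding_misclassified` and the counts
#'   `n`, `n_false_positive` (`NA` values when the model called nothing
#'   amplified).
#' @export
ct_mae <- function(calls, labels, no_amp_ct = 40,
                   include_false_negatives = FALSE) {
  lab <- align_labels(calls, labels)
  pos <- calls$amplified
  if (!any(pos)) {
    return(list(mae = NA_real_, mae_excluding_misclassified = NA_real_,
                n = 0L, n_false_positive = 0L,
                note = "no reactions called amplified"))
  }
  gold_ct <- ifelse(lab$amplified, lab$ct, no_amp_ct)
  err <- abs(calls$ct[pos] - gold_ct[pos])
  true_pos <- lab$amplified[pos]
  if (include_false_negatives) {
    fn <- !pos & lab$amplified
    err <- c(err, abs(no_amp_ct - lab$ct[fn]))
    true_pos <- c(true_pos, rep(FALSE, sum(fn)))
  }
  list(mae = mean(err),
       mae_excluding_misclassified =
         if (any(true_pos)) mean(err[true_pos]) else NA_real_,
       n = length(err),
       n_false_positive = sum(!true_pos))
}

#' Full evaluation report for a set of calls
#'
#' Combines the confusion matrix, classification metrics, Ct MAE (both
#' variants) and -- when the calls carry a `flagged` column -- the
#' flag/misclassification cross-counts used to check that uncertain calls
#' are enriched for disagreements with the gold standard.
#'
#' @param calls Call records (see [predict.tac_model()]).
#' @param labels Gold-standard labels.
#' @param no_amp_ct Ct substituted for false positives in the MAE.
#' @return A `tac_eval` list: `confusion`, `metrics`, `mae`,
#'   `mae_excluding_misclassified`, `n_misclassified`, and flag counts
#'   `n_flagged_misclassified`, `n_flagged_correct`,
#'   `flagged_rate_misclassified`, `flagged_rate_correct`.
#' @export
evaluate_calls <- function(calls, labels, no_amp_ct = 40) {
  lab <- align_labels(calls, labels)
  cm <- confusion_matrix(calls, labels)
  metrics <- classification_metrics(cm)
  mae <- ct_mae(calls, labels, no_amp_ct = no_amp_ct)
  out <- list(confusion = cm, metrics = metrics,
              mae = mae$mae,
              mae_excluding_misclassified = mae$mae_excluding_misclassified,
              n = metrics$n, n_misclassified = metrics$n_misclassified)
  if (!is.null(calls$flagged)) {
    wrong <- calls$amplified != lab$amplified
    out$n_flagged_misclassified <- sum(calls$flagged & wrong)
    out$n_flagged_correct <- sum(calls$flagged & !wrong)
    out$flagged_rate_misclassified <-
      if (any(wrong)) mean(calls$flagged[wrong]) else NA_real_
    out$flagged_rate_correct <-
      if (any(!wrong)) mean(calls$flagged[!wrong]) else NA_real_
  }
  structure(out, class = "tac_eval")
}

#' @export
print.tac_eval <- function(x, ...) {
  print(x$metrics)
  f <- function(v) if (is.na(v)) "--" else sprintf("%.3f", v)
  cat(sprintf("Ct MAE %s (excluding misclassified: %s)\n",
              f(x$mae), f(x$mae_excluding_misclassified)))
  if (!is.null(x$n_flagged_misclassified)) {
    cat(sprintf("flagged: %d of %d misclassified (%s), %d of %d correct (%s)\n",
                x$n_flagged_misclassified, x$n_misclassified,
                f(x$flagged_rate_misclassified),
                x$n_flagged_correct, x$n - x$n_misclassified,
                f(x$flagged_rate_correct)))
  }
  invisible(x)
}

#' Compare analyst call tables against the gold standard
#'
#' Scores each analyst's calls (and, optionally, the automated model's) with
#' accuracy and the two Ct MAE variants, as in a multi-laboratory external
#' quality assessment. Rows are sorted by ascending accuracy, ties broken by
#' MAE (lower first).
#'
#' @param analysts Named list of call data frames (each with `reaction_id`,
#'   `amplified`, `ct`).
#' @param gold Gold-standard label data frame.
#' @param automated Optional call data frame for the automated model, added
#'   as a row named `"Automated Analysis"`.
#' @param no_amp_ct Ct substituted for false positives in the MAE.
#' @return Data frame with columns `analyst`, `accuracy`, `mae`,
#'   `mae_excluding_misclassified`.
#' @export
compare_analysts <- function(analysts, gold, automated = NULL,
                             no_amp_ct = 40) {
  stopifnot(is.list(analysts), length(analysts) >= 1L,
            !is.null(names(analysts)), all(nzchar(names(analysts))))
  if (!is.null(automated)) {
    analysts <- c(analysts, list(`Automated Analysis` = automated))
  }
  rows <- lapply(names(analysts), function(nm) {
    calls <- analysts[[nm]]
    missing_ids <- setdiff(gold$reaction_id, calls$reaction_id)
    if (length(missing_ids)) {
      stop(sprintf("analyst '%s' is missing reaction(s): %s", nm,
                   paste(utils::head(missing_ids, 10), collapse = ", ")),
           call. = FALSE)
    }
    metrics <- classification_metrics(confusion_matrix(calls, gold))
    mae <- ct_mae(calls, gold, no_amp_ct = no_amp_ct)
    data.frame(analyst = nm, accuracy = metrics$accuracy, mae = mae$mae,
               mae_excluding_misclassified = mae$mae_excluding_misclassified,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accuracy, out$mae, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
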
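# Builds aligned calls/labels realizing given confusion counts.
counts_to_tables <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  ids <- sprintf("r%05d", seq_len(n))
  gold <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  pred <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
  list(
    calls = data.frame(reaction_id = ids, probability = ifelse(pred, 0.99, 0.01),
                       amplified = pred, ct = ifelse(pred, 30, NA_real_),
                       flagged = FALSE, stringsAsFactors = FALSE),
    labels = data.frame(reaction_id = ids, amplified = gold,
                        ct = ifelse(gold, 30, NA_real_),
                        stringsAsFactors = FALSE)
  )
}

test_that("confusion counts partition the reactions", {
  tb <- counts_to_tables(2, 0, 0, 2)
  cm <- confusion_matrix(tb$calls, tb$labels)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))

  tb <- counts_to_tables(0, 7, 0, 0)
  cm <- confusion_matrix(tb$calls, tb$labels)
  expect_equal(cm$fp, 7L)

  tb <- counts_to_tables(3, 1, 2, 4)
  tb$labels$reaction_id[1] <- "stranger"
  expect_error(confusion_matrix(tb$calls, tb$labels), "unmatched")
})

test_that("internal-validation confusion counts give accuracy 0.996 and 125 misclassified", {
  tb <- counts_to_tables(tp = 7752, fp = 72, fn = 53, tn = 25166)
  cm <- confusion_matrix(tb$calls, tb$labels)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 33043L)
  m <- classification_metrics(cm)
  expect_equal(round(m$accuracy, 3), 0.996)
  expect_equal(m$n_misclassified, 125L)
  expect_equal(round(100 * m$n_misclassified / m$n, 2), 0.38)
})

test_that("external-validation confusion counts give accuracy 0.997 and 5 misclassified", {
  tb <- counts_to_tables(tp = 349, fp = 2, fn = 3, tn = 1118)
  m <- classification_metrics(confusion_matrix(tb$calls, tb$labels))
  expect_equal(m$n, 1472L)
  expect_equal(round(m$accuracy, 3), 0.997)
  expect_equal(m$n_misclassified, 5L)
  expect_equal(round(100 * m$n_misclassified / m$n, 2), 0.34)
})

test_that("metric formulas behave at the boundaries", {
  m <- classification_metrics(list(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 ppv = 1, npv = 1))
  # no positives at all: Se and PPV undefined, reported absent
  m <- classification_metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 1)
  # accuracy == 1 - (fp+fn)/total, algebraically, on random counts
  set.seed(9)
  for (i in 1:50) {
    cm <- as.list(setNames(rpois(4, 20), c("tp", "fp", "fn", "tn")))
    total <- do.call(sum, cm)
    if (total == 0) next
    m <- classification_metrics(cm)
    expect_equal(m$accuracy, 1 - (cm$fp + cm$fn) / total)
  }
})

test_that("Ct MAE applies the Ct-40 convention to false positives", {
  labels <- data.frame(reaction_id = c("a", "b", "c"),
                       amplified = c(TRUE, TRUE, FALSE),
                       ct = c(20, 30, NA))
  calls <- data.frame(reaction_id = c("a", "b", "c"),
                      probability = c(0.99, 0.99, 0.8),
                      amplified = c(TRUE, TRUE, TRUE),
                      ct = c(20.4, 30.8, 37), flagged = FALSE)
  res <- ct_mae(calls, labels)
  expect_equal(res$mae, (0.4 + 0.8 + 3) / 3)  # == 1.4
  expect_equal(res$mae_excluding_misclassified, 0.6)
  expect_equal(res$n_false_positive, 1L)

  # perfect agreement
  calls$amplified <- labels$amplified
  calls$ct <- labels$ct
  expect_equal(ct_mae(calls, labels)$mae, 0)

  # nothing called amplified: absent values with a note
  calls$amplified <- FALSE
  calls$ct <- NA_real_
  res <- ct_mae(calls, labels)
  expect_true(is.na(res$mae))
  expect_match(res$note, "no reactions")
})

test_that("dropping false positives lowers the MAE when their errors dominate", {
  # The reduction is guaranteed whenever every false positive's |pred - 40|
  # exceeds the true positives' errors -- the regime a trained model is in,
  # where Ct residuals are fractions of a cycle and false positives sit
  # cycles away from 40.
  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    gold_amp <- runif(n) < 0.5
    gold_ct <- ifelse(gold_amp, runif(n, 5, 38), NA)
    pred_amp <- gold_amp
    pred_amp[sample(n, 2)] <- TRUE  # inject false positives
    pred_ct <- ifelse(gold_amp, pmin(gold_ct + runif(n, -0.5, 0.5), 40),
                      runif(n, 20, 38))  # FP error >= 2 cycles
    labels <- data.frame(reaction_id = sprintf("r%d", 1:n),
                         amplified = gold_amp, ct = gold_ct)
    calls <- data.frame(reaction_id = sprintf("r%d", 1:n),
                        probability = ifelse(pred_amp, 0.95, 0.05),
                        amplified = pred_amp,
                        ct = ifelse(pred_amp, pred_ct, NA), flagged = FALSE)
    res <- ct_mae(calls, labels)
    if (!is.na(res$mae_excluding_misclassified) && res$n_false_positive > 0) {
      expect_lte(res$mae_excluding_misclassified, res$mae)
    }
  }
  # and on actual model output
  fx <- small_fit()
  res <- ct_mae(fx$calls, labels_of(fx$test))
  expect_lte(res$mae_excluding_misclassified, res$mae)
})

test_that("the symmetric MAE option adds missed amplifications at Ct 40", {
  labels <- data.frame(reaction_id = c("a", "b"),
                       amplified = c(TRUE, TRUE), ct = c(20, 35))
  calls <- data.frame(reaction_id = c("a", "b"),
                      probability = c(0.99, 0.2),
                      amplified = c(TRUE, FALSE), ct = c(21, NA),
                      flagged = FALSE)
  expect_equal(ct_mae(calls, labels)$mae, 1)
  res <- ct_mae(calls, labels, include_false_negatives = TRUE)
  expect_equal(res$mae, (1 + 5) / 2)
})

test_that("analyst comparison ranks by ascending accuracy, MAE breaking ties", {
  n <- 10
  gold_amp <- rep(c(TRUE, FALSE), each = 5)
  gold <- data.frame(reaction_id = sprintf("r%d", 1:n), amplified = gold_amp,
                     ct = ifelse(gold_amp, seq(20, 36, length.out = n), NA))
  perfect <- data.frame(reaction_id = gold$reaction_id, probability = NA_real_,
                        amplified = gold$amplified, ct = gold$ct,
                        flagged = FALSE)
  oneoff <- perfect
  oneoff$amplified[1] <- FALSE
  oneoff$ct[1] <- NA
  out <- compare_analysts(list(good = perfect, sloppy = oneoff), gold)
  expect_equal(out$analyst, c("sloppy", "good"))
  expect_equal(out$accuracy, c(0.9, 1))
  expect_equal(out$mae[out$analyst == "good"], 0)

  # single perfect analyst plus the automated row
  out <- compare_analysts(list(solo = perfect), gold, automated = oneoff)
  expect_equal(out$analyst, c("Automated Analysis", "solo"))

  # missing reactions are reported
  short <- perfect[-3, ]
  expect_error(compare_analysts(list(short = short), gold), "short.*r3")
})

test_that("injected analyst error rates are recovered in the ranking", {
  sim <- simulate_dataset(sim_config(n_reactions = 1500, seed = 61))
  gold <- sim$labels
  rates <- c(A = 0, B = 0.0125, C = 0.025, D = 0.0375, E = 0.05)
  set.seed(62)
  analysts <- lapply(rates, function(r) {
    calls <- data.frame(reaction_id = gold$reaction_id, probability = NA_real_,
                        amplified = gold$amplified,
                        ct = gold$ct, flagged = FALSE)
    flip <- which(runif(nrow(gold)) < r)
    calls$amplified[flip] <- !calls$amplified[flip]
    calls$ct[flip] <- ifelse(calls$amplified[flip], 30, NA)
    calls
  })
  out <- compare_analysts(analysts, gold)
  # ascending accuracy == descending injected error rate
  expect_equal(out$analyst, c("E", "D", "C", "B", "A"))
})

test_that("evaluation reports cross-tabulate flags with misclassification", {
  tb <- counts_to_tables(tp = 5, fp = 2, fn = 1, tn = 12)
  tb$calls$flagged <- c(rep(FALSE, 5), TRUE, TRUE, TRUE, rep(FALSE, 12))
  rep <- evaluate_calls(tb$calls, tb$labels)
  expect_equal(rep$n_misclassified, 3L)
  expect_equal(rep$n_flagged_misclassified, 3L)
  expect_equal(rep$n_flagged_correct, 0L)
  expect_equal(rep$flagged_rate_misclassified, 1)
  expect_equal(rep$flagged_rate_correct, 0)
})
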
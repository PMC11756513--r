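test_that("call rules: strict >0.5 cutoff, closed flag interval, conditional Ct", {
  p <- c(0.5, 0.95, 0.30, 0.0999, 0.1, 0.9, 0.9001, 0.500001)
  ct <- rep(25, length(p))
  calls <- call_records(sprintf("r%d", seq_along(p)), p, ct)
  # exactly 0.5 is a negative call, but inside the flag interval
  expect_false(calls$amplified[1]); expect_true(calls$flagged[1])
  expect_true(is.na(calls$ct[1]))
  # 0.95: confident positive
  expect_true(calls$amplified[2]); expect_false(calls$flagged[2])
  expect_equal(calls$ct[2], 25)
  # 0.30: flagged negative, no Ct
  expect_false(calls$amplified[3]); expect_true(calls$flagged[3])
  expect_true(is.na(calls$ct[3]))
  # flag endpoints are inclusive
  expect_equal(calls$flagged, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_true(calls$amplified[8])
  expect_error(call_records("a", 1.2, 3), "probabilities")
})

test_that("predictions carry a Ct exactly when called amplified", {
  fx <- small_fit()
  calls <- fx$calls
  expect_equal(nrow(calls), nrow(fx$test$x))
  expect_identical(calls$amplified, calls$probability > 0.5)
  expect_identical(is.na(calls$ct), !calls$amplified)
  expect_identical(calls$flagged,
                   calls$probability >= 0.1 & calls$probability <= 0.9)
})

test_that("the regressor trains only on gold-amplified rows", {
  fx <- small_fit()
  expect_equal(fx$model$meta$n_amplified, sum(fx$train$amplified))
  expect_equal(fx$model$meta$n_train, nrow(fx$train$x))
  expect_lt(fx$model$meta$n_amplified, fx$model$meta$n_train)
})

test_that("an all-negative training set cannot fit the Ct regressor", {
  sim <- simulate_dataset(sim_config(n_reactions = 60, prevalence = 0,
                                     seed = 6))
  ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
  expect_error(suppressWarnings(tac_fit(ds)), "regressor cannot be trained")
})

test_that("prediction rejects a cycle-count mismatch", {
  fx <- small_fit()
  expect_error(predict(fx$model, fx$test$x[, 1:39]), "40 cycles.*39")
})

test_that("fitting is deterministic for fixed data, params and seed", {
  sim <- simulate_dataset(sim_config(n_reactions = 400, seed = 55))
  ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
  params <- tac_default_params()
  params$classifier$n_rounds <- 40L
  params$regressor$n_rounds <- 60L
  m1 <- tac_fit(ds, params$classifier, params$regressor, seed = 9)
  m2 <- tac_fit(ds, params$classifier, params$regressor, seed = 9)
  expect_identical(predict(m1, ds)$probability, predict(m2, ds)$probability)
  expect_identical(predict(m1, ds)$ct, predict(m2, ds)$ct)
})

test_that("the default tuning grid enumerates 2,916 candidate settings", {
  g <- tac_grid()
  expect_equal(nrow(g), 4 * 9 * 3 * 3 * 3 * 3)
  expect_equal(nrow(unique(g)), nrow(g))
})

test_that("tuning a singleton grid returns that point, reproducibly", {
  sim <- simulate_dataset(sim_config(n_reactions = 400, seed = 77))
  ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
  g <- tac_grid(eta = 0.3, max_depth = 4, min_child_weight = 1,
                subsample = 1, gamma = 0, colsample_bytree = 1)
  t1 <- tune_tac(ds, g, g, nfolds = 3, seed = 12, max_rounds = 40,
                 patience = 5)
  expect_equal(t1$classifier$eta, 0.3)
  expect_equal(t1$classifier$max_depth, 4)
  expect_gte(t1$classifier$n_rounds, 1L)
  t2 <- tune_tac(ds, g, g, nfolds = 3, seed = 12, max_rounds = 40,
                 patience = 5)
  expect_identical(t1$classifier, t2$classifier)
  expect_identical(t1$regressor, t2$regressor)
})

test_that("tuning picks the better of two grid points on clean data", {
  sim <- simulate_dataset(sim_config(n_reactions = 600, seed = 88))
  ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
  # a deliberately crippled point (one stump, heavy regularization) vs a
  # reasonable one
  g <- rbind(tac_grid(eta = 0.001, max_depth = 1, min_child_weight = 100,
                      subsample = 0.5, gamma = 0.2, colsample_bytree = 0.5),
             tac_grid(eta = 0.3, max_depth = 5, min_child_weight = 1,
                      subsample = 1, gamma = 0, colsample_bytree = 1))
  tuned <- tune_tac(ds, g, g, nfolds = 3, seed = 2, max_rounds = 40,
                    patience = 10)
  expect_equal(tuned$classifier$max_depth, 5)
  expect_equal(tuned$regressor$max_depth, 5)
})

test_that("single-class training data is refused for cross-validation", {
  sim <- simulate_dataset(sim_config(n_reactions = 60, prevalence = 0,
                                     seed = 14))
  ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
  expect_error(tune_tac(ds, tac_grid(eta = 0.3), tac_grid(eta = 0.3)),
               "single class")
})

test_that("a saved model bundle restores to identical predictions", {
  fx <- small_fit()
  dir <- tempfile()
  save_tac_model(fx$model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_tac_model(dir)
  expect_equal(back$cycles, 40L)
  expect_equal(back$threshold, 0.5)
  expect_equal(back$flag_interval, c(0.1, 0.9))
  expect_identical(predict(back, fx$test)$probability,
                   fx$calls$probability)
})

test_that("held-out performance degrades as reporter noise grows", {
  acc <- vapply(c(0.05, 0.2, 0.5), function(sigma) {
    sim <- simulate_dataset(sim_config(n_reactions = 2000, noise_sd = sigma,
                                       seed = 321))
    ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
    parts <- split_dataset(ds, 0.8, seed = 321)
    params <- tac_default_params()
    params$classifier$n_rounds <- 80L
    params$regressor$n_rounds <- 120L
    model <- tac_fit(parts$train, params$classifier, params$regressor,
                     seed = 321)
    calls <- predict(model, parts$test)
    classification_metrics(confusion_matrix(calls, labels_of(parts$test)))$accuracy
  }, numeric(1))
  expect_gte(acc[1], acc[2])
  expect_gte(acc[2], acc[3])
})
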
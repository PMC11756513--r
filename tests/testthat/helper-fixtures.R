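# Builders shared across test files. Everything is generated in code; no
# stored fixtures.

make_trace <- function(reporter, rox, id = "r1", dye = "FAM",
                       well = NA_character_) {
  structure(list(reaction_id = id, dye = dye, target = NA_character_,
                 well = well, reporter = reporter, rox = rox),
            class = "tac_trace")
}

# Long-CSV text for a set of traces, written to a temp file.
write_trace_csv <- function(traces, path = tempfile(fileext = ".csv")) {
  write_curves(traces, path)
  path
}

random_calls <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n)
  ct <- ifelse(p > 0.5, runif(n, 5, 40), NA_real_)
  call_records(sprintf("r%03d", seq_len(n)), p, ct)
}

# One small fitted model shared by model/pipeline tests (built once).
fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (is.null(fixture_env$fit)) {
    cfg <- sim_config(n_reactions = 1500, seed = 11)
    sim <- simulate_dataset(cfg)
    ds <- assemble_dataset(normalize_batch(sim$traces), sim$labels)
    parts <- split_dataset(ds, 0.8, seed = 11)
    params <- tac_default_params()
    params$classifier$n_rounds <- 80L
    params$regressor$n_rounds <- 150L
    model <- tac_fit(parts$train, params$classifier, params$regressor,
                     seed = 11)
    fixture_env$fit <- list(sim = sim, dataset = ds, train = parts$train,
                            test = parts$test, model = model,
                            calls = predict(model, parts$test))
  }
  fixture_env$fit
}

labels_of <- function(ds) {
  data.frame(reaction_id = ds$reaction_id, amplified = ds$amplified,
             ct = ds$ct, stringsAsFactors = FALSE)
}
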
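#' Configuration for the synthetic amplification-curve simulator
#'
#' The simulator emulates the structure of a TaqMan Array Card run: 40-cycle
#' traces in FAM and VIC channels with a ROX reference channel, a share of
#' duplexed wells, roughly one quarter of reactions amplifying, negative
#' curves with linear baseline drift, and late amplifiers whose exponential
#' growth starts near cycle 40. An amplifying reaction follows a logistic
#' (sigmoid) rise of amplitude `A` (plateau, in ROX-standardized units),
#' midpoint `m` (cycle) and slope `k` (per cycle) on top of the baseline;
#' a fraction of amplified curves additionally shows a post-plateau "hook"
#' decay. The ground-truth Ct is the cycle at which the noiseless logistic
#' component reaches fraction `crossing_fraction` of its plateau, which has
#' the closed form implemented in [closed_form_ct()].
#'
#' @param n_reactions Number of reactions to simulate.
#' @param prevalence Fraction of reactions drawn as amplifying (default
#'   0.25, the amplification rate typical of enteric TAC panels).
#' @param cycles Cycles per run (default 40).
#' @param amplitude_range,midpoint_range,slope_range Uniform draw ranges for
#'   the logistic amplitude `A`, midpoint `m` and slope `k`. The default
#'   midpoint range extends past the last cycle so some draws amplify too
#'   late to be called, and late amplifiers with Ct in the high 30s occur.
#' @param baseline_range,drift_range Uniform ranges for the baseline
#'   intercept and linear per-cycle drift (standardized units).
#' @param noise_sd Gaussian noise SD on the reporter signal (standardized
#'   units; default 0.05).
#' @param rox_mean,rox_sd Mean and SD of the ROX channel (instrument units).
#' @param hook_prob,hook_decay Probability that an amplified curve hooks, and
#'   the post-plateau linear decay rate (fraction of amplitude per cycle).
#' @param crossing_fraction Plateau fraction defining the ground-truth Ct
#'   (default 0.05).
#' @param duplex_fraction Fraction of reactions belonging to duplexed wells
#'   (two dyes, one well; default 0.126).
#' @param vic_fraction Probability that a singleplex reaction uses VIC
#'   (default 0.298).
#' @param seed Integer seed; the same configuration and seed always yield an
#'   identical dataset.
#' @return A `sim_config` list.
#' @seealso [simulate_dataset()], [closed_form_ct()]
#' @export
sim_config <- function(n_reactions = 1000L,
                       prevalence = 0.25,
                       cycles = 40L,
                       amplitude_range = c(1.5, 6),
                       midpoint_range = c(12, 42),
                       slope_range = c(0.4, 1.2),
                       baseline_range = c(0.8, 1.6),
                       drift_range = c(-0.005, 0.01),
                       noise_sd = 0.05,
                       rox_mean = 1.5,
                       rox_sd = 0.02,
                       hook_prob = 0.1,
                       hook_decay = 0.02,
                       crossing_fraction = 0.05,
                       duplex_fraction = 0.126,
                       vic_fraction = 0.298,
                       seed = NULL) {
  stopifnot(n_reactions >= 1L, cycles >= 2L)
  if (prevalence < 0 || prevalence > 1) {
    stop("prevalence must be in [0, 1]", call. = FALSE)
  }
  if (crossing_fraction <= 0 || crossing_fraction >= 1) {
    stop("crossing_fraction must be in (0, 1)", call. = FALSE)
  }
  if (noise_sd < 0 || rox_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (any(slope_range <= 0)) {
    stop("slope_range must be strictly positive", call. = FALSE)
  }
  structure(
    list(n_reactions = as.integer(n_reactions), prevalence = prevalence,
         cycles = as.integer(cycles),
         amplitude_range = amplitude_range, midpoint_range = midpoint_range,
         slope_range = slope_range, baseline_range = baseline_range,
         drift_range = drift_range, noise_sd = noise_sd,
         rox_mean = rox_mean, rox_sd = rox_sd,
         hook_prob = hook_prob, hook_decay = hook_decay,
         crossing_fraction = crossing_fraction,
         duplex_fraction = duplex_fraction, vic_fraction = vic_fraction,
         seed = seed),
    class = "sim_config"
  )
}

#' Closed-form ground-truth cycle threshold of a noiseless logistic curve
#'
#' For the logistic amplification component `A / (1 + exp(-k (c - m)))`, the
#' cycle at which the curve reaches fraction `q` of its plateau `A` is
#' `m + log(q / (1 - q)) / k`, independent of `A`. This defines the
#' simulator's ground-truth Ct.
#'
#' @param m Logistic midpoint (cycle).
#' @param k Logistic slope (> 0, per cycle).
#' @param q Plateau fraction in (0, 1).
#' @return The fractional crossing cycle (vectorized over `m` and `k`).
#' @examples
#' closed_form_ct(25, 1, 0.5)   # the midpoint itself
#' closed_form_ct(25, 1, 0.05)  # 25 + log(1/19) = 22.0556
#' @export
closed_form_ct <- function(m, k, q = 0.05) {
  if (any(k <= 0)) stop("slope k must be > 0", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)", call. = FALSE)
  m + log(q / (1 - q)) / k
}

#' Simulate a single reaction
#'
#' Draws latent curve parameters from the configuration's distributions using
#' the current RNG state and renders one fluorescence trace plus its
#' gold-standard label. A reaction is labelled amplified exactly when it was
#' drawn as amplifying and its noiseless crossing cycle (see
#' [closed_form_ct()]) falls within the run.
#'
#' @param config A [sim_config()].
#' @param reaction_id,dye,well,target Identifiers for the generated trace.
#' @return A list with `trace` (fluorescence trace), `label` (one-row data
#'   frame with `reaction_id`, `amplified`, `ct`) and `params` (one-row data
#'   frame of latent parameters).
#' @export
simulate_reaction <- function(config, reaction_id = "r1", dye = "FAM",
                              well = NA_character_, target = NA_character_) {
  C <- config$cycles
  amplifying <- stats::runif(1) < config$prevalence
  A <- if (amplifying) stats::runif(1, config$amplitude_range[1], config$amplitude_range[2]) else 0
  m <- stats::runif(1, config$midpoint_range[1], config$midpoint_range[2])
  k <- stats::runif(1, config$slope_range[1], config$slope_range[2])
  B0 <- stats::runif(1, config$baseline_range[1], config$baseline_range[2])
  B1 <- stats::runif(1, config$drift_range[1], config$drift_range[2])
  hooked <- amplifying && stats::runif(1) < config$hook_prob

  cyc <- seq_len(C)
  amp <- A / (1 + exp(-k * (cyc - m)))
  if (hooked) {
    plateau_start <- m + 4 / k  # logistic ~98% of plateau
    amp <- pmax(amp - config$hook_decay * A * pmax(cyc - plateau_start, 0), 0)
  }
  signal <- B0 + B1 * cyc + amp + stats::rnorm(C, 0, config$noise_sd)
  reporter <- pmax(config$rox_mean * signal, 1e-6)
  rox <- pmax(config$rox_mean + stats::rnorm(C, 0, config$rox_sd),
              0.05 * config$rox_mean)

  ct0 <- if (amplifying) closed_form_ct(m, k, config$crossing_fraction) else NA_real_
  amplified <- amplifying && !is.na(ct0) && ct0 <= C && ct0 > 0
  list(
    trace = new_trace(reaction_id = reaction_id, dye = dye,
                      target = target, well = well,
                      reporter = reporter, rox = rox),
    label = data.frame(reaction_id = reaction_id, amplified = amplified,
                       ct = if (amplified) ct0 else NA_real_,
                       stringsAsFactors = FALSE),
    params = data.frame(reaction_id = reaction_id, amplifying = amplifying,
                        A = A, m = m, k = k, B0 = B0, B1 = B1,
                        hooked = hooked, stringsAsFactors = FALSE)
  )
}

#' Simulate a dataset of reactions with known ground truth
#'
#' Generates `config$n_reactions` reactions, a share of which sit in duplexed
#' wells (a FAM and a VIC reaction sharing one well). The output is directly
#' writable with [write_curves()] and [write_labels()].
#'
#' @param config A [sim_config()]. If `config$seed` is set the dataset is a
#'   deterministic function of the configuration.
#' @return An object of class `tac_sim`: a list with `traces` (list of
#'   fluorescence traces), `labels` (data frame), `params` (data frame of
#'   latent parameters) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    n <- config$n_reactions
    n_duplex_wells <- floor(config$duplex_fraction * n / 2)
    n_single <- n - 2L * n_duplex_wells
    ids <- sprintf("r%05d", seq_len(n))
    dye <- character(n)
    well <- character(n)
    target <- character(n)
    i <- 1L
    w <- 1L
    if (n_duplex_wells > 0L) {
      for (d in seq_len(n_duplex_wells)) {
        well_id <- sprintf("w%04d", w); w <- w + 1L
        dye[i] <- "FAM"; well[i] <- well_id; target[i] <- "targetA"
        dye[i + 1L] <- "VIC"; well[i + 1L] <- well_id; target[i + 1L] <- "targetB"
        i <- i + 2L
      }
    }
    if (n_single > 0L) {
      vic <- stats::runif(n_single) < config$vic_fraction
      for (s in seq_len(n_single)) {
        well[i] <- sprintf("w%04d", w); w <- w + 1L
        dye[i] <- if (vic[s]) "VIC" else "FAM"
        target[i] <- "targetA"
        i <- i + 1L
      }
    }
    sims <- vector("list", n)
    for (j in seq_len(n)) {
      sims[[j]] <- simulate_reaction(config, reaction_id = ids[j],
                                     dye = dye[j], well = well[j],
                                     target = target[j])
    }
    structure(
      list(traces = lapply(sims, `[[`, "trace"),
           labels = do.call(rbind, lapply(sims, `[[`, "label")),
           params = do.call(rbind, lapply(sims, `[[`, "params")),
           config = config),
      class = "tac_sim"
    )
  }
  if (!is.null(config$seed)) with_seed(config$seed, run()) else run()
}

#' @export
print.tac_sim <- function(x, ...) {
  cat(sprintf("<tac_sim> %d reactions, %d cycles, %d amplified (%.1f%%)\n",
              length(x$traces), x$config$cycles, sum(x$labels$amplified),
              100 * mean(x$labels$amplified)))
  invisible(x)
}

#' Fractional cycle at which a curve first crosses a threshold
#'
#' Scans the per-cycle values (cycles 1..C) for the first crossing of
#' `threshold` from below and interpolates between the bracketing cycles.
#' With `method = "linear"` the interpolation is on the values themselves;
#' with `method = "log"` it is on `log(values - baseline)`, which is the
#' natural scale during the exponential growth phase (log-fluorescence is
#' close to linear in cycle there) and therefore locates the crossing of an
#' amplification curve much more precisely. Used as the geometric
#' counterpart of [closed_form_ct()] when checking the simulator's ground
#' truth.
#'
#' @param values Numeric per-cycle values.
#' @param threshold Threshold level.
#' @param method `"linear"` or `"log"`.
#' @param baseline Baseline subtracted before taking logs (default 1, the
#'   minimum of a normalized trace).
#' @return The fractional crossing cycle, or `NA` if the curve never reaches
#'   the threshold (or, for `method = "log"`, if the bracketing value does
#'   not exceed the baseline).
#' @export
threshold_crossing <- function(values, threshold,
                               method = c("linear", "log"), baseline = 1) {
  method <- match.arg(method)
  above <- values >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(1)
  if (method == "linear") {
    (i - 1) + (threshold - values[i - 1L]) / (values[i] - values[i - 1L])
  } else {
    u <- values - baseline
    if (u[i - 1L] <= 0 || threshold <= baseline) return(NA_real_)
    (i - 1) + (log(threshold - baseline) - log(u[i - 1L])) /
      (log(u[i]) - log(u[i - 1L]))
  }
}

#' Evaluate an expression under a temporary RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
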
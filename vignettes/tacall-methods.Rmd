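---
title: "Methods: automated amplification calling for arrayed qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated amplification calling for arrayed qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `tacall`, the assumptions of the
synthetic curve simulator used to test it, and the numerical and design
choices a maintainer would want spelled out.

## The calling problem

An arrayed qPCR run (e.g., a TaqMan Array Card) yields, per reaction, 40
per-cycle fluorescence readings of a reporter dye (FAM or VIC) and of the
ROX passive reference. The post-run question is binary-plus-quantitative:
did target amplification occur, and if so at what (fractional) cycle
threshold Ct did the signal rise above background? Manual analysis adjusts
baselines well-by-well and is slow and analyst-dependent; `tacall` replaces
it with a supervised pipeline trained against expert manual calls.

## Normalization

Two deterministic steps map raw traces to model features:

1. `standardize()`: $F_{stand}(c) = \mathrm{reporter}(c) / \mathrm{ROX}(c)$
   per cycle $c$. ROX is a passive dye, so the ratio cancels well-to-well
   optical path and volume differences; scaling reporter and ROX jointly by
   any $k > 0$ leaves the result unchanged (property-tested).
2. `normalize_fluorescence()`: $F_{norm}(c) = F_{stand}(c) - (F_{min} - 1)$,
   with $F_{min}$ the minimum standardized value *of that reaction's own
   cycles* — no cross-well pooling. Every normalized curve therefore has
   minimum exactly 1 (tested to $10^{-12}$).

Nothing else is done to the curves: no smoothing, no baseline regression,
no curve-shape feature extraction. The 40 normalized values are the feature
vector, which keeps the pipeline computationally trivial and avoids
abstraction layers between the data and the models.

## The two-stage model

Both stages are gradient-boosted tree ensembles (XGBoost):

- **Stage 1, classifier** (`binary:logistic`): trained on all reactions,
  label = gold-standard amplified. A reaction is called amplified only when
  the predicted probability *strictly* exceeds 0.5; exactly 0.5 is a
  negative call. The strict inequality is deliberate — the decision rule is
  "greater than", and the boundary case should fall on the conservative
  (negative) side.
- **Stage 2, Ct regressor** (`reg:squarederror`): trained *only* on
  gold-standard amplified reactions, and applied at prediction time only to
  reactions stage 1 called amplified. Reactions called negative carry
  `ct = NA`, never a sentinel.
- **Review flags**: a call with probability in the closed interval
  $[0.1, 0.9]$ is flagged for manual review. Endpoints are included — the
  conservative (more-flagging) reading of "between". The flag exists
  because misclassified curves concentrate at intermediate probabilities;
  the test suite checks that the flagged rate among misclassified calls
  exceeds that among correct calls.

### Hyperparameters

`tac_grid()` spans eta {0.1, 0.3, 0.5, 0.7}, max_depth 10–18,
min_child_weight {1, 5, 10}, subsample {0.5, 0.7, 1}, gamma {0, 0.1, 0.2}
and colsample_bytree {0.5, 0.7, 1} — 2,916 candidates per stage.
`tune_tac()` scores each by 5-fold cross-validation: mean validation
log-loss for the classifier, mean validation MAE (the reported regression
metric) for the regressor, the regressor's CV running on the amplified
subset only. `tac_default_params()` ships the grid points selected by this
search on a large archived TAC dataset (classifier: eta 0.5, depth 13;
regressor: eta 0.1, depth 16, min_child_weight 10); on data with other
noise structure — including this package's synthetic data — a fresh search
may select different points, so treat the presets as provenance, not as
universally optimal.

### Boosting rounds and probability calibration

The round count is not a grid axis. Both `tune_tac()` and the default path
of `tac_fit()` select it by early stopping within cross-validation
(patience 20, cap 500). This matters beyond fit quality: boosting a
log-loss model far past its CV optimum drives predicted probabilities
towards 0/1. Accuracy is unharmed, but the flag mechanism lives entirely in
the intermediate-probability band, so a saturated classifier flags nothing
— including its own mistakes. Fixing `n_rounds` explicitly skips the
selection (the test suite does this where speed matters and calibration
does not).

Reproducibility: with `nthread = 1` (the default) and a fixed seed,
fitting, prediction and the full `run_train_eval()` pipeline are
deterministic; reruns produce byte-identical calls and reports. Multiple
threads are opt-in and may not be bit-reproducible.

## Evaluation conventions

- Positive class is amplification everywhere: Se = tp/(tp+fn),
  Sp = tn/(tn+fp), PPV = tp/(tp+fp), NPV = tn/(tn+fn). A metric with a zero
  denominator is reported as `NA`, not 0.
- **Ct MAE population**: the mean absolute Ct error is taken over reactions
  the *model* called amplified. For false positives the gold Ct is taken as
  40 (the run length); the "excluding misclassified" variant drops them.
  False negatives are not in the default MAE population — the substitution
  rule is defined for false positives, and the excluding variant removes
  exactly those — but `include_false_negatives = TRUE` provides a symmetric
  mode (missed amplifications enter with predicted Ct 40) for users who
  want one error number covering all gold-amplified reactions.
  Note the excluding variant is *not* guaranteed to be smaller than the
  full MAE in pathological cases (a false positive predicted at Ct 39.9
  contributes error 0.1, below a typical true-positive residual); it is
  smaller whenever false-positive errors dominate true-positive residuals,
  which is the regime a trained model operates in.
- `compare_analysts()` ranks analyst call tables (plus optionally the
  automated model) by ascending accuracy, ties broken by lower MAE first —
  the layout of a multi-laboratory EQA comparison table.
- Display rounding is 3 decimals; computations are never rounded.

## The synthetic data generator

`simulate_dataset()` exists so the pipeline can be trained and scored with
a known ground truth. Each reaction draws:

| parameter | default | meaning |
|---|---|---|
| amplified? | Bernoulli(0.25) | ~one quarter of arrayed enteric-panel reactions amplify |
| $A$ | U[1.5, 6] | logistic plateau, in ROX-standardized units |
| $m$ | U[12, 42] cycles | logistic midpoint; extends past cycle 40 so late amplifiers and just-missed curves occur |
| $k$ | U[0.4, 1.2] /cycle | logistic slope |
| $B_0$ | U[0.8, 1.6] | baseline intercept (standardized units) |
| $B_1$ | U[−0.005, 0.01] /cycle | linear baseline drift, also on negatives |
| $\sigma$ | 0.05 | Gaussian reporter noise SD (standardized units) |
| ROX | mean 1.5, SD 0.02 | reference channel, clipped positive |
| hook | prob 0.1, decay 0.02·A/cycle | post-plateau fluorescence decline |

The reporter is `rox_mean · (B0 + B1·c + amp(c) + ε)`, so standardization
approximately recovers the latent signal. A duplex fraction (default 12.6%)
of reactions is emitted as FAM/VIC pairs sharing a well; singleplex dye is
VIC with probability 0.298. These defaults were fixed once, as plausible
values for arrayed enteric-panel data, before any model tuning; they are
deliberately not adjusted to make tests easier or harder.

**Ground-truth Ct.** Real gold standards come from human
baseline-threshold calling with no closed form. The simulator instead
*defines* truth geometrically: the cycle where the noiseless logistic
component reaches fraction $q$ (default 0.05) of its plateau,
$Ct = m + \ln(q/(1-q))/k$ (`closed_form_ct()`). A reaction is labelled
amplified exactly when it was drawn as amplifying and this crossing falls
within the run's 40 cycles — so an amplifying draw with a late midpoint is
a *negative* label with a visible partial rise, the hardest negative class.

**Oracle equivalence check.** The tests confirm the geometry: on noiseless,
drift-free curves, the interpolated threshold crossing of the normalized
trace at level $1 + qA$ agrees with the closed form to ≤ 0.1 cycles over
1,000+ random draws. Two numerical subtleties shape this check. First,
interpolation is done in log space (`threshold_crossing(..., method =
"log")`): the growth phase is exponential, so log-signal is nearly linear
in cycle, whereas *linear* interpolation of a convex exponential between
integer cycles has a systematic early bias that exceeds 0.1 cycles at the
steeper slopes in the simulator's support. Second, midpoints for this check
are drawn in [18, 42]: for very early midpoints the logistic tail is
already non-negligible at cycle 1, leaks into $F_{min}$, and shifts the
geometric crossing — a property of the normalization, not an error in
either computation.

**What the simulator does not emulate**: PCR efficiency chemistry,
inter-well spatial effects, instrument drift across cards, heavy-tailed or
correlated noise, and human labelling noise near the calling boundary. The
last point matters for interpreting test results: synthetic labels are a
deterministic function of latent parameters that are nearly recoverable
from the trace, so held-out accuracy on synthetic data (≈0.99+) sits above
what heterogeneous real data with imperfect gold standards yields, and
misclassifications concentrate almost exclusively in late amplifiers with
Ct just under 40. Passing the synthetic recovery tests demonstrates the
pipeline's mechanics — normalization, conditional two-stage structure,
thresholding, flagging — not field performance.

## Dataset handling

- `split_dataset()` assigns exactly `floor(fraction · N)` reactions to
  training (165,214 at 0.8 gives 132,171/33,043), uniformly at random by
  reaction. Splitting by reaction is the default; a `group` argument splits
  whole wells/cards instead for leakage-sensitive analyses, honoring group
  boundaries while targeting the same fraction.
- `amplified_subset()` retains exactly the gold-amplified rows (warning,
  not error, when empty; `tac_fit()` errors, since the regressor is then
  untrainable).
- Degenerate inputs fail loudly with the offending reaction named: missing
  or duplicated cycles, non-positive ROX, labels with a Ct on non-amplified
  rows, traces without labels, mixed cycle counts.

## Problem sizes used in the checks

The shipped tests train on datasets of 400–10,000 synthetic reactions; the
headline recovery check trains on 10,000 reactions at the conditions above
and evaluates on an independently simulated 20,000-reaction set. The large
held-out set is a statistical necessity, not a convenience: at ≈99.9%
synthetic accuracy a 2,000-reaction test set yields only one or two
misclassifications, making a comparison of flag rates between misclassified
and correct calls meaningless in a single run; 20,000 reactions put tens of
events behind each rate. The training size is kept at 10,000 so the fitted
model matches the documented study conditions.

## Known limitations

- The classifier's probabilities are used directly for flagging without a
  separate calibration step; early-stopped boosting keeps them usable, but
  they are not calibrated probabilities in the strict sense.
- The Ct regressor is trained on gold-amplified reactions only and is
  unreliable when the classifier is wrong — which is precisely why false
  positives are reported both inside and outside the MAE.
- Models are tied to the cycle count they were trained at (40 by default);
  applying a bundle to a run with a different cycle count is an error, not
  a resample.
- The simulator's Gaussian-noise assumption is a modelling floor, not a
  ceiling; heavier-tailed noise can be emulated by raising `noise_sd` but
  not by changing the noise family without extending `sim_config()`.
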
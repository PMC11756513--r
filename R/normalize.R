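#' Standardize reporter fluorescence against the ROX reference dye
#'
#' Divides the raw reporter (FAM or VIC) value by the ROX passive-reference
#' value at the corresponding cycle. ROX is constant in an ideal well, so the
#' ratio removes well-to-well optical variation; scaling reporter and ROX by
#' a common factor leaves the result unchanged.
#'
#' @param trace A fluorescence trace (see [read_curves()]), or any list with
#'   numeric `reporter` and `rox` of equal length.
#' @return Numeric vector of standardized fluorescence values, one per cycle.
#' @export
standardize <- function(trace) {
  reporter <- trace$reporter
  rox <- trace$rox
  if (length(reporter) != length(rox)) {
    stop("reporter and rox differ in length", call. = FALSE)
  }
  bad <- which(!is.finite(rox) | rox <= 0)
  if (length(bad)) {
    stop(sprintf("reaction '%s': non-positive ROX at cycle(s) %s",
                 if (is.null(trace$reaction_id)) "?" else trace$reaction_id,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  reporter / rox
}

#' Shift-normalize a standardized fluorescence curve
#'
#' Subtracts `min(x) - 1` from every cycle, where the minimum is taken across
#' that reaction's own cycles, so the normalized curve has minimum exactly 1.
#' Together with [standardize()] this produces the model feature vector; no
#' smoothing, baseline regression or outlier rejection is applied.
#'
#' @param x Numeric vector of standardized fluorescence values.
#' @return Numeric vector of the same length with minimum exactly 1.
#' @export
normalize_fluorescence <- function(x) {
  if (length(x) == 0L) stop("empty fluorescence vector", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite standardized value", call. = FALSE)
  x - (min(x) - 1)
}

#' Normalize a batch of traces
#'
#' Applies [standardize()] then [normalize_fluorescence()] to each trace,
#' preserving input order.
#'
#' @param traces List of fluorescence traces.
#' @return A list of normalized traces; each element is a list with
#'   `reaction_id`, `dye` and `values` (numeric, minimum exactly 1).
#' @export
normalize_batch <- function(traces) {
  lapply(traces, function(tr) {
    values <- normalize_fluorescence(standardize(tr))
    structure(
      list(reaction_id = tr$reaction_id, dye = tr$dye, values = values),
      class = "tac_norm"
    )
  })
}

#' @export
print.tac_norm <- function(x, ...) {
  cat(sprintf("<tac_norm> %s  dye=%s  cycles=%d  max=%.3f\n",
              x$reaction_id, x$dye, length(x$values), max(x$values)))
  invisible(x)
}
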
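#' Read per-cycle fluorescence traces from a long CSV
#'
#' The canonical trace format is a long CSV with header
#' `reaction_id,well,target,dye,cycle,reporter,rox`: one row per cycle per
#' dye, cycles numbered 1..C. A duplexed well (FAM and VIC read against two
#' targets in the same physical well) appears as two reactions sharing a
#' `well` value.
#'
#' @param path Path to a traces CSV.
#' @param expected_cycles Number of cycles every reaction must cover
#'   (default 40, the standard TaqMan Array Card run length).
#' @return A list of fluorescence traces. Each trace is a list with elements
#'   `reaction_id`, `dye` (`"FAM"` or `"VIC"`), `target`, `well`,
#'   `reporter` (numeric, length `expected_cycles`) and `rox` (numeric,
#'   strictly positive, same length).
#' @seealso [write_curves()], [normalize_batch()]
#' @export
read_curves <- function(path, expected_cycles = 40L) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("reaction_id", "dye", "cycle", "reporter", "rox")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trace file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$well)) df$well <- NA_character_
  if (is.null(df$target)) df$target <- NA_character_
  if (nrow(df) == 0L) return(list())

  key <- paste(df$reaction_id, df$dye, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    block <- df[idx, , drop = FALSE]
    block <- block[order(block$cycle), , drop = FALSE]
    rid <- block$reaction_id[[1L]]
    if (anyDuplicated(block$cycle)) {
      dup <- unique(block$cycle[duplicated(block$cycle)])
      stop(sprintf("reaction '%s' (%s): duplicate cycle row(s) %s",
                   rid, block$dye[[1L]], paste(dup, collapse = ", ")),
           call. = FALSE)
    }
    absent <- setdiff(seq_len(expected_cycles), block$cycle)
    if (length(absent) || nrow(block) != expected_cycles) {
      stop(sprintf("reaction '%s' (%s): expected cycles 1..%d, missing %s",
                   rid, block$dye[[1L]], expected_cycles,
                   if (length(absent)) paste(absent, collapse = ", ")
                   else "none (extra cycles present)"),
           call. = FALSE)
    }
    new_trace(
      reaction_id = rid,
      dye = block$dye[[1L]],
      target = block$target[[1L]],
      well = block$well[[1L]],
      reporter = as.numeric(block$reporter),
      rox = as.numeric(block$rox)
    )
  })
}

#' @noRd
new_trace <- function(reaction_id, dye, reporter, rox,
                      target = NA_character_, well = NA_character_) {
  if (length(reporter) != length(rox)) {
    stop(sprintf("reaction '%s': reporter and rox differ in length (%d vs %d)",
                 reaction_id, length(reporter), length(rox)), call. = FALSE)
  }
  if (length(reporter) < 2L) {
    stop(sprintf("reaction '%s': needs at least 2 cycles", reaction_id),
         call. = FALSE)
  }
  if (any(!is.finite(rox)) || any(rox <= 0)) {
    bad <- which(!is.finite(rox) | rox <= 0)
    stop(sprintf("reaction '%s': non-positive ROX at cycle(s) %s",
                 reaction_id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(reaction_id = as.character(reaction_id), dye = as.character(dye),
         target = target, well = well,
         reporter = reporter, rox = rox),
    class = "tac_trace"
  )
}

#' @export
print.tac_trace <- function(x, ...) {
  cat(sprintf("<tac_trace> %s  dye=%s  well=%s  cycles=%d\n",
              x$reaction_id, x$dye,
              ifelse(is.na(x$well), "-", x$well), length(x$reporter)))
  invisible(x)
}

#' Write fluorescence traces to the canonical long CSV
#'
#' @param traces A list of traces as returned by [read_curves()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    C <- length(tr$reporter)
    data.frame(
      reaction_id = tr$reaction_id,
      well = if (is.null(tr$well)) NA_character_ else tr$well,
      target = if (is.null(tr$target)) NA_character_ else tr$target,
      dye = tr$dye,
      cycle = seq_len(C),
      reporter = tr$reporter,
      rox = tr$rox,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), well = character(),
               target = character(), dye = character(), cycle = integer(),
               reporter = numeric(), rox = numeric())
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read gold-standard amplification labels
#'
#' A labels CSV has columns `reaction_id,amplified,ct`. `ct` must be present
#' exactly when `amplified` is true; non-amplified rows carry an empty `ct`
#' field (no sentinel value -- the Ct-40 convention for false positives is
#' applied only inside [ct_mae()]).
#'
#' @param path Path to a labels CSV.
#' @param max_ct Upper bound for valid Ct values (default 40, the run's cycle
#'   count).
#' @return A data frame with columns `reaction_id` (character), `amplified`
#'   (logical) and `ct` (numeric, `NA` where not amplified).
#' @export
read_labels <- function(path, max_ct = 40) {
  if (!file.exists(path)) {
    stop("label file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reaction_id = "character"))
  required <- c("reaction_id", "amplified", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("label file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  amp <- parse_logical(df$amplified, "amplified")
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- !amp & !is.na(ct)
  if (any(bad)) {
    stop("non-amplified label(s) carry a ct value: ",
         paste(df$reaction_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- amp & is.na(ct)
  if (any(bad)) {
    stop("amplified label(s) missing a ct value: ",
         paste(df$reaction_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(ct) & (ct <= 0 | ct > max_ct)
  if (any(bad)) {
    stop(sprintf("ct outside (0, %s] for reaction(s): %s", format(max_ct),
                 paste(df$reaction_id[bad], collapse = ", ")), call. = FALSE)
  }
  data.frame(reaction_id = df$reaction_id, amplified = amp, ct = ct,
             stringsAsFactors = FALSE)
}

#' Write gold-standard labels
#'
#' @param labels Data frame with `reaction_id`, `amplified`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- labels[, c("reaction_id", "amplified", "ct")]
  out$amplified <- ifelse(out$amplified, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write model call records
#'
#' A calls CSV has columns `reaction_id,probability,amplified,ct,flagged`.
#' `amplified` is true exactly when `probability > 0.5`; `ct` is present only
#' for amplified calls; `flagged` is true when the probability lies in the
#' manual-review interval (by default `[0.1, 0.9]`). Probabilities round-trip
#' through the file to at least six decimal places.
#'
#' @param calls Data frame of call records (as returned by
#'   [predict.tac_model()]).
#' @param path File path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` returns
#'   the call data frame.
#' @export
write_calls <- function(calls, path) {
  out <- calls[, c("reaction_id", "probability", "amplified", "ct", "flagged")]
  out$probability <- sprintf("%.9f", out$probability)
  out$ct <- ifelse(is.na(out$ct), "", sprintf("%.6f", out$ct))
  out$amplified <- ifelse(out$amplified, "true", "false")
  out$flagged <- ifelse(out$flagged, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) {
    stop("calls file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reaction_id = "character"))
  required <- c("reaction_id", "probability", "amplified", "ct", "flagged")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("calls file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    reaction_id = df$reaction_id,
    probability = as.numeric(df$probability),
    amplified = parse_logical(df$amplified, "amplified"),
    ct = suppressWarnings(as.numeric(df$ct)),
    flagged = parse_logical(df$flagged, "flagged"),
    stringsAsFactors = FALSE
  )
  bad <- !out$amplified & !is.na(out$ct)
  if (any(bad)) {
    stop("non-amplified call(s) carry a ct: ",
         paste(out$reaction_id[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' @noRd
parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column '%s' has unparseable value(s): %s", what,
                 paste(unique(v[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}
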
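#' Assemble a model-ready dataset from normalized traces and labels
#'
#' Builds the N x C feature matrix of normalized fluorescence values (one row
#' per reaction, one column per cycle) and aligns the gold-standard labels to
#' it by `reaction_id`. Duplexed wells contribute one row per dye. Rows keep
#' the input trace order.
#'
#' @param normalized List of normalized traces from [normalize_batch()].
#' @param labels Label data frame from [read_labels()] (or
#'   [simulate_dataset()]'s `labels`).
#' @return A `tac_dataset`: list with `x` (matrix, rownames = reaction ids),
#'   `amplified` (logical), `ct` (numeric, `NA` when not amplified),
#'   `reaction_id` and `dye`.
#' @export
assemble_dataset <- function(normalized, labels) {
  if (length(normalized) == 0L) stop("no traces to assemble", call. = FALSE)
  ids <- vapply(normalized, `[[`, character(1), "reaction_id")
  lens <- vapply(normalized, function(z) length(z$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("traces have mixed cycle counts: ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(ids, labels$reaction_id)
  if (length(unmatched)) {
    stop("trace(s) without a label: ",
         paste(utils::head(unmatched, 10), collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(labels$reaction_id, ids)
  if (length(unmatched)) {
    stop("label(s) without a trace: ",
         paste(utils::head(unmatched, 10), collapse = ", "), call. = FALSE)
  }
  x <- do.call(rbind, lapply(normalized, `[[`, "values"))
  rownames(x) <- ids
  colnames(x) <- paste0("cycle_", seq_len(ncol(x)))
  lab <- labels[match(ids, labels$reaction_id), , drop = FALSE]
  structure(
    list(x = x,
         amplified = lab$amplified,
         ct = lab$ct,
         reaction_id = ids,
         dye = vapply(normalized, `[[`, character(1), "dye")),
    class = "tac_dataset"
  )
}

#' @export
print.tac_dataset <- function(x, ...) {
  cat(sprintf("<tac_dataset> %d reactions x %d cycles, %d amplified (%.1f%%)\n",
              nrow(x$x), ncol(x$x), sum(x$amplified),
              100 * mean(x$amplified)))
  invisible(x)
}

#' @export
`[.tac_dataset` <- function(x, i, ...) {
  structure(
    list(x = x$x[i, , drop = FALSE], amplified = x$amplified[i],
         ct = x$ct[i], reaction_id = x$reaction_id[i], dye = x$dye[i]),
    class = "tac_dataset"
  )
}

#' Train/test sizes under the floor split rule
#'
#' The training partition gets `floor(fraction * n)` reactions and the test
#' partition the remainder; the two are disjoint and exhaustive.
#'
#' @param n Total number of reactions.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @return Named integer vector with elements `train` and `test`.
#' @examples
#' split_sizes(165214, 0.8)  # train 132171, test 33043
#' @export
split_sizes <- function(n, train_fraction = 0.8) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(floor(train_fraction * n))
  c(train = n_train, test = as.integer(n) - n_train)
}

#' Randomly split a dataset into train and test partitions
#'
#' Reactions are assigned uniformly at random (by reaction, not by card or
#' well). Pass `group` to instead split whole groups -- e.g. wells or cards
#' -- into the same partition, which avoids leakage when reactions within a
#' group are correlated; group splitting targets the same train fraction but
#' honors group boundaries.
#'
#' @param dataset A `tac_dataset`.
#' @param train_fraction Fraction of reactions for training (default 0.8).
#' @param seed Optional integer seed making the partition reproducible.
#' @param group Optional vector (length N) of group ids for grouped
#'   splitting.
#' @return List with `train` and `test` datasets.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = NULL,
                          group = NULL) {
  stopifnot(inherits(dataset, "tac_dataset"))
  n <- nrow(dataset$x)
  if (n < 2L) stop("need at least 2 reactions to split", call. = FALSE)
  sizes <- split_sizes(n, train_fraction)
  pick <- function() {
    if (is.null(group)) {
      sample.int(n, sizes[["train"]])
    } else {
      stopifnot(length(group) == n)
      gids <- sample(unique(group))
      counts <- cumsum(table(group)[as.character(gids)])
      keep <- gids[seq_len(which.min(abs(counts - sizes[["train"]])))]
      which(group %in% keep)
    }
  }
  idx <- if (!is.null(seed)) with_seed(seed, pick()) else pick()
  list(train = dataset[sort(idx)], test = dataset[setdiff(seq_len(n), sort(idx))])
}

#' Subset a dataset to gold-standard amplified reactions
#'
#' The Ct regressor is trained only on reactions the gold standard calls
#' amplified; this returns that subset (every retained row has a Ct).
#'
#' @param dataset A `tac_dataset`.
#' @return A `tac_dataset` of the amplified rows; empty with a warning if no
#'   reaction amplified.
#' @export
amplified_subset <- function(dataset) {
  stopifnot(inherits(dataset, "tac_dataset"))
  keep <- which(dataset$amplified)
  if (length(keep) == 0L) {
    warning("no amplified reactions in dataset", call. = FALSE)
  }
  dataset[keep]
}
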
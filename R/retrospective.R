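# Snapshot-comparison protocol: train on an older annotation release,
# predict its unresolved ORFs, and measure how many of the genes verified
# by the newer release were already predicted coding.

#' Bundle an annotation release into a snapshot
#'
#' @param label Release label (e.g. a date).
#' @param records ORF record data frame ([read_annotation()]); `orf_id`
#'   must be unique within a snapshot.
#' @return An object of class `orf_snapshot`.
#' @export
snapshot <- function(label, records) {
  if (anyDuplicated(records$orf_id))
    stop("orf_id values must be unique within a snapshot", call. = FALSE)
  structure(list(label = label, records = records), class = "orf_snapshot")
}

#' @export
print.orf_snapshot <- function(x, ...) {
  cat(sprintf("snapshot %s: %d ORFs (%s)\n", x$label, nrow(x$records),
              paste(sprintf("%s %d", names(table(x$records$category)),
                            table(x$records$category)), collapse = ", ")))
  invisible(x)
}

#' Genes newly verified between two snapshots
#'
#' ORFs annotated in *both* snapshots whose category is not `verified` in
#' the older release but is `verified` in the newer one. Matching is by
#' systematic name (`orf_id`); ORFs present only in the newer snapshot are
#' excluded.
#'
#' @param older,newer `orf_snapshot` objects.
#' @return Character vector of orf_ids.
#' @export
newly_verified <- function(older, newer) {
  stopifnot(inherits(older, "orf_snapshot"), inherits(newer, "orf_snapshot"))
  shared <- intersect(older$records$orf_id, newer$records$orf_id)
  old_cat <- older$records$category[match(shared, older$records$orf_id)]
  new_cat <- newer$records$category[match(shared, newer$records$orf_id)]
  shared[old_cat != "verified" & new_cat == "verified"]
}

#' Coverage from counts
#'
#' `100 * (n_new - n_missed) / n_new`: the percentage of newly verified
#' genes that were already predicted coding.
#'
#' @param n_new Number of newly verified genes.
#' @param n_missed How many of them the model failed to predict as coding.
#' @return Coverage percentage (`NA` when `n_new` is 0).
#' @export
#' @examples
#' coverage_from_counts(127, 1)  # 99.21...
coverage_from_counts <- function(n_new, n_missed) {
  stopifnot(n_missed <= n_new, n_missed >= 0)
  if (n_new == 0) return(NA_real_)
  100 * (n_new - n_missed) / n_new
}

#' Pooled coverage over a snapshot series
#'
#' Total hits over total newly verified genes across all adjacent pairs,
#' as a percentage.
#'
#' @param n_new Vector of newly-verified counts per pair.
#' @param n_missed Vector of missed counts per pair.
#' @return Pooled coverage percentage.
#' @export
#' @examples
#' pooled_coverage(c(127, 94, 216, 39, 103, 45), c(1, 1, 4, 0, 2, 0))
pooled_coverage <- function(n_new, n_missed) {
  stopifnot(length(n_new) == length(n_missed), all(n_missed <= n_new))
  100 * sum(n_new - n_missed) / sum(n_new)
}

#' Snapshot-pair coverage of newly verified genes
#'
#' The five-step protocol: (1) build training sets from the older
#' snapshot — its verified ORFs as positives, its intergenic runs longer
#' than `min_len` bp as negatives; (2) train the class-weighted linear SVM;
#' (3) predict the older snapshot's unresolved (dubious + uncharacterized)
#' ORFs; (4) find the genes annotated in both snapshots that the newer one
#' upgraded to verified; (5) report what fraction of those the model had
#' already predicted coding.
#'
#' @param genome Named character vector of chromosome sequences for the
#'   older snapshot's reference.
#' @param older,newer `orf_snapshot` objects.
#' @param selection Measurement blocks (default all six).
#' @param C,w_ratio SVM hyperparameters (tuned defaults).
#' @param min_len Strict minimum intergenic length in bp.
#' @return List of class `coverage_result`: `pair`, `n_new_verified`,
#'   `n_predicted` (predicted-coding count over the whole test set),
#'   `missed` (orf_ids among the newly verified that were not predicted
#'   coding), `coverage` (percent, `NA` if no newly verified genes).
#' @export
snapshot_coverage <- function(genome, older, newer, selection = 1:6,
                              C = 2^-3.5, w_ratio = 2^0.6, min_len = 300L) {
  stopifnot(inherits(older, "orf_snapshot"), inherits(newer, "orf_snapshot"))
  sets <- build_datasets(genome, older$records, min_len = min_len)
  if (nrow(sets$positive) == 0L || nrow(sets$negative) == 0L)
    stop("older snapshot yields an empty training class", call. = FALSE)
  train <- rbind(sets$positive,
                 sets$negative[, c("seq_id", "sequence", "label", "source")])
  model <- train_orf_model(train[, c("seq_id", "sequence", "label")],
                           selection = selection, C = C, w_ratio = w_ratio)
  test_seqs <- stats::setNames(sets$test$sequence, sets$test$seq_id)
  pred <- predict_orfs(model, test_seqs)
  predicted_coding <- pred$orf_id[pred$label == "coding"]
  new_ids <- newly_verified(older, newer)
  missed <- setdiff(new_ids, predicted_coding)
  structure(
    list(pair = paste(older$label, newer$label, sep = "-"),
         n_new_verified = length(new_ids),
         n_predicted = length(predicted_coding),
         missed = missed,
         coverage = coverage_from_counts(length(new_ids), length(missed)),
         model = model),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("%s: %d newly verified, %d predicted coding, coverage %s\n",
              x$pair, x$n_new_verified, x$n_predicted,
              if (is.na(x$coverage)) "undefined"
              else sprintf("%.2f%%", x$coverage)))
  if (length(x$missed)) cat("missed:", paste(x$missed, collapse = " "), "\n")
  invisible(x)
}

#' Retrospective examination over an ordered snapshot series
#'
#' Runs [snapshot_coverage()] on each adjacent pair and appends a pooled
#' row (total hits over total newly verified genes).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param snapshots List of `orf_snapshot` objects in chronological order
#'   (length >= 2).
#' @inheritParams snapshot_coverage
#' @return Data frame: `pair`, `n_new_verified`, `n_predicted`,
#'   `n_missed`, `missed_ids`, `coverage`; the final row pools the series.
#' @export
retrospect_series <- function(genome, snapshots, selection = 1:6,
                              C = 2^-3.5, w_ratio = 2^0.6, min_len = 300L) {
  if (length(snapshots) < 2L)
    stop("a snapshot series needs at least two snapshots", call. = FALSE)
  rows <- lapply(seq_len(length(snapshots) - 1L), function(i) {
    res <- snapshot_coverage(genome, snapshots[[i]], snapshots[[i + 1L]],
                             selection = selection, C = C, w_ratio = w_ratio,
                             min_len = min_len)
    data.frame(pair = res$pair, n_new_verified = res$n_new_verified,
               n_predicted = res$n_predicted, n_missed = length(res$missed),
               missed_ids = paste(res$missed, collapse = " "),
               coverage = res$coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(
    pair = "pooled", n_new_verified = sum(out$n_new_verified),
    n_predicted = NA_integer_, n_missed = sum(out$n_missed),
    missed_ids = "",
    coverage = pooled_coverage(out$n_new_verified, out$n_missed),
    stringsAsFactors = FALSE)
  rbind(out, pooled)
}
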
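#' Read-level benchmarking against simulation truth
#'
#' Decontamination output is scored per sample at the read (count) level,
#' with a positive case indicating a contaminant read: for each feature,
#' reads removed from a contaminant feature are true positives, reads
#' retained on it false negatives; reads removed from a non-contaminant
#' feature are false positives and reads retained on it true negatives.
#' Whole-feature removal is the special case where the post-filter count is
#' zero.
#'
#' @name benchmark
NULL

#' Per-sample read-level confusion counts
#'
#' @param pre pre-filter count tibble.
#' @param post post-filter count tibble (element-wise `<= pre`; features
#'   absent from `post` count as fully removed). Scoring covers exactly the
#'   samples present in `post`, so control samples dropped by a pipeline
#'   are not scored.
#' @param truth tibble with `feature_id` and logical `contaminant`,
#'   labelling every feature of `pre`.
#' @return tibble with `sample_id`, `tp`, `fp`, `tn`, `fn`; the four cells
#'   of each row sum to the sample's pre-filter read total.
#' @export
per_sample_confusion <- function(pre, post, truth) {
  x <- count_matrix(pre)
  y0 <- count_matrix(post)
  extra_s <- setdiff(rownames(y0), rownames(x))
  if (length(extra_s)) {
    abort(paste0("Post-filter sample(s) not present pre-filter: ",
                 paste(extra_s, collapse = ", ")))
  }
  unlabeled <- setdiff(colnames(x), truth$feature_id)
  if (length(unlabeled)) {
    abort(paste0("Feature(s) without a truth label: ",
                 paste(head(unlabeled, 5), collapse = ", ")))
  }
  x <- x[rownames(y0), , drop = FALSE]
  y <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  y[, colnames(y0)] <- y0
  if (any(y > x + 1e-9)) {
    abort("Post-filter counts exceed pre-filter counts.")
  }
  is_contam <- truth$contaminant[match(colnames(x), truth$feature_id)]
  removed <- x - y
  tibble::tibble(
    sample_id = rownames(x),
    tp = unname(rowSums(removed[, is_contam, drop = FALSE])),
    fp = unname(rowSums(removed[, !is_contam, drop = FALSE])),
    tn = unname(rowSums(y[, !is_contam, drop = FALSE])),
    fn = unname(rowSums(y[, is_contam, drop = FALSE]))
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 per sample. Precision is undefined
#' (`NA`, not 0) when nothing was removed (`tp + fp = 0`); recall is
#' undefined when the sample holds no contaminant reads. F1 is 0 when
#' precision is undefined but recall is 0, the harmonic mean when both
#' parents are defined (0 if both are 0), and `NA` otherwise.
#'
#' @param confusion tibble from [per_sample_confusion()].
#' @return tibble with `sample_id`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(confusion) {
  dplyr::mutate(
    confusion,
    total = .data$tp + .data$fp + .data$tn + .data$fn,
    accuracy = (.data$tp + .data$tn) / .data$total,
    precision = dplyr::if_else(.data$tp + .data$fp > 0,
                               .data$tp / (.data$tp + .data$fp), NA_real_),
    recall = dplyr::if_else(.data$tp + .data$fn > 0,
                            .data$tp / (.data$tp + .data$fn), NA_real_),
    f1 = dplyr::case_when(
      !is.na(.data$precision) & !is.na(.data$recall) &
        .data$precision + .data$recall == 0 ~ 0,
      !is.na(.data$precision) & !is.na(.data$recall) ~
        2 * .data$precision * .data$recall / (.data$precision + .data$recall),
      is.na(.data$precision) & !is.na(.data$recall) & .data$recall == 0 ~ 0,
      TRUE ~ NA_real_
    )
  ) |>
    dplyr::select("sample_id", "accuracy", "precision", "recall", "f1")
}

#' Average metrics over samples
#'
#' Arithmetic mean of each metric over its defined values only; a metric
#' undefined in every sample averages to `NA`. The average row is appended
#' with `sample_id = "average"`, preserving the incoming sample order.
#'
#' @param metric_rows tibble from [confusion_metrics()].
#' @return the input with an appended average row; attribute `"n_defined"`
#'   records how many samples contributed to each average.
#' @export
summarize_metrics <- function(metric_rows) {
  if (!nrow(metric_rows)) abort("At least one metric row is required.")
  cols <- c("accuracy", "precision", "recall", "f1")
  avg <- tibble::tibble(sample_id = "average")
  n_def <- integer(0)
  for (cl in cols) {
    v <- metric_rows[[cl]]
    avg[[cl]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    n_def[cl] <- sum(!is.na(v))
  }
  out <- dplyr::bind_rows(metric_rows, avg)
  attr(out, "n_defined") <- n_def
  out
}

#' Benchmark a decontamination run against simulation truth
#'
#' Convenience wrapper: confusion counts, per-sample metrics and the
#' average row in one call.
#'
#' @inheritParams per_sample_confusion
#' @return metrics tibble (with average row); confusion counts in the
#'   `"confusion"` attribute.
#' @export
benchmark_decontamination <- function(pre, post, truth) {
  confusion <- per_sample_confusion(pre, post, truth)
  out <- summarize_metrics(confusion_metrics(confusion))
  attr(out, "confusion") <- confusion
  out
}
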
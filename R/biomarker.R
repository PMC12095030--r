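#' Contaminant-flagging steps and consensus filtering
#'
#' The biomarker-identification pipeline flags suspected contaminant
#' features with up to four independent lines of evidence, then removes
#' whole features flagged by at least a user-chosen number of steps:
#'
#' 1. `step_batch_da()` — features whose composition differs across
#'    sequencing batches (bias-corrected log-linear batch test).
#' 2. `step_control_prevalence()` — features more prevalent in negative
#'    controls than in biological samples.
#' 3. `step_replicate_concordance()` — features whose detection disagrees
#'    between technical replicates sequenced in different batches.
#' 4. `step_blocklist()` — features whose taxonomy matches a curated list of
#'    known reagent contaminants.
#'
#' Each step returns a `step_flags` tibble (`feature_id`, `flagged`,
#' `score`) with the step name and parameters stored as attributes; the
#' steps are computed independently on the same input so that every feature
#' receives a verdict from every step.
#'
#' @name biomarker-steps
NULL

new_step_flags <- function(step, feature_id, flagged, score, params) {
  out <- tibble::tibble(feature_id = feature_id,
                        flagged = flagged, score = score)
  attr(out, "step") <- step
  attr(out, "params") <- params
  class(out) <- c("step_flags", class(out))
  out
}

step_name <- function(flags) attr(flags, "step")

#' Step 1: batch differential-abundance flagging
#'
#' Bias-corrected log-linear test for batch-dependent abundance, run on
#' non-control samples. Counts are log-transformed with a pseudocount; each
#' feature is regressed on batch indicators by OLS; per-sample sampling
#' fraction offsets (the across-feature mean residual) are estimated and
#' subtracted iteratively; a Wald chi-squared test of batch-coefficient
#' equality is Benjamini-Hochberg adjusted across features. Features
#' detected in at least one sample of one batch and in no sample of another
#' ("structural zeros") are flagged regardless of the test.
#'
#' @param dataset a `lobiclean_dataset` from [align_dataset()].
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @param pseudocount added before the log transform (default 1).
#' @return a `step_flags` tibble; `score` is the BH-adjusted p-value.
#' @export
step_batch_da <- function(dataset, alpha = 0.05, pseudocount = 1) {
  sheet <- dataset$sheet
  keep <- !sheet$is_control
  batches <- factor(dataset_batches(sheet)[keep])
  if (nlevels(batches) < 2) {
    abort(paste0("Batch differential abundance needs >= 2 batches; ",
                 "single-batch data should use the composition pipeline."))
  }
  if (any(table(batches) < 2)) {
    abort("Every batch needs >= 2 non-control samples for the batch test.")
  }
  m <- count_matrix(dataset$counts)[keep, , drop = FALSE]
  y <- log(m + pseudocount)
  n <- nrow(y); p <- ncol(y)
  X <- stats::model.matrix(~batches)
  XtXinv <- solve(crossprod(X))
  hat_coef <- function(yy) XtXinv %*% crossprod(X, yy)
  B <- hat_coef(y)
  for (it in seq_len(100)) {
    resid <- y - X %*% B
    d_inc <- rowMeans(resid)
    y <- y - d_inc
    B <- hat_coef(y)
    if (max(abs(d_inc)) < 1e-6) break
  }
  # Wald test of equality of batch coefficients (rows 2..B of the design)
  k <- nlevels(batches)
  L <- cbind(0, diag(k - 1))
  LVL <- L %*% XtXinv %*% t(L)
  LVLinv <- solve(LVL)
  resid <- y - X %*% B
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - k)
  pvals <- vapply(seq_len(p), function(j) {
    lb <- L %*% B[, j]
    q <- drop(t(lb) %*% LVLinv %*% lb)
    if (sigma2[j] <= 0) return(if (q > 1e-12) 0 else 1)
    stats::pchisq(q / sigma2[j], df = k - 1, lower.tail = FALSE)
  }, numeric(1))
  padj <- p.adjust(pvals, method = "BH")
  # structural zeros: detected in >=1 sample of one batch, none of another
  det <- m > 0
  det_by_batch <- rowsum(det + 0, batches) > 0
  structural <- apply(det_by_batch, 2, function(z) any(z) && !all(z))
  new_step_flags("batch_da", colnames(m),
                 flagged = unname(padj < alpha | structural),
                 score = unname(padj),
                 params = list(alpha = alpha, pseudocount = pseudocount))
}

#' Step 2: negative-control prevalence flagging
#'
#' Per feature, presence (count above a detection threshold) is
#' cross-tabulated against control status and tested one-sided for higher
#' prevalence in negative controls, using the continuity-corrected
#' chi-squared statistic with Fisher's exact test as fallback whenever any
#' expected cell is below 5. Features absent everywhere are never flagged.
#'
#' @param dataset a `lobiclean_dataset`.
#' @param threshold flag when the one-sided p-value is below this (default 0.1).
#' @param min_count detection requires count strictly above this (default 0).
#' @return a `step_flags` tibble; `score` is the one-sided p-value
#'   (`NA` for features absent everywhere).
#' @export
step_control_prevalence <- function(dataset, threshold = 0.1, min_count = 0) {
  if (threshold <= 0 || threshold > 1) {
    abort("Prevalence threshold must lie in (0, 1].")
  }
  sheet <- dataset$sheet
  if (!any(sheet$is_control)) {
    abort("Control-prevalence flagging requires at least one negative control.")
  }
  if (all(sheet$is_control)) {
    abort("Control-prevalence flagging requires at least one biological sample.")
  }
  m <- count_matrix(dataset$counts)
  is_ctrl <- sheet$is_control
  nc <- sum(is_ctrl); ns <- sum(!is_ctrl)
  det <- m > min_count
  a <- colSums(det[is_ctrl, , drop = FALSE])
  b <- colSums(det[!is_ctrl, , drop = FALSE])
  score <- vapply(seq_along(a), function(j) {
    prevalence_pvalue(a[j], nc, b[j], ns)
  }, numeric(1))
  new_step_flags("control_prevalence", colnames(m),
                 flagged = unname(!is.na(score) & score < threshold),
                 score = unname(score),
                 params = list(threshold = threshold, min_count = min_count))
}

# one-sided p for prevalence higher in controls; NA if absent everywhere
prevalence_pvalue <- function(a, nc, b, ns) {
  if (a + b == 0) return(NA_real_)
  tab <- matrix(c(a, nc - a, b, ns - b), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    return(fisher.test(tab, alternative = "greater")$p.value)
  }
  p2 <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  if (a / nc > b / ns) p2 / 2 else 1 - p2 / 2
}

#' Step 3: technical-replicate concordance flagging
#'
#' For every technical replicate sequenced in two or more batches, feature
#' detection is compared between the cross-batch members. A feature is
#' flagged when its detection disagrees in at least `max_discordant_fraction`
#' of the replicate pairs (default: all of them) and it is detected in at
#' least one replicate sample. Cohen's unweighted kappa per pair, over all
#' features, is reported as a QC diagnostic in the `"kappa"` attribute.
#' When no replicate spans two batches the step is skipped with a notice
#' and returns all-false flags.
#'
#' @param dataset a `lobiclean_dataset`; replicates are identified by the
#'   sheet's `replicate_id` column.
#' @param max_discordant_fraction flag when the discordant fraction reaches
#'   this value (default 1.0, i.e. discordant in every pair).
#' @return a `step_flags` tibble; `score` is the discordance fraction.
#' @export
step_replicate_concordance <- function(dataset, max_discordant_fraction = 1.0) {
  sheet <- dataset$sheet
  m <- count_matrix(dataset$counts)
  feats <- colnames(m)
  params <- list(max_discordant_fraction = max_discordant_fraction)
  skip <- function(msg) {
    inform(paste0("Replicate-concordance step skipped: ", msg))
    new_step_flags("replicate_concordance", feats,
                   flagged = rep(FALSE, length(feats)),
                   score = rep(NA_real_, length(feats)), params = params)
  }
  if (!"replicate_id" %in% names(sheet)) {
    return(skip("no replicate_id column in the sample sheet."))
  }
  batches <- dataset_batches(sheet)
  reps <- sheet[!sheet$is_control & !is.na(sheet$replicate_id), ]
  reps$batch_lbl <- batches[match(reps$sample_id, sheet$sample_id)]
  pairs <- list()
  for (rid in unique(reps$replicate_id)) {
    rr <- reps[reps$replicate_id == rid, ]
    if (nrow(rr) < 2) next
    if (length(unique(rr$batch_lbl)) < 2) {
      warn(paste0("Replicate '", rid,
                  "' has members in a single batch only; pair ignored."))
      next
    }
    combos <- utils::combn(seq_len(nrow(rr)), 2)
    for (ci in seq_len(ncol(combos))) {
      i <- combos[1, ci]; j <- combos[2, ci]
      if (rr$batch_lbl[i] != rr$batch_lbl[j]) {
        pairs[[length(pairs) + 1]] <-
          list(replicate_id = rid, a = rr$sample_id[i], b = rr$sample_id[j])
      }
    }
  }
  if (!length(pairs)) {
    return(skip("no technical replicate spans two batches."))
  }
  det <- m > 0
  disagree <- matrix(FALSE, length(pairs), length(feats))
  any_det <- rep(FALSE, length(feats))
  kappa_rows <- purrr::map_dfr(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    da <- det[pr$a, ]; db <- det[pr$b, ]
    disagree[k, ] <<- da != db
    any_det <<- any_det | da | db
    tibble::tibble(replicate_id = pr$replicate_id,
                   sample_a = pr$a, sample_b = pr$b,
                   kappa = cohen_kappa(sum(da & db), sum(da & !db),
                                       sum(!da & db), sum(!da & !db)))
  })
  frac <- colMeans(disagree)
  out <- new_step_flags("replicate_concordance", feats,
                        flagged = unname(frac >= max_discordant_fraction & any_det),
                        score = unname(frac), params = params)
  attr(out, "kappa") <- kappa_rows
  out
}

#' Cohen's unweighted kappa for a 2x2 agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d) / n` and chance agreement `p_e` from the marginal
#' detection rates. Degenerate tables with `p_e = 1` return 1 under perfect
#' agreement and 0 otherwise.
#'
#' @param a count with both raters positive.
#' @param b count with first rater only positive.
#' @param c count with second rater only positive.
#' @param d count with both raters negative.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(NA_real_)
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Step 4: blocklist flagging
#'
#' Flags features whose taxonomic lineage matches a blocklist entry at the
#' entry's rank (default genus); matching is case-insensitive and exact on
#' the name. Features without taxonomy are never flagged.
#'
#' @param feature_ids character vector of features to assess.
#' @param taxonomy taxonomy tibble from [read_taxonomy()].
#' @param blocklist blocklist tibble (`rank`, `name`) from
#'   [read_blocklist()], or a list of them (concatenated).
#' @return a `step_flags` tibble; `score` is a 0/1 match indicator (`NA`
#'   for features without taxonomy).
#' @export
step_blocklist <- function(feature_ids, taxonomy, blocklist) {
  if (is.list(blocklist) && !is.data.frame(blocklist)) {
    blocklist <- dplyr::bind_rows(blocklist)
  }
  if (is.null(blocklist) || nrow(blocklist) == 0) {
    abort("Blocklist step enabled with an empty blocklist.")
  }
  tax <- taxonomy[match(feature_ids, taxonomy$feature_id), , drop = FALSE]
  has_tax <- !is.na(tax$feature_id)
  if (!any(has_tax)) {
    abort("No feature has taxonomy; cannot run the blocklist step.")
  }
  if (any(!has_tax)) {
    inform(paste0(sum(!has_tax), " feature(s) lack taxonomy and are not ",
                  "assessed by the blocklist step."))
  }
  hit <- rep(FALSE, length(feature_ids))
  for (r in unique(blocklist$rank)) {
    if (!r %in% names(tax)) next
    names_r <- tolower(blocklist$name[blocklist$rank == r])
    hit <- hit | (!is.na(tax[[r]]) & tolower(tax[[r]]) %in% names_r)
  }
  score <- ifelse(has_tax, as.numeric(hit), NA_real_)
  new_step_flags("blocklist", feature_ids, flagged = hit, score = score,
                 params = list(n_entries = nrow(blocklist)))
}

#' Consensus whole-feature removal
#'
#' Removes every feature flagged by at least `threshold` of the executed
#' steps, drops control samples, and computes the filtering loss of the
#' removal on the non-control sub-matrix.
#'
#' @param dataset a `lobiclean_dataset`.
#' @param flags list of `step_flags` tibbles (the executed steps).
#' @param threshold minimum number of flagging steps for removal (default 1).
#' @return a `biomarker_result` object: `filtered` (count tibble, controls
#'   dropped), `removed_features`, `step_matrix`, `threshold`, `fl`.
#' @export
consensus_filter <- function(dataset, flags, threshold = 1) {
  if (!length(flags)) abort("At least one executed step is required.")
  if (threshold < 1 || threshold > length(flags)) {
    abort(paste0("Consensus threshold must lie between 1 and the number of ",
                 "executed steps (", length(flags), ")."))
  }
  feats <- names(dataset$counts)[-1]
  step_matrix <- tibble::tibble(feature_id = feats)
  for (fl in flags) {
    stopifnot(identical(fl$feature_id, feats))
    step_matrix[[step_name(fl)]] <- fl$flagged
  }
  n_flagging <- rowSums(as.matrix(step_matrix[, -1, drop = FALSE]))
  removed <- feats[n_flagging >= threshold]
  pre <- dataset$counts[!dataset$sheet$is_control, , drop = FALSE]
  filtered <- pre[, c("sample_id", setdiff(feats, removed)), drop = FALSE]
  fl_res <- filtering_loss(pre, filtered)
  structure(list(filtered = filtered, removed_features = removed,
                 step_matrix = step_matrix, threshold = threshold,
                 fl = fl_res, flags = flags),
            class = "biomarker_result")
}

#' Overlap of step flag sets (Venn regions)
#'
#' Counts, for every non-empty combination of steps, the features flagged by
#' exactly that combination. The region counts sum to the size of the union
#' of all flag sets.
#'
#' @param flags list of >= 2 `step_flags` tibbles.
#' @return tibble with one logical column per step, the `combination` label,
#'   and the region count `n` (all `2^k - 1` regions, including empty ones).
#' @export
step_overlap_summary <- function(flags) {
  if (length(flags) < 2) abort("Overlap summary needs at least two steps.")
  steps <- vapply(flags, step_name, character(1))
  feats <- flags[[1]]$feature_id
  flag_mat <- vapply(flags, function(f) f$flagged, logical(length(feats)))
  colnames(flag_mat) <- steps
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(steps))))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  colnames(grid) <- steps
  n <- apply(grid, 1, function(g) {
    sum(apply(flag_mat, 1, function(row) all(row == g)))
  })
  out <- tibble::as_tibble(grid)
  out$combination <- apply(grid, 1, function(g) paste(steps[g], collapse = "+"))
  out$n <- as.integer(n)
  out
}

#' Run the full biomarker-identification pipeline
#'
#' Executes the applicable flagging steps (the batch test always; control
#' prevalence when controls exist; replicate concordance when replicates
#' exist; the blocklist step when taxonomy and a blocklist are supplied) and
#' applies the consensus filter.
#'
#' @param dataset a `lobiclean_dataset`; needs >= 2 batches.
#' @param taxonomy optional taxonomy tibble (enables the blocklist step).
#' @param blocklist optional blocklist tibble or list of tibbles.
#' @param threshold consensus threshold (default 1).
#' @param alpha step-1 significance level (default 0.05).
#' @param prevalence_threshold step-2 p-value cut (default 0.1).
#' @param max_discordant_fraction step-3 discordance cut (default 1.0).
#' @param pseudocount step-1 pseudocount (default 1).
#' @param min_count step-2 detection threshold (default 0).
#' @return a `biomarker_result` object.
#' @export
run_biomarker <- function(dataset, taxonomy = NULL, blocklist = NULL,
                          threshold = 1, alpha = 0.05,
                          prevalence_threshold = 0.1,
                          max_discordant_fraction = 1.0,
                          pseudocount = 1, min_count = 0) {
  batches <- dataset_batches(dataset$sheet)
  if (length(unique(batches)) < 2) {
    abort(paste0("The biomarker pipeline requires multiple batches; ",
                 "use the composition pipeline for single-batch data."))
  }
  flags <- list(step_batch_da(dataset, alpha = alpha,
                              pseudocount = pseudocount))
  if (any(dataset$sheet$is_control)) {
    flags <- c(flags, list(step_control_prevalence(
      dataset, threshold = prevalence_threshold, min_count = min_count)))
  } else {
    inform("No negative controls: control-prevalence step not executed.")
  }
  flags <- c(flags, list(step_replicate_concordance(
    dataset, max_discordant_fraction = max_discordant_fraction)))
  if (!is.null(taxonomy) && !is.null(blocklist)) {
    flags <- c(flags, list(step_blocklist(names(dataset$counts)[-1],
                                          taxonomy, blocklist)))
  }
  consensus_filter(dataset, flags, threshold = threshold)
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("<biomarker_result> removed ", length(x$removed_features), " of ",
      nrow(x$step_matrix), " features (consensus threshold ", x$threshold,
      ")\n  filtering loss: ", format(x$fl$fl, digits = 4), "\n", sep = "")
  invisible(x)
}
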
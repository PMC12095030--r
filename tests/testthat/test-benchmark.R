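mk_pre_post <- function(pre_m, post_m) {
  list(pre = as_count_tbl(pre_m), post = as_count_tbl(post_m))
}

test_that("confusion counts follow the read-attribution rule", {
  # 3 features, pre 10/10/10, post 0/5/10, contaminants T/T/F
  pre <- matrix(10, 1, 3, dimnames = list("S1", c("c1", "c2", "ok")))
  post <- pre; post[1, ] <- c(0, 5, 10)
  truth <- tibble::tibble(feature_id = colnames(pre),
                          contaminant = c(TRUE, TRUE, FALSE))
  ct <- per_sample_confusion(as_count_tbl(pre), as_count_tbl(post), truth)
  expect_equal(unlist(ct[1, c("tp", "fp", "tn", "fn")]),
               c(tp = 15, fp = 0, tn = 10, fn = 5))
  met <- confusion_metrics(ct)
  expect_equal(met$accuracy, 25 / 30)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 0.75)
  expect_equal(met$f1, 6 / 7)

  # identity filtering on clean features: everything is a true negative
  ct0 <- per_sample_confusion(as_count_tbl(pre), as_count_tbl(pre),
                              tibble::tibble(feature_id = colnames(pre),
                                             contaminant = FALSE))
  expect_equal(unlist(ct0[1, c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 0, tn = 30, fn = 0))
  expect_equal(confusion_metrics(ct0)$accuracy, 1)
})

test_that("confusion totals conserve reads and reject invalid input", {
  withr::local_seed(17)
  pre <- random_counts(6, 8)
  post_m <- count_matrix(pre) -
    matrix(rbinom(48, size = count_matrix(pre), prob = 0.4), 6, 8)
  truth <- tibble::tibble(feature_id = names(pre)[-1],
                          contaminant = rep(c(TRUE, FALSE), 4))
  ct <- per_sample_confusion(pre, as_count_tbl(post_m), truth)
  expect_equal(ct$tp + ct$fp + ct$tn + ct$fn,
               unname(rowSums(count_matrix(pre))))

  too_big <- count_matrix(pre) + 1
  expect_error(per_sample_confusion(pre, as_count_tbl(too_big), truth),
               "exceed")
  expect_error(per_sample_confusion(pre, pre, truth[-1, ]), "truth label")
})

test_that("undefined metrics mirror the no-removal and no-contaminant cases", {
  ct <- tibble::tibble(sample_id = "S1", tp = 0, fp = 0, tn = 20, fn = 10)
  met <- confusion_metrics(ct)
  expect_true(is.na(met$precision))  # nothing removed: precision undefined
  expect_equal(met$recall, 0)
  expect_equal(met$f1, 0)            # undefined precision with zero recall

  all_one <- confusion_metrics(tibble::tibble(sample_id = "S", tp = 1,
                                              fp = 0, tn = 0, fn = 0))
  expect_equal(unlist(all_one[, -1]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # no contaminant reads at all: recall undefined, not zero
  met2 <- confusion_metrics(tibble::tibble(sample_id = "S", tp = 0, fp = 2,
                                           tn = 18, fn = 0))
  expect_true(is.na(met2$recall))
  expect_true(is.na(met2$f1))
})

test_that("averages skip undefined entries instead of imputing zero", {
  rows <- tibble::tibble(sample_id = c("a", "b", "c"),
                         accuracy = c(0.2, 0.4, 0.6),
                         precision = c(1, NA, NA),
                         recall = c(0.2, 0.4, 0.6),
                         f1 = c(NA, NA, NA))
  avg <- summarize_metrics(rows)
  expect_equal(nrow(avg), 4)
  expect_equal(avg$accuracy[4], 0.4)
  expect_equal(avg$precision[4], 1)      # mean over the single defined cell
  expect_true(is.na(avg$f1[4]))          # undefined everywhere stays NA
  expect_equal(unname(attr(avg, "n_defined")["precision"]), 1L)
  # identical rows average to the row itself
  same <- summarize_metrics(rows[c(1, 1), ])
  expect_equal(unlist(same[3, -1]), unlist(same[1, -1]))
})

test_that("whole-feature removal scores identically read-wise and feature-wise", {
  withr::local_seed(19)
  pre <- random_counts(5, 10, max_count = 30)
  x <- count_matrix(pre)
  drop <- c(2, 5, 9)
  post <- as_count_tbl(x[, -drop, drop = FALSE])
  truth <- tibble::tibble(feature_id = colnames(x),
                          contaminant = seq_len(10) %in% c(2, 5, 7))
  ct <- per_sample_confusion(pre, post, truth)
  # feature-wise expectation: removed feature's reads all count to tp/fp
  exp_tp <- rowSums(x[, intersect(drop, c(2, 5, 7)), drop = FALSE])
  exp_fp <- rowSums(x[, setdiff(drop, c(2, 5, 7)), drop = FALSE])
  expect_equal(ct$tp, unname(exp_tp))
  expect_equal(ct$fp, unname(exp_fp))
})

test_that("the consensus pipeline out-recalls its prevalence step alone", {
  sim <- simulate_multibatch(sim_config(seed = 2))
  ds <- align_dataset(sim$counts, sim$sheet)
  full <- suppressMessages(run_biomarker(ds, taxonomy = sim$taxonomy,
                                         blocklist = default_blocklist()))
  prev <- suppressMessages(
    consensus_filter(ds, list(step_control_prevalence(ds)), 1))
  pre <- ds$counts[!ds$sheet$is_control, ]
  avg_recall <- function(res) {
    b <- benchmark_decontamination(pre, res$filtered, sim$truth)
    b$recall[b$sample_id == "average"]
  }
  expect_gt(avg_recall(full), avg_recall(prev))
})
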
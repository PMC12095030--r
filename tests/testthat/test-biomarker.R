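two_batch_dataset <- function(m, is_control = rep(FALSE, nrow(m)),
                              batch = NULL, replicate_id = NULL) {
  if (is.null(batch)) batch <- rep(c("b1", "b2"), each = nrow(m) / 2)
  align_dataset(as_count_tbl(m),
                tiny_sheet(rownames(m), is_control = is_control,
                           batch = batch, replicate_id = replicate_id))
}

test_that("batch test flags spiked and structural-zero features only", {
  withr::local_seed(31)
  m <- matrix(round(runif(10 * 20, 40, 60)), 10, 20,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("f%02d", 1:20)))
  m[6:10, 1] <- m[6:10, 1] * 20          # strong batch-2 shift in f01
  m[1:5, 2] <- 0                          # structural zero: absent in batch 1
  ds <- two_batch_dataset(m)
  flags <- step_batch_da(ds)
  expect_true(flags$flagged[1])
  expect_true(flags$flagged[2])
  expect_lte(mean(flags$flagged[-(1:2)]), 0.15)
  expect_true(all(flags$score >= 0 & flags$score <= 1))
})

test_that("batch test requires two proper batches without controls", {
  withr::local_seed(32)
  m <- matrix(rpois(8 * 5, 30), 8, 5,
              dimnames = list(paste0("S", 1:8), paste0("f", 1:5)))
  expect_error(step_batch_da(two_batch_dataset(m, batch = rep("b1", 8))),
               "composition")
  expect_error(step_batch_da(two_batch_dataset(m, batch = rep(c("b1", "b2"),
                                                              c(7, 1)))),
               ">= 2 non-control")
})

test_that("control prevalence flags control-enriched features, skips absent ones", {
  m <- matrix(0, 14, 3, dimnames = list(sprintf("S%02d", 1:14),
                                        c("inCtrl", "inSamp", "absent")))
  is_ctrl <- rep(c(TRUE, FALSE), c(4, 10))
  m[is_ctrl, "inCtrl"] <- 5
  m[!is_ctrl, "inSamp"] <- 5
  ds <- align_dataset(as_count_tbl(m), tiny_sheet(rownames(m), is_control = is_ctrl))
  flags <- step_control_prevalence(ds)
  expect_true(flags$flagged[flags$feature_id == "inCtrl"])
  expect_false(flags$flagged[flags$feature_id == "inSamp"])
  expect_false(flags$flagged[flags$feature_id == "absent"])
  expect_true(is.na(flags$score[flags$feature_id == "absent"]))

  # prevalence is presence-based: scaling all counts changes nothing
  ds10 <- align_dataset(as_count_tbl(m * 10),
                        tiny_sheet(rownames(m), is_control = is_ctrl))
  expect_equal(step_control_prevalence(ds10)$flagged, flags$flagged)

  expect_error(step_control_prevalence(ds, threshold = 0), "0, 1")
  no_ctrl <- align_dataset(as_count_tbl(m), tiny_sheet(rownames(m)))
  expect_error(step_control_prevalence(no_ctrl), "control")
})

test_that("prevalence p-value equals the exact hypergeometric tail (3/1 vs 1/9)", {
  # controls: 3 present / 1 absent; samples: 1 present / 9 absent
  p <- lobiclean:::prevalence_pvalue(3, 4, 1, 10)
  expect_equal(p, hyper_tail_p(3, 4, 1, 10))
  expect_equal(p, sum(sapply(3:4, function(a) stats::dhyper(a, 4, 10, 4))))
})

test_that("kappa arithmetic matches the closed form", {
  expect_equal(cohen_kappa(40, 10, 10, 40), 0.6)
  expect_equal(cohen_kappa(25, 0, 0, 75), 1)
  expect_equal(cohen_kappa(100, 0, 0, 0), 1)  # degenerate, perfect agreement
})

test_that("replicate concordance flags fully discordant detected features", {
  m <- matrix(0, 4, 3, dimnames = list(c("R1A", "R1B", "R2A", "R2B"),
                                       c("stable", "flaky", "absent")))
  m[, "stable"] <- 10
  m[c("R1A", "R2A"), "flaky"] <- 8    # detected in batch-1 member only
  ds <- two_batch_dataset(m, batch = c("b1", "b2", "b1", "b2"),
                          replicate_id = c("R1", "R1", "R2", "R2"))
  flags <- step_replicate_concordance(ds)
  expect_false(flags$flagged[flags$feature_id == "stable"])
  expect_true(flags$flagged[flags$feature_id == "flaky"])
  expect_false(flags$flagged[flags$feature_id == "absent"])  # never detected
  kap <- attr(flags, "kappa")
  expect_equal(nrow(kap), 2)

  # no cross-batch replicate: skipped with all-false flags
  ds2 <- two_batch_dataset(m, batch = c("b1", "b2", "b1", "b2"))
  expect_message(flags2 <- step_replicate_concordance(ds2), "skipped")
  expect_false(any(flags2$flagged))
})

test_that("blocklist matching is rank-aware and case-insensitive", {
  tax <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                        kingdom = "Bacteria", phylum = NA, class = NA,
                        order = NA, family = c(NA, "Comamonadaceae", NA),
                        genus = c("ralstonia", NA, "Roseburia"),
                        species = NA)
  bl <- tibble::tibble(rank = c("genus", "family"),
                       name = c("Ralstonia", "comamonadaceae"))
  flags <- step_blocklist(c("f1", "f2", "f3"), tax, bl)
  expect_equal(flags$flagged, c(TRUE, TRUE, FALSE))
  expect_error(step_blocklist("f1", tax, bl[0, ]), "empty")
  # a feature without taxonomy is never flagged
  expect_message(
    f4 <- step_blocklist(c("f1", "unknown"), tax, bl), "lack taxonomy")
  expect_false(f4$flagged[f4$feature_id == "unknown"])
})

test_that("consensus removal follows the step-count threshold exactly", {
  withr::local_seed(41)
  m <- matrix(rpois(8 * 6, 20) + 1, 8, 6,
              dimnames = list(paste0("S", 1:8), paste0("f", 1:6)))
  ds <- two_batch_dataset(m)
  fake_flags <- function(step, idx) {
    fl <- rep(FALSE, 6); fl[idx] <- TRUE
    lobiclean:::new_step_flags(step, paste0("f", 1:6), fl,
                               rep(NA_real_, 6), list())
  }
  flags <- list(fake_flags("batch_da", c(1, 2)),
                fake_flags("control_prevalence", c(2, 3)),
                fake_flags("replicate_concordance", integer(0)),
                fake_flags("blocklist", c(2, 4)))
  # brute-force per-feature flag counts: f1=1, f2=3, f3=1, f4=1, f5=f6=0
  res1 <- consensus_filter(ds, flags, threshold = 1)
  expect_setequal(res1$removed_features, c("f1", "f2", "f3", "f4"))
  res2 <- consensus_filter(ds, flags, threshold = 2)
  expect_equal(res2$removed_features, "f2")
  res4 <- consensus_filter(ds, flags, threshold = 4)
  expect_equal(res4$removed_features, character(0))
  expect_equal(res4$fl$fl, 0)
  # threshold monotonicity: higher threshold removes a subset
  expect_true(all(res2$removed_features %in% res1$removed_features))
  expect_error(consensus_filter(ds, flags, threshold = 5), "between 1 and")
  # retained columns are untouched
  expect_equal(res2$filtered$f5, as.vector(m[, "f5"]))
})

test_that("overlap summary reproduces brute-force Venn region counts", {
  withr::local_seed(43)
  feats <- paste0("f", 1:30)
  mk <- function(step) {
    lobiclean:::new_step_flags(step, feats, runif(30) < 0.4,
                               rep(NA_real_, 30), list())
  }
  flags <- list(mk("batch_da"), mk("control_prevalence"), mk("blocklist"))
  ov <- step_overlap_summary(flags)
  expect_equal(nrow(ov), 2^3 - 1)
  fm <- sapply(flags, function(f) f$flagged)
  expect_equal(sum(ov$n), sum(rowSums(fm) > 0))
  for (k in seq_len(nrow(ov))) {
    memb <- unlist(ov[k, c("batch_da", "control_prevalence", "blocklist")])
    expect_equal(ov$n[k],
                 sum(apply(fm, 1, function(r) all(r == memb))))
  }
  # disjoint and identical flag sets
  a <- lobiclean:::new_step_flags("a", feats, c(TRUE, rep(FALSE, 29)),
                                  rep(NA_real_, 30), list())
  b <- lobiclean:::new_step_flags("b", feats, c(FALSE, TRUE, rep(FALSE, 28)),
                                  rep(NA_real_, 30), list())
  ov2 <- step_overlap_summary(list(a, b))
  expect_equal(ov2$n[ov2$combination == "a"], 1)
  expect_equal(ov2$n[ov2$combination == "b"], 1)
  expect_equal(ov2$n[ov2$combination == "a+b"], 0)
  a2 <- lobiclean:::new_step_flags("b", feats, a$flagged,
                                   rep(NA_real_, 30), list())
  ov3 <- step_overlap_summary(list(a, a2))
  expect_equal(sum(ov3$n), ov3$n[ov3$combination == "a+b"])
})

test_that("the full biomarker run drops controls and reports all steps", {
  sim <- simulate_multibatch(sim_config(seed = 4))
  ds <- align_dataset(sim$counts, sim$sheet)
  res <- suppressMessages(run_biomarker(ds, taxonomy = sim$taxonomy,
                                        blocklist = default_blocklist()))
  expect_s3_class(res, "biomarker_result")
  expect_equal(ncol(res$step_matrix) - 1L, 4L)
  expect_false(any(sim$sheet$sample_id[sim$sheet$is_control] %in%
                     res$filtered$sample_id))
  expect_equal(nrow(res$step_matrix), 110)
  # removed <=> flagged by >= threshold steps
  n_flags <- rowSums(as.matrix(res$step_matrix[, -1]))
  expect_setequal(res$removed_features,
                  res$step_matrix$feature_id[n_flags >= res$threshold])
  expect_error(run_biomarker(align_dataset(
    sim$counts[1:7, ], sim$sheet[1:7, ])), "multiple batches")
})
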
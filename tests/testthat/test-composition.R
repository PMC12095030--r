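test_that("pseudo-well assignment follows the plate fill order", {
  sheet3 <- tiny_sheet(c("A", "B", "C"))
  expect_equal(assign_pseudo_wells(sheet3, "vertical")$well,
               c("A1", "B1", "C1"))
  expect_equal(assign_pseudo_wells(sheet3, "horizontal")$well,
               c("A1", "A2", "A3"))
  sheet13 <- tiny_sheet(sprintf("S%02d", 1:13))
  expect_equal(assign_pseudo_wells(sheet13, "vertical")$well[9], "A2")
  expect_equal(assign_pseudo_wells(sheet13, "horizontal")$well[13], "B1")
  expect_error(assign_pseudo_wells(tiny_sheet(sprintf("S%03d", 1:97))), "96")
  # per-batch assignment restarts the plate
  sheet2b <- tiny_sheet(c("A", "B", "C", "D"), batch = c("b1", "b1", "b2", "b2"))
  expect_equal(assign_pseudo_wells(sheet2b)$well, c("A1", "B1", "A1", "B1"))
})

test_that("EM degenerates gracefully and bounds its outputs", {
  m <- matrix(c(10, 20, 0, 0), 2, 2,
              dimnames = list(c("S1", "NC1"), c("f1", "f2")))
  m["NC1", ] <- 0
  sheet <- tiny_sheet(c("S1", "NC1"), is_control = c(FALSE, TRUE))
  expect_message(fit <- fit_mixture_em(as_count_tbl(m), sheet), "zero reads")
  expect_equal(fit$contamination$p, 0)
  expect_true(fit$converged)

  no_ctrl <- tiny_sheet(c("S1", "NC1"))
  expect_error(fit_mixture_em(as_count_tbl(m), no_ctrl), "negative control")
})

test_that("EM fit normalizes profiles and never decreases the log-likelihood", {
  b <- simulate_mixture_batch(n_samples = 6, contamination = c(0.1, 0.4),
                              reads = 2e4, seed = 5)
  fit <- fit_mixture_em(b$counts, b$sheet)
  expect_equal(sum(fit$gamma), 1, tolerance = 1e-8)
  expect_equal(unname(rowSums(fit$intrinsic)), rep(1, 6), tolerance = 1e-8)
  expect_true(all(fit$contamination$p >= 0 & fit$contamination$p <= 1))
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-8 * abs(fit$loglik_trace[-1])))
})

test_that("a sample matching the contaminant profile is called almost fully contaminated", {
  withr::local_seed(7)
  gam <- rgamma(30, 2); gam <- gam / sum(gam)
  ids <- c(sprintf("S%02d", 1:10), "NC1", "NC2")
  m <- matrix(0, 12, 30, dimnames = list(ids, sprintf("f%03d", 1:30)))
  for (i in 1:10) m[i, ] <- rmultinom(1, 5e4, gam)
  m[11, ] <- rmultinom(1, 5e3, gam)
  m[12, ] <- rmultinom(1, 5e3, gam)
  sheet <- tiny_sheet(ids, is_control = c(rep(FALSE, 10), TRUE, TRUE))
  fit <- fit_mixture_em(as_count_tbl(m), sheet)
  expect_true(all(fit$contamination$p >= 0.9))
})

test_that("decontamination applies the posterior and respects bounds", {
  m <- matrix(c(10, 5, 7, 3), 2, 2,
              dimnames = list(c("S1", "NC1"), c("f1", "f2")))
  fit <- structure(list(
    posterior = matrix(c(0.25, 0.5), 1, 2,
                       dimnames = list("S1", c("f1", "f2"))),
    converged = TRUE), class = "mixture_fit")
  out <- decontaminate_batch(as_count_tbl(m), fit)
  # 10*(1-0.25)=7.5 -> 8 (half to even); 7*(1-0.5)=3.5 -> 4
  expect_equal(unname(unlist(out[1, -1])), c(8, 4))
  expect_false("NC1" %in% out$sample_id)
  frac <- decontaminate_batch(as_count_tbl(m), fit, round_counts = FALSE)
  expect_equal(unname(unlist(frac[1, -1])), c(7.5, 3.5))

  # p = 0 leaves counts untouched; p = 1 empties the sample
  id_fit <- fit; id_fit$posterior[] <- 0
  expect_equal(unname(unlist(decontaminate_batch(as_count_tbl(m), id_fit)[1, -1])),
               c(10, 7))
  full_fit <- fit; full_fit$posterior[] <- 1
  expect_equal(unname(unlist(decontaminate_batch(as_count_tbl(m), full_fit)[1, -1])),
               c(0, 0))
})

test_that("leakage warning fires strictly above 0.10", {
  mk_fit <- function(leak) {
    structure(list(leakage = tibble::tibble(control_id = "NC1",
                                            leakage = leak)),
              class = "mixture_fit")
  }
  expect_silent(estimate_well_leakage(mk_fit(0.10)))   # boundary: no warning
  expect_warning(estimate_well_leakage(mk_fit(0.100001)), "well")
  expect_false(attr(estimate_well_leakage(mk_fit(0.05)), "leakage_warning"))
})

test_that("injected well-to-well leakage is recovered; its absence is not invented", {
  b0 <- simulate_mixture_batch(n_samples = 10, contamination = 0.2,
                               leakage = 0, seed = 42)
  fit0 <- fit_mixture_em(b0$counts, b0$sheet)
  expect_true(all(fit0$leakage$leakage < 0.05))
  expect_false(attr(estimate_well_leakage(fit0), "leakage_warning"))

  b25 <- simulate_mixture_batch(n_samples = 10, contamination = 0.2,
                                leakage = 0.25, seed = 42)
  fit25 <- fit_mixture_em(b25$counts, b25$sheet)
  expect_warning(lk <- estimate_well_leakage(fit25), "well")
  expect_true(attr(lk, "leakage_warning"))
  expect_equal(lk$leakage, rep(0.25, 2), tolerance = 0.3)
})

test_that("the composition run equals per-batch runs concatenated", {
  sim <- simulate_multibatch(sim_config(seed = 6))
  ds <- align_dataset(sim$counts, sim$sheet)
  full <- suppressMessages(suppressWarnings(run_composition(ds)))

  pieces <- lapply(c("batch1", "batch2"), function(b) {
    in_b <- sim$sheet$batch == b
    dsb <- align_dataset(sim$counts[in_b, ], sim$sheet[in_b, ])
    suppressMessages(suppressWarnings(run_composition(dsb)))$filtered
  })
  expect_identical(count_matrix(full$filtered),
                   count_matrix(dplyr::bind_rows(pieces)))

  # output never exceeds input
  pre <- count_matrix(ds$counts[!ds$sheet$is_control, ])
  expect_true(all(count_matrix(full$filtered) <= pre))

  # a batch without controls is refused, naming the batch
  sheet_noctrl <- sim$sheet
  sheet_noctrl$is_control[sheet_noctrl$batch == "batch2"] <- FALSE
  ds2 <- align_dataset(sim$counts, sheet_noctrl)
  expect_error(run_composition(ds2), "batch2")
})

test_that("a batch column is optional: one batch is assumed", {
  b <- simulate_mixture_batch(n_samples = 4, contamination = 0.2, seed = 9)
  ds <- align_dataset(b$counts, b$sheet[, c("sample_id", "is_control", "group")])
  res <- suppressMessages(suppressWarnings(run_composition(ds)))
  expect_equal(length(res$fits), 1L)
  expect_equal(nrow(res$filtered), 4L)
})
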
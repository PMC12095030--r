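# small in-code fixtures shared across test files

tiny_counts <- function(m = matrix(c(5, 2, 0, 0, 7, 1), 3, 2,
                                   dimnames = list(c("S1", "S2", "S3"),
                                                   c("fA", "fB")))) {
  as_count_tbl(m)
}

tiny_sheet <- function(ids, is_control = rep(FALSE, length(ids)),
                       group = "g", batch = NULL, replicate_id = NULL,
                       well = NULL) {
  sheet <- tibble::tibble(sample_id = ids, is_control = is_control,
                          group = group)
  if (!is.null(batch)) sheet$batch <- batch
  if (!is.null(replicate_id)) sheet$replicate_id <- replicate_id
  if (!is.null(well)) sheet$well <- well
  sheet
}

# random integer count tibble
random_counts <- function(n, p, max_count = 9, prefix = "f") {
  m <- matrix(sample(0:max_count, n * p, replace = TRUE), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  as_count_tbl(m)
}

# two identically-generated batches: no contamination, no batch effect
null_two_batch_dataset <- function(n_per_batch = 5, n_features = 50) {
  n <- 2 * n_per_batch
  m <- matrix(round(pmax(runif(n * n_features, 20, 90) +
                           rnorm(n * n_features, 0, 10), 0)),
              n, n_features,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(n_features))))
  sheet <- tiny_sheet(rownames(m),
                      batch = rep(c("b1", "b2"), each = n_per_batch))
  align_dataset(as_count_tbl(m), sheet)
}

# exact one-sided hypergeometric tail for a 2x2 prevalence table
# (a present of nc controls, b present of ns samples)
hyper_tail_p <- function(a, nc, b, ns) {
  stats::phyper(a - 1, m = a + b, n = nc + ns - a - b, k = nc,
                lower.tail = FALSE)
}

default_blocklist <- function() read_blocklist(default_blocklist_path())

true_genera <- function() {
  c("Bacteroides", "Bifidobacterium", "Roseburia", "Butyrivibrio",
    "Parabacteroides", "Peptostreptococcus", "Alistipes", "Eubacterium",
    "Faecalibacterium", "Ruminococcus")
}

# retained true genera after the consensus biomarker pipeline on one
# regenerated simulation
biomarker_retained <- function(seed) {
  sim <- simulate_multibatch(sim_config(seed = seed))
  ds <- align_dataset(sim$counts, sim$sheet)
  res <- suppressMessages(run_biomarker(ds, taxonomy = sim$taxonomy,
                                        blocklist = default_blocklist()))
  sum(!true_genera() %in% res$removed_features)
}

composition_retained <- function(seed) {
  sim <- simulate_multibatch(sim_config(seed = seed))
  ds <- align_dataset(sim$counts, sim$sheet)
  res <- suppressMessages(suppressWarnings(run_composition(ds)))
  sum(colSums(count_matrix(res$filtered)[, true_genera()]) > 0)
}
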
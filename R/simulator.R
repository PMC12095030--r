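#' Multi-batch contamination simulator
#'
#' Regenerates a two-batch 16S count dataset with known contamination for
#' benchmarking decontamination methods. Ten genera commonly found in the
#' human gut form the true biological signal (five of them differentially
#' abundant between a "Disease" and a "Healthy control" group); a shared set
#' of contaminant features receives batch-specific values, plus a
#' batch-dependent leakage component that couples samples and their
#' negative controls; a zero-inflation pass sparsifies the final matrix.
#' Every random draw is governed by the config seed, so a config reproduces
#' its dataset exactly.
#'
#' @name simulator
NULL

TRUE_GENERA <- c("Bacteroides", "Bifidobacterium", "Roseburia",
                 "Butyrivibrio", "Parabacteroides", "Peptostreptococcus",
                 "Alistipes", "Eubacterium", "Faecalibacterium",
                 "Ruminococcus")
DA_GENERA <- c("Roseburia", "Bacteroides", "Bifidobacterium",
               "Butyrivibrio", "Parabacteroides")
CONTAM_GENERA <- c("Ralstonia", "Sphingomonas", "Pseudomonas", "Burkholderia",
                   "Bradyrhizobium", "Methylobacterium", "Acinetobacter",
                   "Cutibacterium", "Corynebacterium", "Delftia", "Comamonas",
                   "Stenotrophomonas", "Herbaspirillum", "Aquabacterium",
                   "Variovorax", "Pelomonas", "Phyllobacterium",
                   "Mesorhizobium", "Novosphingobium", "Caulobacter")

#' Simulation configuration
#'
#' Defaults regenerate the canonical two-batch benchmark design: 10 true
#' genera plus 100 contaminant features (110 features), 5 samples + 2
#' DNA-extraction negative controls per batch, two technical replicate
#' pairs spanning the batches.
#'
#' @param n_contaminant_features number of contaminant features shared by
#'   both batches (values regenerated per batch; default 100).
#' @param replicate_count_range uniform range for technical-replicate base
#'   counts (default c(10, 100); the base draw is shared by the two members
#'   of a pair, measurement noise is not).
#' @param replicate_noise_sd Gaussian noise sd on replicate counts (default 10).
#' @param batch1_count_range,batch2_count_range uniform ranges for
#'   non-replicate sample counts (defaults c(20, 90) and c(30, 100)).
#' @param nonrep_noise_sd Gaussian noise sd on non-replicate counts (default 10).
#' @param contaminant_range uniform range for contaminant base counts
#'   (default c(0, 20)), drawn per sample and per control.
#' @param contaminant_noise_sd Gaussian noise sd on contaminant counts
#'   (default 2).
#' @param disease_scale,healthy_scale uniform ranges for the group scaling
#'   applied to the five differential genera (defaults c(1.5, 2.5) and
#'   c(0.5, 0.8)).
#' @param leakage_nb size and success probability of the negative-binomial
#'   batch leakage vector (default c(1, 0.5): number of failures before the
#'   first success with success probability 0.5, mean 1).
#' @param sample_leak_scale,control_leak_scale uniform ranges for the
#'   per-sample and per-control leakage scaling (defaults c(1, 1.5) and
#'   c(2, 3); controls receive the stronger dose).
#' @param zero_relax multiplier relaxing the zero-inflation probabilities
#'   (default 0.6).
#' @param seed master seed; the true-signal stream uses `seed`, batch 1's
#'   contaminant stream `seed + 1`, batch 2's `seed + 2` unless overridden.
#' @param seed_batch1,seed_batch2 optional explicit per-batch contaminant
#'   stream seeds (the batch streams also drive leakage and
#'   zero-inflation of the batch's rows).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_contaminant_features = 100,
                       replicate_count_range = c(10, 100),
                       replicate_noise_sd = 10,
                       batch1_count_range = c(20, 90),
                       batch2_count_range = c(30, 100),
                       nonrep_noise_sd = 10,
                       contaminant_range = c(0, 20),
                       contaminant_noise_sd = 2,
                       disease_scale = c(1.5, 2.5),
                       healthy_scale = c(0.5, 0.8),
                       leakage_nb = c(size = 1, prob = 0.5),
                       sample_leak_scale = c(1, 1.5),
                       control_leak_scale = c(2, 3),
                       zero_relax = 0.6,
                       seed = 1,
                       seed_batch1 = NULL,
                       seed_batch2 = NULL) {
  cfg <- list(n_contaminant_features = n_contaminant_features,
              replicate_count_range = replicate_count_range,
              replicate_noise_sd = replicate_noise_sd,
              batch1_count_range = batch1_count_range,
              batch2_count_range = batch2_count_range,
              nonrep_noise_sd = nonrep_noise_sd,
              contaminant_range = contaminant_range,
              contaminant_noise_sd = contaminant_noise_sd,
              disease_scale = disease_scale,
              healthy_scale = healthy_scale,
              leakage_nb = unname(leakage_nb),
              sample_leak_scale = sample_leak_scale,
              control_leak_scale = control_leak_scale,
              zero_relax = zero_relax,
              seed = as.integer(seed),
              seed_batch1 = as.integer(seed_batch1 %||% (seed + 1)),
              seed_batch2 = as.integer(seed_batch2 %||% (seed + 2)))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character(0)
  chk_range <- function(name) {
    v <- cfg[[name]]
    if (length(v) != 2 || v[1] > v[2]) {
      problems <<- c(problems, paste0(name, " must be c(low, high) with low <= high"))
    }
  }
  for (nm in c("replicate_count_range", "batch1_count_range",
               "batch2_count_range", "contaminant_range", "disease_scale",
               "healthy_scale", "sample_leak_scale", "control_leak_scale")) {
    chk_range(nm)
  }
  if (cfg$n_contaminant_features < 1) {
    problems <- c(problems, "n_contaminant_features must be >= 1")
  }
  if (any(c(cfg$replicate_noise_sd, cfg$nonrep_noise_sd,
            cfg$contaminant_noise_sd) < 0)) {
    problems <- c(problems, "noise sds must be non-negative")
  }
  if (cfg$zero_relax < 0 || cfg$zero_relax > 1) {
    problems <- c(problems, "zero_relax must lie in [0, 1]")
  }
  if (cfg$leakage_nb[1] <= 0 || cfg$leakage_nb[2] <= 0 ||
      cfg$leakage_nb[2] > 1) {
    problems <- c(problems, "leakage_nb must be (size > 0, 0 < prob <= 1)")
  }
  if (length(problems)) {
    abort(paste0("Invalid simulation config:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  invisible(cfg)
}

#' Probabilistic zero-inflation of a count matrix
#'
#' Within each sample (row), the probability that a count is zeroed is
#' `relax * (1 - x / max(x))`: the row maximum is never zeroed, and small
#' counts are zeroed most often. Each cell is zeroed by an independent
#' Bernoulli draw. All-zero rows pass through unchanged.
#'
#' @param m numeric matrix (samples x features).
#' @param relax relaxation multiplier in `[0, 1]` (default 0.6).
#' @return matrix of the same shape.
#' @export
zero_inflate <- function(m, relax = 0.6) {
  stopifnot(is.matrix(m), relax >= 0, relax <= 1)
  for (i in seq_len(nrow(m))) {
    mx <- max(m[i, ])
    if (mx <= 0) next
    p <- relax * (1 - m[i, ] / mx)
    drop <- stats::rbinom(ncol(m), 1, p) == 1
    m[i, drop] <- 0
  }
  m
}

#' Simulate the two-batch benchmark dataset
#'
#' Per batch, generation proceeds: (1) true-genus base counts (replicate
#' pairs share a uniform base draw plus member-specific Gaussian noise;
#' non-replicates draw from the batch's uniform range plus noise);
#' (2) group scaling of the five differential genera; (3) contaminant base
#' counts per sample and control; (4) a negative-binomial leakage vector
#' added to samples and, with a larger scale, to controls of the batch;
#' (5) clamping of negatives and rounding; (6) zero-inflation. Controls
#' carry contaminant signal only.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` object: `counts` (count tibble), `sheet`
#'   (sample sheet with batch, group, replicate ids), `taxonomy`, `truth`
#'   (`feature_id`, `contaminant`, `differential`, `genus`), `config`.
#' @export
simulate_multibatch <- function(config = sim_config()) {
  validate_sim_config(config)
  nt <- length(TRUE_GENERA)
  ncf <- config$n_contaminant_features
  contam_ids <- sprintf("contam_%03d", seq_len(ncf))
  feats <- c(TRUE_GENERA, contam_ids)

  b1_samp <- c("S1A", "S2A", "S3", "S4", "S5")
  b2_samp <- c("S1B", "S2B", "S6", "S7", "S8")
  b1_ctrl <- c("NC1_B1", "NC2_B1")
  b2_ctrl <- c("NC1_B2", "NC2_B2")
  healthy <- c("S1A", "S2A", "S1B", "S2B", "S7", "S8")

  sheet <- tibble::tibble(
    sample_id = c(b1_samp, b1_ctrl, b2_samp, b2_ctrl),
    is_control = rep(c(FALSE, TRUE, FALSE, TRUE), c(5, 2, 5, 2)),
    group = NA_character_,
    batch = rep(c("batch1", "batch2"), each = 7),
    replicate_id = NA_character_
  )
  sheet$group <- ifelse(sheet$is_control, "control",
                        ifelse(sheet$sample_id %in% healthy,
                               "healthy", "disease"))
  sheet$replicate_id[sheet$sample_id %in% c("S1A", "S1B")] <- "S1"
  sheet$replicate_id[sheet$sample_id %in% c("S2A", "S2B")] <- "S2"

  all_ids <- sheet$sample_id
  m_true <- matrix(0, length(all_ids), nt,
                   dimnames = list(all_ids, TRUE_GENERA))

  # --- true-signal stream ---
  set.seed(config$seed)
  rr <- config$replicate_count_range
  base_rep <- matrix(runif(2 * nt, rr[1], rr[2]), nrow = 2,
                     dimnames = list(c("S1", "S2"), TRUE_GENERA))
  for (sid in c("S1A", "S1B", "S2A", "S2B")) {
    pair <- substr(sid, 1, 2)
    m_true[sid, ] <- base_rep[pair, ] + rnorm(nt, 0, config$replicate_noise_sd)
  }
  for (sid in c("S3", "S4", "S5")) {
    br <- config$batch1_count_range
    m_true[sid, ] <- runif(nt, br[1], br[2]) + rnorm(nt, 0, config$nonrep_noise_sd)
  }
  for (sid in c("S6", "S7", "S8")) {
    br <- config$batch2_count_range
    m_true[sid, ] <- runif(nt, br[1], br[2]) + rnorm(nt, 0, config$nonrep_noise_sd)
  }
  da_idx <- match(DA_GENERA, TRUE_GENERA)
  for (sid in setdiff(all_ids, c(b1_ctrl, b2_ctrl))) {
    sc <- if (sheet$group[sheet$sample_id == sid] == "disease") {
      runif(length(da_idx), config$disease_scale[1], config$disease_scale[2])
    } else {
      runif(length(da_idx), config$healthy_scale[1], config$healthy_scale[2])
    }
    m_true[sid, da_idx] <- m_true[sid, da_idx] * sc
  }
  m_true[c(b1_ctrl, b2_ctrl), ] <- 0  # controls carry no biological signal

  # --- per-batch contaminant streams ---
  gen_batch <- function(samp, ctrl, batch_seed) {
    set.seed(batch_seed)
    ids <- c(samp, ctrl)
    cr <- config$contaminant_range
    contam <- matrix(runif(length(ids) * ncf, cr[1], cr[2]) +
                       rnorm(length(ids) * ncf, 0, config$contaminant_noise_sd),
                     length(ids), ncf, dimnames = list(ids, contam_ids))
    leak <- rnbinom(ncf, size = config$leakage_nb[1],
                    prob = config$leakage_nb[2])
    for (sid in samp) {
      u <- runif(1, config$sample_leak_scale[1], config$sample_leak_scale[2])
      contam[sid, ] <- contam[sid, ] + leak * u
    }
    for (cid in ctrl) {
      v <- runif(1, config$control_leak_scale[1], config$control_leak_scale[2])
      contam[cid, ] <- contam[cid, ] + leak * v
    }
    full <- cbind(m_true[ids, , drop = FALSE], contam)
    full[full < 0] <- 0
    full <- round(full)
    zero_inflate(full, relax = config$zero_relax)
  }
  m1 <- gen_batch(b1_samp, b1_ctrl, config$seed_batch1)
  m2 <- gen_batch(b2_samp, b2_ctrl, config$seed_batch2)
  counts <- as_count_tbl(rbind(m1, m2)[all_ids, , drop = FALSE])

  genus <- c(TRUE_GENERA,
             rep_len(CONTAM_GENERA, ncf))
  taxonomy <- tibble::tibble(feature_id = feats,
                             kingdom = "Bacteria",
                             phylum = NA_character_, class = NA_character_,
                             order = NA_character_, family = NA_character_,
                             genus = genus, species = NA_character_)
  truth <- tibble::tibble(feature_id = feats,
                          contaminant = feats %in% contam_ids,
                          differential = feats %in% DA_GENERA,
                          genus = genus)
  structure(list(counts = counts, sheet = sheet, taxonomy = taxonomy,
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$counts), " rows (",
      sum(x$sheet$is_control), " controls) x ", ncol(x$counts) - 1L,
      " features; ", sum(x$truth$contaminant), " contaminant features\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `truth.tsv` and
#' `config.yaml` (including the seed) so the run is fully reproducible.
#'
#' @param sim a `sim_dataset`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(sim$sheet, file.path(out_dir, "metadata.tsv"))
  readr::write_tsv(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir directory written by [write_simulation()].
#' @return a `sim_dataset`.
#' @export
read_simulation <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$leakage_nb <- unlist(cfg$leakage_nb)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  structure(list(counts = read_count_table(file.path(dir, "counts.tsv")),
                 sheet = read_sample_sheet(file.path(dir, "metadata.tsv")),
                 taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' Simulate a single batch from the contamination mixture model
#'
#' Generates one plate batch directly from the generative model fitted by
#' [fit_mixture_em()]: known contaminant profile, per-sample intrinsic
#' profiles and contamination fractions, and (optionally) well-to-well
#' leakage of neighbouring sample material into the controls. Used for
#' parameter-recovery checks and leakage-warning tests.
#'
#' @param n_samples,n_controls batch composition (defaults 10 and 2).
#' @param n_features number of features (default 40); the contaminant
#'   profile occupies the first half, intrinsic profiles the second half
#'   with a small overlap.
#' @param contamination per-sample contamination fractions (recycled;
#'   default 0.3).
#' @param leakage per-control leakage fraction in `[0, 1)` (default 0).
#' @param reads,control_reads read depths (defaults 5e4 and 5e3).
#' @param seed RNG seed.
#' @return list with `counts`, `sheet` (wells included), `truth`
#'   (list with `contamination`, `leakage`, `gamma`).
#' @export
simulate_mixture_batch <- function(n_samples = 10, n_controls = 2,
                                   n_features = 40, contamination = 0.3,
                                   leakage = 0, reads = 5e4,
                                   control_reads = 5e3, seed = 1) {
  set.seed(seed)
  h <- floor(n_features / 2)
  gam <- rep(0, n_features)
  gam[seq_len(h)] <- stats::rgamma(h, shape = 2)
  gam <- gam / sum(gam)
  p <- rep_len(contamination, n_samples)
  samp_ids <- sprintf("S%02d", seq_len(n_samples))
  ctrl_ids <- sprintf("NC%d", seq_len(n_controls))
  feats <- sprintf("f%03d", seq_len(n_features))
  intr_support <- (h - 2):n_features  # slight overlap with the contaminant support
  r <- matrix(0, n_samples, n_features, dimnames = list(samp_ids, feats))
  for (i in seq_len(n_samples)) {
    ri <- rep(0, n_features)
    ri[intr_support] <- stats::rgamma(length(intr_support), shape = 2)
    r[i, ] <- ri / sum(ri)
  }
  sheet <- tibble::tibble(sample_id = c(samp_ids, ctrl_ids),
                          is_control = rep(c(FALSE, TRUE),
                                           c(n_samples, n_controls)),
                          group = ifelse(rep(c(FALSE, TRUE),
                                             c(n_samples, n_controls)),
                                         "control", "specimen"))
  layout <- assign_pseudo_wells(sheet, order = "vertical")
  m <- matrix(0, n_samples + n_controls, n_features,
              dimnames = list(c(samp_ids, ctrl_ids), feats))
  for (i in seq_len(n_samples)) {
    mix <- (1 - p[i]) * r[i, ] + p[i] * gam
    m[samp_ids[i], ] <- stats::rmultinom(1, reads, mix)
  }
  leak <- rep_len(leakage, n_controls)
  for (k in seq_len(n_controls)) {
    cid <- ctrl_ids[k]
    me <- layout[layout$sample_id == cid, ]
    nb <- layout[layout$sample_id %in% samp_ids &
                   abs(layout$well_row - me$well_row) <= 1 &
                   abs(layout$well_col - me$well_col) <= 1, ]
    s_c <- if (nrow(nb)) colMeans(r[nb$sample_id, , drop = FALSE]) else gam
    mix <- (1 - leak[k]) * gam + leak[k] * s_c
    m[cid, ] <- stats::rmultinom(1, control_reads, mix)
  }
  sheet$well <- layout$well[match(sheet$sample_id, layout$sample_id)]
  list(counts = as_count_tbl(m), sheet = sheet,
       truth = list(contamination = setNames(p, samp_ids),
                    leakage = setNames(leak, ctrl_ids), gamma = gam))
}
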
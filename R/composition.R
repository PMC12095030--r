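#' Composition-preserving decontamination with a per-batch mixture model
#'
#' Each batch is modelled as a two-level multinomial mixture. A biological
#' sample i with read total N_i draws its counts from
#' `Multinomial(N_i, (1 - p_i) r_i + p_i g)`, where `r_i` is the sample's
#' intrinsic composition, `g` the shared contaminant profile, and `p_i` the
#' sample's contamination fraction. A negative control c draws its counts
#' from `Multinomial(N_c, (1 - a_c) g + a_c s_c)`, where `a_c` is the
#' control's well-to-well leakage (the proportion of the control that
#' originates from biological samples) and `s_c` is the read-weighted mean
#' composition of the sample wells in the control's 8-neighbourhood on the
#' 96-well plate. The model is fitted by EM; the fitted per-read contaminant
#' posterior is then subtracted from each sample, removing the estimated
#' contaminant share of every count rather than whole features.
#'
#' @name composition-pipeline
NULL

#' Assign pseudo-wells on a 96-well plate
#'
#' When real well locations are unknown, samples are placed on the plate in
#' sheet order, assuming a common loading order: `vertical` fills
#' A1, B1, ..., H1, A2, ...; `horizontal` fills A1, A2, ..., A12, B1, ....
#' Assignment is per batch.
#'
#' @param sheet sample-sheet tibble.
#' @param order `"vertical"` (default) or `"horizontal"`.
#' @return plate-layout tibble: `sample_id`, `batch`, `well`, `well_row`,
#'   `well_col`, `provenance = "pseudo"`.
#' @export
assign_pseudo_wells <- function(sheet, order = c("vertical", "horizontal")) {
  order <- match.arg(order)
  batches <- dataset_batches(sheet)
  purrr::map_dfr(unique(batches), function(b) {
    ids <- sheet$sample_id[batches == b]
    if (length(ids) > 96) {
      abort(paste0("Batch '", b, "' has ", length(ids), " samples; a 96-well ",
                   "plate holds 96. Annotate plates as separate batches."))
    }
    k <- seq_along(ids) - 1L
    if (order == "vertical") {
      row <- k %% 8L + 1L; col <- k %/% 8L + 1L
    } else {
      row <- k %/% 12L + 1L; col <- k %% 12L + 1L
    }
    tibble::tibble(sample_id = ids, batch = b,
                   well = paste0(LETTERS[row], col),
                   well_row = row, well_col = col,
                   provenance = "pseudo")
  })
}

# layout for one batch: real wells when completely annotated, else pseudo
batch_layout <- function(sheet, order = "vertical") {
  if ("well" %in% names(sheet) && !anyNA(sheet$well)) {
    pw <- parse_well(sheet$well)
    tibble::tibble(sample_id = sheet$sample_id,
                   batch = dataset_batches(sheet),
                   well = pw$well, well_row = pw$well_row,
                   well_col = pw$well_col, provenance = "given")
  } else {
    assign_pseudo_wells(sheet, order = order)
  }
}

# sample wells Moore-adjacent (8-neighbourhood) to a control's well
neighbour_ids <- function(layout, control_id, sample_ids) {
  me <- layout[layout$sample_id == control_id, ]
  nb <- layout[layout$sample_id %in% sample_ids &
                 abs(layout$well_row - me$well_row) <= 1 &
                 abs(layout$well_col - me$well_col) <= 1 &
                 layout$sample_id != control_id, ]
  nb$sample_id
}

# high-mass features of the contaminant profile: the smallest set of
# evidence-backed features covering half of the profile's total mass
ridge_support <- function(gam, evidence) {
  cand <- which(evidence)
  if (!length(cand)) cand <- seq_along(gam)
  ord <- cand[order(gam[cand], decreasing = TRUE)]
  cum <- cumsum(gam[ord])
  ord[seq_len(max(1L, which(cum >= 0.5 * cum[length(cum)])[1]))]
}

#' Fit the per-batch contamination mixture by EM
#'
#' @param batch_counts count tibble for one batch (samples and controls).
#' @param sheet sample-sheet rows for the same samples.
#' @param layout plate-layout tibble (from [assign_pseudo_wells()] or real
#'   wells); defaults to pseudo-wells in sheet order.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @return a `mixture_fit` object: `gamma` (contaminant profile),
#'   `contamination` (per-sample fractions), `intrinsic` (per-sample
#'   profiles), `leakage` (per-control fractions), `posterior` (per-cell
#'   contaminant-origin probabilities), `loglik_trace`, `converged`.
#' @export
fit_mixture_em <- function(batch_counts, sheet, layout = NULL,
                           tol = 1e-6, max_iter = 200) {
  m <- count_matrix(batch_counts)
  sheet <- sheet[match(rownames(m), sheet$sample_id), ]
  is_ctrl <- sheet$is_control
  if (!any(is_ctrl)) {
    abort(paste0("The composition pipeline requires a negative control in ",
                 "every batch; without batch controls use the biomarker ",
                 "pipeline."))
  }
  if (all(is_ctrl)) abort("A batch cannot consist of controls only.")
  if (is.null(layout)) layout <- batch_layout(sheet)
  ctrl_ids <- rownames(m)[is_ctrl]
  samp_ids <- rownames(m)[!is_ctrl]
  p_feat <- ncol(m)
  N <- rowSums(m)
  feats <- colnames(m)

  trivial <- function() {
    z <- matrix(0, length(samp_ids), p_feat,
                dimnames = list(samp_ids, feats))
    r <- m[samp_ids, , drop = FALSE]
    r <- r / pmax(rowSums(r), 1)
    structure(list(
      gamma = setNames(rep(1 / p_feat, p_feat), feats),
      contamination = tibble::tibble(sample_id = samp_ids, p = 0),
      intrinsic = r,
      leakage = tibble::tibble(control_id = ctrl_ids, leakage = 0),
      posterior = z, loglik_trace = numeric(0), converged = TRUE,
      layout = layout), class = "mixture_fit")
  }
  if (sum(m[ctrl_ids, , drop = FALSE]) == 0) {
    inform("Controls carry zero reads; fitting trivial (no-contamination) model.")
    return(trivial())
  }

  Cs <- m[samp_ids, , drop = FALSE]
  Cc <- m[ctrl_ids, , drop = FALSE]
  Ns <- N[samp_ids]; Nc <- N[ctrl_ids]

  # initialization (deterministic). The likelihood is flat along the ridge
  # where a smaller contamination fraction is absorbed into the free
  # intrinsic profile, so EM stays near its starting point; the identified
  # solution is the ridge boundary -- the largest fraction that still
  # leaves every intrinsic abundance non-negative. Initialize there: per
  # sample, the minimum (count-stabilized) ratio of observed proportion to
  # contaminant proportion, over the high-mass half of the contaminant
  # profile where the ratio is least noisy.
  empty <- Ns == 0
  # boundary of the ridge from noisy count ratios: the minimum over m
  # candidate features systematically undershoots, so each ratio carries a
  # sqrt(2 log m) Poisson standard-error allowance (extreme-value
  # recentring of a minimum of m noisy values) before taking the minimum
  boundary_min <- function(cnt, total, prof, supp) {
    rho <- (cnt[supp] + 0.5) / (total * prof[supp])
    se <- sqrt(cnt[supp] + 0.5) / (total * prof[supp])
    min(rho + sqrt(2 * log(length(supp))) * se)
  }
  init_sample_side <- function(gam) {
    supp <- ridge_support(gam, colSums(Cc) > 0)
    p <- vapply(seq_along(samp_ids), function(i) {
      if (empty[i]) return(0)
      boundary_min(Cs[i, ], Ns[i], gam, supp)
    }, numeric(1))
    p <- setNames(pmin(pmax(p, 0), 1), samp_ids)
    resid <- pmax(Cs / pmax(Ns, 1) - outer(p, gam), 0)
    rs0 <- rowSums(resid)
    # keep (p, r) on the ridge: the intrinsic component must carry exactly
    # the residual mass, otherwise EM drifts away from the boundary
    p <- pmin(pmax(1 - rs0, 0), 0.999)
    r <- resid
    r[rs0 > 0, ] <- r[rs0 > 0, , drop = FALSE] / rs0[rs0 > 0]
    r[rs0 == 0, ] <- 1 / p_feat
    r[empty, ] <- 1 / p_feat
    p[empty] <- 0
    list(p = p, r = r)
  }
  gam <- colSums(Cc) + 0.5
  gam <- gam / sum(gam)
  init <- init_sample_side(gam)
  p <- init$p; r <- init$r

  # control-side leakage source: read-weighted mean of the neighbouring
  # wells' initial intrinsic profiles, held fixed during EM (keeping the
  # iteration an exact EM with a non-decreasing log-likelihood)
  S <- matrix(0, length(ctrl_ids), p_feat, dimnames = list(ctrl_ids, feats))
  has_nbr <- setNames(rep(FALSE, length(ctrl_ids)), ctrl_ids)
  for (cid in ctrl_ids) {
    nb <- neighbour_ids(layout, cid, samp_ids)
    if (!length(nb)) next
    # weight neighbours by their intrinsic (non-contaminant) reads; a
    # neighbourhood that is essentially pure contamination offers no
    # estimable leakage source, so leakage stays fixed at zero there
    w_nb <- Ns[nb] * (1 - p[nb])
    if (sum(w_nb) / max(sum(Ns[nb]), 1) < 0.05) next
    sc <- colSums(w_nb * r[nb, , drop = FALSE])
    if (sum(sc) <= 0) next
    S[cid, ] <- sc / sum(sc)
    has_nbr[cid] <- TRUE
  }
  # leakage fractions start at their own ridge boundary: the largest
  # fraction of the neighbour profile subtractable from the control while
  # leaving the contaminant component non-negative
  alpha <- vapply(seq_along(ctrl_ids), function(k) {
    if (!has_nbr[k]) return(0)
    sj <- which(S[k, ] * Nc[k] >= 1)
    if (!length(sj)) return(0)
    boundary_min(Cc[k, ], Nc[k], S[k, ], sj)
  }, numeric(1))
  alpha <- setNames(pmin(pmax(alpha, 0), 0.95), ctrl_ids)

  # subtract the initial leakage component from the pooled control profile
  # (otherwise the leak mass is baked into the contaminant profile and the
  # fit settles with the leakage attributed to contamination), then rebuild
  # the sample-side start against the cleaned profile
  if (any(alpha > 0)) {
    gam <- colSums(pmax(Cc - alpha * (Nc * S), 0)) + 0.5
    gam <- gam / sum(gam)
    init <- init_sample_side(gam)
    p <- init$p; r <- init$r
  }

  loglik <- function(p, r, gam, alpha) {
    mix_s <- (1 - p) * r + outer(p, gam)
    mix_c <- (1 - alpha) * matrix(gam, length(ctrl_ids), p_feat,
                                  byrow = TRUE) + alpha * S
    ll_cell <- function(cnt, prob) {
      use <- cnt > 0
      sum(cnt[use] * log(prob[use]))
    }
    ll_cell(Cs, mix_s) + ll_cell(Cc, mix_c)
  }

  trace <- numeric(0)
  converged <- FALSE
  z <- matrix(0, length(samp_ids), p_feat, dimnames = list(samp_ids, feats))
  for (it in seq_len(max_iter)) {
    # E-step
    num_z <- outer(p, gam)
    den_z <- (1 - p) * r + num_z
    z <- ifelse(den_z > 0, num_z / den_z, 0)
    num_w <- alpha * S
    den_w <- (1 - alpha) * matrix(gam, length(ctrl_ids), p_feat,
                                  byrow = TRUE) + num_w
    w <- ifelse(den_w > 0, num_w / den_w, 0)
    # M-step
    p_new <- rowSums(Cs * z) / pmax(Ns, 1)
    p_new[empty] <- 0
    r_new <- Cs * (1 - z)
    rs <- rowSums(r_new)
    keep <- rs > 0
    r_new[keep, ] <- r_new[keep, ] / rs[keep]
    r_new[!keep, ] <- r[!keep, ]
    g_new <- colSums(Cc * (1 - w)) + colSums(Cs * z)
    if (sum(g_new) > 0) g_new <- g_new / sum(g_new) else g_new <- gam
    a_new <- rowSums(Cc * w) / pmax(Nc, 1)
    a_new[!has_nbr] <- 0
    p <- p_new; r <- r_new; gam <- g_new; alpha <- a_new
    trace <- c(trace, loglik(p, r, gam, alpha))
    if (it > 1) {
      rel <- abs(trace[it] - trace[it - 1]) /
        max(abs(trace[it - 1]), .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warn("EM reached the iteration limit before converging.")
  }
  # final posterior under the converged parameters
  num_z <- outer(p, gam)
  den_z <- (1 - p) * r + num_z
  z <- ifelse(den_z > 0, num_z / den_z, 0)
  dimnames(z) <- list(samp_ids, feats)
  structure(list(
    gamma = setNames(gam, feats),
    contamination = tibble::tibble(sample_id = samp_ids, p = unname(p)),
    intrinsic = r,
    leakage = tibble::tibble(control_id = ctrl_ids, leakage = unname(alpha)),
    posterior = z, loglik_trace = trace, converged = converged,
    layout = layout), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", nrow(x$contamination), " samples, ",
      nrow(x$leakage), " controls, ", length(x$gamma), " features\n",
      "  contamination fractions: ",
      paste(format(x$contamination$p, digits = 3), collapse = ", "), "\n",
      "  converged: ", x$converged, " (", length(x$loglik_trace),
      " iterations)\n", sep = "")
  invisible(x)
}

#' Subtract the estimated contaminant reads from a batch
#'
#' Each count is multiplied by its posterior probability of intrinsic origin
#' `(1 - z_ij)` and, by default, rounded half-to-even back to integers.
#' Controls are excluded from the output.
#'
#' @param batch_counts count tibble for the batch.
#' @param fit a `mixture_fit` for the same batch.
#' @param round_counts round to integers (default TRUE); FALSE keeps
#'   fractional counts.
#' @return decontaminated count tibble (samples only); never exceeds the
#'   input element-wise.
#' @export
decontaminate_batch <- function(batch_counts, fit, round_counts = TRUE) {
  if (!fit$converged) {
    warn("Decontaminating with a fit that hit the iteration limit.")
  }
  m <- count_matrix(batch_counts)
  samp_ids <- rownames(fit$posterior)
  out <- m[samp_ids, , drop = FALSE] * (1 - fit$posterior)
  if (round_counts) out <- round(out)
  as_count_tbl(out)
}

#' Per-control well-to-well leakage
#'
#' Extracts the fitted proportion of each negative control that originates
#' from neighbouring biological samples. Any control strictly above the
#' 0.10 warning level triggers an advisory to obtain real well locations
#' and rerun the composition pipeline with them.
#'
#' @param fit a `mixture_fit`.
#' @param warn_threshold leakage level above which to warn (default 0.10,
#'   strict inequality).
#' @return tibble (`control_id`, `leakage`) with attribute
#'   `"leakage_warning"` (logical).
#' @export
estimate_well_leakage <- function(fit, warn_threshold = 0.10) {
  out <- fit$leakage
  flag <- any(out$leakage > warn_threshold)
  if (flag) {
    warn(paste0("Estimated well-to-well leakage exceeds ", warn_threshold,
                " for control(s): ",
                paste(out$control_id[out$leakage > warn_threshold],
                      collapse = ", "),
                ". Obtain the plate well locations for these data and run ",
                "them through the composition pipeline with real wells."))
  }
  attr(out, "leakage_warning") <- flag
  out
}

#' Run the composition-estimation pipeline
#'
#' Splits the dataset by batch, fits the contamination mixture and removes
#' the estimated contaminant reads in each batch independently, then
#' reassembles the samples in their original order. Pseudo-wells are
#' assigned automatically for batches without well annotations.
#'
#' @param dataset a `lobiclean_dataset`; every batch must contain at least
#'   one negative control.
#' @param well_order pseudo-well fill order (default `"vertical"`).
#' @param round_counts round decontaminated counts to integers (default TRUE).
#' @param tol,max_iter EM controls passed to [fit_mixture_em()].
#' @return a `composition_result` object: `filtered` (count tibble, samples
#'   only), `fits` (per batch), `fl` (filtering loss), `leakage`
#'   (per-control tibble), `leakage_warning`.
#' @export
run_composition <- function(dataset, well_order = c("vertical", "horizontal"),
                            round_counts = TRUE, tol = 1e-6, max_iter = 200) {
  well_order <- match.arg(well_order)
  sheet <- dataset$sheet
  batches <- dataset_batches(sheet)
  no_ctrl <- setdiff(unique(batches), unique(batches[sheet$is_control]))
  if (length(no_ctrl)) {
    abort(paste0("Batch(es) without a negative control: ",
                 paste(no_ctrl, collapse = ", "),
                 ". The composition pipeline requires controls in every ",
                 "batch; consider the biomarker pipeline."))
  }
  fits <- list()
  pieces <- list()
  for (b in unique(batches)) {
    in_b <- batches == b
    bc <- dataset$counts[in_b, , drop = FALSE]
    bs <- sheet[in_b, , drop = FALSE]
    layout <- batch_layout(bs, order = well_order)
    fit <- fit_mixture_em(bc, bs, layout, tol = tol, max_iter = max_iter)
    fits[[b]] <- fit
    pieces[[b]] <- decontaminate_batch(bc, fit, round_counts = round_counts)
  }
  filtered <- dplyr::bind_rows(pieces)
  samp_order <- dataset$counts$sample_id[!sheet$is_control]
  filtered <- filtered[match(samp_order, filtered$sample_id), , drop = FALSE]
  pre <- dataset$counts[!sheet$is_control, , drop = FALSE]
  fl_res <- filtering_loss(pre, filtered)
  leakage <- purrr::map_dfr(names(fits), function(b) {
    dplyr::mutate(fits[[b]]$leakage, batch = b, .before = 1)
  })
  flag <- any(leakage$leakage > 0.10)
  for (b in names(fits)) estimate_well_leakage(fits[[b]])
  structure(list(filtered = filtered, fits = fits, fl = fl_res,
                 leakage = leakage, leakage_warning = flag),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  removed <- sum(count_matrix(x$filtered))
  cat("<composition_result> ", nrow(x$filtered), " samples across ",
      length(x$fits), " batch(es)\n  filtering loss: ",
      format(x$fl$fl, digits = 4),
      "\n  leakage warning: ", x$leakage_warning, "\n", sep = "")
  invisible(x)
}
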
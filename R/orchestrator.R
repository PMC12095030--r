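#' Run a decontamination pipeline end to end
#'
#' Single entry point implementing the pipeline decision flow: the
#' `"biomarker"` goal (stringent consensus whole-feature removal; requires
#' at least two batches) or the `"orig-composition"` goal (mixture-model
#' partial read removal; requires a negative control in every batch, with
#' pseudo-wells assigned automatically when the sheet carries no well
#' locations). The filtering loss is always computed and reported. When
#' `out_dir` is given, a machine-readable `result.json` (filtering loss,
#' goal, parameters, package version, input checksums), the filtered count
#' table and a human-readable `run.log` are written.
#'
#' @param dataset a `lobiclean_dataset` from [align_dataset()].
#' @param goal `"biomarker"` or `"orig-composition"`.
#' @param taxonomy,blocklist optional inputs enabling the biomarker
#'   blocklist step.
#' @param threshold consensus threshold for the biomarker goal (default 1).
#' @param alpha batch-test significance level (default 0.05).
#' @param prevalence_threshold control-prevalence p-value cut (default 0.1).
#' @param max_discordant_fraction replicate-discordance cut (default 1.0).
#' @param well_order pseudo-well fill order for the composition goal.
#' @param round_counts round decontaminated counts (composition goal).
#' @param out_dir optional output directory.
#' @return a `biomarker_result` or `composition_result`.
#' @export
run_pipeline <- function(dataset,
                         goal = c("biomarker", "orig-composition"),
                         taxonomy = NULL, blocklist = NULL,
                         threshold = 1, alpha = 0.05,
                         prevalence_threshold = 0.1,
                         max_discordant_fraction = 1.0,
                         well_order = c("vertical", "horizontal"),
                         round_counts = TRUE, out_dir = NULL) {
  goal <- match.arg(goal)
  well_order <- match.arg(well_order)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  note("goal: ", goal, "; ", nrow(dataset$counts), " samples x ",
       ncol(dataset$counts) - 1L, " features")
  params <- list(goal = goal, threshold = threshold, alpha = alpha,
                 prevalence_threshold = prevalence_threshold,
                 max_discordant_fraction = max_discordant_fraction,
                 well_order = well_order, round_counts = round_counts)
  result <- withCallingHandlers(
    if (goal == "biomarker") {
      run_biomarker(dataset, taxonomy = taxonomy, blocklist = blocklist,
                    threshold = threshold, alpha = alpha,
                    prevalence_threshold = prevalence_threshold,
                    max_discordant_fraction = max_discordant_fraction)
    } else {
      run_composition(dataset, well_order = well_order,
                      round_counts = round_counts)
    },
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      note(sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  if (goal == "biomarker") {
    note("removed ", length(result$removed_features), " features; fl = ",
         format(result$fl$fl, digits = 4))
  } else {
    note("fl = ", format(result$fl$fl, digits = 4),
         "; leakage warning: ", result$leakage_warning)
    if (result$leakage_warning) {
      warn(paste0("Well-to-well leakage above 0.10 detected. Obtain the ",
                  "plate well locations for these data and rerun the ",
                  "composition pipeline with real wells."))
    }
  }
  if (!is.null(out_dir)) {
    write_run_outputs(dataset, result, params, out_dir, log_lines)
  }
  result
}

write_run_outputs <- function(dataset, result, params, out_dir, log_lines) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(result$filtered, file.path(out_dir, "filtered_counts.tsv"))
  info <- list(
    fl = result$fl$fl,
    goal = params$goal,
    parameters = params,
    tool = "lobiclean",
    version = as.character(utils::packageVersion("lobiclean")),
    input_checksums = list(counts = rlang::hash(dataset$counts),
                           sheet = rlang::hash(dataset$sheet))
  )
  if (inherits(result, "biomarker_result")) {
    writeLines(result$removed_features,
               file.path(out_dir, "removed_features.txt"))
    sm <- result$step_matrix
    for (fl in result$flags) {
      sm[[paste0("score_", step_name(fl))]] <- fl$score
    }
    readr::write_tsv(sm, file.path(out_dir, "step_matrix.tsv"))
    if (length(result$flags) >= 2) {
      readr::write_tsv(step_overlap_summary(result$flags),
                       file.path(out_dir, "overlap_summary.tsv"))
    }
    info$removed_features <- length(result$removed_features)
    info$threshold <- result$threshold
  } else {
    fits <- purrr::map(result$fits, function(f) {
      list(gamma = unname(f$gamma),
           contamination = setNames(as.list(f$contamination$p),
                                    f$contamination$sample_id),
           leakage = setNames(as.list(f$leakage$leakage),
                              f$leakage$control_id),
           converged = f$converged)
    })
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    info$leakage_warning <- result$leakage_warning
  }
  jsonlite::write_json(info, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
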
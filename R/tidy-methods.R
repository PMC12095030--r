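#' Tidiers and plots for lobiclean result objects
#'
#' `tidy()` returns the per-feature or per-sample detail of a result as a
#' tibble, `glance()` a one-row summary, and `autoplot()` a ggplot2 figure.
#'
#' @name lobiclean-tidiers
NULL

#' @describeIn lobiclean-tidiers per-feature step verdicts (long format).
#' @param x a result object.
#' @param ... unused.
#' @method tidy biomarker_result
#' @export
tidy.biomarker_result <- function(x, ...) {
  purrr::map_dfr(x$flags, function(fl) {
    tibble::tibble(feature_id = fl$feature_id, step = step_name(fl),
                   flagged = fl$flagged, score = fl$score)
  }) |>
    dplyr::left_join(
      tibble::tibble(feature_id = x$step_matrix$feature_id,
                     removed = x$step_matrix$feature_id %in% x$removed_features),
      by = "feature_id")
}

#' @describeIn lobiclean-tidiers one-row biomarker-run summary.
#' @method glance biomarker_result
#' @export
glance.biomarker_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$step_matrix),
                 n_removed = length(x$removed_features),
                 n_steps = length(x$flags),
                 threshold = x$threshold,
                 fl = x$fl$fl)
}

#' @describeIn lobiclean-tidiers bar chart of step-combination overlap counts.
#' @param object a result object.
#' @method autoplot biomarker_result
#' @export
autoplot.biomarker_result <- function(object, ...) {
  ov <- step_overlap_summary(object$flags)
  ov <- ov[ov$n > 0, , drop = FALSE]
  ggplot2::ggplot(ov, ggplot2::aes(
    x = stats::reorder(.data$combination, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "flagged by", y = "features",
                  title = "Contaminant flags by step combination") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn lobiclean-tidiers per-sample contamination fractions of a fit.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$contamination, id = .data$sample_id, role = "sample",
                     fraction = .data$p),
    dplyr::transmute(x$leakage, id = .data$control_id, role = "control",
                     fraction = .data$leakage))
}

#' @describeIn lobiclean-tidiers one-row EM fit summary.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$contamination),
                 n_controls = nrow(x$leakage),
                 iterations = length(x$loglik_trace),
                 loglik = if (length(x$loglik_trace))
                   x$loglik_trace[length(x$loglik_trace)] else NA_real_,
                 converged = x$converged,
                 max_leakage = max(c(x$leakage$leakage, 0)))
}

#' @describeIn lobiclean-tidiers contamination fractions and control leakage.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$fraction,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.10, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "estimated fraction",
                  title = "Contamination fractions and control leakage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn lobiclean-tidiers per-sample reads removed by the composition run.
#' @method tidy composition_result
#' @export
tidy.composition_result <- function(x, ...) {
  post <- count_matrix(x$filtered)
  tibble::tibble(sample_id = rownames(post),
                 reads_post = rowSums(post)) |>
    dplyr::left_join(
      purrr::map_dfr(names(x$fits), function(b) {
        f <- x$fits[[b]]
        tibble::tibble(sample_id = f$contamination$sample_id, batch = b,
                       contamination = f$contamination$p)
      }), by = "sample_id")
}

#' @describeIn lobiclean-tidiers one-row composition-run summary.
#' @method glance composition_result
#' @export
glance.composition_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$filtered),
                 n_batches = length(x$fits),
                 fl = x$fl$fl,
                 leakage_warning = x$leakage_warning,
                 max_leakage = max(c(x$leakage$leakage, 0)))
}

#' @describeIn lobiclean-tidiers per-sample contamination estimates across batches.
#' @method autoplot composition_result
#' @export
autoplot.composition_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$contamination,
                                  fill = .data$batch)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contamination fraction",
                  title = "Estimated per-sample contamination") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn lobiclean-tidiers one-row filtering-loss summary.
#' @method glance filtering_loss
#' @export
glance.filtering_loss <- function(x, ...) {
  tibble::tibble(fl = x$fl, pre_frob_sq = x$pre_frob_sq,
                 post_frob_sq = x$post_frob_sq)
}
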
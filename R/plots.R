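#' Plot a cut-off sweep
#'
#' For a [sweep_count()] / [sweep_mean()] result, draws the empirical ROC
#' curve (1 - specificity vs sensitivity) with the Youden-optimal
#' operating point highlighted.
#'
#' @param object A `fat_sweep` tibble.
#' @param reader Which reader view to draw (`"avg"`, `"1"`, `"2"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fat_sweep
#' @export
autoplot.fat_sweep <- function(object, reader = "avg", ...) {
  rows <- object[object$reader == reader & !is.na(object$youden), ]
  best <- youden_select(object, reader)
  ggplot2::ggplot(rows, ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = best, colour = "red", size = 2.5) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s-statistic ROC (reader %s)",
                      attr(object, "statistic"), reader),
      subtitle = sprintf("Youden-optimal cut-off %.4g (J = %.2f)",
                         best$threshold, best$youden)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves for both subject-level statistics
#'
#' Convenience wrapper running [sweep_mean()] and [sweep_count()] and
#' overlaying their ROC curves for one reader view.
#'
#' @param cohort A cohort tibble.
#' @param params A [score_params()] object.
#' @param reader `"avg"`, `"1"`, or `"2"`.
#' @return A ggplot object.
#' @export
plot_roc <- function(cohort, params = score_params(), reader = "avg") {
  both <- dplyr::bind_rows(
    dplyr::mutate(sweep_mean(cohort, params), statistic = "mean PDFF"),
    dplyr::mutate(sweep_count(cohort, params), statistic = "ROI count > tau")
  )
  rows <- both[both$reader == reader & !is.na(both$youden), ]
  ggplot2::ggplot(rows, ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity,
                                     colour = .data$statistic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Statistic",
                  title = sprintf("Empirical ROC (reader %s)", reader)) +
    ggplot2::theme_minimal()
}

#' Subject-level mean PDFF by diagnosis group
#'
#' Box-and-jitter display of the per-subject mean PDFF for one reader,
#' the visual companion of the intergroup comparison table.
#'
#' @param cohort A cohort tibble.
#' @param reader 1 or 2.
#' @return A ggplot object.
#' @export
plot_group_pdff <- function(cohort, reader = 1L) {
  cohort <- validate_cohort(cohort)
  d <- tibble::tibble(
    diagnosis = cohort$diagnosis,
    mean_pdff = rowMeans(grid_matrix(cohort, reader))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diagnosis, y = .data$mean_pdff)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.55) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "Subject mean PDFF (%)",
                  title = sprintf("Mean PDFF by diagnosis (reader %d)", reader)) +
    ggplot2::theme_minimal()
}
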
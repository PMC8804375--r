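#' 2x2 confusion counts with axSpA as the positive class
#'
#' @param prediction Logical vector of positive-MRI calls, one per subject.
#' @param truth Logical vector: `TRUE` for axSpA cases.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
confusion_counts <- function(prediction, truth) {
  if (length(prediction) != length(truth)) {
    stop("prediction and truth must cover the same subjects", call. = FALSE)
  }
  if (anyNA(prediction) || anyNA(truth)) {
    stop("prediction and truth must be non-missing", call. = FALSE)
  }
  prediction <- as.logical(prediction); truth <- as.logical(truth)
  tibble::tibble(
    tp = sum(prediction & truth),
    fp = sum(prediction & !truth),
    fn = sum(!prediction & truth),
    tn = sum(!prediction & !truth)
  )
}

#' Diagnostic accuracy metrics from 2x2 counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive and
#' negative predictive values, and the Youden index
#' (sensitivity + specificity - 1). A metric whose denominator is zero is
#' reported as `NA`, never coerced to 0. All values are proportions in
#' \[0, 1\]; multiply by 100 for the percent rendering used in reports.
#'
#' @param counts A one-row data frame with `tp`, `fp`, `fn`, `tn`
#'   (e.g. from [confusion_counts()]).
#' @return A one-row tibble with `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `youden`.
#' @examples
#' # a published operating point: 65 true / 9 false positives,
#' # 24 false / 49 true negatives
#' diagnostic_metrics(tibble::tibble(tp = 65, fp = 9, fn = 24, tn = 49))
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)), nrow(counts) == 1)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(counts$tp, counts$tp + counts$fn)
  spec <- safe_div(counts$tn, counts$fp + counts$tn)
  tibble::tibble(
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(counts$tp, counts$tp + counts$fp),
    npv = safe_div(counts$tn, counts$tn + counts$fn),
    youden = sens + spec - 1
  )
}

#' Reader-averaged operating point
#'
#' Averages the two readers' sensitivities and specificities at a common
#' cut-off and recomputes the Youden index from the averages. Predictive
#' values are not averaged (they are prevalence-weighted quantities with
#' no meaningful two-reader mean) and are returned as `NA`.
#'
#' @param m1,m2 One-row metric tibbles (see [diagnostic_metrics()]).
#' @return A one-row tibble in the same layout.
#' @export
reader_average <- function(m1, m2) {
  sens <- (m1$sensitivity + m2$sensitivity) / 2
  spec <- (m1$specificity + m2$specificity) / 2
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    ppv = NA_real_, npv = NA_real_,
    youden = sens + spec - 1
  )
}

#' Evaluate a candidate definition on a cohort
#'
#' Applies one positive-MRI definition for one reader and tabulates the
#' per-group positive counts (the published tables' row layout) together
#' with the accuracy metrics against the axSpA case/non-case split.
#'
#' @param cohort A cohort tibble.
#' @param definition One of [candidate_definitions()].
#' @param params A [score_params()] object.
#' @param reader 1 or 2.
#' @return A one-row tibble: `definition`, `reader`, positive counts
#'   `pos_hc`, `pos_nonspa`, `pos_nraxspa`, `pos_raxspa`, then
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`.
#' @export
evaluate_definition <- function(cohort, definition, params = score_params(),
                                reader = 1L) {
  definition <- match.arg(definition, candidate_definitions())
  stopifnot(reader %in% c(1L, 2L))
  scores <- subject_scores(cohort, params)
  scores <- scores[scores$reader == reader, ]
  pos <- scores[[definition]]
  by_group <- vapply(diagnosis_levels(), function(g) {
    sum(pos[as.character(scores$diagnosis) == g])
  }, integer(1))
  metrics <- diagnostic_metrics(confusion_counts(pos, scores$axspa))
  dplyr::bind_cols(
    tibble::tibble(
      definition = definition, reader = as.integer(reader),
      pos_hc = by_group[["HC"]], pos_nonspa = by_group[["nonSpA"]],
      pos_nraxspa = by_group[["nr-axSpA"]], pos_raxspa = by_group[["r-axSpA"]]
    ),
    metrics
  )
}

#' @rdname evaluate_definition
#' @param readers Readers to evaluate (default both).
#' @return `evaluate_definitions()` stacks all five definitions for the
#'   requested readers — the full published-table analogue.
#' @export
evaluate_definitions <- function(cohort, params = score_params(),
                                 readers = c(1L, 2L)) {
  purrr::map_dfr(readers, function(rd) {
    purrr::map_dfr(candidate_definitions(), function(def) {
      evaluate_definition(cohort, def, params, rd)
    })
  })
}

new_sweep <- function(rows, statistic) {
  rows <- tibble::as_tibble(rows)
  class(rows) <- c("fat_sweep", class(rows))
  attr(rows, "statistic") <- statistic
  rows
}

sweep_at_thresholds <- function(scores, thresholds, positive_at, statistic) {
  truth1 <- scores$axspa[scores$reader == 1]
  truth2 <- scores$axspa[scores$reader == 2]
  s1 <- scores[scores$reader == 1, ]
  s2 <- scores[scores$reader == 2, ]
  rows <- purrr::map_dfr(thresholds, function(th) {
    m1 <- diagnostic_metrics(confusion_counts(positive_at(s1, th), truth1))
    m2 <- diagnostic_metrics(confusion_counts(positive_at(s2, th), truth2))
    mavg <- reader_average(m1, m2)
    dplyr::bind_rows(
      dplyr::mutate(m1, reader = "1"),
      dplyr::mutate(m2, reader = "2"),
      dplyr::mutate(mavg, reader = "avg")
    ) |>
      dplyr::mutate(threshold = th, .before = 1)
  })
  new_sweep(
    dplyr::select(rows, "threshold", "reader", "sensitivity", "specificity",
                  "ppv", "npv", "youden"),
    statistic
  )
}

#' Cut-off sweeps over the two subject-level statistics
#'
#' `sweep_count()` evaluates the exceedance-count rule (positive when the
#' count is >= k) at every k from 1 to 36. `sweep_mean()` evaluates the
#' mean-PDFF rule (positive when the subject mean is strictly above the
#' threshold) at the empirical ROC thresholds: midpoints between
#' consecutive distinct observed subject means, pooled over both readers.
#' Each row carries per-reader (`reader` `"1"`, `"2"`) and reader-averaged
#' (`"avg"`) sensitivity, specificity and Youden index; for each reader,
#' sensitivity is non-increasing and specificity non-decreasing along the
#' sweep.
#'
#' @param cohort A cohort tibble.
#' @param params A [score_params()] object (the count sweep uses its
#'   `tau_roi`).
#' @return A `fat_sweep` tibble: `threshold`, `reader`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden`.
#' @seealso [youden_select()] to pick the operating point, [autoplot.fat_sweep()].
#' @export
sweep_count <- function(cohort, params = score_params()) {
  scores <- subject_scores(cohort, params)
  sweep_at_thresholds(
    scores, 1:36,
    function(s, k) s$exceedance_count >= k,
    statistic = "count"
  )
}

#' @rdname sweep_count
#' @export
sweep_mean <- function(cohort, params = score_params()) {
  scores <- subject_scores(cohort, params)
  vals <- sort(unique(scores$mean_pdff))
  thresholds <- if (length(vals) < 2) vals else (head(vals, -1) + vals[-1]) / 2
  sweep_at_thresholds(
    scores, thresholds,
    function(s, th) s$mean_pdff > th,
    statistic = "mean"
  )
}

#' Youden-optimal operating point of a sweep
#'
#' Selects the sweep row maximizing the Youden index for the requested
#' reader view. Ties are broken toward higher specificity, then toward the
#' higher threshold (the more conservative rule).
#'
#' @param sweep A [sweep_count()] / [sweep_mean()] result.
#' @param reader `"avg"` (default), `"1"`, or `"2"`.
#' @return The selected one-row tibble.
#' @export
youden_select <- function(sweep, reader = c("avg", "1", "2")) {
  reader <- match.arg(reader)
  rows <- sweep[sweep$reader == reader & !is.na(sweep$youden), ]
  if (nrow(rows) == 0) stop("no defined Youden values in sweep", call. = FALSE)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$youden),
                         dplyr::desc(.data$specificity),
                         dplyr::desc(.data$threshold))
  rows[1, ]
}

#' Mann-Whitney AUC with a DeLong confidence interval
#'
#' The area under the empirical ROC curve computed as the Mann-Whitney
#' probability that a randomly chosen case outscores a randomly chosen
#' non-case, with half credit for ties; equivalently the trapezoidal area
#' under the empirical ROC. The confidence interval uses DeLong's
#' placement-value variance estimator on the normal scale, truncated to
#' \[0, 1\].
#'
#' @param score Numeric vector of the continuous or ordinal statistic
#'   (higher = more disease-like), one per subject.
#' @param truth Logical vector: `TRUE` for axSpA cases.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `n_cases`,
#'   `n_controls`.
#' @examples
#' roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(score, truth, conf_level = 0.95) {
  stopifnot(length(score) == length(truth))
  if (anyNA(score) || anyNA(truth)) stop("score and truth must be non-missing", call. = FALSE)
  truth <- as.logical(truth)
  x <- score[truth]; y <- score[!truth]
  if (length(x) == 0 || length(y) == 0) {
    stop("AUC requires at least one case and one non-case", call. = FALSE)
  }
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # placement values of cases
  v01 <- colMeans(psi)   # placement values of controls
  var1 <- function(v) if (length(v) > 1) var(v) else 0
  se <- sqrt(var1(v10) / length(x) + var1(v01) / length(y))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auc = auc,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    n_cases = length(x),
    n_controls = length(y)
  )
}

#' bDMARDs-excluded sensitivity-analysis subset
#'
#' Removes axSpA case subjects with a bDMARDs medication history; healthy
#' controls and non-SpA subjects are retained unchanged (their bDMARDs
#' field does not apply). This is the subset underlying the published
#' sensitivity analysis.
#'
#' @param cohort A cohort tibble.
#' @return The filtered cohort tibble.
#' @export
exclude_bdmards <- function(cohort) {
  cohort <- validate_cohort(cohort)
  drop <- is_axspa(cohort$diagnosis) &
    !is.na(cohort$bdmards) & cohort$bdmards == 1
  out <- cohort[!drop, ]
  attr(out, "provenance") <- attr(cohort, "provenance")
  out
}
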
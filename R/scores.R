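#' Scoring parameters for the positive-MRI definitions
#'
#' @param tau_roi ROI exceedance threshold in percent PDFF (default 70):
#'   an ROI "exceeds" when its PDFF is strictly greater than `tau_roi`.
#' @param k_min Exceedance-count cut-off (default 8): the count rule is
#'   positive when at least `k_min` of the 36 ROIs exceed.
#' @param mean_cutoff Overall-mean cut-off in percent (default 65): the
#'   mean rule is positive when the subject's mean PDFF is strictly
#'   greater than `mean_cutoff`.
#' @return A list of class `score_params`.
#' @export
score_params <- function(tau_roi = 70, k_min = 8L, mean_cutoff = 65) {
  stopifnot(
    is.finite(tau_roi), tau_roi > 0, tau_roi < 100,
    is.finite(k_min), k_min >= 1, k_min <= 36,
    is.finite(mean_cutoff), mean_cutoff > 0, mean_cutoff < 100
  )
  structure(
    list(tau_roi = tau_roi, k_min = as.integer(k_min), mean_cutoff = mean_cutoff),
    class = "score_params"
  )
}

#' The five candidate definitions of a positive SIJ MRI
#'
#' @return Character vector of the definition codes, in table order:
#'   `mean_gt` (mean PDFF > cutoff), `count_ge` (exceedance count >=
#'   `k_min`), `bme_or_mean`, `bme_or_count` (the disjunctions with the
#'   bone-marrow-edema read), and `bme_only`.
#' @export
candidate_definitions <- function() {
  c("mean_gt", "count_ge", "bme_or_mean", "bme_or_count", "bme_only")
}

definition_labels <- function() {
  c(mean_gt = "Mean PDFF values over 65%",
    count_ge = ">=8 ROIs (PDFF>70%)",
    bme_or_mean = "BME or mean PDFF values over 65%",
    bme_or_count = "BME or >=8 ROIs (PDFF>70%)",
    bme_only = "BME")
}

grid_matrix <- function(cohort, reader) {
  m <- as.matrix(cohort[, pdff_cols(reader)])
  if (anyNA(m)) stop("incomplete ROI grid", call. = FALSE)
  m
}

#' Per-subject, per-reader summary scores
#'
#' Computes, for each subject and each reader, the two subject-level
#' statistics the diagnostic definitions are built on — the unweighted
#' arithmetic mean of the 36 ROI PDFF values and the exceedance count
#' (number of ROIs with PDFF strictly greater than `tau_roi`) — together
#' with the binary bone-marrow-edema read and the five candidate
#' positive-MRI classifications.
#'
#' Boundary conventions follow the definitions' wording: "over" thresholds
#' (`tau_roi`, `mean_cutoff`) are strict, while the count cut-off `k_min`
#' is inclusive. Means and counts are always computed per reader, never
#' pooled across readers.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param params A [score_params()] object.
#' @return A tibble with one row per subject per reader: `subject_id`,
#'   `diagnosis`, `axspa`, `reader`, `mean_pdff`, `exceedance_count`,
#'   `bme`, and one logical column per candidate definition.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1))
#' scores <- subject_scores(cohort)
#' dplyr::count(scores, reader, count_ge)
#' @export
subject_scores <- function(cohort, params = score_params()) {
  cohort <- validate_cohort(cohort)
  one_reader <- function(rd) {
    g <- grid_matrix(cohort, rd)
    tibble::tibble(
      subject_id = cohort$subject_id,
      diagnosis = cohort$diagnosis,
      axspa = is_axspa(cohort$diagnosis),
      reader = rd,
      mean_pdff = rowMeans(g),
      exceedance_count = as.integer(rowSums(g > params$tau_roi)),
      bme = cohort[[paste0("bme_r", rd)]] == 1
    )
  }
  scores <- dplyr::bind_rows(one_reader(1L), one_reader(2L))
  for (def in candidate_definitions()) {
    scores[[def]] <- classify_definition(scores, def, params)
  }
  scores
}

#' Apply one candidate definition to subject scores
#'
#' @param scores A tibble with columns `mean_pdff`, `exceedance_count`,
#'   `bme` (e.g. from [subject_scores()]).
#' @param definition One of [candidate_definitions()].
#' @param params A [score_params()] object.
#' @return Logical vector: the definition's positive/negative call per row.
#' @export
classify_definition <- function(scores, definition, params = score_params()) {
  definition <- match.arg(definition, candidate_definitions())
  mean_pos <- scores$mean_pdff > params$mean_cutoff
  count_pos <- scores$exceedance_count >= params$k_min
  bme <- as.logical(scores$bme)
  switch(definition,
    mean_gt = mean_pos,
    count_ge = count_pos,
    bme_or_mean = bme | mean_pos,
    bme_or_count = bme | count_pos,
    bme_only = bme
  )
}
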
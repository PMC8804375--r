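#' Two-reader intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation computed from the two-way ANOVA mean squares
#' (subjects x readers), with the F-distribution confidence bounds for
#' that form. This is the standard agreement coefficient for two raters
#' regarded as a random sample of possible raters.
#'
#' The mean-squares estimator can stray slightly outside \[-1, 1\] on
#' adversarial data; estimate and bounds are truncated to that range.
#' With zero total variance the estimate is undefined and reported `NA`.
#'
#' @param values_r1,values_r2 Paired per-subject measurements (length >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `model`
#'   (fixed label `"ICC(2,1) two-way random, absolute agreement"`), `n`.
#' @examples
#' icc_two_reader(c(1, 2, 3, 4), c(1.1, 2.0, 2.9, 4.2))
#' @export
icc_two_reader <- function(values_r1, values_r2, conf_level = 0.95) {
  stopifnot(length(values_r1) == length(values_r2))
  if (anyNA(values_r1) || anyNA(values_r2)) {
    stop("paired values must be non-missing", call. = FALSE)
  }
  n <- length(values_r1)
  if (n < 3) stop("ICC requires at least 3 paired subjects", call. = FALSE)
  k <- 2
  x <- cbind(values_r1, values_r2)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  label <- "ICC(2,1) two-way random, absolute agreement"
  if (sst <= .Machine$double.eps * max(1, abs(grand))^2) {
    return(tibble::tibble(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, model = label, n = n))
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  est <- (msr - mse) / denom
  # McGraw & Wong F-based bounds for ICC(A,1)
  alpha <- 1 - conf_level
  r <- max(min(est, 1 - 1e-12), -1 + 1e-12)
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  clamp <- function(z) pmin(pmax(z, -1), 1)
  tibble::tibble(
    estimate = clamp(est), ci_low = clamp(lower), ci_high = clamp(upper),
    model = label, n = n
  )
}

#' Inter-reader agreement on a cohort
#'
#' Computes the two-reader ICC for the subject-level statistics the study
#' reports agreement on: the overall mean PDFF and the ROI exceedance
#' count. The count is the continuous-like quantity consistent with an
#' ICC; agreement "for the >=8-ROI rule" is interpreted as agreement on
#' the underlying counts, not on the dichotomized calls.
#'
#' @param cohort A cohort tibble.
#' @param params A [score_params()] object.
#' @return A tibble with one row per statistic (`mean_pdff`,
#'   `exceedance_count`) and the [icc_two_reader()] columns.
#' @export
icc_cohort <- function(cohort, params = score_params()) {
  scores <- subject_scores(cohort, params)
  s1 <- scores[scores$reader == 1, ]
  s2 <- scores[scores$reader == 2, ]
  s2 <- s2[match(s1$subject_id, s2$subject_id), ]
  dplyr::bind_rows(
    dplyr::mutate(icc_two_reader(s1$mean_pdff, s2$mean_pdff),
                  statistic = "mean_pdff", .before = 1),
    dplyr::mutate(icc_two_reader(s1$exceedance_count, s2$exceedance_count),
                  statistic = "exceedance_count", .before = 1)
  )
}

# Table-2-style grouping keys. Case-only keys restrict to axSpA subjects.
grouping_keys <- function() {
  tibble::tribble(
    ~parameter, ~cases_only,
    "diagnosis", FALSE,
    "age_group", FALSE,
    "sex", FALSE,
    "duration_group", TRUE,
    "bmi_group", TRUE,
    "hla_b27", TRUE,
    "smoking", TRUE,
    "bdmards", TRUE,
    "asdas_group", TRUE
  )
}

band3 <- function(x, lo, hi, labels) {
  factor(ifelse(x < lo, labels[1], ifelse(x > hi, labels[3], labels[2])),
         levels = labels)
}

subcategory_of <- function(cohort, parameter) {
  switch(parameter,
    diagnosis = cohort$diagnosis,
    age_group = band3(cohort$age, 25, 35, c("<25", "25-35", ">35")),
    sex = factor(cohort$sex, levels = c("F", "M"),
                 labels = c("Female", "Male")),
    duration_group = band3(cohort$disease_duration, 5, 10,
                           c("<5", "5-10", ">10")),
    bmi_group = band3(cohort$bmi, 20, 24, c("<20", "20-24", ">24")),
    hla_b27 = factor(cohort$hla_b27, levels = c(0, 1),
                     labels = c("Negative", "Positive")),
    smoking = factor(cohort$smoking, levels = c(0, 1), labels = c("No", "Yes")),
    bdmards = factor(cohort$bdmards, levels = c(0, 1), labels = c("No", "Yes")),
    asdas_group = band3(cohort$asdas, 1.4, 2.1, c("<1.4", "1.4-2.1", ">2.1")),
    stop("unknown grouping parameter: ", parameter, call. = FALSE)
  )
}

#' Group-wise PDFF summaries with a one-way ANOVA test
#'
#' For one grouping parameter, summarizes the subject-level mean PDFF per
#' subcategory (n, percent of the block total, mean, SD) and tests for a
#' difference across subcategories with a one-way ANOVA — the published
#' intergroup table's layout. Parameters defined only for patients
#' (disease duration, BMI bands, HLA-B27, smoking, bDMARDs, ASDAS)
#' restrict the block to axSpA cases.
#'
#' Subcategory bands follow the published table: age <25 / 25-35 / >35
#' years, duration <5 / 5-10 / >10 years, BMI <20 / 20-24 / >24 kg/m2,
#' ASDAS <1.4 / 1.4-2.1 / >2.1. The SD of a single-subject subcategory and
#' the ANOVA p with fewer than two subcategories are reported `NA`.
#'
#' @param cohort A cohort tibble.
#' @param parameter One of `"diagnosis"`, `"age_group"`, `"sex"`,
#'   `"duration_group"`, `"bmi_group"`, `"hla_b27"`, `"smoking"`,
#'   `"bdmards"`, `"asdas_group"`.
#' @param reader `"1"`, `"2"`, or `"avg"` — which reader's subject means
#'   enter the summary (default `"1"`).
#' @return A tibble: `parameter`, `subcategory`, `n`, `pct`, `mean_pdff`,
#'   `sd_pdff`, `p_value` (block-level ANOVA p, repeated on each row).
#' @export
group_summary <- function(cohort, parameter, reader = c("1", "2", "avg")) {
  reader <- match.arg(reader)
  cohort <- validate_cohort(cohort)
  keys <- grouping_keys()
  if (!parameter %in% keys$parameter) {
    stop("unknown grouping parameter: ", parameter, call. = FALSE)
  }
  if (keys$cases_only[keys$parameter == parameter]) {
    cohort <- cohort[is_axspa(cohort$diagnosis), ]
  }
  value <- switch(reader,
    "1" = rowMeans(grid_matrix(cohort, 1)),
    "2" = rowMeans(grid_matrix(cohort, 2)),
    "avg" = (rowMeans(grid_matrix(cohort, 1)) + rowMeans(grid_matrix(cohort, 2))) / 2
  )
  sub <- subcategory_of(cohort, parameter)
  keep <- !is.na(sub)
  sub <- droplevels(factor(sub[keep]))
  value <- value[keep]
  empty <- setdiff(levels(subcategory_of(cohort, parameter)), levels(sub))
  if (length(empty) > 0) {
    warning("parameter '", parameter, "': empty subcategorie(s) excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  p <- if (nlevels(sub) >= 2 && length(value) > nlevels(sub)) {
    fit <- aov(value ~ sub)
    tab <- anova(fit)
    tab[["Pr(>F)"]][1]
  } else {
    NA_real_
  }
  tibble::tibble(value = value, subcategory = sub) |>
    dplyr::group_by(.data$subcategory) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pdff = mean(.data$value),
      sd_pdff = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      parameter = parameter,
      pct = 100 * .data$n / sum(.data$n),
      p_value = p
    ) |>
    dplyr::select("parameter", "subcategory", "n", "pct",
                  "mean_pdff", "sd_pdff", "p_value")
}

#' @rdname group_summary
#' @return `group_summary_all()` stacks every grouping parameter — the full
#'   intergroup table analogue.
#' @export
group_summary_all <- function(cohort, reader = c("1", "2", "avg")) {
  reader <- match.arg(reader)
  purrr::map_dfr(grouping_keys()$parameter, function(p) {
    group_summary(cohort, p, reader)
  })
}

#' All-pairs diagnosis-group contrasts with Tukey adjustment
#'
#' Mean differences of subject-level mean PDFF between every pair of the
#' four diagnosis groups, with Tukey honestly-significant-difference
#' adjusted p-values (studentized range) from the one-way ANOVA fit — the
#' published pairwise table's layout (6 rows).
#'
#' @param cohort A cohort tibble with at least 2 subjects in each group.
#' @param reader `"1"`, `"2"`, or `"avg"`.
#' @return A tibble: `contrast`, `difference` (percentage points),
#'   `ci_low`, `ci_high`, `p_adj`.
#' @export
pairwise_contrasts <- function(cohort, reader = c("1", "2", "avg")) {
  reader <- match.arg(reader)
  cohort <- validate_cohort(cohort)
  value <- switch(reader,
    "1" = rowMeans(grid_matrix(cohort, 1)),
    "2" = rowMeans(grid_matrix(cohort, 2)),
    "avg" = (rowMeans(grid_matrix(cohort, 1)) + rowMeans(grid_matrix(cohort, 2))) / 2
  )
  grp <- droplevels(cohort$diagnosis)
  if (any(table(grp) < 2) || nlevels(grp) < 2) {
    stop("pairwise contrasts need >= 2 subjects in >= 2 groups", call. = FALSE)
  }
  fit <- aov(value ~ grp)
  tk <- TukeyHSD(fit)$grp
  tibble::tibble(
    contrast = rownames(tk),
    difference = unname(tk[, "diff"]),
    ci_low = unname(tk[, "lwr"]),
    ci_high = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
}
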
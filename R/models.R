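#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()], convergence tolerance `1e-8`, at most 100
#' iterations) reporting per-predictor odds ratios with 95% Wald
#' confidence intervals `exp(coef +/- z * SE)` and Wald p-values. Apparent
#' perfect separation (non-convergence or runaway coefficients) is flagged
#' via `converged = FALSE` rather than silently reported.
#'
#' @param data A data frame holding outcome and predictors.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `fat_logit`; use [tidy()] for the
#'   coefficient table and [glance()] for fit-level summaries.
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 5, 5, 10)),
#'                 x = rep(c(1, 1, 0, 0), c(10, 5, 5, 10)))
#' tidy(fit_logistic(d, "y", "x"))  # odds ratio (10*10)/(5*5) = 4
#' @export
fit_logistic <- function(data, outcome, predictors, conf_level = 0.95) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  cols <- c(outcome, predictors)
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (length(unique(y)) < 2) {
    stop("outcome is constant; logistic fit is undefined", call. = FALSE)
  }
  if (nrow(d) <= length(predictors)) {
    stop("need more observations than predictors", call. = FALSE)
  }
  degenerate <- predictors[vapply(predictors, function(p) {
    length(unique(d[[p]])) < 2
  }, logical(1))]
  if (length(degenerate) > 0) {
    stop("constant predictor(s): ", paste(degenerate, collapse = ", "),
         call. = FALSE)
  }
  form <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  mm <- stats::model.matrix(form, d)
  kap <- kappa(mm, exact = FALSE)
  if (is.finite(kap) && kap > 1e8) {
    warning("design matrix is near-collinear (condition number ",
            format(kap, digits = 3), ")", call. = FALSE)
  }
  fit <- glm(form, family = binomial(), data = d,
             control = list(epsilon = 1e-8, maxit = 100))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separated <- !fit$converged || any(abs(cf) > 15) || any(se > 1e3)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std_error = unname(se),
    odds_ratio = exp(unname(cf)),
    ci_low = exp(unname(cf) - z * se),
    ci_high = exp(unname(cf) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(cf) / se))
  )
  structure(
    list(model = fit, coefficients = tab, n = nrow(d),
         converged = !separated, outcome = outcome, predictors = predictors),
    class = "fat_logit"
  )
}

#' @export
print.fat_logit <- function(x, ...) {
  cat("<fat_logit> logistic fit of", x$outcome, "on",
      paste(x$predictors, collapse = " + "), "\n")
  cat("  n =", x$n,
      if (x$converged) "" else " [NOT CONVERGED / possible separation]", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `fat_logit` object.
#' @param ... Unused.
#' @method tidy fat_logit
#' @export
tidy.fat_logit <- function(x, ...) x$coefficients

#' @rdname fit_logistic
#' @method glance fat_logit
#' @export
glance.fat_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    converged = x$converged,
    deviance = x$model$deviance,
    null_deviance = x$model$null.deviance,
    aic = x$model$aic
  )
}

# analysis frame for the association models: axSpA cases only, with the
# reader's exceedance count and the extensive-fat indicator attached
association_frame <- function(cohort, params, reader) {
  cohort <- validate_cohort(cohort)
  scores <- subject_scores(cohort, params)
  counts <- if (reader == "mean") {
    s1 <- scores[scores$reader == 1, ]
    s2 <- scores[scores$reader == 2, ]
    (s1$exceedance_count + s2$exceedance_count[match(s1$subject_id, s2$subject_id)]) / 2
  } else {
    s <- scores[scores$reader == as.integer(reader), ]
    s$exceedance_count[match(cohort$subject_id, s$subject_id)]
  }
  d <- cohort[is_axspa(cohort$diagnosis), ]
  idx <- match(d$subject_id, cohort$subject_id)
  tibble::tibble(
    subject_id = d$subject_id,
    extensive_fat = as.integer(counts[idx] >= params$k_min),
    mny = d$mny,
    roi_count = counts[idx],
    age = d$age,
    sex_male = as.integer(d$sex == "M"),
    disease_duration = d$disease_duration,
    bmi = d$bmi,
    smoking = d$smoking,
    bdmards = d$bdmards,
    asdas = d$asdas
  )
}

default_predictors <- function(outcome) {
  base <- c("age", "sex_male", "disease_duration", "bmi", "smoking",
            "bdmards", "asdas")
  if (outcome == "mny") c(base, "roi_count") else base
}

#' Univariate logistic screen of clinical predictors
#'
#' Fits one single-predictor logistic regression per clinical parameter,
#' among axSpA cases only, for either association outcome:
#' `"extensive_fat"` (exceedance count >= `k_min` on the chosen reader's
#' counts) or `"mny"` (fulfilment of the modified New York criteria, i.e.
#' the radiographic subtype). For the `mny` outcome the ROI exceedance
#' count joins the predictor set, entered linearly (per-ROI odds ratio).
#' A predictor constant across subjects is flagged degenerate and
#' excluded from the result with a warning.
#'
#' @param cohort A cohort tibble.
#' @param outcome `"extensive_fat"` or `"mny"`.
#' @param predictors Character vector of predictor names; defaults to the
#'   published predictor set.
#' @param params A [score_params()] object (its `k_min`/`tau_roi` define
#'   the extensive-fat outcome).
#' @param reader `"1"`, `"2"`, or `"mean"` — whose exceedance counts feed
#'   the outcome/predictor (default reader 1).
#' @return A tibble with one row per predictor: `predictor`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `converged`.
#' @export
univariate_screen <- function(cohort, outcome = c("extensive_fat", "mny"),
                              predictors = NULL,
                              params = score_params(),
                              reader = c("1", "2", "mean")) {
  outcome <- match.arg(outcome)
  reader <- match.arg(reader)
  if (is.null(predictors)) predictors <- default_predictors(outcome)
  frame <- association_frame(cohort, params, reader)
  purrr::map_dfr(predictors, function(p) {
    res <- tryCatch(fit_logistic(frame, outcome, p), error = function(e) e)
    if (inherits(res, "error")) {
      warning("predictor '", p, "' excluded: ", conditionMessage(res),
              call. = FALSE)
      return(NULL)
    }
    row <- res$coefficients[res$coefficients$term == p, ]
    tibble::tibble(
      predictor = p, odds_ratio = row$odds_ratio,
      ci_low = row$ci_low, ci_high = row$ci_high, p_value = row$p_value,
      n = res$n, converged = res$converged
    )
  })
}

#' Multivariate logistic fit with univariate pre-selection
#'
#' Joint logistic fit of the predictors passing the selection rule
#' (default: univariate Wald p < `selection_p`), among axSpA cases — the
#' published tables' multivariate column, where predictors failing the
#' screen carry dashes.
#'
#' @inheritParams univariate_screen
#' @param selection_p Univariate p-value threshold for inclusion
#'   (default 0.05). Set to `Inf` (or 1) to fit all predictors jointly.
#' @return A `fat_logit` object for the joint fit.
#' @export
multivariate_fit <- function(cohort, outcome = c("extensive_fat", "mny"),
                             predictors = NULL,
                             params = score_params(),
                             reader = c("1", "2", "mean"),
                             selection_p = 0.05) {
  outcome <- match.arg(outcome)
  reader <- match.arg(reader)
  if (is.null(predictors)) predictors <- default_predictors(outcome)
  screen <- univariate_screen(cohort, outcome, predictors, params, reader)
  selected <- screen$predictor[!is.na(screen$p_value) &
                                 screen$p_value < selection_p]
  if (length(selected) < 2) {
    stop("fewer than 2 predictors pass the selection rule (p < ",
         selection_p, ")", call. = FALSE)
  }
  frame <- association_frame(cohort, params, reader)
  fit_logistic(frame, outcome, selected)
}

#' Combined univariate/multivariate association table
#'
#' The published association tables' layout: one row per predictor with
#' the univariate odds ratio, CI and p-value, and the multivariate columns
#' filled only for predictors passing the selection rule (`NA` where the
#' tables print dashes).
#'
#' @inheritParams multivariate_fit
#' @return A tibble: `predictor`, `or_uni`, `ci_low_uni`, `ci_high_uni`,
#'   `p_uni`, `or_multi`, `ci_low_multi`, `ci_high_multi`, `p_multi`.
#' @export
association_table <- function(cohort, outcome = c("extensive_fat", "mny"),
                              predictors = NULL,
                              params = score_params(),
                              reader = c("1", "2", "mean"),
                              selection_p = 0.05) {
  outcome <- match.arg(outcome)
  reader <- match.arg(reader)
  if (is.null(predictors)) predictors <- default_predictors(outcome)
  screen <- univariate_screen(cohort, outcome, predictors, params, reader)
  out <- tibble::tibble(
    predictor = screen$predictor,
    or_uni = screen$odds_ratio,
    ci_low_uni = screen$ci_low, ci_high_uni = screen$ci_high,
    p_uni = screen$p_value,
    or_multi = NA_real_, ci_low_multi = NA_real_, ci_high_multi = NA_real_,
    p_multi = NA_real_
  )
  multi <- tryCatch(
    multivariate_fit(cohort, outcome, predictors, params, reader, selection_p),
    error = function(e) NULL
  )
  if (!is.null(multi)) {
    tab <- multi$coefficients
    hit <- match(out$predictor, tab$term)
    ok <- !is.na(hit)
    out$or_multi[ok] <- tab$odds_ratio[hit[ok]]
    out$ci_low_multi[ok] <- tab$ci_low[hit[ok]]
    out$ci_high_multi[ok] <- tab$ci_high[hit[ok]]
    out$p_multi[ok] <- tab$p_value[hit[ok]]
  }
  out
}
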
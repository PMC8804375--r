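test_that("confusion counts cross-tabulate correctly, including random data", {
  expect_equal(
    as.list(confusion_counts(rep(c(TRUE, FALSE), c(6, 4)),
                             rep(c(TRUE, FALSE), c(6, 4)))),
    list(tp = 6L, fp = 0L, fn = 0L, tn = 4L)
  )
  expect_equal(confusion_counts(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))$tp, 0L)
  set.seed(1)
  for (i in 1:10) {
    pred <- runif(40) > 0.5
    truth <- runif(40) > 0.5
    cc <- confusion_counts(pred, truth)
    # brute-force pairwise tally
    tally <- table(factor(pred, c(FALSE, TRUE)), factor(truth, c(FALSE, TRUE)))
    expect_equal(unname(c(cc$tp, cc$fp, cc$fn, cc$tn)),
                 unname(c(tally["TRUE", "TRUE"], tally["TRUE", "FALSE"],
                          tally["FALSE", "TRUE"], tally["FALSE", "FALSE"])))
  }
  expect_error(confusion_counts(c(TRUE, FALSE), c(TRUE, FALSE, TRUE)), "same subjects")
})

test_that("metrics reproduce published 2x2 operating points", {
  # the >=8-count rule, reader 1: 65 of 89 cases, 9 of 58 non-cases positive
  m <- diagnostic_metrics(tibble::tibble(tp = 65, fp = 9, fn = 24, tn = 49))
  expect_equal(round(100 * m$sensitivity, 2), 73.03)
  expect_equal(round(100 * m$specificity, 2), 84.48)
  expect_equal(round(100 * m$ppv, 2), 87.84)
  expect_equal(round(100 * m$npv, 2), 67.12)
  # the BME-alone definition, reader 1
  m2 <- diagnostic_metrics(tibble::tibble(tp = 59, fp = 5, fn = 30, tn = 53))
  expect_equal(round(100 * m2$sensitivity, 2), 66.29)
  expect_equal(round(100 * m2$specificity, 2), 91.38)
  # a perfect classifier
  m3 <- diagnostic_metrics(tibble::tibble(tp = 89, fp = 0, fn = 0, tn = 58))
  expect_equal(unlist(m3), c(sensitivity = 1, specificity = 1, ppv = 1,
                             npv = 1, youden = 1))
})

test_that("empty denominators surface as NA, never zero", {
  m <- diagnostic_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$youden))
})

test_that("reader averaging reproduces the published pooled operating point", {
  m1 <- diagnostic_metrics(tibble::tibble(tp = 65, fp = 9, fn = 24, tn = 49))
  m2 <- diagnostic_metrics(tibble::tibble(tp = 64, fp = 7, fn = 25, tn = 51))
  avg <- reader_average(m1, m2)
  expect_equal(round(100 * avg$sensitivity, 2), 72.47)
  expect_equal(round(100 * avg$specificity, 2), 86.21)
  expect_equal(round(avg$youden, 2), 0.59)
  # idempotence and the symmetric null case
  expect_equal(reader_average(m1, m1)$sensitivity, m1$sensitivity)
  a <- tibble::tibble(sensitivity = 1, specificity = 0, ppv = NA, npv = NA, youden = 0)
  b <- tibble::tibble(sensitivity = 0, specificity = 1, ppv = NA, npv = NA, youden = 0)
  avg2 <- reader_average(a, b)
  expect_equal(c(avg2$sensitivity, avg2$specificity, avg2$youden), c(0.5, 0.5, 0))
})

test_that("evaluate_definition equals classify + confusion + metrics composed manually", {
  co <- small_cohort(seed = 31)
  params <- score_params()
  for (def in candidate_definitions()) {
    got <- evaluate_definition(co, def, params, reader = 2L)
    s <- subject_scores(co, params)
    s <- s[s$reader == 2, ]
    oracle <- diagnostic_metrics(confusion_counts(s[[def]], s$axspa))
    expect_equal(got$sensitivity, oracle$sensitivity)
    expect_equal(got$specificity, oracle$specificity)
    expect_equal(got$ppv, oracle$ppv)
    expect_equal(got$npv, oracle$npv)
    expect_equal(got$pos_hc + got$pos_nonspa + got$pos_nraxspa + got$pos_raxspa,
                 sum(s[[def]]))
  }
})

test_that("BME-only sensitivity is zero on a cohort with no positive BME reads", {
  co <- dplyr::bind_rows(
    constant_cohort(50),
    dplyr::mutate(constant_cohort(50), subject_id = "X2", diagnosis = "r-axSpA",
                  disease_duration = 5, hla_b27 = 1L, bdmards = 0L,
                  asdas = 2, mny = 1L)
  )
  got <- evaluate_definition(co, "bme_only", reader = 1L)
  expect_equal(got$sensitivity, 0)
})

test_that("count sweep is monotone and saturates on separable data", {
  sep <- make_fixture("perfect")
  sw <- sweep_count(sep)
  for (rd in c("1", "2", "avg")) {
    rows <- sw[sw$reader == rd, ]
    expect_equal(rows$sensitivity, rep(1, 36))
    expect_equal(rows$specificity, rep(1, 36))
  }
  sw2 <- sweep_count(small_cohort(seed = 41))
  for (rd in c("1", "2")) {
    rows <- sw2[sw2$reader == rd, ]
    rows <- rows[order(rows$threshold), ]
    expect_true(all(diff(rows$sensitivity) <= 1e-12))
    expect_true(all(diff(rows$specificity) >= -1e-12))
    expect_equal(min(rows$sensitivity), rows$sensitivity[36])
  }
})

test_that("mean sweep uses midpoints between distinct observed means", {
  co <- dplyr::bind_rows(
    set_grid(constant_cohort(60), 1, 2, rep(60, 36)),
    set_grid(set_grid(dplyr::mutate(constant_cohort(0), subject_id = "X2",
                                    diagnosis = "r-axSpA", disease_duration = 2,
                                    hla_b27 = 1L, bdmards = 0L, asdas = 2,
                                    mny = 1L), 1, 1, rep(70, 36)), 1, 2, rep(70, 36))
  )
  sw <- sweep_mean(co)
  expect_equal(unique(sw$threshold), 65)
  # all-identical means: degenerate single-row sweep
  co2 <- dplyr::bind_rows(constant_cohort(50),
                          dplyr::mutate(constant_cohort(50), subject_id = "X2",
                                        diagnosis = "nr-axSpA",
                                        disease_duration = 2, hla_b27 = 1L,
                                        bdmards = 0L, asdas = 2, mny = 0L))
  sw2 <- sweep_mean(co2)
  expect_equal(length(unique(sw2$threshold)), 1)
})

test_that("mean-sweep rows agree with an independent closed-form evaluation", {
  co <- small_cohort(seed = 43)
  sw <- sweep_mean(co)
  s <- subject_scores(co)
  s1 <- s[s$reader == 1, ]
  rows <- sw[sw$reader == "1", ]
  for (i in seq_len(nrow(rows))) {
    pred <- s1$mean_pdff > rows$threshold[i]
    sens <- sum(pred & s1$axspa) / sum(s1$axspa)
    spec <- sum(!pred & !s1$axspa) / sum(!s1$axspa)
    expect_equal(rows$sensitivity[i], sens)
    expect_equal(rows$specificity[i], spec)
  }
})

test_that("youden selection matches an argmax oracle and breaks ties as documented", {
  set.seed(17)
  for (i in 1:10) {
    n <- 12
    fake <- tibble::tibble(
      threshold = seq_len(n), reader = "avg",
      sensitivity = runif(n), specificity = runif(n),
      ppv = NA_real_, npv = NA_real_
    )
    fake$youden <- fake$sensitivity + fake$specificity - 1
    got <- youden_select(fake, "avg")
    expect_equal(got$youden, max(fake$youden))
  }
  tie <- tibble::tibble(
    threshold = c(1, 2, 3), reader = "avg",
    sensitivity = c(0.9, 0.8, 0.7), specificity = c(0.5, 0.6, 0.7),
    ppv = NA_real_, npv = NA_real_, youden = c(0.4, 0.4, 0.4)
  )
  expect_equal(youden_select(tie, "avg")$threshold, 3) # higher spec, then higher cut
  expect_error(youden_select(tie[0, ], "avg"), "no defined")
})

test_that("AUC handles separation and ties by hand-checked enumeration", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # pairs (1,1) (1,2) (2,1) (2,2): credits 0.5 + 0 + 1 + 0.5 over 4
  expect_equal(roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "non-case")
})

test_that("AUC equals the trapezoidal area under the empirical ROC", {
  co <- small_cohort(seed = 47)
  s <- subject_scores(co)
  s1 <- s[s$reader == 1, ]
  got <- roc_auc(s1$exceedance_count, s1$axspa)$auc
  thresholds <- c(-Inf, sort(unique(s1$exceedance_count)), Inf)
  pts <- t(sapply(thresholds, function(th) {
    pred <- s1$exceedance_count > th
    c(fpr = mean(pred[!s1$axspa]), tpr = mean(pred[s1$axspa]))
  }))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), ]
  trap <- sum(diff(pts[, "fpr"]) * (head(pts[, "tpr"], -1) + pts[-1, "tpr"]) / 2)
  expect_equal(got, trap, tolerance = 1e-12)
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  co <- small_cohort(seed = 53)
  s <- subject_scores(co)
  s1 <- s[s$reader == 1, ]
  got <- roc_auc(s1$mean_pdff, s1$axspa)
  ref <- pROC::roc(response = s1$axspa, predictor = s1$mean_pdff,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(c(got$ci_low, got$ci_high), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("AUC is invariant under strictly increasing transforms", {
  co <- small_cohort(seed = 59)
  s <- subject_scores(co)
  s1 <- s[s$reader == 1, ]
  a <- roc_auc(s1$mean_pdff, s1$axspa)$auc
  expect_equal(roc_auc(exp(s1$mean_pdff / 20), s1$axspa)$auc, a)
  expect_equal(roc_auc(rank(s1$mean_pdff, ties.method = "average"), s1$axspa)$auc, a)
})

test_that("bDMARDs exclusion removes only treated cases", {
  co <- make_fixture("table5")
  sub <- exclude_bdmards(co)
  expect_equal(nrow(sub), 124)
  expect_equal(as.vector(table(sub$diagnosis)), c(34, 24, 29, 37))
  # no treated cases: identity
  none <- co[is.na(co$bdmards) | co$bdmards == 0, ]
  expect_equal(nrow(exclude_bdmards(none)), nrow(none))
})

test_that("cohort-level disjunction dominance holds on every simulated dataset", {
  for (seed in c(61, 67, 71)) {
    co <- small_cohort(seed = seed)
    for (rd in 1:2) {
      or_rule <- evaluate_definition(co, "bme_or_count", reader = rd)
      bme <- evaluate_definition(co, "bme_only", reader = rd)
      cnt <- evaluate_definition(co, "count_ge", reader = rd)
      expect_gte(or_rule$sensitivity, bme$sensitivity)
      expect_gte(or_rule$sensitivity, cnt$sensitivity)
      expect_lte(or_rule$specificity, bme$specificity)
      expect_lte(or_rule$specificity, cnt$specificity)
    }
  }
})
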
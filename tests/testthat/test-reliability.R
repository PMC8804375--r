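test_that("ICC is 1 for perfect agreement and symmetric in reader order", {
  x <- c(1, 2, 3, 4)
  res <- icc_two_reader(x, x)
  expect_equal(res$estimate, 1)
  set.seed(3)
  a <- rnorm(20, 60, 10)
  b <- a + rnorm(20, 0, 3)
  expect_equal(icc_two_reader(a, b)$estimate, icc_two_reader(b, a)$estimate)
})

test_that("ICC matches a mean-squares oracle built from aov()", {
  oracle_icc21 <- function(r1, r2) {
    n <- length(r1)
    d <- data.frame(
      y = c(r1, r2),
      subject = factor(rep(seq_len(n), 2)),
      rater = factor(rep(1:2, each = n))
    )
    ms <- anova(aov(y ~ subject + rater, data = d))[["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  set.seed(11)
  for (i in 1:6) {
    r1 <- rnorm(15, 60, 12)
    r2 <- 0.8 * r1 + rnorm(15, 10, 6)
    got <- icc_two_reader(r1, r2)$estimate
    expect_equal(got, oracle_icc21(r1, r2), tolerance = 1e-10)
  }
  # anti-correlated readers: estimate below zero (clamped to [-1, 1])
  got_neg <- icc_two_reader(c(1, 2, 3), c(3, 2, 1))$estimate
  expect_lt(got_neg, 0)
  expect_gte(got_neg, -1)
})

test_that("ICC confidence bounds bracket the estimate and zero variance is NA", {
  set.seed(5)
  a <- rnorm(30, 60, 10)
  b <- a + rnorm(30, 0, 4)
  res <- icc_two_reader(a, b)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
  flat <- icc_two_reader(rep(5, 6), rep(5, 6))
  expect_true(is.na(flat$estimate))
})

test_that("added reader noise decreases expected agreement", {
  set.seed(29)
  deltas <- replicate(100, {
    truth <- rnorm(25, 60, 12)
    clean <- icc_two_reader(truth, truth + rnorm(25, 0, 2))$estimate
    noisy <- icc_two_reader(truth, truth + rnorm(25, 0, 10))$estimate
    clean - noisy
  })
  expect_gt(mean(deltas), 0)
})

test_that("group summary blocks report the expected denominators and ANOVA p", {
  co <- generate_cohort(generator_config(seed = 2))
  tab <- group_summary_all(co)
  totals <- tapply(tab$n, tab$parameter, sum)
  all_subject <- c("diagnosis", "age_group", "sex")
  case_only <- c("duration_group", "bmi_group", "hla_b27", "smoking",
                 "bdmards", "asdas_group")
  expect_true(all(totals[all_subject] == nrow(co)))
  expect_true(all(totals[case_only] == sum(is_axspa(co$diagnosis))))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
})

test_that("the ANOVA p matches a textbook sums-of-squares oracle", {
  co <- generate_cohort(generator_config(seed = 4))
  tab <- group_summary(co, "diagnosis")
  y <- rowMeans(as.matrix(co[, pdff_cols(1)]))
  g <- co$diagnosis
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, length) * (tapply(y, g, mean) - grand)^2)
  ss_within <- sum((y - ave(y, g))^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  f <- (ss_between / df1) / (ss_within / df2)
  p_oracle <- pf(f, df1, df2, lower.tail = FALSE)
  expect_equal(unique(tab$p_value), p_oracle, tolerance = 1e-12)
})

test_that("identical groups give equal means and p = 1", {
  base <- constant_cohort(0)
  mk <- function(id, dx, vals) {
    out <- dplyr::mutate(base, subject_id = id, diagnosis = dx)
    if (is_axspa(dx)) {
      out <- dplyr::mutate(out, disease_duration = 2, hla_b27 = 1L,
                           bdmards = 0L, asdas = 2,
                           mny = as.integer(dx == "r-axSpA"))
    }
    set_grid(set_grid(out, 1, 1, rep(vals, 36)), 1, 2, rep(vals, 36))
  }
  co <- dplyr::bind_rows(
    mk("a1", "HC", 10), mk("a2", "HC", 20), mk("a3", "HC", 30),
    mk("b1", "nonSpA", 10), mk("b2", "nonSpA", 20), mk("b3", "nonSpA", 30)
  )
  expect_warning(tab <- group_summary(co, "diagnosis"), "empty subcategorie")
  expect_equal(tab$mean_pdff[1], tab$mean_pdff[2])
  expect_equal(unique(tab$p_value), 1)
})

test_that("pairwise contrasts produce all six pairs with Tukey adjustment", {
  co <- generate_cohort(generator_config(seed = 6))
  pw <- pairwise_contrasts(co)
  expect_equal(nrow(pw), 6)
  # differences agree with the subcategory means
  m <- tapply(rowMeans(as.matrix(co[, pdff_cols(1)])), co$diagnosis, mean)
  row <- pw[pw$contrast == "r-axSpA-HC", ]
  expect_equal(row$difference, unname(m["r-axSpA"] - m["HC"]), tolerance = 1e-10)
  # Tukey-adjusted p is at least the unadjusted pooled-variance t p-value
  y <- rowMeans(as.matrix(co[, pdff_cols(1)]))
  fit <- aov(y ~ co$diagnosis)
  mse <- anova(fit)[["Mean Sq"]][2]
  df_resid <- fit$df.residual
  pairs <- utils::combn(diagnosis_levels(), 2)
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    label <- paste(g2, g1, sep = "-")
    row <- pw[pw$contrast == label, ]
    expect_equal(nrow(row), 1)
    n1 <- sum(co$diagnosis == g1); n2 <- sum(co$diagnosis == g2)
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    p_unadj <- 2 * pt(-abs(row$difference) / se, df_resid)
    expect_gte(row$p_adj + 1e-12, p_unadj)
  }
})
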
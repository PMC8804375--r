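published_r1 <- tibble::tribble(
  ~definition, ~pos, ~sens, ~spec, ~ppv, ~npv,
  "mean_gt", c(2, 3, 19, 39), 65.17, 91.38, 92.06, 63.10,
  "count_ge", c(2, 7, 22, 43), 73.03, 84.48, 87.84, 67.12,
  "bme_or_mean", c(3, 6, 28, 51), 88.76, 84.48, 89.77, 83.05,
  "bme_or_count", c(4, 10, 30, 51), 91.01, 75.86, 85.26, 84.62,
  "bme_only", c(2, 3, 18, 41), 66.29, 91.38, 92.19, 63.86
)

published_r2 <- tibble::tribble(
  ~definition, ~pos, ~sens, ~spec,
  "mean_gt", c(2, 4, 19, 38), 64.04, 89.66,
  "count_ge", c(2, 5, 21, 43), 71.91, 87.93,
  "bme_or_mean", c(3, 4, 28, 50), 87.64, 87.93,
  "bme_or_count", c(3, 5, 28, 51), 88.76, 86.21,
  "bme_only", c(1, 1, 18, 38), 62.92, 96.55
)

test_that("the table fixture reproduces every published reader-1 row through the pipeline", {
  fx <- make_fixture("table5")
  expect_equal(nrow(fx), 147)
  got <- evaluate_definitions(fx, readers = 1L)
  for (i in seq_len(nrow(published_r1))) {
    row <- got[got$definition == published_r1$definition[i], ]
    expect_equal(c(row$pos_hc, row$pos_nonspa, row$pos_nraxspa, row$pos_raxspa),
                 published_r1$pos[[i]])
    expect_equal(round(100 * row$sensitivity, 2), published_r1$sens[i])
    expect_equal(round(100 * row$specificity, 2), published_r1$spec[i])
    expect_equal(round(100 * row$ppv, 2), published_r1$ppv[i])
    expect_equal(round(100 * row$npv, 2), published_r1$npv[i])
  }
})

test_that("the table fixture reproduces every published reader-2 row through the pipeline", {
  fx <- make_fixture("table5")
  got <- evaluate_definitions(fx, readers = 2L)
  for (i in seq_len(nrow(published_r2))) {
    row <- got[got$definition == published_r2$definition[i], ]
    expect_equal(c(row$pos_hc, row$pos_nonspa, row$pos_nraxspa, row$pos_raxspa),
                 published_r2$pos[[i]])
    expect_equal(round(100 * row$sensitivity, 2), published_r2$sens[i])
    expect_equal(round(100 * row$specificity, 2), published_r2$spec[i])
  }
})

test_that("bDMARDs exclusion of the fixture reproduces the sensitivity-analysis rows", {
  fx <- make_fixture("table6_reader1")
  expect_equal(nrow(fx), 124)
  expect_equal(as.vector(table(fx$diagnosis)), c(34, 24, 29, 37))
  got <- evaluate_definitions(fx, readers = 1L)
  expected <- tibble::tribble(
    ~definition, ~pos, ~sens, ~spec,
    "mean_gt", c(2, 3, 16, 31), 71.21, 91.38,
    "count_ge", c(2, 7, 19, 33), 78.79, 84.48,
    "bme_or_mean", c(3, 6, 22, 37), 89.39, 84.48,
    "bme_or_count", c(4, 10, 24, 37), 92.42, 75.86,
    "bme_only", c(2, 3, 13, 28), 62.12, 91.38
  )
  for (i in seq_len(nrow(expected))) {
    row <- got[got$definition == expected$definition[i], ]
    expect_equal(c(row$pos_hc, row$pos_nonspa, row$pos_nraxspa, row$pos_raxspa),
                 expected$pos[[i]])
    expect_equal(round(100 * row$sensitivity, 2), expected$sens[i])
    expect_equal(round(100 * row$specificity, 2), expected$spec[i])
  }
})

test_that("the separable fixture is perfectly classified at every count cut-off", {
  fx <- make_fixture("perfect")
  sw <- sweep_count(fx)
  expect_true(all(sw$sensitivity == 1 & sw$specificity == 1))
  s <- subject_scores(fx)
  s1 <- s[s$reader == 1, ]
  expect_equal(roc_auc(s1$mean_pdff, s1$axspa)$auc, 1)
  expect_error(make_fixture("no-such-table"), "unknown fixture")
})

test_that("run_report writes the full deterministic table suite", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  files_a <- run_report(out_dir = dir_a, seed = 5)
  files_b <- run_report(out_dir = dir_b, seed = 5)
  expected <- c("table2.tsv", "table3.tsv", "table4.tsv", "table5.tsv",
                "table6.tsv", "roc.tsv", "icc.tsv", "table7.tsv",
                "table8.tsv", "manifest.json")
  expect_setequal(names(files_a), expected)
  for (f in setdiff(expected, "manifest.json")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), info = f)
  }
})

test_that("run_report on an engineered cohort reproduces a published table row", {
  dir <- withr::local_tempdir()
  # constant fixture covariates make most association predictors degenerate;
  # the screen warns and drops them, which is expected here
  suppressWarnings(run_report(cohort = make_fixture("table5"), out_dir = dir))
  t5 <- readr::read_tsv(file.path(dir, "table5.tsv"), show_col_types = FALSE)
  row <- t5[t5$definition == "count_ge" & t5$reader == 1, ]
  expect_equal(row$sensitivity_pct, "73.03%")
  expect_equal(c(row$pos_hc, row$pos_nonspa, row$pos_nraxspa, row$pos_raxspa),
               c(2, 7, 22, 43))
})

test_that("a cohort without cases aborts with a stage-named message and no leftovers", {
  co <- generate_cohort(generator_config(
    groups = group_calibration(c(10L, 8L, 0L, 0L)), seed = 9
  ))
  dir <- file.path(withr::local_tempdir(), "report")
  expect_error(suppressWarnings(run_report(cohort = co, out_dir = dir)), "stage")
  expect_length(list.files(dir), 0)
})
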
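test_that("cohort CSV round-trips losslessly and outcome codings are mapped", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy_cohort_df(), f, row.names = FALSE)
  ch <- read_cohort(f)
  expect_s3_class(ch, "cohort_table")
  expect_identical(ch[["Heart Disease"]], c(1L, 0L, 1L))

  # numeric 0/1 outcome accepted too
  df2 <- toy_cohort_df(); df2[["Heart Disease"]] <- c(1, 0, 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, f2, row.names = FALSE)
  expect_identical(read_cohort(f2)[["Heart Disease"]], c(1L, 0L, 1L))

  # write-then-read identity on a synthetic 270-row cohort
  sim <- generate_cohort(seed = 42, table1_mode = TRUE)$data
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim, f3)
  back <- read_cohort(f3)
  expect_equal(as.data.frame(back), as.data.frame(sim))
})

test_that("schema and domain violations are rejected with informative errors", {
  df <- toy_cohort_df()
  expect_error(as_cohort(df[setdiff(names(df), "Thallium")]), "Thallium")

  df_na <- df; df_na$BP[2] <- NA
  expect_error(as_cohort(df_na), "row 2")

  df_bad <- df; df_bad$Thallium[1] <- 5
  expect_error(as_cohort(df_bad), "Thallium")
  df_bad2 <- df; df_bad2[["Number of vessels fluro"]][3] <- 9
  expect_error(as_cohort(df_bad2), "vessels")
  df_bad3 <- df; df_bad3[["Heart Disease"]] <- c("yes", "no", "yes")
  expect_error(as_cohort(df_bad3), "outcome")

  # header matching is whitespace- and case-tolerant
  df_h <- df; names(df_h)[13] <- "  THALLIUM "
  expect_s3_class(as_cohort(df_h), "cohort_table")
})

test_that("binarisation rules follow the clinical cut-offs", {
  expect_identical(binarize_vessels(c(3, 0, 2, 1)), c(1L, 0L, 0L, 0L))
  expect_identical(binarize_thallium(c(7, 3, 6)), c(1L, 0L, 0L))
  expect_identical(binarize_cholesterol(c(240, 126, 564, 239)),
                   c(1L, 0L, 1L, 0L))
  expect_error(binarize_vessels(4), "vessels")
  expect_error(binarize_thallium(5), "Thallium")
  expect_error(binarize_cholesterol(c(200, -1)), "positive")
})

test_that("binarisation is idempotent on its own output", {
  set.seed(1)
  for (i in 1:20) {
    v <- binarize_vessels(sample(2:3, 50, replace = TRUE))
    expect_identical(binarize_vessels(v), v)
    th <- binarize_thallium(sample(c(3, 6, 7), 50, replace = TRUE))
    expect_identical(binarize_thallium(th), th)
    ch <- binarize_cholesterol(sample(126:564, 50, replace = TRUE))
    expect_identical(binarize_cholesterol(ch), ch)
  }
})

test_that("treatment frames partition the candidate set S without duplication", {
  ch <- generate_cohort(seed = 9, table1_mode = TRUE)$data
  expected_cols <- c(vessels = "vessels_bin", thallium = "thallium_bin",
                     sex = "sex", cholesterol = "cholesterol_bin")
  for (trt in names(treatment_set())) {
    fr <- make_treatment_frame(ch, trt)
    expect_setequal(fr$confounder_names,
                    unname(expected_cols[setdiff(names(expected_cols), trt)]))
    expect_length(fr$confounder_names, 3)
    expect_true(all(fr$T %in% 0:1))
    expect_identical(fr$Y, ch[["Heart Disease"]])
  }
  fr_sex <- make_treatment_frame(ch, "Sex")
  expect_setequal(fr_sex$confounder_names,
                  c("vessels_bin", "thallium_bin", "cholesterol_bin"))

  expect_error(make_treatment_frame(ch, "Age"), "treatment must be")

  # degenerate single-arm treatment is refused
  ch2 <- as.data.frame(ch); ch2$Thallium <- 7
  expect_error(make_treatment_frame(as_cohort(ch2), "thallium"),
               "empty arm")
})

test_that("raw-scale confounders are available as an option", {
  ch <- generate_cohort(seed = 9, table1_mode = TRUE)$data
  fr <- make_treatment_frame(ch, "thallium", binarize_confounders = FALSE)
  expect_setequal(fr$confounder_names, c("vessels", "sex", "cholesterol"))
  expect_true(max(fr$C[, "cholesterol"]) > 1) # mg/dl scale retained
})
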
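make_mini_cohort <- function() {
  patients <- data.frame(patient_id = c("P1", "P2"),
                         time_to_recovery_days = c(10, 20))
  biopsies <- data.frame(patient_id = rep(c("P1", "P2"), each = 2),
                         timepoint = rep(c("M3", "M12"), 2),
                         mif_percent = c(10, 14, 12, 18), ci = c(1, 2, 1, 2))
  cohort_table(patients, biopsies)
}

test_that("cohort validation catches schema violations", {
  co <- make_mini_cohort()
  expect_identical(nrow(co$biopsies), 4L)

  expect_error(cohort_table(data.frame(patient_id = "P1"),
                            data.frame(patient_id = "P9", timepoint = "M3",
                                       mif_percent = 5)),
               class = "fq_schema_error", regexp = "unknown patients")
  expect_error(cohort_table(data.frame(patient_id = "P1"),
                            data.frame(patient_id = c("P1", "P1"),
                                       timepoint = c("M3", "M3"),
                                       mif_percent = c(5, 6))),
               class = "fq_schema_error", regexp = "duplicate")
  expect_error(cohort_table(data.frame(patient_id = "P1"),
                            data.frame(patient_id = "P1", timepoint = "M6",
                                       mif_percent = 5)),
               class = "fq_schema_error", regexp = "timepoint")
  expect_error(cohort_table(data.frame(patient_id = "P1"),
                            data.frame(patient_id = "P1", timepoint = "M3",
                                       ci = 7)),
               class = "fq_schema_error", regexp = "ci grades")
})

test_that("cohorts round-trip through CSV files", {
  co <- generate_synthetic_cohort(seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(file.path(dir, "patients.csv"),
                      file.path(dir, "biopsies.csv"))
  expect_equal(back$biopsies$mif_percent, co$biopsies$mif_percent)
  expect_identical(nrow(back$patients), nrow(co$patients))
  expect_error(load_cohort(file.path(dir, "nope.csv"),
                           file.path(dir, "biopsies.csv")),
               class = "fq_input_error")
})

test_that("the synthetic cohort reproduces the published design", {
  co <- generate_synthetic_cohort(seed = 11)
  expect_identical(nrow(co$patients), 66L)
  counts <- table(factor(co$biopsies$timepoint,
                         levels = c("D0", "D15_30", "M3", "M12")))
  expect_identical(as.integer(counts), c(43L, 20L, 28L, 28L))

  # a paired subgroup with all of D15-30, M3 and M12 exists
  by_pt <- split(co$biopsies$timepoint, co$biopsies$patient_id)
  n_all3 <- sum(vapply(by_pt, function(tp)
    all(c("D15_30", "M3", "M12") %in% tp), logical(1)))
  expect_gte(n_all3, 7L)

  # grade means are monotone in ci (threshold construction)
  gs <- group_summary(co$biopsies$mif_percent, co$biopsies$ci)
  expect_true(all(diff(gs$mean) > 0))

  expect_identical(generate_synthetic_cohort(seed = 11)$biopsies$mif_percent,
                   co$biopsies$mif_percent)
  expect_error(generate_synthetic_cohort(r2_time_to_recovery = 1.2, seed = 1),
               class = "fq_parameter_error")
})

test_that("generator marginals converge to the timepoint specs", {
  specs <- timepoint_specs_default()
  big <- specs; big$n <- c(5000L, 5000L, 5000L, 5000L)
  co <- generate_synthetic_cohort(n_patients = 5000, timepoint_specs = big,
                                  seed = 21)
  for (i in seq_len(4)) {
    v <- co$biopsies$mif_percent[co$biopsies$timepoint == specs$timepoint[i]]
    expect_lt(abs(mean(v) - specs$mean[i]) / specs$mean[i], 0.02)
    expect_lt(abs(sd(v) - specs$sd[i]) / specs$sd[i], 0.05)
  }
})

test_that("zero correlation and zero target R-squared give independence", {
  co <- generate_synthetic_cohort(n_patients = 2000,
                                  within_patient_corr = 0,
                                  r2_time_to_recovery = 0,
                                  r2_creatinine_m12 = 0,
                                  r2_creatinine_last = 0, seed = 5)
  wide <- stats::reshape(co$biopsies[, c("patient_id", "timepoint", "mif_percent")],
                         idvar = "patient_id", timevar = "timepoint",
                         direction = "wide")
  m3 <- wide$mif_percent.M3; m12 <- wide$mif_percent.M12
  ok <- stats::complete.cases(m3, m12)
  expect_lt(abs(cor(m3[ok], m12[ok])), 0.08)

  fit <- association_analysis(co)$mif_m12_vs_time_to_recovery
  expect_lt(fit$r_squared, 0.01)
})

test_that("progression analysis reports increasing fibrosis and paired tests", {
  co <- generate_synthetic_cohort(seed = 2)
  pr <- progression_analysis(co)
  expect_identical(pr$summaries$timepoint, c("D0", "D15_30", "M3", "M12"))
  # generator means increase by construction; at n = 66 the sample should
  # follow at least from D0 to M3 and M3 to M12
  expect_gt(pr$summaries$mif_mean[3], pr$summaries$mif_mean[1])
  expect_gt(pr$summaries$mif_mean[4], pr$summaries$mif_mean[3])
  expect_identical(nrow(pr$comparisons), 3L)
  expect_true(all(pr$comparisons$p_unpaired_wilcoxon >= 0 &
                  pr$comparisons$p_unpaired_wilcoxon <= 1))

  flat <- make_mini_cohort()
  flat$biopsies$mif_percent <- 5
  pf <- progression_analysis(flat)
  expect_null(pf$comparisons)  # n < 5 per timepoint: comparisons skipped
})

test_that("a paired M3 to M12 shift like the published subgroup is detected", {
  # seven patients, published paired means 11.4 -> 17.7 with SD <= 3
  hits <- sapply(1:200, function(i) fibroquant:::with_seed(40000 + i, {
    m3 <- rnorm(7, 11.4, 2.7)
    m12 <- rnorm(7, 17.7, 3)
    paired_location_test(m3, m12)$p_wilcoxon < 0.05
  }))
  expect_gt(mean(hits), 0.8)
})

test_that("association analysis fits the pre-registered pairs and skips sparse ones", {
  co <- generate_synthetic_cohort(seed = 7)
  fits <- association_analysis(co)
  expect_named(fits, c("mif_m12_vs_time_to_recovery",
                       "mif_m12_vs_creatinine_m12",
                       "mif_m12_vs_creatinine_last",
                       "mif_m3_vs_creatinine_m12",
                       "ldh_d3_vs_time_to_recovery"))
  fit <- fits$mif_m12_vs_time_to_recovery
  expect_s3_class(fit, "regression_result")
  expect_identical(fit$n, 28L)

  # perfectly linear outcome gives R^2 = 1
  lin <- co
  m12 <- lin$biopsies[lin$biopsies$timepoint == "M12", ]
  lin$patients$time_to_recovery_days <- NA_real_
  idx <- match(m12$patient_id, lin$patients$patient_id)
  lin$patients$time_to_recovery_days[idx] <- 2 * m12$mif_percent + 1
  fit1 <- suppressWarnings(association_analysis(lin))  # exact fit
  expect_equal(fit1$mif_m12_vs_time_to_recovery$r_squared, 1,
               tolerance = 1e-12)

  sparse <- make_mini_cohort()
  expect_match(association_analysis(sparse)$mif_m12_vs_time_to_recovery,
               "skipped")
})

test_that("analyses are invariant to biopsy row order", {
  co <- generate_synthetic_cohort(seed = 13)
  shuffled <- co
  perm <- fibroquant:::with_seed(1, sample.int(nrow(co$biopsies)))
  shuffled$biopsies <- co$biopsies[perm, ]
  expect_equal(progression_analysis(shuffled)$summaries,
               progression_analysis(co)$summaries)
  expect_equal(association_analysis(shuffled)$mif_m12_vs_creatinine_m12$slope,
               association_analysis(co)$mif_m12_vs_creatinine_m12$slope)
})
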
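test_that("identical seed, config and truth give byte-identical cohorts", {
  a <- simulate_cohort(cohort_config(n_participants = 120, seed = 77),
                       cohort_truth())
  b <- simulate_cohort(cohort_config(n_participants = 120, seed = 77),
                       cohort_truth())
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_cohort(cohort_config(n_participants = 120, seed = 78),
                        cohort_truth())
  expect_false(identical(a$stroop_w1, c_$stroop_w1))
})

test_that("full retention leaves no missing EF cells", {
  co <- simulate_cohort(cohort_config(n_participants = 100, seed = 1,
                                      retention = c(1, 1)), cohort_truth())
  ef_cols <- grep("_w[123]$", names(co), value = TRUE)
  ef_cols <- grep("stroop|hayling|brixton|ctrails", ef_cols, value = TRUE)
  expect_false(anyNA(co[, ef_cols]))
})

test_that("degenerate truth gives flat trajectories at the intercept mean", {
  tr <- cohort_truth(growth_means = c(intercept = 0.3, slope = 0),
                     growth_covariance = matrix(0, 2, 2),
                     ef_residual_variance = 0,
                     residual_variances = rep(1e-12, 4),
                     beta_risk_on_intercept = 0, beta_risk_on_slope = 0,
                     beta_sex_on_intercept = 0, beta_sex_on_slope = 0)
  co <- simulate_cohort(cohort_config(n_participants = 50, seed = 2,
                                      retention = c(1, 1)), tr)
  # marker indicator (loading 1, intercept 0) equals the latent value
  for (w in 1:3) {
    expect_equal(co[[paste0("stroop_w", w)]], rep(0.3, 50), tolerance = 1e-4)
  }
})

test_that("attrition is monotone and wave ages strictly increase", {
  co <- quick_cohort(n = 400, seed = 10)
  w2 <- !is.na(co$stroop_w2)
  w3 <- !is.na(co$stroop_w3)
  expect_true(all(!w3 | w2))         # observed at w3 implies observed at w2
  expect_true(all(co$age_w2 > co$age_w1 & co$age_w3 > co$age_w2))
  expect_true(all(co$age_w1 >= 53 & co$age_w1 <= 85))
})

test_that("wave-2 retention is calibrated to its target", {
  co <- simulate_cohort(cohort_config(n_participants = 600, seed = 31),
                        cohort_truth())
  r2 <- mean(!is.na(co$stroop_w2))
  # binomial 99% interval around 0.81 at n = 600
  half <- 2.576 * sqrt(0.81 * 0.19 / 600)
  expect_gt(r2, 0.81 - half)
  expect_lt(r2, 0.81 + half)
  # and the same under MCAR
  co2 <- simulate_cohort(cohort_config(n_participants = 600, seed = 32,
                                       attrition_mechanism = "MCAR"),
                         cohort_truth())
  r2b <- mean(!is.na(co2$stroop_w2))
  expect_gt(r2b, 0.81 - half)
  expect_lt(r2b, 0.81 + half)
})

test_that("attrition under the MAR mechanism tracks age and baseline EF", {
  co <- simulate_cohort(cohort_config(n_participants = 4000, seed = 33),
                        cohort_truth())
  drop2 <- is.na(co$stroop_w2)
  # older and lower-EF participants drop out more often
  expect_gt(mean(co$age_w1[drop2]), mean(co$age_w1[!drop2]))
  expect_lt(mean(co$stroop_w1[drop2]), mean(co$stroop_w1[!drop2]))
})

test_that("indicator distributions converge to their configured targets", {
  co <- simulate_cohort(cohort_config(n_participants = 10000, seed = 4),
                        cohort_truth())
  msd <- cohort_config()$indicator_means_sds
  for (v in c("pp", "bmi", "grip", "act_phys", "act_soc", "act_integ",
              "act_novel")) {
    se <- msd["sd", v] / sqrt(10000)
    expect_lt(abs(mean(co[[v]]) - msd["mean", v]), 3 * se)
    expect_lt(abs(sd(co[[v]]) - msd["sd", v]), 3 * msd["sd", v] / sqrt(2 * 10000))
  }
  # sex composition and APOE carrier share
  expect_lt(abs(mean(co$sex) - 0.66), 3 * sqrt(0.66 * 0.34 / 10000))
  grp <- apoe_group(co$apoe)
  keep <- grp != "excluded_e2e4"
  p4 <- mean(grp[keep] == "e4_plus")
  expect_lt(abs(p4 - 149 / 602), 3 * sqrt(0.2475 * 0.7525 / sum(keep)))
})

test_that("generated genotypes drawn under HWE usually pass the HWE test", {
  pass <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_config(n_participants = 500, seed = 500 + s),
                          cohort_truth())
    counts <- table(factor(co$cr1, levels = c("A/A", "A/G", "G/G")))
    hwe_chisq(counts[["A/A"]], counts[["A/G"]], counts[["G/G"]])$p >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95 - 3 * sqrt(0.95 * 0.05 / 40))
})

test_that("cohort CSV round-trips bit-for-bit and validates its schema", {
  co <- quick_cohort(n = 40, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  for (v in names(co)) {
    if (is.numeric(co[[v]]))
      expect_identical(as.numeric(back[[v]]), as.numeric(co[[v]]))
    else expect_equal(as.character(back[[v]]), as.character(co[[v]]))
  }
  # single complete participant round-trips to a cohort of size one
  one <- co[which(!is.na(co$stroop_w3))[1], ]
  p1 <- tempfile(fileext = ".csv")
  write_cohort(one, p1)
  expect_equal(nrow(read_cohort(p1)), 1L)
  # missing mandatory column is named in the error
  df <- utils::read.csv(path)
  df$age_w2 <- NULL
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "age_w2")
  # non-monotone ages are named by row
  df2 <- utils::read.csv(path)
  df2$age_w2[3] <- df2$age_w1[3] - 1
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, p3, row.names = FALSE)
  expect_error(read_cohort(p3), "strictly increasing")
})

test_that("invalid configurations and truths are rejected with diagnostics", {
  expect_error(cohort_config(n_participants = 0), "count")
  expect_error(cohort_config(retention = c(1.2, 0.5)), "proportions")
  expect_error(cohort_config(baseline_age_range = c(40, 85)), "53")
  expect_error(cohort_truth(growth_covariance = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(cohort_truth(residual_variances = c(-1, 1, 1, 1)),
               "non-negative")
})
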
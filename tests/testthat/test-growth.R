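test_that("marginal growth likelihood matches per-person brute force", {
  d <- sim_growth(n = 15, seed = 2, risk_b = -0.1, risk_s = -0.005,
                  sex_b = 0.2, sex_s = 0.01, miss = 0.3)
  beta <- c(0.1, -0.12, 0.25, -0.02, -0.006, 0.012)
  G <- matrix(c(0.5, -0.008, -0.008, 0.0015), 2)
  rv <- c(0.3, 0.25, 0.35)
  ours <- growth_loglik(d$Y, d$ages, beta, G, rv, risk = d$risk, sex = d$sex)
  brute <- bruteforce_growth_loglik(d$Y, d$ages, beta, G, rv,
                                    risk = d$risk, sex = d$sex)
  expect_equal(ours, brute, tolerance = 1e-9)
  # unconditional model, common residual
  beta0 <- c(0.05, -0.018)
  ours0 <- growth_loglik(d$Y, d$ages, beta0, G, 0.3)
  brute0 <- bruteforce_growth_loglik(d$Y, d$ages, beta0, G, 0.3)
  expect_equal(ours0, brute0, tolerance = 1e-9)
})

test_that("zero slope variance reduces to a compound-symmetry likelihood", {
  d <- sim_growth(n = 25, seed = 3)
  beta <- c(0.1, -0.02)
  s2_int <- 0.5; s2_e <- 0.3
  G0 <- matrix(c(s2_int, 0, 0, 0), 2)
  ours <- growth_loglik(d$Y, d$ages, beta, G0, s2_e)
  # direct compound-symmetry oracle: V = s2_int J + s2_e I
  t <- d$ages - 75
  direct <- 0
  for (i in 1:25) {
    V <- matrix(s2_int, 3, 3) + diag(s2_e, 3)
    e <- d$Y[i, ] - (beta[1] + beta[2] * t[i, ])
    direct <- direct - 0.5 * (3 * log(2 * pi) +
                              determinant(V, log = TRUE)$modulus +
                              drop(t(e) %*% solve(V) %*% e))
  }
  expect_equal(ours, as.numeric(direct), tolerance = 1e-9)
})

test_that("maximized likelihood matches lme4 on complete data", {
  skip_if_not_installed("lme4")
  d <- sim_growth(n = 150, seed = 4)
  fit <- ef_growth(d$Y, d$ages, stage = "random_slope",
                   residuals = "common", se = FALSE)
  long <- data.frame(y = as.vector(d$Y),
                     t = as.vector(d$ages - 75),
                     id = rep(seq_len(150), 3))
  lm4 <- lme4::lmer(y ~ t + (t | id), data = long, REML = FALSE)
  expect_equal(fit$logL, as.numeric(logLik(lm4)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients),
               unname(lme4::fixef(lm4)), tolerance = 1e-3)
})

test_that("conditional growth model recovers planted effects", {
  d <- sim_growth(n = 2000, seed = 5, beta_int = 0.2, beta_slope = -0.02,
                  risk_b = -0.161, risk_s = -0.007, sex_b = 0.275,
                  sex_s = 0.015, miss = 0.2)
  fit <- ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex)
  b <- fit$coefficients
  expect_lt(abs(b[["risk"]] - (-0.161)), 3 * fit$se[["risk"]])
  expect_lt(abs(b[["risk_slope"]] - (-0.007)), 3 * fit$se[["risk_slope"]])
  expect_lt(abs(b[["sex"]] - 0.275), 3 * fit$se[["sex"]])
  expect_lt(abs(b[["sex_slope"]] - 0.015), 3 * fit$se[["sex_slope"]])
  expect_equal(fit$k, 12)
  expect_true(all(fit$se[c("risk", "risk_slope")] > 0))
  # random-effect covariance is PSD with sensible magnitudes
  expect_gte(min(eigen(fit$G)$values), -1e-10)
  expect_lt(abs(fit$G[1, 1] - 0.6), 0.15)
})

test_that("permuted risk scores give a null effect", {
  d <- sim_growth(n = 600, seed = 6, risk_b = -0.161, risk_s = -0.007)
  set.seed(99)
  risk_perm <- sample(d$risk)
  fit <- ef_growth(d$Y, d$ages, risk = risk_perm, sex = d$sex)
  expect_lt(abs(fit$coefficients[["risk"]]), 3 * fit$se[["risk"]])
  expect_lt(abs(fit$coefficients[["risk_slope"]]), 3 * fit$se[["risk_slope"]])
})

test_that("information criteria reproduce their defining identities", {
  ic <- information_criteria(-700.892, 12, 524)
  expect_equal(unname(ic["minus2LL"]), 1401.784)
  expect_equal(unname(ic["aic"]), 1425.784)
  expect_equal(unname(ic["bic"]), 1476.922, tolerance = 1e-6)
  # guards
  ic0 <- information_criteria(0, 0, 1)
  expect_equal(unname(ic0["aic"]), 2)
  expect_equal(unname(ic0["bic"]), 0)  # k * ln(1) = 0
})

test_that("a constant sex covariate is dropped with k reduced by 2", {
  d <- sim_growth(n = 150, seed = 7)
  expect_warning(
    fit <- ef_growth(d$Y, d$ages, risk = d$risk, sex = rep(1, 150)),
    "constant")
  expect_equal(fit$k, 10)
  expect_false("sex" %in% names(fit$coefficients))
})

test_that("slope stages are rejected for single-wave data", {
  d <- sim_growth(n = 50, seed = 8)
  Y1 <- d$Y; Y1[, 2:3] <- NA
  expect_error(ef_growth(Y1, d$ages, stage = "random_slope"),
               "not identified")
  # but the intercept-only stages still fit
  f <- ef_growth(Y1, d$ages, stage = "random_intercept", se = FALSE)
  expect_true(is.finite(f$logL))
})

test_that("results are invariant to a common shift of ages and centering", {
  d <- sim_growth(n = 120, seed = 9, risk_b = -0.1)
  f1 <- ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex, center = 75,
                  se = FALSE)
  f2 <- ef_growth(d$Y, d$ages + 5, risk = d$risk, sex = d$sex, center = 80,
                  se = FALSE)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
})

test_that("the model-building ladder orders likelihoods and flags boundaries", {
  d <- sim_growth(n = 300, seed = 10)
  lad <- growth_ladder(d$Y, d$ages)
  lls <- lad$steps$logL
  expect_true(all(diff(lls) >= -1e-6))
  expect_true(all(lad$steps$d_chi2[-1] >= 0))
  expect_equal(lad$steps$boundary,
               c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # data with real random slopes prefer the random-slope stage
  expect_equal(lad$preferred, "random_slope")
})

test_that("flat data with no variance components keep the null model", {
  set.seed(11)
  d <- sim_growth(n = 200, seed = 11, beta_slope = 0,
                  G = matrix(0, 2, 2), resid = c(0.3, 0.3, 0.3))
  lad <- growth_ladder(d$Y, d$ages)
  # random-intercept addition should not be significant (boundary test
  # conservative, so this holds with high probability under the null)
  expect_true(lad$steps$p[2] > 0.05 || lad$steps$d_chi2[2] < 3)
})

test_that("stratified fit with one stratum equals the plain conditional fit", {
  d <- sim_growth(n = 200, seed = 12, risk_b = -0.1)
  f1 <- ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex)
  fs <- ef_growth_stratified(d$Y, d$ages, d$risk, d$sex,
                             strata = rep("all", 200))
  expect_equal(fs$logL, f1$logL, tolerance = 1e-8)
  expect_equal(fs$k, f1$k)
  expect_equal(fs$fits$all$coefficients, f1$coefficients, tolerance = 1e-6)
})

test_that("stratified fits combine likelihoods additively and flag low n", {
  d <- sim_growth(n = 200, seed = 13, risk_b = -0.1)
  strata <- rep(c("a", "b"), c(188, 12))
  expect_no_error(fs <- ef_growth_stratified(d$Y, d$ages, d$risk, d$sex,
                                             strata = strata))
  expect_equal(fs$logL, fs$fits$a$logL + fs$fits$b$logL, tolerance = 1e-10)
  expect_equal(fs$k, fs$fits$a$k + fs$fits$b$k)
  expect_equal(fs$low_n, "b")
  expect_equal(fs$n, fs$fits$a$n + fs$fits$b$n)
})

test_that("equal-parameter strata do not beat the pooled fit meaningfully", {
  d <- sim_growth(n = 400, seed = 14, risk_b = -0.12, risk_s = -0.005)
  strata <- rep(c("g1", "g2"), each = 200)
  pooled <- ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex, se = FALSE)
  fs <- ef_growth_stratified(d$Y, d$ages, d$risk, d$sex, strata, se = FALSE)
  d_chi2 <- 2 * (fs$logL - pooled$logL)
  d_df <- fs$k - pooled$k
  expect_gte(d_chi2, -1e-6)
  expect_gt(pchisq(max(0, d_chi2), d_df, lower.tail = FALSE), 0.001)
})

test_that("planted between-stratum slope differences are recovered", {
  d1 <- sim_growth(n = 400, seed = 15, risk_s = -0.010)
  d2 <- sim_growth(n = 400, seed = 16, risk_s = 0)
  Y <- rbind(d1$Y, d2$Y); ages <- rbind(d1$ages, d2$ages)
  risk <- c(d1$risk, d2$risk); sex <- c(d1$sex, d2$sex)
  strata <- rep(c("hit", "nil"), each = 400)
  fs <- ef_growth_stratified(Y, ages, risk, sex, strata)
  b_hit <- fs$fits$hit$coefficients[["risk_slope"]]
  b_nil <- fs$fits$nil$coefficients[["risk_slope"]]
  expect_lt(abs(b_hit - (-0.010)), 3 * fs$fits$hit$se[["risk_slope"]])
  expect_lt(abs(b_nil), 3 * fs$fits$nil$se[["risk_slope"]])
  expect_lt(b_hit, b_nil)
})

test_that("simulate() round-trips the fitted generating process", {
  d <- sim_growth(n = 1500, seed = 17, risk_b = -0.15)
  fit <- ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex, se = FALSE)
  sims <- simulate(fit, nsim = 1, seed = 1, ages = d$ages,
                   risk = d$risk, sex = d$sex)
  refit <- ef_growth(sims[[1]], d$ages, risk = d$risk, sex = d$sex,
                     se = FALSE)
  expect_lt(abs(refit$coefficients[["risk"]] - fit$coefficients[["risk"]]),
            0.03)
  # residuals are centered near zero
  r <- residuals(fit, d$Y, d$ages, risk = d$risk, sex = d$sex)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.05)
})

test_that("slope-effect estimates concentrate as the sample grows", {
  est <- function(n, seeds) vapply(seeds, function(s) {
    d <- sim_growth(n = n, seed = s, risk_b = -0.161, risk_s = -0.007,
                    miss = 0.2)
    ef_growth(d$Y, d$ages, risk = d$risk, sex = d$sex,
              se = FALSE)$coefficients[["risk_slope"]]
  }, numeric(1))
  e_small <- est(150, 300 + 1:30)
  e_large <- est(600, 400 + 1:30)
  # both unbiased within Monte-Carlo error ...
  expect_lt(abs(mean(e_small) + 0.007), 4 * sd(e_small) / sqrt(30))
  expect_lt(abs(mean(e_large) + 0.007), 4 * sd(e_large) / sqrt(30))
  # ... with sampling error shrinking in n (roughly like 1/sqrt(n))
  expect_lt(sd(e_large), sd(e_small))
})
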
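# single-wave data straight from a one-factor model
sim_one_factor <- function(n, loadings = c(1, 0.9, 0.8, 0.85),
                           tau = c(0, 0.2, -0.1, 0.3),
                           theta = c(0.4, 0.35, 0.5, 0.45),
                           psi = 0.8, seed = 1) {
  set.seed(seed)
  eta <- rnorm(n, 0, sqrt(psi))
  Y <- sapply(1:4, function(i)
    tau[i] + loadings[i] * eta + rnorm(n, 0, sqrt(theta[i])))
  colnames(Y) <- paste0(c("stroop", "hayling", "brixton", "ctrails"), "_w1")
  list(Y = Y, eta = eta, loadings = loadings, psi = psi, tau = tau,
       theta = theta)
}

test_that("sample moments equal to implied moments give a zero chi-square", {
  sim <- sim_one_factor(400, seed = 2)
  # recolor the data so its sample MLE moments are exactly the implied ones
  L <- matrix(sim$loadings, 4)
  Sigma <- L %*% t(L) * sim$psi + diag(sim$theta)
  mu <- sim$tau
  Y <- sim$Y
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  S <- crossprod(Yc) / nrow(Y)
  Yw <- Yc %*% solve(chol(S)) %*% chol(Sigma)
  Yx <- sweep(Yw, 2, mu, "+")
  colnames(Yx) <- colnames(Y)
  fit <- ef_cfa(Yx, waves = 1L, factors = "one")
  expect_lt(fit$fit$chi2, 0.02)
  expect_gt(fit$fit$cfi, 0.999)
})

test_that("one-factor parameters are recovered from model-generated data", {
  sim <- sim_one_factor(2000, seed = 3)
  fit <- ef_cfa(sim$Y, waves = 1L, factors = "one")
  s <- summary(fit)
  expect_true(fit$converged)
  # loadings within ~3 Monte-Carlo SEs (generous absolute band)
  expect_lt(max(abs(unname(s$loadings[, 1]) - sim$loadings)), 0.06)
  expect_lt(max(abs(unname(s$intercepts[, 1]) - sim$tau)), 0.08)
  expect_lt(max(abs(unname(s$residual_variances[, 1]) - sim$theta)), 0.12)
  expect_lt(abs(s$factor_cov[1, 1] - sim$psi), 0.12)
  expect_lte(fit$fit$rmsea, 0.05)
  expect_gte(fit$fit$cfi, 0.95)
})

test_that("two-factor data prefer the two-factor model by AIC", {
  set.seed(4)
  n <- 800
  r <- 0.3
  f <- MASS_less_mvrnorm(n, c(0, 0), matrix(c(1, r, r, 1), 2))
  Y <- cbind(f[, 1] + rnorm(n, 0, 0.5), 0.9 * f[, 1] + rnorm(n, 0, 0.5),
             f[, 2] + rnorm(n, 0, 0.5), 0.9 * f[, 2] + rnorm(n, 0, 0.5))
  colnames(Y) <- paste0(c("stroop", "hayling", "brixton", "ctrails"), "_w1")
  f1 <- ef_cfa(Y, waves = 1L, factors = "one")
  f2 <- ef_cfa(Y, waves = 1L, factors = "two")
  expect_gt(f1$fit$aic, f2$fit$aic)
  expect_gt(f2$fit$cfi, f1$fit$cfi)
})

test_that("fit indices satisfy their defining identities", {
  co <- quick_cohort(n = 300, seed = 8)
  fit <- ef_cfa(co, waves = 3L, invariance = "metric")
  expect_equal(fit$fit$aic, -2 * fit$logL + 2 * fit$k, tolerance = 1e-10)
  expect_equal(fit$fit$bic, -2 * fit$logL + fit$k * log(fit$n),
               tolerance = 1e-10)
  expect_equal(fit$fit$chi2, 2 * (fit$saturated$logL - fit$logL),
               tolerance = 1e-6)
  expect_equal(fit$fit$df, fit$saturated$k - fit$k)
  expect_gte(fit$fit$cfi, 0); expect_lte(fit$fit$cfi, 1)
  expect_gte(fit$fit$rmsea, 0)
})

test_that("FIML fit on complete data equals complete-data ML", {
  co <- simulate_cohort(cohort_config(n_participants = 300, seed = 12,
                                      retention = c(1, 1)), cohort_truth())
  fit <- ef_cfa(co, waves = 3L, invariance = "configural")
  # likelihood at the optimum must equal the direct complete-data density
  mo <- fit$moments
  Y <- fit$data
  expect_equal(fit$logL, bruteforce_mvn_loglik(Y, mo$mu, mo$Sigma),
               tolerance = 1e-6)
})

test_that("nested invariance fits have ordered log-likelihoods", {
  co <- quick_cohort(n = 350, seed = 14)
  inv <- ef_invariance(co, restarts = 1)
  lls <- vapply(inv$fits[c("configural", "metric", "scalar", "residual")],
                function(f) f$logL, numeric(1))
  expect_true(all(diff(lls) <= 1e-6))
  # difference tests are non-negative with positive df
  steps <- inv$steps[-1, ]
  expect_true(all(steps$d_chi2 >= 0))
  expect_true(all(steps$d_df > 0))
})

test_that("fit is invariant to participant order", {
  co <- quick_cohort(n = 250, seed = 15)
  f1 <- ef_cfa(co, waves = 3L, invariance = "metric", restarts = 1)
  perm <- sample(nrow(co))
  f2 <- ef_cfa(co[perm, ], waves = 3L, invariance = "metric", restarts = 1)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
})

test_that("regression factor scores match the closed-form oracle", {
  co <- simulate_cohort(cohort_config(n_participants = 200, seed = 16,
                                      retention = c(1, 1)), cohort_truth())
  fit <- ef_cfa(co, waves = 3L, invariance = "scalar", restarts = 1)
  sc <- predict(fit, method = "regression")
  mo <- fit$moments
  # oracle: alpha + Psi Lambda' Sigma^{-1} (y - mu), complete data
  A <- mo$Psi %*% t(mo$Lambda) %*% solve(mo$Sigma)
  Y <- fit$data
  oracle <- t(apply(Y, 1, function(y) mo$alpha + drop(A %*% (y - mo$mu))))
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-8)
})

test_that("Bartlett scores are unbiased given the latent value", {
  co <- simulate_cohort(cohort_config(n_participants = 1500, seed = 17,
                                      retention = c(1, 1)), cohort_truth())
  lat <- attr(co, "latent")
  fit <- ef_cfa(co, waves = 3L, invariance = "scalar", restarts = 1)
  sc <- predict(fit, method = "bartlett")
  # regressing the score on the true latent EF gives slope ~ 1
  for (w in 1:3) {
    b <- coef(lm(sc[, w] ~ lat$ef[, w]))[2]
    expect_lt(abs(b - 1), 0.05)
  }
  # while regression-method scores shrink (slope < 1)
  sr <- predict(fit, method = "regression")
  b1 <- coef(lm(sr[, 1] ~ lat$ef[, 1]))[2]
  expect_lt(b1, 0.99)
})

test_that("factor-score accuracy approaches the determinacy bound", {
  co <- simulate_cohort(cohort_config(n_participants = 1000, seed = 18,
                                      retention = c(1, 1)), cohort_truth())
  lat <- attr(co, "latent")
  fit <- ef_cfa(co, waves = 3L, invariance = "scalar", restarts = 1)
  sr <- predict(fit, method = "regression")
  mo <- fit$moments
  # determinacy for wave-1 factor from fitted parameters
  A <- mo$Psi %*% t(mo$Lambda) %*% solve(mo$Sigma)
  rho2 <- (A %*% mo$Sigma %*% t(A))[1, 1] / mo$Psi[1, 1]
  expect_gt(cor(sr[, 1], lat$ef[, 1]), sqrt(rho2) - 0.05)
})

test_that("scores are missing only where a wave has no observed indicators", {
  co <- quick_cohort(n = 200, seed = 19)
  fit <- ef_cfa(co, waves = 3L, invariance = "scalar", restarts = 1)
  for (m in c("bartlett", "regression")) {
    sc <- predict(fit, method = m)
    expect_equal(is.na(sc[, 3]), is.na(co$stroop_w3))
    expect_false(anyNA(sc[, 1]))
  }
})

test_that("noiseless indicators reproduce the latent variable exactly", {
  tr <- cohort_truth(residual_variances = rep(1e-8, 4))
  co <- simulate_cohort(cohort_config(n_participants = 150, seed = 20,
                                      retention = c(1, 1)), tr)
  lat <- attr(co, "latent")
  # score with the generating parameters: in the zero-noise limit the
  # Bartlett combination must return the latent value itself
  fit <- ef_cfa(co, waves = 3L, invariance = "configural", restarts = 1)
  L <- matrix(0, 12, 3)
  for (w in 1:3) L[(w - 1) * 4 + 1:4, w] <- tr$loadings
  mo <- list(Lambda = L, Theta = diag(1e-8, 12), tau = rep(0, 12),
             mu = rep(0, 12), Psi = diag(1, 3), alpha = rep(0, 3),
             Sigma = L %*% t(L) + diag(1e-8, 12))
  fit$moments <- mo
  sc <- predict(fit, method = "bartlett")
  for (w in 1:3)
    expect_lt(max(abs(sc[, w] - lat$ef[, w])), 1e-3)
  # the estimated-parameter scores agree closely too
  fit2 <- ef_cfa(co, waves = 3L, invariance = "configural", restarts = 1)
  expect_gt(cor(predict(fit2, method = "bartlett")[, 1], lat$ef[, 1]), 0.995)
})
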
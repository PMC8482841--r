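# Independent brute-force oracles.  These deliberately avoid the package's
# pattern-grouped likelihood code paths: every case is evaluated on its own
# with explicit submatrix extraction and solve().

# casewise multivariate-normal log-likelihood, one case at a time
bruteforce_mvn_loglik <- function(Y, mu, Sigma) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    yo <- Y[i, o]
    So <- Sigma[o, o, drop = FALSE]
    d <- yo - mu[o]
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                      determinant(So, logarithm = TRUE)$modulus +
                      drop(t(d) %*% solve(So) %*% d))
  }
  as.numeric(ll)
}

# growth-model marginal likelihood: per person, V = Z G Z' + R on observed
# waves, mean from explicit design rows
bruteforce_growth_loglik <- function(scores, ages, beta, G, resid_var,
                                     risk = NULL, sex = NULL, center = 75,
                                     quadratic = FALSE) {
  n <- nrow(scores)
  W <- ncol(scores)
  if (length(resid_var) == 1L) resid_var <- rep(resid_var, W)
  ll <- 0
  for (i in seq_len(n)) {
    o <- which(!is.na(scores[i, ]) & !is.na(ages[i, ]))
    if (!length(o)) next
    t_i <- ages[i, o] - center
    Z <- cbind(1, t_i)
    X <- NULL
    for (a in seq_along(o)) {
      xrow <- c(1, if (!is.null(risk)) risk[i], if (!is.null(sex)) sex[i])
      xrow <- c(xrow, t_i[a] * xrow)
      if (quadratic) xrow <- c(xrow, t_i[a]^2)
      X <- rbind(X, xrow)
    }
    V <- Z %*% G %*% t(Z) + diag(resid_var[o], length(o))
    d <- scores[i, o] - drop(X %*% beta)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                      determinant(V, logarithm = TRUE)$modulus +
                      drop(t(d) %*% solve(V) %*% d))
  }
  as.numeric(ll)
}

# small complete/missing toy dataset generator for likelihood checks
toy_mvn_data <- function(n, p, miss_prob = 0.25, seed = 42) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) / p + diag(0.5, p)
  mu <- rnorm(p)
  Y <- MASS_less_mvrnorm(n, mu, Sigma)
  mask <- matrix(runif(n * p) < miss_prob, n, p)
  # keep at least one observed variable per row
  for (i in seq_len(n)) if (all(mask[i, ])) mask[i, sample(p, 1)] <- FALSE
  Y[mask] <- NA
  list(Y = Y, mu = mu, Sigma = Sigma)
}

# multivariate normal draw via Cholesky (avoids depending on MASS)
MASS_less_mvrnorm <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  sweep(matrix(rnorm(n * length(mu)), n) %*% L, 2, mu, "+")
}

# enumerate all attainable weight combinations of the scoring scheme
enumerate_score_ranges <- function() {
  pp <- 0:2; grip <- 0:1; bmi <- 0:2
  act <- 0:1; edu <- 0:2
  frs <- outer(outer(pp, grip, "+"), bmi, "+")
  lrs_vals <- c()
  for (a1 in act) for (a2 in act) for (a3 in act) for (a4 in act)
    for (e in edu) lrs_vals <- c(lrs_vals, a1 + a2 + a3 + a4 + e)
  list(frs = as.vector(frs), lrs = lrs_vals,
       mcrs = as.vector(outer(as.vector(frs), lrs_vals, "+")))
}

# small three-wave cohort for quick pipeline-level tests
quick_cohort <- function(n = 250, seed = 11, ...) {
  simulate_cohort(cohort_config(n_participants = n, seed = seed, ...),
                  cohort_truth())
}

# direct simulation of growth-model data (no measurement layer)
sim_growth <- function(n = 200, seed = 1, beta_int = 0, beta_slope = -0.02,
                       risk_b = 0, risk_s = 0, sex_b = 0, sex_s = 0,
                       G = matrix(c(0.6, -0.01, -0.01, 0.002), 2),
                       resid = c(0.25, 0.25, 0.25), miss = 0) {
  set.seed(seed)
  age1 <- runif(n, 53, 85)
  ages <- cbind(age1, age1 + 4.4, age1 + 8.9)
  t <- ages - 75
  risk <- sample(0:8, n, replace = TRUE)
  sex <- rbinom(n, 1, 0.66)
  L <- t(chol(G + diag(1e-12, 2)))
  u <- L %*% matrix(rnorm(2 * n), 2)
  b0 <- beta_int + risk_b * risk + sex_b * sex + u[1, ]
  b1 <- beta_slope + risk_s * risk + sex_s * sex + u[2, ]
  Y <- b0 + b1 * t + matrix(rnorm(3 * n, 0, rep(sqrt(resid), each = n)), n)
  if (miss > 0) {
    gone2 <- runif(n) < miss
    gone3 <- gone2 | runif(n) < miss
    Y[gone2, 2] <- NA; Y[gone3, 3] <- NA
  }
  list(Y = Y, ages = ages, risk = risk, sex = sex)
}
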
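# Full-information maximum likelihood (FIML) machinery for multivariate
# normal data with arbitrary missingness.  The casewise log-likelihood is
# evaluated through per-missingness-pattern sufficient statistics: within a
# pattern every case shares the same observed subset, so the sum of casewise
# densities collapses to a mean/scatter form and the cost of one likelihood
# evaluation no longer grows with n.

# Group rows of Y (matrix with NAs) by missingness pattern and precompute
# per-pattern count, mean and MLE scatter (divided by m, not m-1).
fiml_prepare <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop_ef("data for FIML must be numeric")
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(Y)), key)
  pats <- lapply(idx, function(rows) {
    o <- which(obs[rows[1L], ])
    sub <- Y[rows, o, drop = FALSE]
    m <- nrow(sub)
    ybar <- colMeans(sub)
    d <- sweep(sub, 2L, ybar)
    list(obs = o, m = m, ybar = ybar, S = crossprod(d) / m)
  })
  structure(list(patterns = pats, n = nrow(Y), p = ncol(Y),
                 vars = colnames(Y)), class = "fiml_data")
}

# Observed-data log-likelihood of N(mu, Sigma) for prepared pattern data.
# Returns -Inf (not an error) when an observed submatrix is not positive
# definite, so optimizers can back off.
fiml_loglik_prepared <- function(prep, mu, Sigma) {
  ll <- 0
  for (pt in prep$patterns) {
    o <- pt$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- pt$ybar - mu[o]
    quad <- sum(Sinv * pt$S) + drop(crossprod(d, Sinv %*% d))
    ll <- ll - 0.5 * pt$m * (length(o) * log(2 * pi) + logdet + quad)
  }
  ll
}

#' Casewise (full-information) multivariate-normal log-likelihood
#'
#' Evaluates the observed-data log-likelihood of a multivariate normal
#' distribution for data with missing entries: each case contributes the
#' normal log-density of its observed variables under the corresponding
#' marginal of `N(mu, Sigma)`.  This is the likelihood underlying every
#' measurement and growth fit in the package, exposed directly so it can be
#' checked against independent implementations.
#'
#' @param Y numeric matrix (cases by variables), `NA` for missing entries.
#'   Cases with no observed variables are dropped.
#' @param mu mean vector, length `ncol(Y)`.
#' @param Sigma covariance matrix, `ncol(Y)` square, positive definite on
#'   every observed subset.
#' @return the scalar log-likelihood; `-Inf` if some observed submatrix of
#'   `Sigma` is not positive definite.
#' @examples
#' Y <- cbind(rnorm(10), rnorm(10))
#' Y[1, 2] <- NA
#' fiml_loglik(Y, c(0, 0), diag(2))
#' @export
fiml_loglik <- function(Y, mu, Sigma) {
  prep <- fiml_prepare(Y)
  if (length(mu) != prep$p || !all(dim(Sigma) == prep$p))
    stop_ef("mu/Sigma dimensions do not match data")
  fiml_loglik_prepared(prep, mu, Sigma)
}

# Saturated FIML model: unstructured mean and covariance maximizing the
# observed-data likelihood, estimated by EM for the multivariate normal with
# missing data.  Anchors the likelihood-ratio chi-square of every
# measurement fit and the SRMR residuals.
fiml_saturated <- function(Y, maxit = 2000L, tol = 1e-10) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  prep <- fiml_prepare(Y)
  n <- prep$n
  # initial values from available cases
  mu <- vapply(seq_len(p), function(j) mean(Y[, j], na.rm = TRUE), numeric(1))
  v <- vapply(seq_len(p), function(j) stats::var(Y[, j], na.rm = TRUE), numeric(1))
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  cc <- stats::complete.cases(Y)
  if (sum(cc) > p + 1) {
    Scc <- stats::cov(Y[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
    if (all(is.finite(Scc)) && min(eigen(Scc, symmetric = TRUE,
                                         only.values = TRUE)$values) > 1e-8)
      Sigma <- Scc
  }
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    # E-step: expected sufficient statistics, pattern by pattern
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pt in prep$patterns) {
      o <- pt$obs
      m <- setdiff(seq_len(p), o)
      mfull <- pt$m
      Eyo <- pt$ybar
      Syy <- pt$S + tcrossprod(pt$ybar)       # E[y_o y_o'] / pattern mean form
      if (length(m) == 0L) {
        T1[o] <- T1[o] + mfull * Eyo
        T2[o, o] <- T2[o, o] + mfull * Syy
      } else {
        B <- Sigma[m, o, drop = FALSE] %*% chol2inv(chol(Sigma[o, o, drop = FALSE]))
        C <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
        Eym_bar <- mu[m] + drop(B %*% (pt$ybar - mu[o]))
        # E over cases of y_m: mu_m + B (y_o - mu_o); collect cross moments
        # E[y_m y_o'] = B * E[y_o y_o'] + (mu_m - B mu_o) ybar'
        a <- mu[m] - drop(B %*% mu[o])
        Eymo <- B %*% Syy + tcrossprod(a, pt$ybar)
        # E[y_m y_m'] = C + B E[y_o y_o'] B' + a (B ybar)' + (B ybar) a' + a a'
        Bybar <- drop(B %*% pt$ybar)
        Eymm <- C + B %*% Syy %*% t(B) + tcrossprod(a, Bybar) +
          tcrossprod(Bybar, a) + tcrossprod(a)
        T1[o] <- T1[o] + mfull * Eyo
        T1[m] <- T1[m] + mfull * Eym_bar
        T2[o, o] <- T2[o, o] + mfull * Syy
        T2[m, o] <- T2[m, o] + mfull * Eymo
        T2[o, m] <- T2[o, m] + mfull * t(Eymo)
        T2[m, m] <- T2[m, m] + mfull * Eymm
      }
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- fiml_loglik_prepared(prep, mu, Sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, logL = ll,
       k = p + p * (p + 1) / 2, n = n, iterations = it)
}

# Independence baseline (means and variances free, covariances zero).  Under
# casewise likelihood the variables separate, so per-variable observed-data
# normal MLEs are exact.
fiml_baseline <- function(Y) {
  Y <- as.matrix(Y)
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    y <- y[!is.na(y)]
    m <- length(y)
    mu <- mean(y)
    s2 <- sum((y - mu)^2) / m
    ll <- ll - 0.5 * m * (log(2 * pi) + log(s2) + 1)
  }
  list(logL = ll, k = 2L * ncol(Y))
}
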
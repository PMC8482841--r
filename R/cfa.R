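# Confirmatory factor analysis of the four-test EF battery across one or
# three waves, estimated by casewise (full-information) maximum likelihood.
# Identification is the marker-indicator convention: the first loading of
# each factor is fixed at 1 and factor means are fixed at 0 at wave 1 (all
# waves, until the scalar model frees wave-2/3 factor means against
# wave-constant intercepts).  Cross-wave covariances among the wave factors
# are free, as are same-indicator residual covariances across waves.

# ---- model template ---------------------------------------------------------

# Builds the parameter bookkeeping for a given spec.  Equality constraints
# are expressed by sharing parameter names: entries mapped to one name are
# one free parameter.
cfa_template <- function(waves = 3L, factors = c("one", "two"),
                         invariance = c("configural", "metric", "scalar",
                                        "partial_scalar", "residual"),
                         free_intercepts = character()) {
  factors <- match.arg(factors)
  invariance <- match.arg(invariance)
  if (waves == 1L && invariance != "configural")
    stop_ef("invariance levels need multi-wave data")
  ind <- ef_indicators
  fmap <- if (factors == "one") list(ef = 1:4) else
    list(inhibition = 1:2, shifting = 3:4)
  Fw <- length(fmap)
  nfac <- Fw * waves
  nvar <- 4L * waves
  vnames <- paste0(rep(ind, waves), "_w", rep(seq_len(waves), each = 4L))
  fnames <- paste0(rep(names(fmap), waves), "_w",
                   rep(seq_len(waves), each = Fw))

  eq_load <- invariance %in% c("metric", "scalar", "partial_scalar", "residual")
  eq_tau <- invariance %in% c("scalar", "partial_scalar", "residual")
  eq_thv <- invariance == "residual"

  lam <- NULL
  tau_par <- character(nvar)
  thv_par <- character(nvar)
  for (w in seq_len(waves)) for (g in seq_len(Fw)) {
    idx <- fmap[[g]]
    for (pos in seq_along(idx)) {
      i <- idx[pos]
      v <- (w - 1L) * 4L + i
      par <- if (pos == 1L) NA_character_ else if (eq_load)
        paste0("lam_", ind[i]) else paste0("lam_", ind[i], "_w", w)
      lam <- rbind(lam, data.frame(v = v, f = (w - 1L) * Fw + g, par = par,
                                   stringsAsFactors = FALSE))
    }
  }
  for (w in seq_len(waves)) for (i in 1:4) {
    v <- (w - 1L) * 4L + i
    freed <- paste0(ind[i], "_w", w) %in% free_intercepts
    tau_par[v] <- if (eq_tau && !freed) paste0("tau_", ind[i]) else
      paste0("tau_", ind[i], "_w", w)
    thv_par[v] <- if (eq_thv) paste0("thv_", ind[i]) else
      paste0("thv_", ind[i], "_w", w)
  }
  thc <- NULL
  if (waves > 1L) {
    for (i in 1:4) {
      pairs <- utils::combn(seq_len(waves), 2L)
      for (k in seq_len(ncol(pairs))) {
        w1 <- pairs[1L, k]; w2 <- pairs[2L, k]
        thc <- rbind(thc, data.frame(
          v1 = (w1 - 1L) * 4L + i, v2 = (w2 - 1L) * 4L + i,
          par = paste0("thc_", ind[i], "_w", w1, w2),
          stringsAsFactors = FALSE))
      }
    }
  }
  psi <- NULL
  for (r in seq_len(nfac)) for (cc in seq_len(r)) {
    psi <- rbind(psi, data.frame(r = r, c = cc,
                                 par = paste0("psi_l_", r, "_", cc),
                                 diag = r == cc, stringsAsFactors = FALSE))
  }
  alpha_par <- rep(NA_character_, nfac)
  if (eq_tau && waves > 1L) {
    for (w in 2:waves) for (g in seq_len(Fw))
      alpha_par[(w - 1L) * Fw + g] <- paste0("alpha_", names(fmap)[g], "_w", w)
  }
  free <- unique(c(stats::na.omit(lam$par), tau_par, thv_par, thc$par,
                   psi$par, stats::na.omit(alpha_par)))
  tpl <- list(waves = waves, factors = factors, invariance = invariance,
              free_intercepts = free_intercepts, fmap = fmap, Fw = Fw,
              nfac = nfac, nvar = nvar, vnames = vnames, fnames = fnames,
              lam = lam, tau_par = tau_par, thv_par = thv_par, thc = thc,
              psi = psi, alpha_par = alpha_par, par_names = free,
              k = length(free))
  # integer index maps (0 = fixed) so moment assembly avoids name lookups
  pidx <- function(p) ifelse(is.na(p), 0L, match(p, free))
  tpl$ix <- list(
    lam_v = lam$v, lam_f = lam$f, lam_i = pidx(lam$par),
    tau_i = pidx(tau_par), thv_i = pidx(thv_par),
    thc_v1 = thc$v1, thc_v2 = thc$v2, thc_i = pidx(thc$par),
    psi_r = psi$r, psi_c = psi$c, psi_i = pidx(psi$par),
    psi_diag = psi$diag, alpha_i = pidx(alpha_par))
  tpl
}

# theta (vector aligned to tpl$par_names) -> list(mu, Sigma, Lambda, Psi,
# Theta, tau, alpha).  Variance-type parameters (thv_*, psi diagonal) live
# on the log scale.  Index-map based: no name lookups on the hot path.
cfa_moments <- function(tpl, theta) {
  ix <- tpl$ix
  L <- matrix(0, tpl$nvar, tpl$nfac)
  lam_val <- rep(1, length(ix$lam_i))
  free <- ix$lam_i > 0L
  lam_val[free] <- theta[ix$lam_i[free]]
  L[cbind(ix$lam_v, ix$lam_f)] <- lam_val
  tau <- theta[ix$tau_i]
  thv <- exp(theta[ix$thv_i])
  Theta <- diag(thv, tpl$nvar)
  if (length(ix$thc_i)) {
    vals <- theta[ix$thc_i]
    Theta[cbind(ix$thc_v1, ix$thc_v2)] <- vals
    Theta[cbind(ix$thc_v2, ix$thc_v1)] <- vals
  }
  Lo <- matrix(0, tpl$nfac, tpl$nfac)
  pv <- theta[ix$psi_i]
  pv[ix$psi_diag] <- exp(pv[ix$psi_diag])
  Lo[cbind(ix$psi_r, ix$psi_c)] <- pv
  Psi <- tcrossprod(Lo)
  alpha <- numeric(tpl$nfac)
  has_a <- ix$alpha_i > 0L
  if (any(has_a)) alpha[has_a] <- theta[ix$alpha_i[has_a]]
  mu <- as.numeric(tau + L %*% alpha)
  Sigma <- L %*% Psi %*% t(L) + Theta
  list(mu = mu, Sigma = (Sigma + t(Sigma)) / 2, Lambda = L, Psi = Psi,
       Theta = Theta, tau = as.numeric(tau), alpha = alpha)
}

# Heuristic starting values from observed moments.
cfa_start <- function(tpl, Y) {
  th <- numeric(tpl$k)
  names(th) <- tpl$par_names
  mny <- vapply(seq_len(tpl$nvar), function(j) mean(Y[, j], na.rm = TRUE),
                numeric(1))
  vry <- vapply(seq_len(tpl$nvar), function(j) {
    v <- stats::var(Y[, j], na.rm = TRUE)
    if (!is.finite(v) || v <= 1e-8) 1 else v
  }, numeric(1))
  for (v in seq_len(tpl$nvar)) {
    th[tpl$tau_par[v]] <- mny[v]
    th[tpl$thv_par[v]] <- log(0.4 * vry[v])
  }
  # marker variable per factor
  markers <- integer(tpl$nfac)
  for (k in seq_len(nrow(tpl$lam))) {
    row <- tpl$lam[k, ]
    if (is.na(row$par) && markers[row$f] == 0L) markers[row$f] <- row$v
  }
  for (f in seq_len(tpl$nfac))
    th[paste0("psi_l_", f, "_", f)] <- 0.5 * log(0.6 * vry[markers[f]])
  lam_free <- unique(stats::na.omit(tpl$lam$par))
  th[lam_free] <- 0.9
  # averaged tau for shared intercepts
  shared_tau <- unique(tpl$tau_par[duplicated(tpl$tau_par)])
  for (p in shared_tau) th[p] <- mean(mny[tpl$tau_par == p])
  th
}

# ---- fitting ----------------------------------------------------------------

cfa_negloglik <- function(theta, tpl, prep) {
  mo <- cfa_moments(tpl, theta)
  ll <- fiml_loglik_prepared(prep, mo$mu, mo$Sigma)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Analytic gradient of the negative log-likelihood.  Per pattern the
# derivatives of the log-likelihood with respect to the implied moments are
#   dl/dSigma_oo = m/2 (S^{-1} (S + d d') S^{-1} - S^{-1}),
#   dl/dmu_o     = m S^{-1} d,
# which are assembled into full-matrix accumulators and contracted with the
# structured derivatives of (mu, Sigma) in each parameter.
cfa_negloglik_gr <- function(theta, tpl, prep) {
  mo <- cfa_moments(tpl, theta)
  nv <- tpl$nvar
  A <- matrix(0, nv, nv)
  b <- numeric(nv)
  for (pt in prep$patterns) {
    o <- pt$obs
    So <- mo$Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    Sinv <- chol2inv(ch)
    d <- pt$ybar - mo$mu[o]
    M <- Sinv %*% (pt$S + tcrossprod(d)) %*% Sinv
    A[o, o] <- A[o, o] + pt$m / 2 * (M - Sinv)
    b[o] <- b[o] + pt$m * drop(Sinv %*% d)
  }
  ix <- tpl$ix
  grad <- numeric(length(theta))
  acc <- function(idx, contrib) {
    keep <- idx > 0L
    if (!any(keep)) return(invisible())
    s <- rowsum(contrib[keep], idx[keep])
    j <- as.integer(rownames(s))
    grad[j] <<- grad[j] + s[, 1L]
  }
  LP <- mo$Lambda %*% mo$Psi            # nvar x nfac
  MA <- A %*% LP                        # nvar x nfac
  # loadings: dSigma = e_v (Lambda Psi)_f' + sym; dmu = alpha_f e_v
  acc(ix$lam_i, 2 * MA[cbind(ix$lam_v, ix$lam_f)] +
        b[ix$lam_v] * mo$alpha[ix$lam_f])
  # intercepts
  acc(ix$tau_i, b)
  # residual log-variances
  acc(ix$thv_i, diag(A) * exp(theta[ix$thv_i]))
  # residual cross-wave covariances
  if (length(ix$thc_i)) acc(ix$thc_i, 2 * A[cbind(ix$thc_v1, ix$thc_v2)])
  # factor-covariance Cholesky
  B <- crossprod(mo$Lambda, A %*% mo$Lambda)   # nfac x nfac, symmetric
  Lo <- matrix(0, tpl$nfac, tpl$nfac)
  pv <- theta[ix$psi_i]
  pv[ix$psi_diag] <- exp(pv[ix$psi_diag])
  Lo[cbind(ix$psi_r, ix$psi_c)] <- pv
  BL <- B %*% Lo
  contrib <- 2 * BL[cbind(ix$psi_r, ix$psi_c)]
  contrib[ix$psi_diag] <- contrib[ix$psi_diag] * pv[ix$psi_diag]
  acc(ix$psi_i, contrib)
  # factor means
  acc(ix$alpha_i, drop(crossprod(mo$Lambda, b)))
  -grad
}

#' Fit the EF measurement model by full-information maximum likelihood
#'
#' One- or two-factor confirmatory factor analysis of the four EF
#' indicators, across one or three waves, with the chosen level of
#' longitudinal equality constraints.  Missing indicator values contribute
#' through their observed marginals (casewise likelihood).  Likelihood-ratio
#' fit statistics are computed against the saturated FIML model (means and
#' covariances unstructured, estimated by EM), with CFI from the
#' independence baseline, RMSEA as sqrt(max(chi2 - df, 0) / (df n)), and
#' SRMR from correlation-scale residuals between the saturated and
#' model-implied moments.
#'
#' @param data cohort data frame or numeric matrix holding the indicator
#'   columns (`stroop_w1`, ..., `ctrails_w3`; for `waves = 1` only `_w1`).
#' @param waves 1 or 3.
#' @param factors `"one"` (all four tests on one EF factor) or `"two"`
#'   (Stroop + Hayling on inhibition, Brixton + Color Trails on shifting).
#' @param invariance equality level: `"configural"`, `"metric"` (equal
#'   loadings), `"scalar"` (+ equal intercepts), `"partial_scalar"` (equal
#'   intercepts except `free_intercepts`), `"residual"` (+ equal residual
#'   variances).
#' @param free_intercepts character vector like `"hayling_w3"` naming
#'   intercepts left free under `"partial_scalar"`.
#' @param start optional named starting values.
#' @param restarts maximum number of (jittered) optimization attempts.
#' @param se compute standard errors from the inverse observed information
#'   (numerical Hessian); disable in tight simulation loops.
#' @return object of class `ef_cfa` with parameter estimates, fit indices
#'   (`$fit`), the implied moments, and a `converged` flag.
#' @seealso [predict.ef_cfa()] for factor scores, [ef_invariance()] for the
#'   invariance ladder.
#' @export
ef_cfa <- function(data, waves = 3L, factors = c("one", "two"),
                   invariance = c("configural", "metric", "scalar",
                                  "partial_scalar", "residual"),
                   free_intercepts = character(), start = NULL,
                   restarts = 3L, se = FALSE) {
  factors <- match.arg(factors)
  invariance <- match.arg(invariance)
  tpl <- cfa_template(waves, factors, invariance, free_intercepts)
  Y <- as.matrix(as.data.frame(data)[, tpl$vnames])
  storage.mode(Y) <- "double"
  if (nrow(Y) <= tpl$k)
    stop_ef("need more cases (", nrow(Y), ") than free parameters (", tpl$k, ")")
  prep <- fiml_prepare(Y)
  th0 <- cfa_start(tpl, Y)
  if (!is.null(start)) {
    common <- intersect(names(start), names(th0))
    th0[common] <- start[common]
  }
  best <- NULL
  for (attempt in seq_len(max(1L, restarts))) {
    init <- if (attempt == 1L) th0 else
      th0 + stats::rnorm(length(th0), 0, 0.1)
    opt <- tryCatch(
      stats::optim(init, cfa_negloglik, gr = cfa_negloglik_gr,
                   tpl = tpl, prep = prep, method = "BFGS",
                   control = list(maxit = 1000L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (!is.null(best) && best$convergence == 0 && best$value < 1e9) break
  }
  if (is.null(best)) stop_ef("measurement model optimization failed")
  theta <- best$par
  logL <- -best$value
  mo <- cfa_moments(tpl, theta)
  sat <- fiml_saturated(Y)
  base <- fiml_baseline(Y)
  n <- prep$n
  fit <- cfa_fit_indices(logL, tpl$k, sat, base, n, mo)
  heywood <- any(exp(theta[tpl$thv_par]) < 1e-4)
  ses <- NULL
  if (se) {
    H <- num_hessian(cfa_negloglik, theta, tpl = tpl, prep = prep)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      ses <- ifelse(d > 0, sqrt(d), NA_real_)
      names(ses) <- names(theta)
    }
  }
  out <- list(theta = theta, se = ses, template = tpl, moments = mo,
              logL = logL, k = tpl$k, n = n, fit = fit,
              saturated = sat, baseline = base,
              converged = best$convergence == 0, heywood = heywood,
              data = Y)
  class(out) <- "ef_cfa"
  out
}

cfa_fit_indices <- function(logL, k, sat, base, n, mo) {
  chi2 <- max(0, 2 * (sat$logL - logL))
  df <- sat$k - k
  chi2_b <- max(0, 2 * (sat$logL - base$logL))
  df_b <- sat$k - base$k
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * n)) else 0
  cfi <- {
    num <- max(chi2 - df, 0)
    den <- max(chi2 - df, chi2_b - df_b, 0)
    if (den <= 0) 1 else 1 - num / den
  }
  # SRMR on correlation residuals between saturated and implied moments
  Ssat <- sat$Sigma; Simp <- mo$Sigma
  dsat <- sqrt(diag(Ssat)); dimp <- sqrt(diag(Simp))
  Rsat <- Ssat / tcrossprod(dsat); Rimp <- Simp / tcrossprod(dimp)
  p_ <- nrow(Ssat)
  lower <- lower.tri(Rsat)
  res <- c((Rsat - Rimp)[lower], (dsat - dimp) / dsat,
           (sat$mu - mo$mu) / dsat)
  srmr <- sqrt(mean(c((Rsat - Rimp)[lower], ((dsat - dimp) / dsat))^2))
  list(chi2 = chi2, df = df, p = p, cfi = cfi, rmsea = rmsea, srmr = srmr,
       logL = logL, n_free_params = k,
       aic = -2 * logL + 2 * k, bic = -2 * logL + k * log(n))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ef_cfa <- function(x, ...) {
  tpl <- x$template
  cat("EF measurement model (", tpl$factors, "-factor, ", tpl$waves,
      " wave", if (tpl$waves > 1L) "s", ", ", tpl$invariance,
      " invariance)\n", sep = "")
  if (length(tpl$free_intercepts))
    cat("  freed intercepts:", paste(tpl$free_intercepts, collapse = ", "), "\n")
  cat(sprintf("  n = %d, free parameters = %d, logL = %.3f%s\n", x$n, x$k,
              x$logL, if (x$converged) "" else "  [NOT CONVERGED]"))
  with(x$fit, cat(sprintf(
    "  chi2(%d) = %.3f, p = %.3f | CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
    df, chi2, p, cfi, rmsea, srmr)))
  if (x$heywood) cat("  note: residual variance at boundary (Heywood case)\n")
  invisible(x)
}

#' @export
coef.ef_cfa <- function(object, ...) object$theta

#' @export
logLik.ef_cfa <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.ef_cfa <- function(object, ...) {
  tpl <- object$template
  mo <- object$moments
  loadings <- matrix(NA_real_, 4L, tpl$nfac,
                     dimnames = list(ef_indicators, tpl$fnames))
  for (k in seq_len(nrow(tpl$lam))) {
    row <- tpl$lam[k, ]
    i <- (row$v - 1L) %% 4L + 1L
    loadings[i, row$f] <- mo$Lambda[row$v, row$f]
  }
  out <- list(call_info = tpl, loadings = loadings,
              intercepts = matrix(mo$tau, 4L, tpl$waves,
                                  dimnames = list(ef_indicators,
                                                  paste0("w", seq_len(tpl$waves)))),
              residual_variances = matrix(diag(mo$Theta), 4L, tpl$waves,
                                          dimnames = list(ef_indicators,
                                                          paste0("w", seq_len(tpl$waves)))),
              factor_cov = mo$Psi, factor_means = mo$alpha,
              fit = object$fit, converged = object$converged,
              heywood = object$heywood, n = object$n)
  class(out) <- "summary.ef_cfa"
  out
}

#' @export
print.summary.ef_cfa <- function(x, digits = 3, ...) {
  cat("Loadings:\n"); print(round(x$loadings, digits))
  cat("Intercepts:\n"); print(round(x$intercepts, digits))
  cat("Residual variances:\n"); print(round(x$residual_variances, digits))
  cat("Factor covariance matrix:\n"); print(round(x$factor_cov, digits))
  if (any(x$factor_means != 0)) {
    cat("Factor means:\n"); print(round(x$factor_means, digits))
  }
  with(x$fit, cat(sprintf(
    "chi2(%d) = %.3f, p = %.3f | CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
    df, chi2, p, cfi, rmsea, srmr)))
  invisible(x)
}

#' Serialize a measurement fit to JSON
#'
#' Writes parameter estimates, standard errors (if computed), fit indices
#' and the constraint map.
#'
#' @param fit an `ef_cfa` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_measurement_json <- function(fit, path) {
  tpl <- fit$template
  obj <- list(model = list(factors = tpl$factors, waves = tpl$waves,
                           invariance = tpl$invariance,
                           free_intercepts = tpl$free_intercepts),
              estimates = as.list(fit$theta),
              se = if (is.null(fit$se)) NULL else as.list(fit$se),
              fit = fit$fit, n = fit$n, converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
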
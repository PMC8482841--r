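# Latent growth models for EF factor scores on an age metric (accelerated
# longitudinal design; age centered at 75 by default).  Each participant's
# observed waves contribute a marginal multivariate-normal density with
# mean X_i beta and covariance Z_i G Z_i' + R_i, where Z_i = (1, t_i) holds
# the centered ages, G is the random intercept/slope covariance and R_i is
# diagonal with per-wave (default) or common residual variances.  Fixed
# effects are profiled out by generalized least squares at each variance
# evaluation, so the optimizer works in at most six dimensions; the
# likelihood itself is evaluated per missingness pattern with closed-form
# inverses of the (at most 3 x 3) per-person covariance, vectorized over
# participants.

growth_stages <- c("null", "random_intercept", "fixed_slope",
                   "random_slope", "fixed_quadratic")

# ---- likelihood internals ---------------------------------------------------

# Precompute per-pattern data.  scores/ages: n x W matrices; Xint/Xslp:
# fixed-effect covariate matrices at intercept and slope level.
growth_prepare <- function(scores, ages, Xint, Xslp, quad, center) {
  obs <- !is.na(scores) & !is.na(ages)
  keep <- rowSums(obs) > 0L
  idx_keep <- which(keep)
  obs <- obs[keep, , drop = FALSE]
  scores <- scores[keep, , drop = FALSE]
  tmat <- (ages - center)[keep, , drop = FALSE]
  Xint <- Xint[keep, , drop = FALSE]
  if (!is.null(Xslp)) Xslp <- Xslp[keep, , drop = FALSE]
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- lapply(split(seq_len(nrow(scores)), key), function(rows) {
    waves <- which(obs[rows[1L], ])
    k <- length(waves)
    Tm <- tmat[rows, waves, drop = FALSE]
    Ym <- scores[rows, waves, drop = FALSE]
    Xl <- lapply(seq_len(k), function(a) {
      blocks <- list(Xint[rows, , drop = FALSE])
      if (!is.null(Xslp)) blocks <- c(blocks, list(Tm[, a] * Xslp[rows, , drop = FALSE]))
      if (quad) blocks <- c(blocks, list(matrix(Tm[, a]^2, ncol = 1L)))
      do.call(cbind, blocks)
    })
    list(rows = rows, waves = waves, k = k, m = length(rows),
         Tm = Tm, Ym = Ym, Xl = Xl)
  })
  list(patterns = pats, n = nrow(scores), N = sum(obs),
       p = ncol(pats[[1L]]$Xl[[1L]]), kept = idx_keep,
       max_obs = max(rowSums(obs)))
}

# Closed-form inverse and log-determinant of the stack of per-person k x k
# covariance matrices (k <= 3), given entries as m-vectors.
vinv_stack <- function(V, k) {
  if (k == 1L) {
    d <- V[[1]][[1]]
    if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
    list(W = list(list(1 / d)), logdet = log(d))
  } else if (k == 2L) {
    a <- V[[1]][[1]]; b <- V[[1]][[2]]; d <- V[[2]][[2]]
    det <- a * d - b^2
    if (any(!is.finite(det)) || any(det <= 0) || any(a <= 0)) return(NULL)
    W <- list(list(d / det, -b / det), list(-b / det, a / det))
    list(W = W, logdet = log(det))
  } else {
    a <- V[[1]][[1]]; b <- V[[1]][[2]]; cc <- V[[1]][[3]]
    d <- V[[2]][[2]]; e <- V[[2]][[3]]; f <- V[[3]][[3]]
    A11 <- d * f - e^2
    A12 <- cc * e - b * f
    A13 <- b * e - cc * d
    det <- a * A11 + b * A12 + cc * A13
    if (any(!is.finite(det)) || any(det <= 0) || any(a <= 0)) return(NULL)
    A22 <- a * f - cc^2
    A23 <- b * cc - a * e
    A33 <- a * d - b^2
    W <- list(list(A11 / det, A12 / det, A13 / det),
              list(A12 / det, A22 / det, A23 / det),
              list(A13 / det, A23 / det, A33 / det))
    list(W = W, logdet = log(det))
  }
}

# Build the stack of V entries for one pattern from variance components.
growth_V <- function(pt, g, r, common_resid) {
  k <- pt$k
  V <- vector("list", k)
  for (a in seq_len(k)) {
    V[[a]] <- vector("list", k)
    for (b in seq_len(k)) {
      if (b < a) { V[[a]][[b]] <- V[[b]][[a]]; next }
      v <- rep(g[1L], pt$m)
      if (length(g) > 1L)
        v <- v + g[2L] * (pt$Tm[, a] + pt$Tm[, b]) + g[3L] * pt$Tm[, a] * pt$Tm[, b]
      if (a == b)
        v <- v + if (common_resid) r[1L] else r[pt$waves[a]]
      V[[a]][[b]] <- v
    }
  }
  V
}

# phi -> variance components for a given stage
phi_to_vc <- function(phi, stage, common_resid, n_waves) {
  nr <- if (common_resid) 1L else n_waves
  r <- exp(phi[seq_len(nr)])
  rest <- phi[-seq_len(nr)]
  g <- if (stage == "null") 0 else
    if (stage %in% c("random_intercept", "fixed_slope"))
    exp(rest[1L])^2 else {
      L <- matrix(c(exp(rest[1L]), rest[2L], 0, exp(rest[3L])), 2L)
      G <- L %*% t(L)
      c(G[1L, 1L], G[1L, 2L], G[2L, 2L])
    }
  list(g = g, r = r)
}

# Profiled negative log-likelihood: GLS fixed effects at each phi.
# Returns the value plus (optionally) beta and its GLS information.
growth_profile <- function(phi, prep, stage, common_resid, n_waves,
                           want_beta = FALSE) {
  vc <- phi_to_vc(phi, stage, common_resid, n_waves)
  p <- prep$p
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  Ws <- vector("list", length(prep$patterns))
  logdet_sum <- 0
  for (j in seq_along(prep$patterns)) {
    pt <- prep$patterns[[j]]
    V <- growth_V(pt, vc$g, vc$r, common_resid)
    iv <- vinv_stack(V, pt$k)
    if (is.null(iv)) return(if (want_beta) NULL else 1e10)
    Ws[[j]] <- iv$W
    logdet_sum <- logdet_sum + sum(iv$logdet)
    for (a in seq_len(pt$k)) for (b in seq_len(pt$k)) {
      w <- iv$W[[a]][[b]]
      A <- A + crossprod(pt$Xl[[a]], w * pt$Xl[[b]])
      bvec <- bvec + drop(crossprod(pt$Xl[[a]], w * pt$Ym[, b]))
    }
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(if (want_beta) NULL else 1e10)
  quad <- 0
  for (j in seq_along(prep$patterns)) {
    pt <- prep$patterns[[j]]
    E <- vapply(seq_len(pt$k), function(a)
      pt$Ym[, a] - drop(pt$Xl[[a]] %*% beta), numeric(pt$m))
    E <- matrix(E, nrow = pt$m)
    for (a in seq_len(pt$k)) for (b in seq_len(pt$k))
      quad <- quad + sum(Ws[[j]][[a]][[b]] * E[, a] * E[, b])
  }
  nll <- 0.5 * (logdet_sum + quad + prep$N * log(2 * pi))
  if (want_beta) list(nll = nll, beta = beta, A = A) else nll
}

# Unprofiled negative log-likelihood in (beta, phi); used for the observed
# information (numerical Hessian).
growth_nll_full <- function(par, prep, stage, common_resid, n_waves, p) {
  beta <- par[seq_len(p)]
  phi <- par[-seq_len(p)]
  vc <- phi_to_vc(phi, stage, common_resid, n_waves)
  nll <- 0.5 * prep$N * log(2 * pi)
  for (pt in prep$patterns) {
    V <- growth_V(pt, vc$g, vc$r, common_resid)
    iv <- vinv_stack(V, pt$k)
    if (is.null(iv)) return(1e10)
    E <- vapply(seq_len(pt$k), function(a)
      pt$Ym[, a] - drop(pt$Xl[[a]] %*% beta), numeric(pt$m))
    E <- matrix(E, nrow = pt$m)
    quad <- 0
    for (a in seq_len(pt$k)) for (b in seq_len(pt$k))
      quad <- quad + sum(iv$W[[a]][[b]] * E[, a] * E[, b])
    nll <- nll + 0.5 * (sum(iv$logdet) + quad)
  }
  nll
}

#' Marginal log-likelihood of a growth model
#'
#' Evaluates the growth-model log-likelihood at given parameter values:
#' each participant contributes the multivariate-normal log-density of the
#' scores at their observed waves, with mean `intercept + slope * t`
#' (plus optional predictor and quadratic terms) and covariance
#' `Z G Z' + R`.  Exposed for direct checking against per-case evaluation.
#'
#' @param scores,ages n x W matrices (NA = missing).
#' @param beta named fixed-effect vector as produced by [ef_growth()].
#' @param G random-effect covariance: `NULL` (none), scalar (intercept
#'   variance) or 2 x 2 matrix.
#' @param resid_var residual variances: length W (per wave) or 1 (common).
#' @param risk,sex optional predictor vectors.
#' @param center centering age (default 75).
#' @param stage growth stage, see [ef_growth()].
#' @return scalar log-likelihood.
#' @export
growth_loglik <- function(scores, ages, beta, G = NULL, resid_var,
                          risk = NULL, sex = NULL, center = 75,
                          stage = "random_slope") {
  des <- growth_design(scores, ages, risk, sex, stage, center)
  common <- length(resid_var) == 1L
  phi <- log(resid_var)
  if (stage == "null") {
    gphi <- numeric(0)
  } else if (stage %in% c("random_intercept", "fixed_slope")) {
    gphi <- 0.5 * log(G[1L])
  } else {
    G <- as.matrix(G)
    L <- t(chol(G + diag(1e-14, 2L)))
    gphi <- c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]))
  }
  par <- c(beta, phi, gphi)
  -growth_nll_full(par, des$prep, stage, common, ncol(scores), length(beta))
}

# shared design assembly
growth_design <- function(scores, ages, risk, sex, stage, center) {
  scores <- as.matrix(scores); ages <- as.matrix(ages)
  n <- nrow(scores)
  covs <- list()
  if (!is.null(risk)) covs$risk <- risk
  if (!is.null(sex)) covs$sex <- sex
  dropped <- character()
  for (nm in names(covs)) {
    if (length(unique(covs[[nm]][!is.na(covs[[nm]])])) < 2L) {
      warning("predictor '", nm, "' is constant; dropped from the model",
              call. = FALSE)
      covs[[nm]] <- NULL
      dropped <- c(dropped, nm)
    }
  }
  complete <- rep(TRUE, n)
  for (v in covs) complete <- complete & !is.na(v)
  Xint <- cbind(intercept = rep(1, n),
                if (length(covs)) do.call(cbind, covs))
  colnames(Xint) <- c("intercept", names(covs))
  has_slope <- stage %in% c("fixed_slope", "random_slope", "fixed_quadratic")
  Xslp <- if (has_slope) {
    x <- Xint
    colnames(x) <- c("slope", if (length(covs)) paste0(names(covs), "_slope"))
    x
  } else NULL
  scores[!complete, ] <- NA
  prep <- growth_prepare(scores, ages, Xint, Xslp,
                         quad = stage == "fixed_quadratic", center)
  if (has_slope && prep$max_obs < 2L)
    stop_ef("slope parameters are not identified: no participant has ",
            "more than one observed wave")
  beta_names <- c(colnames(Xint),
                  if (has_slope) colnames(Xslp),
                  if (stage == "fixed_quadratic") "quadratic")
  list(prep = prep, beta_names = beta_names, dropped = dropped,
       n_used = sum(complete & rowSums(!is.na(scores) & !is.na(ages)) > 0))
}

#' Fit a latent growth model on EF factor scores
#'
#' Maximum-likelihood random-coefficient growth model with age (centered at
#' `center`) as the time metric.  Stages follow the model-building ladder:
#' `"null"` (flat mean, no random effects), `"random_intercept"`,
#' `"fixed_slope"`, `"random_slope"` (the default, and the conditional
#' model used for risk-score analyses) and `"fixed_quadratic"`.  Optional
#' `risk` and `sex` predictors enter the intercept regression and, from the
#' fixed-slope stage on, the slope regression.  Participants with missing
#' predictors are dropped; constant predictors are dropped with a warning.
#' Standard errors come from the inverse observed information (numerical
#' Hessian of the joint likelihood) and p-values from two-sided Wald z
#' tests.
#'
#' @param scores n x W matrix of factor scores (or a cohort with
#'   `ef_w*` columns).
#' @param ages n x W matrix of ages at testing (or taken from `age_w*`
#'   columns of `scores` when it is a cohort data frame).
#' @param risk,sex optional per-person predictors (sex: female = 1).
#' @param stage growth stage (see above).
#' @param residuals `"per_wave"` (default) or `"common"`.
#' @param center centering age in years.
#' @param se compute standard errors (disable inside simulation loops).
#' @return object of class `ef_growth` with elements `coefficients`
#'   (fixed effects), `se`, `p`, `G`, `resid_var`, `logL`, `k`, `n`,
#'   `aic`/`bic`, `converged`, `boundary`.
#' @export
ef_growth <- function(scores, ages = NULL, risk = NULL, sex = NULL,
                      stage = c("random_slope", "null", "random_intercept",
                                "fixed_slope", "fixed_quadratic"),
                      residuals = c("per_wave", "common"), center = 75,
                      se = TRUE) {
  stage <- match.arg(stage)
  residuals <- match.arg(residuals)
  if (is.data.frame(scores)) {
    df <- scores
    wcols <- grep("^ef_w[0-9]+$", names(df), value = TRUE)
    if (!length(wcols)) stop_ef("no ef_w* columns found")
    if (is.null(ages)) ages <- as.matrix(df[, sub("^ef", "age", wcols)])
    scores <- as.matrix(df[, wcols])
  }
  scores <- as.matrix(scores); ages <- as.matrix(ages)
  stopifnot(all(dim(scores) == dim(ages)))
  W <- ncol(scores)
  common <- residuals == "common"
  des <- growth_design(scores, ages, risk, sex, stage, center)
  prep <- des$prep
  p <- prep$p

  # variance-parameter start values
  v1 <- stats::var(scores[, 1L], na.rm = TRUE)
  if (!is.finite(v1) || v1 <= 0) v1 <- 1
  nr <- if (common) 1L else W
  phi0 <- rep(log(0.4 * v1), nr)
  if (stage %in% c("random_intercept", "fixed_slope"))
    phi0 <- c(phi0, 0.5 * log(0.6 * v1))
  if (stage %in% c("random_slope", "fixed_quadratic"))
    phi0 <- c(phi0, 0.5 * log(0.6 * v1), 0, log(0.02))

  if (length(phi0)) {
    opt <- stats::optim(phi0, growth_profile, prep = prep, stage = stage,
                        common_resid = common, n_waves = W, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-12))
    phi <- opt$par
    converged <- opt$convergence == 0
  } else {
    phi <- numeric(0); converged <- TRUE
  }
  pr <- growth_profile(phi, prep, stage, common, W, want_beta = TRUE)
  if (is.null(pr)) stop_ef("growth model likelihood degenerate at optimum")
  beta <- pr$beta
  names(beta) <- des$beta_names
  logL <- -pr$nll
  vc <- phi_to_vc(phi, stage, common, W)
  G <- if (stage == "null") NULL else
    if (stage %in% c("random_intercept", "fixed_slope"))
    matrix(vc$g[1L], 1L, 1L) else
      matrix(vc$g[c(1L, 2L, 2L, 3L)], 2L, 2L,
             dimnames = list(c("intercept", "slope"),
                             c("intercept", "slope")))
  k <- p + length(phi)
  n <- des$n_used
  boundary <- length(phi) > 0 &&
    (any(vc$r < 1e-8) || (stage != "null" && vc$g[1L] < 1e-8) ||
     (length(vc$g) == 3L && vc$g[3L] < 1e-10))
  ses <- pvals <- rep(NA_real_, p)
  vcov_full <- NULL
  if (se) {
    H <- num_hessian(growth_nll_full, c(beta, phi), prep = prep,
                     stage = stage, common_resid = common, n_waves = W, p = p)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(p)] > 0)) {
      ses <- sqrt(diag(V)[seq_len(p)])
      pvals <- 2 * stats::pnorm(-abs(beta / ses))
      vcov_full <- V
    }
  }
  names(ses) <- names(pvals) <- names(beta)
  ic <- information_criteria(logL, k, n)
  out <- list(coefficients = beta, se = ses, p = pvals, G = G,
              resid_var = vc$r, stage = stage, residuals = residuals,
              center = center, logL = logL, k = k, n = n, N = prep$N,
              minus2LL = ic[["minus2LL"]], aic = ic[["aic"]],
              bic = ic[["bic"]], converged = converged,
              boundary = boundary, dropped = des$dropped,
              vcov = vcov_full, phi = phi)
  class(out) <- "ef_growth"
  out
}

#' Information criteria from a log-likelihood
#'
#' `-2LL = -2 logL`; `AIC = -2LL + 2k`; `BIC = -2LL + k log(n)`.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters (floored at 1).
#' @param n sample size (floored at 1).
#' @return named vector `minus2LL`, `aic`, `bic`.
#' @examples
#' information_criteria(-700.892, 12, 524)
#' @export
information_criteria <- function(logL, k, n) {
  k <- max(1, k); n <- max(1, n)
  m2 <- -2 * logL
  c(minus2LL = m2, aic = m2 + 2 * k, bic = m2 + k * log(n))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ef_growth <- function(x, digits = 3, ...) {
  cat("Latent growth model (", x$stage, ", ", x$residuals, " residuals, age - ",
      x$center, ")\n", sep = "")
  cat(sprintf("  n = %d participants, %d observations; logL = %.3f, k = %d\n",
              x$n, x$N, x$logL, x$k))
  cat(sprintf("  -2LL = %.3f, AIC = %.3f, BIC = %.3f%s%s\n", x$minus2LL,
              x$aic, x$bic, if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$boundary) "  [variance at boundary]" else ""))
  tab <- data.frame(beta = round(x$coefficients, digits),
                    se = round(x$se, digits), p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' @export
summary.ef_growth <- function(object, ...) {
  object
}

#' @export
coef.ef_growth <- function(object, ...) object$coefficients

#' @export
logLik.ef_growth <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.ef_growth <- function(object, ...) {
  if (is.null(object$vcov)) return(NULL)
  p <- length(object$coefficients)
  V <- object$vcov[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' Predicted mean EF trajectory
#'
#' @param object an `ef_growth` fit.
#' @param ages ages (years) at which to predict.
#' @param risk,sex predictor values (scalars or vectors recycled against
#'   `ages`); required if the model includes them.
#' @param ... unused.
#' @return numeric vector of predicted mean EF.
#' @export
predict.ef_growth <- function(object, ages, risk = NULL, sex = NULL, ...) {
  b <- object$coefficients
  t <- ages - object$center
  out <- rep(b[["intercept"]], length(t))
  if ("risk" %in% names(b)) {
    if (is.null(risk)) stop_ef("model includes risk; supply risk =")
    out <- out + b[["risk"]] * risk
  }
  if ("sex" %in% names(b)) {
    if (is.null(sex)) stop_ef("model includes sex; supply sex =")
    out <- out + b[["sex"]] * sex
  }
  if ("slope" %in% names(b)) {
    slope <- b[["slope"]]
    if ("risk_slope" %in% names(b)) slope <- slope + b[["risk_slope"]] * risk
    if ("sex_slope" %in% names(b)) slope <- slope + b[["sex_slope"]] * sex
    out <- out + slope * t
  }
  if ("quadratic" %in% names(b)) out <- out + b[["quadratic"]] * t^2
  out
}

#' Plot predicted EF trajectories by risk level
#'
#' Draws model-implied mean EF against age over the study's age band for a
#' set of risk-score values (low risk in blue dashed through high risk in
#' solid red), at the average of the sex covariate.
#'
#' @param x an `ef_growth` fit including a risk predictor.
#' @param risk_levels risk-score values to draw.
#' @param age_range age band.
#' @param sex value for the sex covariate (default 0.5: averaged).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ef_growth <- function(x, risk_levels = 0:4 * 2, age_range = c(53, 95),
                           sex = 0.5, ...) {
  ages <- seq(age_range[1L], age_range[2L], length.out = 100L)
  Y <- vapply(risk_levels, function(r)
    predict(x, ages, risk = r,
            sex = if ("sex" %in% names(x$coefficients)) sex else NULL),
    numeric(length(ages)))
  cols <- grDevices::colorRampPalette(c("blue", "red"))(length(risk_levels))
  ltys <- c(2, rep(1, length(risk_levels) - 1L))
  graphics::matplot(ages, Y, type = "l", col = cols, lty = ltys,
                    xlab = "Age (years)", ylab = "Predicted EF", ...)
  graphics::legend("bottomleft", legend = paste("risk =", risk_levels),
                   col = cols, lty = ltys, bty = "n", cex = 0.8)
  invisible(Y)
}

#' Simulate score data from a fitted growth model
#'
#' @param object an `ef_growth` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ages n x W matrix of ages; `risk`, `sex` as in fitting.
#' @param ... unused.
#' @return a list of n x W score matrices (length `nsim`).
#' @export
simulate.ef_growth <- function(object, nsim = 1, seed = NULL, ages,
                               risk = NULL, sex = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- object$coefficients
  n <- nrow(ages)
  t <- ages - object$center
  G <- object$G
  replicate(nsim, {
    b0 <- rep(b[["intercept"]], n)
    b1 <- if ("slope" %in% names(b)) rep(b[["slope"]], n) else numeric(n)
    if ("risk" %in% names(b)) b0 <- b0 + b[["risk"]] * risk
    if ("sex" %in% names(b)) b0 <- b0 + b[["sex"]] * sex
    if ("risk_slope" %in% names(b)) b1 <- b1 + b[["risk_slope"]] * risk
    if ("sex_slope" %in% names(b)) b1 <- b1 + b[["sex_slope"]] * sex
    if (!is.null(G)) {
      L <- t(chol(as.matrix(G) + diag(1e-12, nrow(G))))
      u <- L %*% matrix(stats::rnorm(nrow(G) * n), nrow(G))
      b0 <- b0 + u[1L, ]
      if (nrow(G) == 2L) b1 <- b1 + u[2L, ]
    }
    mu <- b0 + b1 * t
    if ("quadratic" %in% names(b)) mu <- mu + b[["quadratic"]] * t^2
    r <- object$resid_var
    if (length(r) == 1L) r <- rep(r, ncol(ages))
    mu + matrix(stats::rnorm(n * ncol(ages), 0,
                             rep(sqrt(r), each = n)), n)
  }, simplify = FALSE)
}

#' Marginal residuals of a growth fit
#'
#' Observed scores minus the fixed-effect mean at each observed wave.
#'
#' @param object an `ef_growth` fit; `scores`, `ages`, `risk`, `sex` as in
#'   fitting.
#' @param scores,ages,risk,sex the data used to fit.
#' @param ... unused.
#' @return matrix of residuals (NA where unobserved).
#' @export
residuals.ef_growth <- function(object, scores, ages, risk = NULL,
                                sex = NULL, ...) {
  scores <- as.matrix(scores); ages <- as.matrix(ages)
  b <- object$coefficients
  out <- scores
  for (w in seq_len(ncol(scores))) {
    mu <- predict(object, ages[, w], risk = risk, sex = sex)
    out[, w] <- scores[, w] - mu
  }
  out
}
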
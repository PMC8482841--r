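# Per-person factor scores from a fitted measurement model.
#
# Two estimators are offered.  The regression (empirical-Bayes) method uses
# the joint implied moments of all observed indicators:
#   eta_hat = alpha + Psi Lambda' Sigma^{-1} (y - mu)   (observed subset)
# and is the minimum-MSE predictor, but it shrinks toward the factor mean,
# which attenuates regression coefficients when the scores are analysed
# further.  The Bartlett method,
#   eta_hat = (Lambda' Theta^{-1} Lambda)^{-1} Lambda' Theta^{-1} (y - tau),
# computed wave by wave, is conditionally unbiased (E[eta_hat | eta] = eta),
# so downstream growth models treat its measurement error as pure outcome
# noise and their regression coefficients stay unbiased.  Bartlett is the
# default for the two-stage growth pipeline for exactly that reason.

#' Factor scores from a fitted EF measurement model
#'
#' @param object an [ef_cfa()] fit.
#' @param newdata optional data frame/matrix with the indicator columns;
#'   defaults to the fitting data.
#' @param method `"bartlett"` (default; conditionally unbiased, computed
#'   per wave from that wave's observed indicators) or `"regression"`
#'   (empirical-Bayes, computed jointly from all observed indicators).
#' @param ... unused.
#' @return numeric matrix, cases by wave-factors (columns like `ef_w1`);
#'   `NA` where a wave has no observed indicators (or, for Bartlett with a
#'   two-factor model, where a factor has no observed indicator).
#' @export
predict.ef_cfa <- function(object, newdata = NULL,
                           method = c("bartlett", "regression"), ...) {
  method <- match.arg(method)
  tpl <- object$template
  Y <- if (is.null(newdata)) object$data else
    as.matrix(as.data.frame(newdata)[, tpl$vnames])
  storage.mode(Y) <- "double"
  mo <- object$moments
  n <- nrow(Y)
  scores <- matrix(NA_real_, n, tpl$nfac, dimnames = list(NULL, tpl$fnames))
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  for (pattern in unique(key)) {
    rows <- which(key == pattern)
    o <- which(obs[rows[1L], ])
    if (!length(o)) next
    Yo <- Y[rows, o, drop = FALSE]
    if (method == "regression") {
      So <- mo$Sigma[o, o, drop = FALSE]
      A <- mo$Psi %*% t(mo$Lambda[o, , drop = FALSE]) %*% chol2inv(chol(So))
      ctr <- sweep(Yo, 2L, mo$mu[o])
      sc <- sweep(ctr %*% t(A), 2L, mo$alpha, "+")
      scores[rows, ] <- sc
      # a wave-factor with no observed indicator gets no score
      dead <- vapply(seq_len(tpl$nfac), function(f)
        !any(mo$Lambda[o, f] != 0), logical(1))
      if (any(dead)) scores[rows, dead] <- NA_real_
    } else {
      Lo <- mo$Lambda[o, , drop = FALSE]
      live <- which(colSums(Lo != 0) > 0)
      if (!length(live)) next
      Ll <- Lo[, live, drop = FALSE]
      Th <- mo$Theta[o, o, drop = FALSE]
      ch <- tryCatch(chol(Th), error = function(e) NULL)
      if (!is.null(ch)) {
        Tinv <- chol2inv(ch)
      } else {
        # boundary (near-zero residual) fits: clip eigenvalues so the
        # weights stay finite; scores are insensitive to the floor there
        ei <- eigen(Th, symmetric = TRUE)
        floor_ <- max(1e-10, 1e-8 * max(abs(ei$values)))
        Tinv <- ei$vectors %*% diag(1 / pmax(ei$values, floor_),
                                    nrow(Th)) %*% t(ei$vectors)
      }
      M <- crossprod(Ll, Tinv %*% Ll)
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv)) next
      W <- Minv %*% crossprod(Ll, Tinv)
      ctr <- sweep(Yo, 2L, mo$tau[o])
      scores[rows, live] <- ctr %*% t(W)
    }
  }
  scores
}

#' Append EF factor scores to a cohort
#'
#' Convenience wrapper: computes factor scores for a one-factor,
#' three-wave fit and returns the cohort with `ef_w1..ef_w3` columns.
#'
#' @param cohort cohort data frame used to fit `fit` (or compatible).
#' @param fit an [ef_cfa()] one-factor three-wave fit.
#' @param method score estimator, see [predict.ef_cfa()].
#' @return the cohort with three additional `ef_w*` columns.
#' @export
add_factor_scores <- function(cohort, fit, method = "bartlett") {
  sc <- predict(fit, newdata = cohort, method = method)
  colnames(sc) <- paste0("ef_w", seq_len(ncol(sc)))
  cbind(cohort, sc)
}
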
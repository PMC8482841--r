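# Longitudinal measurement-invariance ladder for the one-factor EF model:
# configural -> metric (equal loadings) -> scalar (equal intercepts, with a
# partial-scalar fallback freeing at most two intercepts) -> residual
# (equal residual variances).  Each step is compared to its parent by the
# likelihood-ratio chi-square difference, warm-started from the parent fit
# so the nested log-likelihood ordering holds numerically.

#' Longitudinal invariance ladder
#'
#' Fits the nested sequence of one-factor three-wave measurement models and
#' tests each added constraint with a chi-square difference test at
#' `alpha`.  If strict scalar invariance is rejected, intercepts are freed
#' one at a time (largest likelihood gain first, ties to the lowest
#' indicator index), at most `max_freed`, until the model is no longer
#' significantly worse than the metric model; the achieved level is then
#' `partial_scalar`.  The residual step constrains residual variances on
#' top of whichever scalar-level model was achieved.
#'
#' The achieved level reported in `$level` is the deepest non-rejected
#' constraint set; factor scores for growth modelling require at least
#' partial scalar invariance.
#'
#' @param data cohort data frame or matrix with the 12 indicator columns.
#' @param alpha significance level for the difference tests.
#' @param max_freed maximum intercepts freed in the partial-scalar search.
#' @param restarts,se passed to [ef_cfa()].
#' @return object of class `ef_invariance`: list with `$fits` (named list
#'   of `ef_cfa` objects), `$steps` (comparison table), `$level`,
#'   `$free_intercepts`.
#' @export
ef_invariance <- function(data, alpha = 0.05, max_freed = 2L,
                          restarts = 3L, se = FALSE) {
  fits <- list()
  fits$configural <- ef_cfa(data, waves = 3L, factors = "one",
                            invariance = "configural", restarts = restarts,
                            se = se)
  if (!fits$configural$converged)
    stop_ef("configural model did not converge; ladder aborted")
  fits$metric <- ef_cfa(data, waves = 3L, invariance = "metric",
                        start = metric_start(fits$configural),
                        restarts = restarts, se = se)
  fits$configural <- refit_if_beaten(fits$configural, fits$metric, data,
                                     "configural")
  fits$scalar <- ef_cfa(data, waves = 3L, invariance = "scalar",
                        start = scalar_start(fits$metric),
                        restarts = restarts, se = se)
  fits$metric <- refit_if_beaten(fits$metric, fits$scalar, data, "metric")

  free_int <- character()
  scalar_level <- "scalar"
  d_scalar <- lrt_row(fits$scalar, fits$metric)
  if (is.finite(d_scalar$p) && d_scalar$p < alpha) {
    # partial-scalar search
    current <- fits$scalar
    candidates <- paste0(rep(ef_indicators, 2L), "_w", rep(2:3, each = 4L))
    repeat {
      if (length(free_int) >= max_freed) break
      trial <- lapply(setdiff(candidates, free_int), function(cand) {
        ef_cfa(data, waves = 3L, invariance = "partial_scalar",
               free_intercepts = c(free_int, cand),
               start = current$theta, restarts = 1L, se = se)
      })
      names(trial) <- setdiff(candidates, free_int)
      gains <- vapply(trial, function(f) f$logL, numeric(1))
      # largest likelihood improvement; ties to lowest indicator index
      best_i <- which(gains >= max(gains) - 1e-8)[1L]
      current <- trial[[best_i]]
      free_int <- c(free_int, names(trial)[best_i])
      p_vs_metric <- lrt_row(current, fits$metric)$p
      if (is.finite(p_vs_metric) && p_vs_metric >= alpha) break
    }
    p_final <- lrt_row(current, fits$metric)$p
    if (is.finite(p_final) && p_final >= alpha) {
      scalar_level <- "partial_scalar"
      fits$partial_scalar <- current
    } else {
      scalar_level <- "metric"   # scalar fails even partially
      fits$partial_scalar <- current
      free_int <- character()
    }
  }

  anchor <- if (scalar_level == "partial_scalar") fits$partial_scalar else
    fits$scalar
  fits$residual <- ef_cfa(data, waves = 3L, invariance = "residual",
                          free_intercepts = free_int,
                          start = residual_start(anchor),
                          restarts = restarts, se = se)
  anchor <- refit_if_beaten(anchor, fits$residual, data,
                            if (scalar_level == "partial_scalar")
                              "partial_scalar" else "scalar",
                            free_intercepts = free_int)
  if (scalar_level == "partial_scalar") fits$partial_scalar <- anchor else
    fits$scalar <- anchor

  # achieved level: deepest non-rejected step in sequence
  p_metric <- lrt_row(fits$metric, fits$configural)$p
  p_resid <- lrt_row(fits$residual, anchor)$p
  level <- "configural"
  if (is.finite(p_metric) && p_metric >= alpha) {
    level <- "metric"
    if (scalar_level == "scalar" &&
        is.finite(d_scalar$p) && d_scalar$p >= alpha) level <- "scalar"
    else if (scalar_level == "partial_scalar") level <- "partial_scalar"
    if (level %in% c("scalar", "partial_scalar") &&
        is.finite(p_resid) && p_resid >= alpha) level <- "residual"
  }

  tab <- invariance_table(fits, anchor)
  out <- list(fits = fits, steps = tab, level = level,
              free_intercepts = free_int, alpha = alpha)
  class(out) <- "ef_invariance"
  out
}

lrt_row <- function(child, parent) {
  d_chi2 <- max(0, 2 * (parent$logL - child$logL))
  d_df <- parent$k - child$k
  list(d_chi2 = d_chi2, d_df = d_df,
       p = if (d_df > 0) stats::pchisq(d_chi2, d_df, lower.tail = FALSE)
           else NA_real_)
}

# If optimizer noise makes a constrained (child) fit beat its less
# constrained parent, the parent is under-optimized: refit it starting from
# the child's solution expanded into the parent's parameter names (a shared
# parameter keeps its value; a wave-specific parent parameter starts at the
# child's wave-constant value).
refit_if_beaten <- function(parent, child, data, parent_level,
                            free_intercepts = character()) {
  if (child$logL <= parent$logL + 1e-6) return(parent)
  start <- parent$theta
  for (nm in names(start)) {
    if (nm %in% names(child$theta)) {
      start[nm] <- child$theta[[nm]]
    } else {
      base <- sub("_w[0-9]+$", "", nm)
      if (base %in% names(child$theta)) start[nm] <- child$theta[[base]]
    }
  }
  refit <- ef_cfa(data, waves = 3L,
                  invariance = parent_level,
                  free_intercepts = if (parent_level == "partial_scalar")
                    free_intercepts else character(),
                  start = start, restarts = 1L)
  if (refit$logL > parent$logL) refit else parent
}

metric_start <- function(configural) {
  th <- configural$theta
  out <- th[!grepl("^lam_", names(th))]
  lam_names <- grep("^lam_", names(th), value = TRUE)
  base <- unique(sub("_w[0-9]+$", "", lam_names))
  for (b in base) out[b] <- mean(th[grep(paste0("^", b, "_w"), names(th))])
  out
}

scalar_start <- function(metric) {
  th <- metric$theta
  out <- th[!grepl("^tau_", names(th))]
  tau_names <- grep("^tau_", names(th), value = TRUE)
  base <- unique(sub("_w[0-9]+$", "", tau_names))
  for (b in base) out[b] <- mean(th[grep(paste0("^", b, "_w"), names(th))])
  out
}

residual_start <- function(scalar_fit) {
  th <- scalar_fit$theta
  out <- th[!grepl("^thv_", names(th))]
  thv_names <- grep("^thv_", names(th), value = TRUE)
  base <- unique(sub("_w[0-9]+$", "", thv_names))
  for (b in base) out[b] <- mean(th[grep(paste0("^", b, "_w"), names(th))])
  out
}

invariance_table <- function(fits, anchor) {
  rows <- list(
    c("configural", NA),
    c("metric", "configural"),
    c("scalar", "metric"),
    if (!is.null(fits$partial_scalar)) c("partial_scalar", "metric"),
    c("residual", if (identical(anchor, fits$scalar)) "scalar" else "partial_scalar"))
  rows <- Filter(Negate(is.null), rows)
  do.call(rbind, lapply(rows, function(r) {
    f <- fits[[r[1L]]]
    cmp <- if (!is.na(r[2L])) lrt_row(f, fits[[r[2L]]]) else
      list(d_chi2 = NA_real_, d_df = NA_real_, p = NA_real_)
    data.frame(level = r[1L], against = r[2L], logL = f$logL, k = f$k,
               chi2 = f$fit$chi2, df = f$fit$df, cfi = f$fit$cfi,
               rmsea = f$fit$rmsea, srmr = f$fit$srmr,
               d_chi2 = cmp$d_chi2, d_df = cmp$d_df, p = cmp$p,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.ef_invariance <- function(x, digits = 3, ...) {
  cat("Longitudinal invariance ladder (one-factor EF, 3 waves)\n")
  tab <- x$steps
  tab[, c("logL", "chi2", "cfi", "rmsea", "srmr", "d_chi2")] <-
    round(tab[, c("logL", "chi2", "cfi", "rmsea", "srmr", "d_chi2")], digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("Achieved level:", x$level)
  if (length(x$free_intercepts))
    cat("  (freed intercepts: ", paste(x$free_intercepts, collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}
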
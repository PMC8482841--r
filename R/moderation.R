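# Conditional growth models stratified by genetic risk group, and the
# assembly of the moderation table (one block of rows per research
# question, risk score and stratum, with per-stratum intercept/slope
# regressions and combined model fit indices).

#' Stratified conditional growth model
#'
#' Fits the conditional random-intercept/random-slope model separately in
#' each stratum (all parameters group-specific) and combines them into one
#' multiple-group model: combined log-likelihood is the sum over strata,
#' free parameters the sum of per-stratum counts, and AIC/BIC use the
#' total n.  A stratum below `floor_n` participants is still fit but
#' flagged `low_n`.
#'
#' @param scores,ages n x W matrices.
#' @param risk,sex per-person predictors.
#' @param strata factor of stratum membership (NA rows are dropped).
#' @param floor_n minimum comfortable stratum size.
#' @param center centering age.
#' @param se compute standard errors.
#' @return object of class `ef_growth_strat`: `$fits` (per stratum),
#'   `$logL`, `$k`, `$n`, `$minus2LL`, `$aic`, `$bic`, `$low_n`.
#' @export
ef_growth_stratified <- function(scores, ages, risk, sex, strata,
                                 floor_n = 15L, center = 75, se = TRUE) {
  strata <- as.factor(strata)
  levs <- levels(droplevels(strata))
  if (length(levs) < 1L) stop_ef("no non-empty strata")
  fits <- list()
  low_n <- character()
  for (s in levs) {
    rows <- which(!is.na(strata) & strata == s)
    if (length(rows) < 2L) stop_ef("stratum '", s, "' has fewer than 2 rows")
    if (length(rows) < floor_n) low_n <- c(low_n, s)
    fits[[s]] <- ef_growth(scores[rows, , drop = FALSE],
                           ages[rows, , drop = FALSE],
                           risk = risk[rows], sex = sex[rows],
                           stage = "random_slope", center = center, se = se)
  }
  logL <- sum(vapply(fits, function(f) f$logL, numeric(1)))
  k <- sum(vapply(fits, function(f) f$k, numeric(1)))
  n <- sum(vapply(fits, function(f) f$n, numeric(1)))
  ic <- information_criteria(logL, k, n)
  out <- list(fits = fits, logL = logL, k = k, n = n,
              minus2LL = ic[["minus2LL"]], aic = ic[["aic"]],
              bic = ic[["bic"]], low_n = low_n, strata = levs)
  class(out) <- "ef_growth_strat"
  out
}

#' @export
print.ef_growth_strat <- function(x, ...) {
  cat("Multiple-group conditional growth model (", length(x$strata),
      " strata)\n", sep = "")
  cat(sprintf("  combined logL = %.3f, k = %d, n = %d | -2LL = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$logL, x$k, x$n, x$minus2LL, x$aic, x$bic))
  if (length(x$low_n))
    cat("  low-n strata:", paste(x$low_n, collapse = ", "), "\n")
  for (s in x$strata) {
    cat("---", s, "---\n")
    print(x$fits[[s]])
  }
  invisible(x)
}

# rows of the moderation table for one fitted model (single- or
# multi-group)
moderation_rows <- function(fit, rq, score_name) {
  if (inherits(fit, "ef_growth")) {
    strata <- list(pooled = fit)
    comb <- fit
  } else {
    strata <- fit$fits
    comb <- fit
  }
  do.call(rbind, lapply(names(strata), function(s) {
    f <- strata[[s]]
    b <- f$coefficients
    se <- f$se
    p <- f$p
    pull <- function(term) {
      if (term %in% names(b)) c(b[[term]], se[[term]], p[[term]])
      else c(NA_real_, NA_real_, NA_real_)
    }
    risk_row <- c(pull("risk"), pull("risk_slope"))
    sex_row <- c(pull("sex"), pull("sex_slope"))
    data.frame(
      rq = rq, risk_score = score_name, stratum = s,
      term = c(score_name, "sex"),
      n = f$n,
      intercept_beta = c(risk_row[1L], sex_row[1L]),
      intercept_se = c(risk_row[2L], sex_row[2L]),
      intercept_p = c(risk_row[3L], sex_row[3L]),
      slope_beta = c(risk_row[4L], sex_row[4L]),
      slope_se = c(risk_row[5L], sex_row[5L]),
      slope_p = c(risk_row[6L], sex_row[6L]),
      H0 = comb$logL, free_parameters = comb$k,
      minus2LL = comb$minus2LL, aic = comb$aic, bic = comb$bic,
      converged = f$converged,
      stringsAsFactors = FALSE)
  }))
}

#' Moderation table across research questions
#'
#' Runs the conditional growth models for the selected risk scores and
#' moderation structure and assembles the results in a single table: one
#' pair of rows (risk-score term, sex term) per model and stratum, with
#' per-stratum unstandardized intercept and slope regressions
#' (beta, SE, two-sided Wald p) and the model-level fit indices (H0
#' log-likelihood, free parameter count, -2LL, AIC, BIC; shared across the
#' strata of one multiple-group model).
#'
#' Research questions: `RQ1` regresses EF on each risk score (whole
#' sample); `RQ2` stratifies by APOE group; `RQ3` stratifies by AD-GRS
#' (low/high) within each APOE group.
#'
#' @param cohort cohort data frame with factor-score columns `ef_w*` (see
#'   [add_factor_scores()]).
#' @param scores data frame from [risk_scores()].
#' @param analyses subset of `c("RQ1", "RQ2", "RQ3")`.
#' @param risk_measures subset of `c("frs", "lrs", "mcrs")`.
#' @param center centering age.
#' @param floor_n minimum stratum size before flagging.
#' @return data.frame of class `ef_moderation`.
#' @export
moderation_table <- function(cohort, scores,
                             analyses = c("RQ1", "RQ2", "RQ3"),
                             risk_measures = c("frs", "lrs", "mcrs"),
                             center = 75, floor_n = 15L) {
  stopifnot(length(analyses) > 0)
  ef <- as.matrix(cohort[, grep("^ef_w[0-9]+$", names(cohort))])
  ages <- as.matrix(cohort[, sub("^ef", "age", colnames(ef))])
  sex <- cohort$sex
  apoe <- apoe_group(cohort$apoe)
  gr <- adgrs(cohort$clu, cohort$cr1, cohort$picalm)
  rows <- list()
  for (sc in risk_measures) {
    risk <- scores[[sc]][match(cohort$id, scores$id)]
    if ("RQ1" %in% analyses) {
      f <- ef_growth(ef, ages, risk = risk, sex = sex, center = center)
      rows <- c(rows, list(moderation_rows(f, "RQ1", sc)))
    }
    if ("RQ2" %in% analyses) {
      strat <- factor(ifelse(apoe %in% c("e4_minus", "e4_plus"),
                             as.character(apoe), NA),
                      levels = c("e4_minus", "e4_plus"))
      f <- ef_growth_stratified(ef, ages, risk, sex, strat,
                                floor_n = floor_n, center = center)
      rows <- c(rows, list(moderation_rows(f, "RQ2", sc)))
    }
    if ("RQ3" %in% analyses) {
      for (ap in c("e4_minus", "e4_plus")) {
        sel <- apoe == ap & !is.na(gr$group)
        strat <- factor(ifelse(sel, paste0(ap, ":", ifelse(gr$group == "low",
                                                           "low_adgrs",
                                                           "high_adgrs")),
                               NA))
        f <- ef_growth_stratified(ef, ages, risk, sex, strat,
                                  floor_n = floor_n, center = center)
        rows <- c(rows, list(moderation_rows(f, "RQ3", sc)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ef_moderation", "data.frame")
  out
}

#' Write the moderation table as CSV and a rendered text table
#'
#' @param tab an `ef_moderation` data frame.
#' @param csv_path,txt_path output files (either may be `NULL` to skip).
#' @return `tab`, invisibly.
#' @export
write_moderation <- function(tab, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    fmt <- as.data.frame(tab)
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.3f", x))
    lines <- c(paste(names(fmt), collapse = "\t"),
               apply(fmt, 1L, paste, collapse = "\t"))
    writeLines(lines, txt_path)
  }
  invisible(tab)
}
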
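# Seeded synthetic cohort generator.  Emulates the data structure of a
# three-wave accelerated longitudinal study of non-demented aging: baseline
# age uniform over the recruitment band (53-85, so third-wave ages reach
# about 95), roughly 4.4/4.5-year retest intervals, monotone attrition with
# configurable mechanism, a four-indicator executive-function (EF) battery
# driven by a person-specific latent growth process, baseline functional and
# lifestyle risk indicators, and genotype draws (APOE, CLU, CR1, PICALM)
# under Hardy-Weinberg proportions.

ef_indicators <- c("stroop", "hayling", "brixton", "ctrails")

#' Generator configuration
#'
#' Study-design parameters of the synthetic cohort.  Defaults reproduce the
#' design this package targets: n = 600 per run, baseline age U(53, 85),
#' three waves about 4.4 and 4.5 years apart, wave-to-wave retention 0.81
#' and 0.56 with missingness-at-random attrition driven by baseline age and
#' observed baseline EF, 66% female, an APOE epsilon-4 carrier share of
#' 149/602 among non-e2/e4 genotypes, and baseline indicator means/SDs from
#' the majority (epsilon-4 negative) stratum of the target cohort.
#'
#' @param n_participants cohort size.
#' @param baseline_age_range recruitment band in years, within 53-95.
#' @param wave_interval_means,wave_interval_sd mean (per transition) and SD
#'   of retest intervals, years.
#' @param retention per-transition retention proportions.
#' @param prop_female proportion of women (coded `sex = 1`; men 0, so a
#'   positive sex coefficient downstream means better EF in women).
#' @param allele_freqs named list: `apoe` = frequencies of e2/e3/e4 (e4
#'   derived from `apoe_e4_prop` when `NULL`), and risk-allele frequencies
#'   `clu` (C), `cr1` (A), `picalm` (T).
#' @param apoe_e4_prop target carrier proportion among the analysis strata.
#' @param indicator_means_sds 2-row matrix (mean, sd) with columns `pp`,
#'   `bmi`, `grip`, `act_phys`, `act_soc`, `act_integ`, `act_novel`,
#'   `edu_years`, `mmse`.
#' @param attrition_mechanism `"MAR_on_age_ef"` (default; dropout odds
#'   depend on baseline age and observed baseline EF indicators), or
#'   `"MCAR"`.
#' @param health_flag_rates rates of planted health-history exclusions.
#' @param seed integer seed; mandatory for reproducible pipeline runs.
#' @return list of class `ef_config`.
#' @export
cohort_config <- function(n_participants = 600L,
                          baseline_age_range = c(53, 85),
                          wave_interval_means = c(4.4, 4.5),
                          wave_interval_sd = 0.5,
                          retention = c(0.81, 0.56),
                          prop_female = 0.66,
                          allele_freqs = NULL,
                          apoe_e4_prop = 149 / 602,
                          indicator_means_sds = NULL,
                          attrition_mechanism = c("MAR_on_age_ef", "MCAR"),
                          health_flag_rates = c(antipsychotic = 0.007,
                                                mmse_below_24 = 0.002,
                                                uncontrolled_htn = 0.002,
                                                insulin_diabetes = 0.007,
                                                head_injury = 0.013),
                          seed = 1L) {
  attrition_mechanism <- match.arg(attrition_mechanism)
  if (!is_count(n_participants)) stop_ef("n_participants must be a count >= 1")
  if (!is_prop(retention) || length(retention) != 2L)
    stop_ef("retention must be two proportions in [0, 1]")
  if (!is_prop(prop_female)) stop_ef("prop_female must be in [0, 1]")
  if (baseline_age_range[1L] < 53 - 1e-9 || baseline_age_range[2L] > 95 + 1e-9 ||
      diff(baseline_age_range) < 0)
    stop_ef("baseline_age_range must lie within [53, 95]")
  if (is.null(indicator_means_sds)) {
    indicator_means_sds <- rbind(
      mean = c(pp = 51.56, bmi = 27.10, grip = 29.21, act_phys = 15.58,
               act_soc = 22.76, act_integ = 18.73, act_novel = 74.65,
               edu_years = 15.19, mmse = 28.66),
      sd = c(pp = 10.13, bmi = 4.38, grip = 9.53, act_phys = 5.19,
             act_soc = 6.61, act_integ = 8.87, act_novel = 17.27,
             edu_years = 2.97, mmse = 1.24))
  }
  if (is.null(allele_freqs)) {
    p2 <- 0.078
    # e4 frequency giving the target carrier share among kept (non-e2/e4)
    # genotypes under Hardy-Weinberg proportions
    f <- function(p4) {
      carrier <- 1 - (1 - p4)^2
      e2e4 <- 2 * p2 * p4
      (carrier - e2e4) / (1 - e2e4) - apoe_e4_prop
    }
    p4 <- stats::uniroot(f, c(0.01, 0.45))$root
    allele_freqs <- list(apoe = c(e2 = p2, e3 = 1 - p2 - p4, e4 = p4),
                         clu = 0.60, cr1 = 0.3984, picalm = 0.5747)
  }
  if (!is_prop(unlist(allele_freqs))) stop_ef("allele frequencies must be in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 baseline_age_range = baseline_age_range,
                 wave_interval_means = wave_interval_means,
                 wave_interval_sd = wave_interval_sd,
                 retention = retention, prop_female = prop_female,
                 allele_freqs = allele_freqs, apoe_e4_prop = apoe_e4_prop,
                 indicator_means_sds = indicator_means_sds,
                 attrition_mechanism = attrition_mechanism,
                 health_flag_rates = health_flag_rates,
                 seed = as.integer(seed)),
            class = "ef_config")
}

#' Generating ("true") parameters of the synthetic cohort
#'
#' The latent growth and measurement parameters the generator uses.  The
#' risk and sex regression weights default to the composite-risk-score
#' values this package's growth models are calibrated against (risk on
#' level -0.161 per point, risk on slope -0.007 per point per year; sex
#' 0.275 and 0.015 with women coded 1).  The latent EF metric is scaled so
#' the wave-1 marker indicator has roughly unit variance; indicators are
#' generated already oriented so that higher = better EF.
#'
#' @param loadings factor loadings of the four indicators (first is the
#'   marker, fixed at 1 downstream).
#' @param indicator_intercepts per-indicator intercepts (constant over
#'   waves unless a 4 x 3 matrix is given, which plants an invariance
#'   violation).
#' @param residual_variances per-indicator measurement residual variances
#'   (constant over waves).
#' @param growth_means fixed intercept and linear slope of latent EF at the
#'   age-75 centering.
#' @param growth_covariance 2 x 2 covariance of the random intercept and
#'   slope; must be positive semi-definite.
#' @param ef_residual_variance wave-specific latent EF disturbance variance.
#' @param beta_risk_on_intercept,beta_risk_on_slope effect of the (centered)
#'   composite risk score on the person intercept and slope.
#' @param beta_sex_on_intercept,beta_sex_on_slope effect of sex (female = 1).
#' @param quadratic_mean fixed quadratic term (default 0: linear change).
#' @return list of class `ef_truth`.
#' @export
cohort_truth <- function(loadings = c(1, 0.9, 0.8, 0.85),
                         indicator_intercepts = c(0, 0, 0, 0),
                         residual_variances = c(0.35, 0.40, 0.45, 0.40),
                         growth_means = c(intercept = 0, slope = -0.025),
                         growth_covariance = matrix(c(0.65, -0.01,
                                                      -0.01, 0.002), 2L),
                         ef_residual_variance = 0.18,
                         beta_risk_on_intercept = -0.161,
                         beta_risk_on_slope = -0.007,
                         beta_sex_on_intercept = 0.275,
                         beta_sex_on_slope = 0.015,
                         quadratic_mean = 0) {
  ev <- eigen(growth_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop_ef("growth covariance matrix is not positive semi-definite ",
            "(eigenvalues ", paste(signif(ev, 3), collapse = ", "), ")")
  if (any(residual_variances < 0) || any(ef_residual_variance < 0))
    stop_ef("variances must be non-negative")
  if (is.matrix(indicator_intercepts)) {
    stopifnot(nrow(indicator_intercepts) == 4L, ncol(indicator_intercepts) == 3L)
  }
  structure(list(loadings = loadings,
                 indicator_intercepts = indicator_intercepts,
                 residual_variances = residual_variances,
                 growth_means = growth_means,
                 growth_covariance = growth_covariance,
                 ef_residual_variance = ef_residual_variance,
                 beta_risk_on_intercept = beta_risk_on_intercept,
                 beta_risk_on_slope = beta_risk_on_slope,
                 beta_sex_on_intercept = beta_sex_on_intercept,
                 beta_sex_on_slope = beta_sex_on_slope,
                 quadratic_mean = quadratic_mean),
            class = "ef_truth")
}

# draw a biallelic genotype string under HWE for risk-allele frequency p
draw_snp <- function(n, p, risk, other) {
  a1 <- ifelse(stats::runif(n) < p, risk, other)
  a2 <- ifelse(stats::runif(n) < p, risk, other)
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

# Expected (population) composite risk score given the configured indicator
# distributions; used to center the generating risk effect so the intercept
# mean stays at its configured value.
expected_mcrs <- function(cfg) {
  m <- cfg$indicator_means_sds
  pnormb <- function(x, v) stats::pnorm(x, m["mean", v], m["sd", v])
  pp <- (1 - pnormb(52, "pp")) * 1 + (1 - pnormb(72, "pp")) * 1
  bmi <- 2 * (1 - pnormb(30, "bmi")) +
    (pnormb(30, "bmi") - pnormb(25, "bmi")) + pnormb(18.5, "bmi")
  edu <- 2 * pnormb(8, "edu_years") +
    (pnormb(12, "edu_years") - pnormb(8, "edu_years"))
  pp + 0.5 + bmi + 4 * 0.5 + edu
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort under the configured design ([cohort_config()]) and
#' generating parameters ([cohort_truth()]).  Person-level intercepts and
#' slopes come from a bivariate normal around the fixed means shifted by
#' the true composite-risk and sex effects; latent EF at each wave is
#' intercept + slope * (age - 75) (+ optional quadratic) plus a wave
#' disturbance; indicators are intercept + loading * EF + measurement
#' noise.  Attrition is monotone: once a participant misses a wave, later
#' waves are missing too.  Under the default missing-at-random mechanism the
#' wave-specific retention propensity is a logistic function of baseline age
#' and the mean of the standardized baseline EF indicators, with its
#' intercept calibrated so the average propensity equals the configured
#' retention exactly.
#'
#' @param config an [cohort_config()] object.
#' @param truth an [cohort_truth()] object.
#' @return data.frame of class `ef_cohort`, one row per participant, in the
#'   wide layout documented in [write_cohort()].
#' @export
simulate_cohort <- function(config = cohort_config(), truth = cohort_truth()) {
  stopifnot(inherits(config, "ef_config"), inherits(truth, "ef_truth"))
  set.seed(config$seed)
  n <- config$n_participants
  msd <- config$indicator_means_sds

  sex <- stats::rbinom(n, 1L, config$prop_female)   # female = 1
  age1 <- stats::runif(n, config$baseline_age_range[1L],
                       config$baseline_age_range[2L])
  int12 <- pmax(1, stats::rnorm(n, config$wave_interval_means[1L],
                                config$wave_interval_sd))
  int23 <- pmax(1, stats::rnorm(n, config$wave_interval_means[2L],
                                config$wave_interval_sd))
  age <- cbind(age1, age1 + int12, age1 + int12 + int23)
  colnames(age) <- paste0("age_w", 1:3)

  # baseline risk indicators (independent of genotype by default)
  ind <- vapply(colnames(msd), function(v)
    stats::rnorm(n, msd["mean", v], msd["sd", v]), numeric(n))
  ind <- as.data.frame(ind)
  ind$mmse <- pmin(30, round(pmax(24, ind$mmse), 0))
  ind$edu_years <- round(pmax(4, ind$edu_years))

  # genotypes under HWE
  af <- config$allele_freqs
  apoe_alleles <- replicate(2L, sample(names(af$apoe), n, replace = TRUE,
                                       prob = af$apoe))
  apoe <- paste(pmin(apoe_alleles[, 1L], apoe_alleles[, 2L]),
                pmax(apoe_alleles[, 1L], apoe_alleles[, 2L]), sep = "/")
  clu <- draw_snp(n, af$clu, "C", "T")
  cr1 <- draw_snp(n, af$cr1, "A", "G")
  picalm <- draw_snp(n, af$picalm, "T", "C")

  # planted health-history exclusions
  hf <- config$health_flag_rates
  flags <- vapply(names(hf), function(f) stats::rbinom(n, 1L, hf[[f]]),
                  integer(n))
  flags <- as.data.frame(flags)
  if (!is.null(flags$mmse_below_24) && any(flags$mmse_below_24 == 1L))
    ind$mmse[flags$mmse_below_24 == 1L] <- sample(20:23,
      sum(flags$mmse_below_24), replace = TRUE)

  # true composite risk score using the configured population means as the
  # mean-split cutoffs
  pop_cut <- matrix(rep(msd["mean", mean_split_indicators], each = 2L), 2L,
                    dimnames = list(c("e4_minus", "e4_plus"),
                                    mean_split_indicators))
  class(pop_cut) <- c("ef_cutoffs", class(pop_cut))
  stratum <- ifelse(apoe_group(apoe) == "e4_plus", "e4_plus", "e4_minus")
  frs <- functional_health_score(ind$pp, ind$grip, ind$bmi, pop_cut, stratum)
  lrs <- lifestyle_reserve_score(ind$act_phys, ind$act_soc, ind$act_integ,
                                 ind$act_novel, ind$edu_years, pop_cut, stratum)
  mcrs <- combined_mcrs(frs, lrs)
  mcrs_c <- mcrs - expected_mcrs(config)

  # person growth factors
  G <- truth$growth_covariance
  L <- t(chol(G + diag(1e-12, 2L)))
  u <- L %*% matrix(stats::rnorm(2L * n), 2L)
  b0 <- truth$growth_means[["intercept"]] +
    truth$beta_risk_on_intercept * mcrs_c +
    truth$beta_sex_on_intercept * sex + u[1L, ]
  b1 <- truth$growth_means[["slope"]] +
    truth$beta_risk_on_slope * mcrs_c +
    truth$beta_sex_on_slope * sex + u[2L, ]

  tmat <- age - 75
  ef <- b0 + b1 * tmat + truth$quadratic_mean * tmat^2 +
    matrix(stats::rnorm(3L * n, 0, sqrt(truth$ef_residual_variance)), n, 3L)

  tau <- truth$indicator_intercepts
  if (!is.matrix(tau)) tau <- matrix(tau, 4L, 3L)
  Y <- matrix(NA_real_, n, 12L,
              dimnames = list(NULL, paste0(rep(ef_indicators, 3L), "_w",
                                           rep(1:3, each = 4L))))
  for (w in 1:3) for (i in 1:4) {
    Y[, (w - 1L) * 4L + i] <- tau[i, w] + truth$loadings[i] * ef[, w] +
      stats::rnorm(n, 0, sqrt(truth$residual_variances[i]))
  }

  # attrition: monotone, calibrated to the configured retention
  present <- matrix(TRUE, n, 3L)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_age <- zscore(age1)
  z_ef <- zscore(rowMeans(vapply(1:4, function(i) zscore(Y[, i]), numeric(n))))
  for (w in 2:3) {
    at_risk <- present[, w - 1L]
    target <- config$retention[w - 1L]
    if (target >= 1) next
    if (config$attrition_mechanism == "MCAR") {
      pr <- rep(target, n)
    } else {
      lin <- -0.5 * z_age + 0.5 * z_ef
      a <- stats::uniroot(function(a)
        mean(stats::plogis(a + lin[at_risk])) - target,
        c(-20, 20))$root
      pr <- stats::plogis(a + lin)
    }
    keep <- stats::runif(n) < pr
    present[, w] <- at_risk & keep
  }
  for (w in 2:3) {
    drop <- !present[, w]
    Y[drop, (w - 1L) * 4L + 1:4] <- NA_real_
  }

  out <- data.frame(id = sprintf("P%04d", seq_len(n)), sex = sex,
                    age, Y, ind[, c("pp", "grip", "bmi", "act_phys",
                                    "act_soc", "act_integ", "act_novel",
                                    "edu_years", "mmse")],
                    apoe = apoe, clu = clu, cr1 = cr1, picalm = picalm,
                    flags[, setdiff(names(flags), "mmse_below_24"),
                          drop = FALSE])
  class(out) <- c("ef_cohort", "data.frame")
  attr(out, "config") <- config
  # generating quantities, for oracle checks (not written to CSV)
  attr(out, "latent") <- list(intercept = b0, slope = b1, ef = ef,
                              mcrs_centered = mcrs_c)
  out
}

# --- cohort I/O --------------------------------------------------------------

cohort_required_cols <- c("id", "sex", paste0("age_w", 1:3),
                          paste0(rep(ef_indicators, 3L), "_w", rep(1:3, each = 4L)),
                          "pp", "grip", "bmi", "act_phys", "act_soc",
                          "act_integ", "act_novel", "edu_years",
                          "apoe", "clu", "cr1", "picalm")

validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stop_ef("cohort is missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "))
  ages <- as.matrix(df[, paste0("age_w", 1:3)])
  bad <- which(apply(ages, 1L, function(a) {
    a <- a[!is.na(a)]
    length(a) > 1L && any(diff(a) <= 0)
  }))
  if (length(bad))
    stop_ef("wave ages not strictly increasing for row(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
  df
}

#' Write / read a cohort as wide CSV
#'
#' One row per participant; columns `id`, `sex`, `age_w1..age_w3`, the four
#' EF indicators per wave (`stroop_w1`, ..., `ctrails_w3`), baseline risk
#' indicators (`pp`, `grip`, `bmi`, `act_phys`, `act_soc`, `act_integ`,
#' `act_novel`, `edu_years`), genotypes (`apoe` such as `"e3/e4"`; `clu`,
#' `cr1`, `picalm` such as `"C/T"`), plus any extra columns present (kept
#' verbatim).  Missing values are empty cells.  Numeric values round-trip
#' at full double precision.
#'
#' @param cohort a cohort data frame.
#' @param path CSV file path.
#' @return `read_cohort()` returns the validated `ef_cohort` data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  df <- validate_cohort(df)
  num_cols <- setdiff(cohort_required_cols, c("id", "apoe", "clu", "cr1", "picalm"))
  for (v in num_cols) df[[v]] <- as.numeric(df[[v]])
  class(df) <- c("ef_cohort", "data.frame")
  df
}
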
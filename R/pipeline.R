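# End-to-end orchestration: exclusion filters, cohort descriptives, and the
# simulate -> score -> measure -> grow -> moderate pipeline with seeded
# determinism and provenance stamping.

default_exclusion_rules <- c("antipsychotic", "mmse_below_24",
                             "uncontrolled_htn", "insulin_diabetes",
                             "head_injury", "apoe_e2e4")

#' Apply cohort exclusion rules
#'
#' Removes participants failing any active rule and logs per-rule counts.
#' Available rules: the planted health-history flags (`antipsychotic`,
#' `uncontrolled_htn`, `insulin_diabetes`, `head_injury`), `mmse_below_24`
#' (Mini-Mental State Exam score below 24) and `apoe_e2e4` (the
#' epsilon-2/epsilon-4 genotype, whose alleles have opposing effects).  A
#' participant failing several rules is removed once but counted under each
#' rule.
#'
#' @param cohort cohort data frame.
#' @param rules character vector of active rules (default: all).
#' @return list with `cohort` (filtered) and `log` (data.frame of rule,
#'   n_flagged).
#' @export
apply_exclusions <- function(cohort, rules = default_exclusion_rules) {
  if (!length(rules))
    return(list(cohort = cohort,
                log = data.frame(rule = character(), n_flagged = integer())))
  flagged <- matrix(FALSE, nrow(cohort), length(rules),
                    dimnames = list(NULL, rules))
  for (r in rules) {
    flagged[, r] <- switch(r,
      mmse_below_24 = {
        if (is.null(cohort$mmse)) stop_ef("rule 'mmse_below_24' needs column 'mmse'")
        !is.na(cohort$mmse) & cohort$mmse < 24
      },
      apoe_e2e4 = apoe_group(cohort$apoe) == "excluded_e2e4",
      {
        if (is.null(cohort[[r]])) stop_ef("rule '", r, "' needs column '", r, "'")
        !is.na(cohort[[r]]) & cohort[[r]] == 1
      })
  }
  flagged[is.na(flagged)] <- FALSE
  drop <- rowSums(flagged) > 0
  list(cohort = cohort[!drop, , drop = FALSE],
       log = data.frame(rule = rules, n_flagged = colSums(flagged),
                        row.names = NULL),
       n_removed = sum(drop))
}

#' Cohort descriptives by stratum
#'
#' n, mean (SD) of each baseline indicator and sex counts, per stratum.
#'
#' @param cohort cohort data frame.
#' @param strata factor of stratum membership (default: APOE group).
#' @return data.frame, one row per statistic per stratum.
#' @export
describe_cohort <- function(cohort, strata = NULL) {
  if (nrow(cohort) == 0L) stop_ef("empty cohort")
  if (is.null(strata)) strata <- apoe_group(cohort$apoe)
  strata <- as.factor(strata)
  vars <- c("age_w1", "edu_years", "pp", "bmi", "grip", "act_phys",
            "act_soc", "act_integ", "act_novel")
  vars <- intersect(vars, names(cohort))
  out <- lapply(levels(strata), function(s) {
    rows <- which(!is.na(strata) & strata == s)
    if (!length(rows)) {
      return(data.frame(stratum = s, n = 0L, males = NA, females = NA,
                        t(stats::setNames(rep(NA_real_, 2 * length(vars)),
                                          c(paste0(vars, "_mean"),
                                            paste0(vars, "_sd"))))))
    }
    sub <- cohort[rows, , drop = FALSE]
    m <- vapply(vars, function(v) mean(sub[[v]], na.rm = TRUE), numeric(1))
    s_ <- vapply(vars, function(v) {
      x <- sub[[v]][!is.na(sub[[v]])]
      if (length(x) < 2L) NA_real_ else stats::sd(x)
    }, numeric(1))
    data.frame(stratum = s, n = length(rows),
               males = sum(sub$sex == 0, na.rm = TRUE),
               females = sum(sub$sex == 1, na.rm = TRUE),
               t(stats::setNames(c(m, s_), c(paste0(vars, "_mean"),
                                             paste0(vars, "_sd")))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, applies exclusions, computes risk scores
#' and genetic groups, establishes the measurement model (one- vs
#' two-factor comparison at baseline, then the longitudinal invariance
#' ladder), computes factor scores, runs the growth model-building ladder,
#' and fits the selected moderation analyses.  Deterministic given the
#' seed; every run report carries the configuration hash and seed.
#'
#' @param config list (or path to a YAML/JSON file) with entries:
#'   `seed` (mandatory when simulating), `n` (cohort size, default 600),
#'   `input_csv` (optional path to read instead of simulating),
#'   `analyses` (default `c("RQ1","RQ2","RQ3")`), `risk_measures`
#'   (default `c("frs","lrs","mcrs")`), `center_age` (default 75),
#'   `exclusions` (logical, default TRUE), `out_dir` (optional: write
#'   artifacts), `truth` (optional list of [cohort_truth()] overrides),
#'   `generator` (optional list of [cohort_config()] overrides),
#'   `score_method` (factor-score estimator, default "bartlett"),
#'   `verbose` (default FALSE).
#' @return object of class `ef_report`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(n = 600L, input_csv = NULL, analyses = c("RQ1", "RQ2", "RQ3"),
         risk_measures = c("frs", "lrs", "mcrs"), center_age = 75,
         exclusions = TRUE, out_dir = NULL, truth = list(),
         generator = list(), score_method = "bartlett", verbose = FALSE,
         seed = NULL),
    config)
  say <- function(...) if (isTRUE(cfg$verbose)) message("[efgrowth] ", ...)
  if (!length(cfg$analyses)) stop_ef("no analyses selected")

  if (is.null(cfg$input_csv)) {
    if (is.null(cfg$seed)) stop_ef("seed is mandatory when simulating")
    gen <- do.call(cohort_config,
                   utils::modifyList(list(n_participants = cfg$n,
                                          seed = cfg$seed), cfg$generator))
    truth <- do.call(cohort_truth, cfg$truth)
    say("simulating cohort (n = ", gen$n_participants, ", seed = ",
        gen$seed, ")")
    cohort <- simulate_cohort(gen, truth)
  } else {
    say("reading cohort from ", cfg$input_csv)
    cohort <- read_cohort(cfg$input_csv)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  excl_log <- NULL
  if (isTRUE(cfg$exclusions)) {
    ex <- apply_exclusions(cohort)
    say("exclusions removed ", ex$n_removed, " participants")
    cohort <- ex$cohort
    excl_log <- ex$log
  }

  say("genetic groups and risk scores")
  genet <- data.frame(id = cohort$id,
                      apoe_group = apoe_group(cohort$apoe),
                      adgrs(cohort$clu, cohort$cr1, cohort$picalm))
  cutoffs <- risk_cutoffs(cohort)
  scores <- risk_scores(cohort, cutoffs)

  say("baseline factor structure (one vs two factors)")
  cfa1 <- ef_cfa(cohort, waves = 1L, factors = "one")
  cfa2 <- ef_cfa(cohort, waves = 1L, factors = "two")
  # BIC comparison: the two-factor model nests the one-factor one (their
  # difference is a single inter-factor correlation), so the consistent
  # criterion is the appropriate referee for this structure choice
  factor_choice <- if (cfa1$fit$bic <= cfa2$fit$bic) "one" else "two"

  say("longitudinal invariance ladder")
  inv <- ef_invariance(cohort)
  say("achieved invariance: ", inv$level)
  meas_fit <- inv$fits[[if (inv$level %in% names(inv$fits)) inv$level else
    "scalar"]]
  cohort_sc <- add_factor_scores(cohort, meas_fit, method = cfg$score_method)

  say("growth model-building ladder")
  ef <- as.matrix(cohort_sc[, paste0("ef_w", 1:3)])
  ages <- as.matrix(cohort_sc[, paste0("age_w", 1:3)])
  ladder <- growth_ladder(ef, ages, center = cfg$center_age)
  say("preferred growth stage: ", ladder$preferred)

  say("moderation models (", paste(cfg$analyses, collapse = ", "), ")")
  mod <- moderation_table(cohort_sc, scores, analyses = cfg$analyses,
                          risk_measures = cfg$risk_measures,
                          center = cfg$center_age)

  provenance <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                     package_version = as.character(utils::packageVersion("efgrowth")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report <- list(config = cfg, provenance = provenance,
                 descriptives = describe_cohort(cohort),
                 exclusion_log = excl_log,
                 factor_choice = factor_choice,
                 cfa_baseline = list(one = cfa1$fit, two = cfa2$fit),
                 invariance = inv, growth_ladder = ladder,
                 moderation = mod, cohort = cohort_sc, scores = scores,
                 genetics = genet, cutoffs = cutoffs)
  class(report) <- "ef_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.ef_report <- function(x, ...) {
  cat("EF risk-network pipeline report\n")
  cat("  seed:", x$provenance$seed %||% NA,
      " config hash:", x$provenance$config_hash, "\n")
  cat("  cohort n (after exclusions):", nrow(x$cohort), "\n")
  cat("  factor structure chosen: ", x$factor_choice, "-factor; ",
      "invariance: ", x$invariance$level, "\n", sep = "")
  cat("  preferred growth stage:", x$growth_ladder$preferred, "\n")
  cat("  moderation rows:", nrow(x$moderation), "\n")
  invisible(x)
}

# write all artifacts for a pipeline run
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(report$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  meas <- report$invariance$fits[[if (report$invariance$level %in%
                                      names(report$invariance$fits))
    report$invariance$level else "scalar"]]
  write_measurement_json(meas, file.path(out_dir, "measurement.json"))
  gl <- report$growth_ladder
  jsonlite::write_json(
    list(steps = gl$steps, preferred = gl$preferred,
         provenance = report$provenance),
    file.path(out_dir, "growth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_moderation(report$moderation,
                   csv_path = file.path(out_dir, "moderation_table.csv"),
                   txt_path = file.path(out_dir, "moderation_table.txt"))
  md <- c("# Pipeline run report", "",
          paste0("- seed: ", report$provenance$seed %||% "none"),
          paste0("- config hash: ", report$provenance$config_hash),
          paste0("- package: efgrowth ", report$provenance$package_version),
          paste0("- cohort n: ", nrow(report$cohort)),
          paste0("- factor structure: ", report$factor_choice, "-factor"),
          paste0("- invariance level: ", report$invariance$level),
          paste0("- preferred growth stage: ", report$growth_ladder$preferred),
          "", "See moderation_table.csv for the full results table.")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
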
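# Modifiable risk scoring: functional-health (0-5), lifestyle-reserve (0-6)
# and their composite M-CRS (0-11).  Band indicators (pulse pressure, BMI,
# education) use fixed cut points; grip strength and the four lifestyle
# activity frequencies are dichotomized at the baseline mean of the
# participant's APOE stratum.

#' Default risk weight table
#'
#' The banded weights used to build the modifiable risk scores.  Pulse
#' pressure (mm Hg): below 52 scores 0, 52-72 scores 1, above 72 scores 2.
#' BMI (kg/m^2): 18.5 to below 25 ("normal") scores 0, below 18.5 or 25-30
#' scores 1, above 30 scores 2.  Education (years): 12 or more scores 0,
#' 8-11 scores 1, below 8 scores 2.  Grip strength and each activity domain
#' score 0 at or above the stratum mean and 1 below it.  The table can be
#' serialized (JSON/YAML) and passed back in, so alternative weightings are
#' auditable.
#'
#' @return a list of band definitions, one element per indicator.
#' @export
risk_weight_table <- function() {
  list(
    pp = list(breaks = c(52, 72), weights = c(0L, 1L, 2L),
              note = "low < 52; 52 <= moderate <= 72; high > 72"),
    bmi = list(normal = c(18.5, 25), overweight = c(25, 30),
               weights = c(normal = 0L, under_or_overweight = 1L, obese = 2L)),
    education = list(breaks = c(8, 12), weights = c(2L, 1L, 0L),
                     note = "< 8 -> 2; 8-11 -> 1; >= 12 -> 0"),
    mean_split = list(weights = c(at_or_above = 0L, below = 1L),
                      indicators = c("grip", "act_phys", "act_soc",
                                     "act_integ", "act_novel"))
  )
}

mean_split_indicators <- c("grip", "act_phys", "act_soc", "act_integ", "act_novel")

#' Stratified mean cutoffs for grip strength and lifestyle activities
#'
#' Computes the arithmetic mean of baseline (wave 1) observed values of grip
#' strength and the four activity-frequency scores within each APOE stratum
#' (`e4_minus`, `e4_plus`).  These means are the "strong"/"high" cutoffs for
#' the mean-split indicators.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]) containing
#'   `grip`, `act_phys`, `act_soc`, `act_integ`, `act_novel` and `apoe`.
#' @param stratifier optional factor overriding the APOE grouping derived
#'   from the `apoe` column.
#' @return object of class `ef_cutoffs`: a matrix (stratum by indicator) of
#'   means.
#' @export
risk_cutoffs <- function(cohort, stratifier = NULL) {
  if (is.null(stratifier)) stratifier <- apoe_group(cohort$apoe)
  strata <- c("e4_minus", "e4_plus")
  use <- stratifier %in% strata
  out <- matrix(NA_real_, nrow = 2L, ncol = length(mean_split_indicators),
                dimnames = list(strata, mean_split_indicators))
  for (s in strata) {
    rows <- which(use & stratifier == s)
    if (length(rows) < 2L)
      stop_ef("stratum '", s, "' has fewer than 2 participants with data")
    for (ind in mean_split_indicators)
      out[s, ind] <- mean(cohort[[ind]][rows], na.rm = TRUE)
  }
  if (any(!is.finite(out))) stop_ef("non-finite cutoff computed")
  structure(out, class = c("ef_cutoffs", class(out)))
}

#' Categorize one risk indicator into its weight
#'
#' Applies the risk weight bands to a vector of
#' measurements.  Banded indicators (`"pp"`, `"bmi"`, `"education"`) need no
#' cutoffs; mean-split indicators (`"grip"`, `"act_phys"`, `"act_soc"`,
#' `"act_integ"`, `"act_novel"`) require `cutoffs` and `stratum`.  A value
#' exactly at the stratum mean counts as strong/high (weight 0); BMI exactly
#' 25 counts as overweight and pulse pressure exactly 52 and 72 as moderate.
#' Missing values give missing weights.
#'
#' @param indicator indicator name (see above).
#' @param value numeric vector of measurements.
#' @param cutoffs an [risk_cutoffs()] object, for mean-split indicators.
#' @param stratum `"e4_minus"` or `"e4_plus"` (scalar or vector), for
#'   mean-split indicators.
#' @return integer vector of weights (0, 1 or 2; `NA` where value missing).
#' @examples
#' categorize_indicator("pp", c(45, 60, 80))    # 0 1 2
#' categorize_indicator("bmi", c(22, 27, 32))   # 0 1 2
#' categorize_indicator("education", c(6, 10, 12))  # 2 1 0
#' @export
categorize_indicator <- function(indicator, value, cutoffs = NULL,
                                 stratum = NULL) {
  value <- as.numeric(value)
  w <- rep(NA_integer_, length(value))
  ok <- is.finite(value)
  if (indicator == "pp") {
    w[ok] <- ifelse(value[ok] < 52, 0L, ifelse(value[ok] <= 72, 1L, 2L))
  } else if (indicator == "bmi") {
    w[ok] <- ifelse(value[ok] > 30, 2L,
                    ifelse(value[ok] >= 18.5 & value[ok] < 25, 0L, 1L))
  } else if (indicator == "education") {
    w[ok] <- ifelse(value[ok] >= 12, 0L, ifelse(value[ok] >= 8, 1L, 2L))
  } else if (indicator %in% mean_split_indicators) {
    if (is.null(cutoffs) || is.null(stratum))
      stop_ef("indicator '", indicator, "' needs stratified cutoffs and stratum")
    stratum <- as.character(stratum)
    if (length(stratum) == 1L) stratum <- rep(stratum, length(value))
    if (!all(stratum[ok] %in% c(rownames(cutoffs), NA_character_)))
      stop_ef("unknown stratum in categorize_indicator()")
    cut <- unclass(cutoffs)[cbind(stratum, indicator)]
    w[ok] <- ifelse(value[ok] >= cut[ok], 0L, 1L)
  } else {
    stop_ef("unknown risk indicator: '", indicator, "'")
  }
  w
}

#' Functional-health risk score (0-5)
#'
#' Sum of the pulse-pressure, grip-strength and BMI weights.  Any missing
#' component makes the score missing (the participant drops out of analyses
#' using this score).
#'
#' @param pp,grip,bmi numeric vectors of baseline measurements.
#' @param cutoffs,stratum stratified cutoffs for the grip mean split.
#' @return integer vector in 0..5 with `NA` for incomplete components.
#' @export
functional_health_score <- function(pp, grip, bmi, cutoffs, stratum) {
  categorize_indicator("pp", pp) +
    categorize_indicator("grip", grip, cutoffs, stratum) +
    categorize_indicator("bmi", bmi)
}

#' Lifestyle-reserve risk score (0-6)
#'
#' Sum of the four activity mean-split weights (physical, social,
#' cognitive-integrative, cognitive-novel) and the education band weight.
#'
#' @param act_phys,act_soc,act_integ,act_novel activity frequency scores.
#' @param education years of education.
#' @param cutoffs,stratum stratified cutoffs for the activity mean splits.
#' @return integer vector in 0..6 with `NA` for incomplete components.
#' @export
lifestyle_reserve_score <- function(act_phys, act_soc, act_integ, act_novel,
                                    education, cutoffs, stratum) {
  categorize_indicator("act_phys", act_phys, cutoffs, stratum) +
    categorize_indicator("act_soc", act_soc, cutoffs, stratum) +
    categorize_indicator("act_integ", act_integ, cutoffs, stratum) +
    categorize_indicator("act_novel", act_novel, cutoffs, stratum) +
    categorize_indicator("education", education)
}

#' Modifiable-composite risk score (0-11)
#'
#' @param frs,lrs functional-health and lifestyle-reserve scores.
#' @return `frs + lrs`; missing whenever either component is.
#' @export
combined_mcrs <- function(frs, lrs) frs + lrs

#' Per-participant risk scores with audit trail
#'
#' Computes functional-health (FRS), lifestyle-reserve (LRS) and composite
#' (M-CRS) risk scores for every participant, with the per-indicator weights
#' kept as audit columns (`w_` prefix).  Participants outside the
#' `e4_minus`/`e4_plus` strata (the excluded e2/e4 genotype, or missing
#' APOE) get missing mean-split weights and hence missing scores.
#'
#' @param cohort a cohort data frame.
#' @param cutoffs optional precomputed [risk_cutoffs()]; computed from
#'   `cohort` when omitted.
#' @return data.frame with `id`, `frs`, `lrs`, `mcrs` and audit weights.
#' @export
risk_scores <- function(cohort, cutoffs = NULL) {
  grp <- apoe_group(cohort$apoe)
  if (is.null(cutoffs)) cutoffs <- risk_cutoffs(cohort, grp)
  stratum <- as.character(grp)
  stratum[!stratum %in% rownames(cutoffs)] <- NA
  n <- nrow(cohort)
  w <- data.frame(
    w_pp = categorize_indicator("pp", cohort$pp),
    w_grip = rep(NA_integer_, n),
    w_bmi = categorize_indicator("bmi", cohort$bmi),
    w_act_phys = rep(NA_integer_, n),
    w_act_soc = rep(NA_integer_, n),
    w_act_integ = rep(NA_integer_, n),
    w_act_novel = rep(NA_integer_, n),
    w_education = categorize_indicator("education", cohort$edu_years)
  )
  ok <- !is.na(stratum)
  for (ind in mean_split_indicators) {
    col <- if (ind == "grip") "grip" else ind
    w[[paste0("w_", ind)]][ok] <-
      categorize_indicator(ind, cohort[[col]][ok], cutoffs, stratum[ok])
  }
  frs <- w$w_pp + w$w_grip + w$w_bmi
  lrs <- w$w_act_phys + w$w_act_soc + w$w_act_integ + w$w_act_novel +
    w$w_education
  data.frame(id = cohort$id, frs = frs, lrs = lrs,
             mcrs = combined_mcrs(frs, lrs), w)
}
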
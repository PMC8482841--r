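# Genotype handling: Hardy-Weinberg checks, APOE stratification and the
# three-SNP AD genetic risk score (AD-GRS).

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of one biallelic SNP against Hardy-Weinberg
#' proportions.  Allele frequencies are taken from the observed genotype
#' counts, expected counts are \eqn{np^2, 2npq, nq^2}, and the statistic is
#' \eqn{\sum (O-E)^2/E} on 1 degree of freedom (genotype categories minus
#' allele frequency estimated minus one).  No continuity correction is
#' applied; `exact = TRUE` gives the conditional exact test of Wigginton,
#' Cutler and Abecasis (2005) instead, as a diagnostic option.
#'
#' @param hom_ref,het,hom_alt genotype counts.  May also be supplied as a
#'   single length-3 vector in `hom_ref`.
#' @param exact logical; compute the exact mid-less test p-value instead of
#'   the asymptotic chi-square p.
#' @return list with `chi2`, `df` (1) and `p` (for `exact = TRUE`, `chi2`
#'   is still the Pearson statistic but `p` is the exact p-value).
#' @examples
#' hwe_chisq(213, 332, 85)   # chi2 about 6.22
#' hwe_chisq(25, 50, 25)     # exact Hardy-Weinberg proportions, chi2 = 0
#' @export
hwe_chisq <- function(hom_ref, het, hom_alt = NULL, exact = FALSE) {
  if (length(hom_ref) == 3L && is.null(hom_alt)) {
    counts <- hom_ref
  } else {
    counts <- c(hom_ref, het, hom_alt)
  }
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0))
    stop_ef("genotype counts must be three non-negative numbers")
  n <- sum(counts)
  if (n <= 0) stop_ef("total genotype count must be positive")
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    stop_ef("monomorphic SNP: Hardy-Weinberg statistic undefined")
  e <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - e)^2 / e)
  out <- list(chi2 = chi2, df = 1L,
              p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
  if (exact) out$p <- hwe_exact_p(counts)
  out
}

# Exact HWE test (conditional on allele counts); sums probabilities of
# heterozygote counts no more probable than the observed one.
hwe_exact_p <- function(counts) {
  nAB <- counts[2L]
  nA <- 2 * counts[1L] + counts[2L]
  nB <- 2 * counts[3L] + counts[2L]
  if (nA > nB) { tmp <- nA; nA <- nB; nB <- tmp }
  n <- (nA + nB) / 2
  hets <- seq(nA %% 2, nA, by = 2)
  logp <- vapply(hets, function(h) {
    na <- (nA - h) / 2
    nb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAB, hets)] * (1 + 1e-12)])
}

# --- genotype string parsing -------------------------------------------------

# "e3/e4", "E4/e3" -> sorted allele pair c("e3","e4"); order/case insensitive.
parse_apoe <- function(x) {
  x <- tolower(gsub("[^0-9eE/]", "", as.character(x)))
  parts <- strsplit(x, "/", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) != 2L) return(NULL)
    p <- sub("^([0-9])$", "e\\1", p)
    if (!all(p %in% c("e2", "e3", "e4"))) return(NULL)
    sort(p)
  })
}

# "T/c" -> c("C","T"); order/case insensitive; NA stays NA.
parse_snp <- function(x) {
  x <- toupper(as.character(x))
  parts <- strsplit(x, "/", fixed = TRUE)
  lapply(seq_along(parts), function(i) {
    if (is.na(x[i]) || x[i] == "") return(NA_character_)
    p <- parts[[i]]
    if (length(p) != 2L || !all(p %in% c("A", "C", "G", "T")))
      stop_ef("malformed genotype call: '", x[i], "'")
    sort(p)
  })
}

#' APOE risk grouping
#'
#' Groups APOE genotypes into risk strata: any genotype carrying an
#' \eqn{\epsilon 4} allele is `e4_plus`, the \eqn{\epsilon 2/\epsilon 4}
#' heterozygote is flagged `excluded_e2e4` (the two alleles have opposing
#' effects, so such carriers are removed from stratified analyses), and all
#' remaining genotypes are `e4_minus`.
#'
#' @param apoe character vector of genotype strings such as `"e3/e4"`
#'   (case and allele-order insensitive).
#' @return factor with levels `e4_minus`, `e4_plus`, `excluded_e2e4`.
#' @examples
#' apoe_group(c("e3/e3", "e3/e4", "e2/e4"))
#' @export
apoe_group <- function(apoe) {
  pairs <- parse_apoe(apoe)
  bad <- vapply(pairs, is.null, logical(1)) & !is.na(apoe)
  if (any(bad))
    stop_ef("unknown APOE genotype: '", apoe[which(bad)[1L]], "'")
  out <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p)) return(NA_character_)
    if (identical(p, c("e2", "e4"))) "excluded_e2e4"
    else if ("e4" %in% p) "e4_plus"
    else "e4_minus"
  }, character(1))
  factor(out, levels = c("e4_minus", "e4_plus", "excluded_e2e4"))
}

# risk alleles for the three AD-GRS SNPs (carrier coding)
adgrs_risk_alleles <- c(clu = "C", cr1 = "A", picalm = "T")

#' Three-SNP AD genetic risk score
#'
#' Carrier (dominant) coding of CLU rs11136000, CR1 rs6656401 and PICALM
#' rs3851179: each SNP contributes 1 when at least one risk allele (CLU C,
#' CR1 A, PICALM T) is present, 0 otherwise.  The score is the sum (0-3) and
#' is split into `low` (0-1 risk alleles) and `high` (2-3) groups.
#' Participants missing any of the three calls get `NA` score and group and
#' are thereby excluded from genetic analyses.
#'
#' @param clu,cr1,picalm genotype strings such as `"C/T"` (case and
#'   allele-order insensitive); `NA` for missing calls.
#' @return data.frame with integer `score` (0-3) and factor `group`
#'   (`low`/`high`).
#' @examples
#' adgrs("C/T", "A/G", "T/C")   # score 3, high
#' adgrs("T/T", "G/G", "C/C")   # score 0, low
#' @export
adgrs <- function(clu, cr1, picalm) {
  calls <- list(clu = parse_snp(clu), cr1 = parse_snp(cr1),
                picalm = parse_snp(picalm))
  n <- max(vapply(calls, length, integer(1)))
  carrier <- sapply(names(calls), function(snp) {
    vapply(calls[[snp]], function(g) {
      if (length(g) == 1L && is.na(g)) return(NA_integer_)
      as.integer(adgrs_risk_alleles[[snp]] %in% g)
    }, integer(1))
  })
  carrier <- matrix(carrier, nrow = n)
  score <- as.integer(rowSums(carrier))
  group <- factor(ifelse(is.na(score), NA,
                         ifelse(score <= 1L, "low", "high")),
                  levels = c("low", "high"))
  data.frame(score = score, group = group)
}
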
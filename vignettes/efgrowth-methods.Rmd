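---
title: "Methods: risk scores, latent EF measurement, and growth models in efgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk scores, latent EF measurement, and growth models in efgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`efgrowth` implements a multimodal risk-network analysis of executive-function
(EF) trajectories in non-demented aging: modifiable risk scores and genetic
risk groupings are used to predict individual differences in the level and
rate of change of a latent EF variable, estimated from four standard tests
over three measurement waves.  This vignette is the package's account of the
statistical machinery, the choices made where the design was genuinely open,
and what the synthetic-data tests do and do not establish.

## The data structure

The target design is an accelerated longitudinal study: participants enter
between ages 53 and 85 and are retested about every 4.4-4.5 years over three
waves, so the pooled person-wave ages span roughly 53-95.  Age — not wave —
is the time metric throughout, centered at 75 years (a conventional anchor
at which aging-related cognitive change is clearly underway).  Each wave
contributes four EF test scores (Stroop and Hayling for inhibition, Brixton
and Color Trails for shifting), all oriented so that higher = better EF.
Baseline measurements cover pulse pressure (mm Hg), grip strength (kg/force),
BMI (kg/m^2), four lifestyle-activity frequency totals, education (years),
and genotype calls for APOE and three AD-associated SNPs (CLU rs11136000,
CR1 rs6656401, PICALM rs3851179).

## Genetic risk

`hwe_chisq()` is the df = 1 Pearson goodness-of-fit test against
Hardy-Weinberg proportions, with allele frequencies estimated from the
observed genotype counts and no continuity correction (an exact test is
available as a diagnostic flag, not the default).  `apoe_group()` encodes
the carrier convention: any epsilon-4 carrier is `e4_plus`, except the
epsilon-2/epsilon-4 heterozygote, which is excluded outright because the two
alleles are believed to pull in opposite directions.  `adgrs()` uses carrier
(dominant) coding per SNP — CLU C, CR1 A and PICALM T carriers each
contribute one point — and splits the 0-3 sum at the fixed 0-1 (low) versus
2-3 (high) boundary.  The cut is hard-coded rather than recomputed as a
sample median: the published grouping is an explicit boundary, and a
data-driven median would make group membership dataset-dependent.

## Modifiable risk scores

Scoring follows a banded weight table.  Pulse pressure: below 52 mm Hg
scores 0, 52-72 scores 1, above 72 scores 2.  BMI: 18.5 to below 25 scores
0, below 18.5 or 25-30 scores 1, above 30 scores 2.  Education: 12 or more
completed years scores 0, 8-11 scores 1, under 8 scores 2.  Grip strength
and the four activity totals are dichotomized at the baseline mean of the
participant's APOE stratum (epsilon-4 negative or positive), scoring 0 at or
above the mean.  The functional-health score (FRS, 0-5) sums pulse
pressure, grip and BMI; the lifestyle-reserve score (LRS, 0-6) sums the four
activities and education; the composite M-CRS (0-11) is their sum.

Three boundary conventions had to be fixed because printed band labels abut:
a value exactly at a stratum mean counts as strong/high (weight 0), BMI
exactly 25 counts as overweight, and pulse pressure exactly at 52 or 72
counts as moderate.  These are deterministic, documented conventions — the
original assignments at exact boundaries are unknowable, and at realistic
measurement precision they affect almost no participants.  Stratified
cutoffs are always the APOE-stratum baseline means, including inside AD-GRS
subgroup analyses: the cutoff definition is anchored to APOE stratification
only, and re-deriving cutoffs inside ever-smaller subgroups would change the
meaning of the score across analyses.  Missing components make the affected
score (and only it) missing; such participants drop out of analyses using
that score.

## Latent EF measurement

`ef_cfa()` estimates a confirmatory factor model for the four indicators —
one factor per wave in the main model, or an inhibition/shifting two-factor
alternative for the baseline comparison — by casewise (full-information)
maximum likelihood, so each participant contributes the multivariate-normal
density of whatever indicators they actually have.  Identification uses the
marker convention: the first loading of each factor is fixed at 1, factor
means are 0 at wave 1, and wave-2/3 factor means are freed once intercepts
are constrained.  Cross-wave covariances among the wave factors are free,
and so are same-indicator residual covariances across waves (standard
longitudinal CFA practice; test-specific method variance persists over
time).

The invariance ladder (`ef_invariance()`) fits configural, metric (equal
loadings), scalar (equal intercepts) and residual (equal residual
variances) models in sequence, comparing each step with the likelihood-ratio
chi-square difference at alpha = 0.05.  If strict scalar invariance is
rejected, intercepts are freed one at a time — the candidate giving the
largest likelihood gain first, ties broken toward the lowest indicator
index, at most two of the eight wave-2/3 intercepts — until the model is no
longer significantly worse than the metric model; the result is labelled
partial scalar.  Factor scores for growth modelling require at least
partial scalar invariance, which is exactly the achieved level the ladder
reports.

Fit statistics are likelihood-based throughout because raw-data moments are
undefined under missingness: the model chi-square is twice the gap to the
saturated FIML model (unstructured means and covariances, estimated by EM);
RMSEA is `sqrt(max(chi2 - df, 0) / (df * n))`; CFI uses the independence
baseline (free means and variances, zero covariances, which under casewise
likelihood separates per variable and has a closed-form MLE); and SRMR is
computed on correlation-scale residuals between the saturated-model and
model-implied moments.  The conventional adequacy screens are RMSEA at or
below 0.05, CFI at least 0.95, SRMR at most 0.08.

Optimization runs quasi-Newton (BFGS) on an unconstrained
reparameterization — log residual variances, Cholesky factor of the
factor-covariance block — warm-started from observed-moment heuristics, with
up to three jittered restarts if convergence fails; convergence is accepted
at a relative tolerance of 1e-12 in the negative log-likelihood.  A
non-positive-definite implied covariance is penalized (the likelihood
returns a large value), never silently clamped, and residual variances
collapsing toward zero are reported as Heywood boundary cases.

### Factor scores

The baseline structure comparison (`run_pipeline()`) fits the one-factor
and the inhibition/shifting two-factor model at wave 1 and chooses by BIC:
the two models differ only by a single inter-factor correlation, and under
a true one-factor structure the AIC would flip to the larger model in a
non-trivial share of samples, whereas the BIC choice is consistent.  The
longitudinal invariance ladder and factor scores always use the one-factor
structure, which is the construct the growth models are about.

### Factor scores

`predict.ef_cfa()` offers two estimators.  Regression (empirical-Bayes)
scores, `alpha + Psi Lambda' Sigma^{-1} (y - mu)` on each participant's
observed indicators, minimize mean-squared error but shrink toward the
factor mean.  Bartlett scores,
`(Lambda' Theta^{-1} Lambda)^{-1} Lambda' Theta^{-1} (y - tau)`, are
conditionally unbiased given the latent value.  The growth pipeline uses
Bartlett scores by default: when factor scores serve as the *outcome* of a
second-stage regression, shrinkage in regression scores attenuates every
downstream coefficient, whereas Bartlett measurement error acts as pure
outcome noise and leaves regression coefficients unbiased (the
Skrondal-Laake rule: unbiased scores for the dependent-variable side).
Regression scores remain available and are what the closed-form oracle
tests check.  A wave with no observed indicators yields no score, and the
two-stage design (measurement first, growth second) is deliberate: it
mirrors the common practice of computing factor scores once and reusing
them in all subsequent models, at the cost of ignoring score-estimation
uncertainty (see Limitations).

## Growth models

`ef_growth()` fits random-coefficients growth models by marginal maximum
likelihood: person i's observed scores are multivariate normal with mean
`X_i beta` and covariance `Z_i G Z_i' + R_i`, where `Z_i = (1, t_i)` holds
centered ages, `G` is the random intercept/slope covariance
(Cholesky-parameterized), and `R_i` is diagonal with per-wave residual
variances (the default; a common residual is available).  The
model-building ladder adds, in order: random intercepts, a fixed linear
slope, random slopes, and a fixed quadratic; each addition is tested with
the chi-square difference.  Variance-component additions sit on the
boundary of the parameter space, so their nominal reference is conservative
(the 50:50 mixture caveat); the ladder flags those rows rather than
adjusting them.

The conditional model regresses both growth factors on a risk score and
sex (female = 1, so a positive coefficient means better EF in women).  With
two predictors and per-wave residuals the free-parameter count is
6 regression + 3 random-effect + 3 residual = 12; a constant predictor is
dropped with a warning and removes two parameters.  Fixed effects are
profiled out by generalized least squares at every variance evaluation, so
the optimizer works in at most six dimensions, and the per-person 3x3
covariance inverses use closed-form adjugates vectorized over participants.
Standard errors come from the inverse observed information (a
central-difference numerical Hessian of the joint likelihood in all
parameters) and p-values from two-sided Wald z tests, mirroring common SEM
software; boundary variance estimates are flagged rather than corrected.

Stratified (multiple-group) fits estimate every parameter per group and
combine: the model log-likelihood is the sum over strata, the free-parameter
count is the sum (24 for two groups), and AIC/BIC use the *total* n across
strata — a documented choice, since the alternative per-group-n BIC is
equally defensible and the convention in multi-group SEM output is total n.
Strata below 15 participants are fit but flagged low-n.  `moderation_table()`
assembles the three analysis layers: the whole-sample regressions (RQ1),
APOE-stratified regressions (RQ2), and AD-GRS-stratified regressions within
each APOE group (RQ3), each reporting per-stratum intercept/slope
coefficients with SEs and p-values plus the combined -2LL, AIC and BIC.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the structure the analysis assumes:
baseline age uniform on 53-85; intervals normal around 4.4 and 4.5 years
(SD 0.5, truncated at 1); 66% women; APOE allele frequencies solved so the
epsilon-4 carrier share among analysis-eligible genotypes is 149/602, with
epsilon-2 frequency 0.078; SNP risk-allele frequencies 0.60 (CLU C), 0.3984
(CR1 A) and 0.5747 (PICALM T), the latter two matching published genotype
tables, drawn under Hardy-Weinberg proportions; and baseline indicator
means/SDs set to the majority-stratum published values (for example pulse
pressure 51.56 (10.13) mm Hg, grip 29.21 (9.53) kg/f).  Risk indicators are
generated independently of genotype — the published stratum means are nearly
equal — and independently of each other.

The latent process is a random intercept/slope model: person-level
intercepts and slopes are bivariate normal around fixed means (0 and
-0.025/yr at age 75) shifted by the true risk and sex effects; wave-level
EF adds a disturbance (variance 0.18); indicators add loadings (1, 0.9,
0.8, 0.85) and measurement noise (variances 0.35-0.45).  The default
regression effects are the composite-score calibration: risk on intercept
-0.161 per point, risk on slope -0.007 per point per year, sex 0.275 and
0.015.  The generating risk effect is driven by the participant's composite
score computed with the population means as cutoffs, centered at its
expected value, so refitting the pipeline's own score recovers the
generating coefficients.  Random-effect defaults are intercept variance
0.65, slope variance 0.002 (SD ~0.045/yr, about twice the mean decline
rate) and covariance -0.01: slope heterogeneity of the same order as the
mean rate is what longitudinal aging studies consistently report, and it
makes the random-slope model decisively identifiable at n = 600, matching
the foundational model choice the analysis presumes.

Attrition is monotone with wave-to-wave retention 0.81 and 0.56.  The
default mechanism is missing-at-random: the retention propensity is a
logistic function of standardized baseline age (coefficient -0.5) and the
standardized mean of the baseline EF indicators (+0.5) — older and
lower-performing participants drop out more — with the intercept calibrated
by root-finding so the average propensity equals the target retention
exactly.  Conditioning on *baseline observed* quantities keeps the
mechanism genuinely MAR for likelihood-based fitting.  An MCAR option
exists for oracle tests.  Health-history exclusions (anti-psychotic
medication, MMSE below 24, uncontrolled hypertension, insulin-dependent
diabetes, serious head injury) are planted at low configurable rates so the
exclusion filter is testable.

What the generator does *not* emulate: raw test-score metrics (indicators
are generated directly on the latent-anchored scale, already oriented),
item-level questionnaire structure, genotype linkage disequilibrium,
indicator-genotype correlations, practice/retest effects, and
non-normal measurement error.  Passing the simulation suite therefore shows
that the estimators recover the truth under the model's own assumptions —
it does not validate those assumptions against real cohort data, which
remain restricted.

## Worked example

```{r, eval = FALSE}
library(efgrowth)
report <- run_pipeline(list(n = 600, seed = 1, analyses = c("RQ1", "RQ2"),
                            risk_measures = "mcrs"))
print(report)
subset(report$moderation, term == "mcrs",
       select = c(rq, stratum, n, intercept_beta, intercept_se,
                  slope_beta, slope_se, aic, bic))
```

## Numerical choices and problem sizes

Simulation-based checks in the test suite use cohorts of n = 600 (the
design's analytic scale): 150 replicates for parameter recovery, 400
permutation replicates for the type-I rate, 100 seeds for the invariance
ladder under the null plus 20 with a planted 0.5-SD wave-3 intercept
shift, and 100 seeds for growth-stage selection.  The acceptance script
reports the same quantities at reduced replicate counts (60/150/30/30) so a
full reproduction run stays inexpensive; each JSON entry records the
problem size used.  Likelihood evaluations group participants by
missingness pattern and, for the measurement model, collapse each pattern
to its mean and scatter, so a likelihood evaluation costs the same at
n = 600 as at n = 60.

## Known limitations

Two-stage estimation ignores factor-score uncertainty, so growth-model SEs
are mildly optimistic relative to a single-stage full-SEM fit (which is
deliberately out of scope).  Wald inference uses the normal reference, not
t, and no multiple-testing correction is applied across analysis cells —
both choices mirror the conventions of the emulated analysis.  Boundary
variance tests are flagged, not mixture-corrected.  The partial-scalar
search is greedy and capped at two freed intercepts; with more pervasive
non-invariance it will stop at metric level rather than chase a better
partial solution.  The published PICALM Hardy-Weinberg statistic could not
be reproduced exactly from its printed genotype counts (the Pearson
statistic is 36.903 against a printed 36.955; the CR1 table reproduces to
0.001), so the package reports the exact Pearson value.
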
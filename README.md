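# efgrowth

Multimodal risk scores and latent executive-function growth in
non-demented aging.

## What this package is for

Cognitive aging studies increasingly ask not just *whether* older adults
decline, but *who* declines faster — and whether modifiable health and
lifestyle risk interacts with genetic risk in shaping those trajectories.
`efgrowth` implements that analysis end to end for a latent
executive-function (EF) outcome measured by four standard tests (Stroop,
Hayling, Brixton, Color Trails) over three waves of an accelerated
longitudinal design spanning ages 53-95:

1. **Modifiable risk scores.**  A functional-health score FRS ∈ {0..5}
   (pulse pressure, grip strength, BMI), a lifestyle-reserve score
   LRS ∈ {0..6} (four activity domains plus education), and their composite
   M-CRS = FRS + LRS ∈ {0..11}, with grip and activities dichotomized at
   APOE-stratum baseline means.
2. **Genetic risk.**  Hardy-Weinberg checks (df = 1 Pearson χ²), APOE ε4
   stratification with ε2/ε4 exclusion, and a three-SNP genetic risk score
   (CLU + CR1 + PICALM carrier count 0-3, split low 0-1 / high 2-3).
3. **Latent EF measurement.**  One-factor longitudinal CFA by
   full-information maximum likelihood (FIML), a
   configural → metric → scalar (→ partial scalar) → residual invariance
   ladder, LR-based fit indices (χ², CFI, RMSEA, SRMR), and Bartlett or
   regression factor scores.
4. **Growth models.**  Random-intercept/random-slope models on the age
   metric (centered at 75),

   EF_it = (β₀ + β₀ᵣ·risk_i + β₀ₛ·sex_i + u₀ᵢ)
         + (β₁ + β₁ᵣ·risk_i + β₁ₛ·sex_i + u₁ᵢ)·(age_it − 75) + e_it,

   with (u₀, u₁) ~ N(0, G), per-wave residual variances, a null → random
   intercept → fixed slope → random slope → fixed quadratic model-building
   ladder, and multiple-group (APOE, AD-GRS) moderation fits reporting
   β/SE/p per stratum plus −2LL, AIC = −2LL + 2k, BIC = −2LL + k·ln(n).
5. **A seeded synthetic cohort generator** reproducing the design
   (baseline age U(53, 85), ~4.4/4.5-year waves, 81%/56% retention with
   missing-at-random attrition, 66% female, published genotype frequencies
   and indicator means/SDs), so the whole pipeline is testable without
   access to restricted cohort data.

The intended users are quantitative aging researchers who want a tested,
scriptable reference implementation of this risk-network analysis, or a
simulation bench for planning similar studies.

## Worked example

```r
library(efgrowth)
report <- run_pipeline(list(n = 600, seed = 1, analyses = "RQ1",
                            risk_measures = "mcrs"))
print(report)
#> EF risk-network pipeline report
#>   seed: 1  config hash: 10cb9638
#>   cohort n (after exclusions): 568
#>   factor structure chosen: one-factor; invariance: residual
#>   preferred growth stage: random_slope
#>   moderation rows: 2
subset(report$moderation, term == "mcrs",
       select = c(n, intercept_beta, intercept_se, intercept_p,
                  slope_beta, slope_se, slope_p))
#>     n intercept_beta intercept_se  intercept_p  slope_beta    slope_se
#> 1 568      -0.148784    0.0297539 5.718594e-07 -0.01052032 0.002652899
#>        slope_p
#> 1 7.321368e-05
```

Read: in this simulated cohort each additional point of composite risk is
associated with about 0.15 latent-EF units lower performance at age 75 and
about 0.011 units per year steeper decline, both clearly nonzero (the
generator's true values are −0.161 and −0.007; the one-seed estimates sit
within sampling error of them).
`plot(fit)` on a conditional `ef_growth` fit draws the implied
trajectories by risk level across the 53-95 age band.

Individual stages are available as ordinary fitting functions with the
usual methods: `simulate_cohort()`, `risk_scores()`, `hwe_chisq()`,
`adgrs()`, `ef_cfa()` / `ef_invariance()` (+ `predict()` for factor
scores), `ef_growth()` / `growth_ladder()` / `ef_growth_stratified()` /
`moderation_table()`, and `apply_exclusions()` / `describe_cohort()` /
`run_pipeline()`.

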
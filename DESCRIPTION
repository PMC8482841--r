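Package: efgrowth
Title: Multimodal Risk Scores and Latent Executive-Function Growth in
    Non-Demented Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construct modifiable Alzheimer's-disease risk scores
    (functional-health, lifestyle-reserve and their composite) and genetic
    risk groupings (APOE epsilon-4 strata and a three-SNP genetic risk
    score), build a latent executive-function (EF) variable from four
    standard tests with full-information maximum likelihood and a
    longitudinal measurement-invariance ladder, and fit random-intercept /
    random-slope latent growth models on an age metric (accelerated
    longitudinal design, age centered at 75) with risk-score and sex
    predictors, optionally stratified by genetic risk group.  Includes a
    seeded synthetic cohort generator emulating the multi-wave data
    structure such analyses assume, so the whole pipeline is testable
    without restricted cohort data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
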
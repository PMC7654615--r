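Package: mctsim
Title: Simulation and Analysis of Multicenter Trials with Rare Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing multicenter randomized trials
    with binary outcomes and very low event rates, where randomization is
    stratified by center with permuted blocks. Provides a trial simulator
    (latent-variable logistic data-generating mechanism with a normal center
    random effect, balanced or skewed multinomial center sizes, stratified
    permuted-block randomization) and five estimators of the treatment odds
    ratio: center-unadjusted logistic regression, random-intercept logistic
    regression via adaptive Gauss-Hermite quadrature, the Mantel-Haenszel
    common odds ratio with Robins-Breslow-Greenland variance, logistic GEE
    with exchangeable working correlation and robust (sandwich) standard
    errors, and GEE with the Fay-Graubard small-sample corrected sandwich.
    Includes conditional/marginal odds-ratio conversion, simulation-based
    power calibration, per-scenario performance summaries (type I error,
    power, bias, coverage, convergence) with Monte Carlo standard errors,
    and a scenario-grid runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
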
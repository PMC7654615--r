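---
title: "Center adjustment in multicenter trials with rare binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center adjustment in multicenter trials with rare binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mctsim)
```

## The setting

A multicenter randomized trial stratifies randomization by center, follows
a binary outcome, and — against plan — observes very few events. Several
centers end up with no events, or with events in one arm only. The analysis
must still estimate a treatment odds ratio and account for center. This
vignette documents the models the package implements, the data-generating
mechanism of its simulator, the numerical choices, and what the package's
own simulations can and cannot establish.

## The data-generating mechanism

`generate_trial()` draws from a latent-variable threshold model. For
subject $i$ in center $j$,

$$Y^*_{ij} = \alpha + \beta_{\mathrm{trt}} X_{ij} + u_j + \varepsilon_{ij},
\qquad Y_{ij} = \mathbf{1}\{Y^*_{ij} > 0\},$$

with $u_j \sim N(0, \sigma^2)$ and $\varepsilon_{ij}$ standard logistic.
Equivalently $P(Y_{ij} = 1 \mid X_{ij}, u_j) =
\mathrm{expit}(\alpha + \beta_{\mathrm{trt}} X_{ij} + u_j)$: the model is a
random-intercept logistic regression, and $\beta_{\mathrm{trt}}$ is a
*conditional* (within-center) log odds ratio.

Parameters and their defaults:

- **ICC** (`icc`): the intra-class correlation on the logit scale,
  $\sigma^2/(\sigma^2 + \pi^2/3)$; `icc_to_sigma2()` converts it to the
  random-effect variance using the standard-logistic residual variance
  $\pi^2/3 \approx 3.29$. Trials rarely exceed ICCs of a few percent;
  the simulator is typically run at 0.025 and 0.075.
- **Control event probability** (`p0`): the intercept is set to
  $\alpha = \mathrm{logit}(p_0)$, i.e., $p_0$ is the event probability in
  the *median* center ($u = 0$). We chose this conditional calibration
  because the model is written on the conditional scale and, at the ICCs
  above, averaging over $u$ moves the control rate by well under 2%. Where
  the population-averaged rate must equal $p_0$ exactly,
  `calibrate_intercept = "marginal"` solves
  $E_u[\mathrm{expit}(\alpha + u)] = p_0$ by root finding with 25-node
  Gauss–Hermite integration.
- **Randomization**: 1:1 within center by permuted blocks of 4
  (`block_size` is configurable but must be even). A final incomplete
  block is a freshly permuted block, truncated; the arm imbalance at any
  enrollment prefix is therefore at most 2.
- **Center sizes** (`size_distribution`): `"balanced"` splits
  $n$ equally (any remainder goes one-per-center to the lowest-indexed
  centers, a deterministic rule that only matters off the usual grids);
  `"skewed"` draws the sizes once per trial from a multinomial with equal
  cell probabilities $1/J$. Equal probabilities are the simplest skew
  mechanism that reproduces both realistic size spreads and the collapse
  of the realized center count when $n/J$ is small: with $n = 200$ and
  $J = 100$ the expected number of non-empty centers is
  $100(1 - 0.99^{200}) = 86.6$.

**Prescreening.** Trials with no events, or with all events in a single
arm, carry no information about an odds ratio and break most fitters;
`prescreen_trial()` classifies them and the runner excludes them *before*
fitting, reporting both the generated and the analyzed replicate counts.
Excluded replicates are dropped, not replaced, so a scenario's effective
Monte Carlo size is data-dependent; both counts appear in the output so
the reader can see the difference.

**Reproducibility.** One root seed drives a scenario; each replicate uses
a deterministically derived child seed (`replicate_seeds()`), so results
are identical across worker counts and any single replicate can be
regenerated alone.

## The five estimators

*Unadjusted logistic regression* (`fit_unadjusted`) fits
$\mathrm{logit}(\pi_{ij}) = \alpha + \beta_{\mathrm{trt}} X_{ij}$ by
maximum likelihood and targets a marginal odds ratio.

*Random-intercept logistic regression* (`fit_random_intercept`) adds
$u_j \sim N(0, \sigma^2)$ and integrates it out by adaptive Gauss–Hermite
quadrature with 9 nodes (`lme4::glmer`); it targets the conditional odds
ratio. A boundary fit ($\hat\sigma = 0$) is a legitimate optimum and is
treated as converged. `aghq_loglik()` evaluates the integrated likelihood
directly — quadrature rule centered at each center's posterior mode and
scaled by the curvature there — and the tests verify it against brute-force
trapezoid integration and use it to confirm that fitted optima beat the
generating parameters in likelihood.

*Mantel–Haenszel* (`fit_mantel_haenszel`) pools per-center 2×2 tables:
$\widehat{OR}_{MH} = \sum_j (a_j d_j/n_j) \big/ \sum_j (b_j c_j/n_j)$,
with the Robins–Breslow–Greenland SE for the CI and the Mantel–Haenszel
chi-square test (continuity-corrected by default) for the p-value — the
pairing that standard contingency-table routines produce, which the tests
confirm digit-for-digit against `stats::mantelhaen.test()`. Two behaviors
matter with rare events. First, a stratum with $a_j d_j = b_j c_j = 0$
contributes nothing: its subjects are silently excluded, and the fit
reports the informative-subject count. Second, the method is declared
non-converged when any stratum has fewer than two subjects (standard
routines cannot form the common-table test then and error out) or when the
numerator or denominator of the estimator is zero. The first of these
rules is what collapses the method's convergence rate with many small
skewed centers: at $n = 500$ spread over 100 centers the probability that
*no* center holds exactly one subject — the only trials where the method
runs at all — is only about 2–3%, and at $n = 200$ it is essentially zero.
No 0.5 continuity constant is added to cells for estimation: the estimator
handles zero cells natively, and adding constants would distort its bias.

*Exchangeable GEE* (`fit_gee_exchangeable`) solves the Liang–Zeger
estimating equation $\sum_i D_i' V_i^{-1}(Y_i - \mu_i) = 0$ by Fisher
scoring, re-estimating the working correlation $\rho$ and dispersion from
Pearson residuals each step (pairwise moment estimator with the usual
parameter-count correction in the denominator). SEs come from the robust
sandwich $V = \Omega(\sum_i D_i'V_i^{-1}\hat r_i \hat r_i' V_i^{-1}
D_i)\Omega$. The exchangeable inverse is applied in closed form (rank-one
update), so a 5-center trial of 5000 subjects needs no 1000×1000 matrix.

*Fay–Graubard corrected GEE* (`fay_graubard_correct`) inflates each
cluster's contribution by the diagonal matrix
$C_i = \mathrm{diag}\{(1 - \min(b, \{D_i'V_i^{-1}D_i\Omega\}_{jj}))^{-1/2}\}$
(bound $b = 0.75$ by default) without moving the point estimate. Because a
normal reference is exactly what fails with few clusters, the corrected
Wald statistic is referred to a $t$ distribution. The degrees of freedom
are moment-matched to the distribution of the corrected variance under the
working model, *including* the cross-cluster covariance that the shared
coefficient estimate induces in the residuals
($\mathrm{Cov}(\hat r_i, \hat r_j) = \delta_{ij}V_i - D_i\Omega D_j'$):
$\hat d = (\sum_i A_{ii})^2 / \sum_{ij} A_{ij}^2$ with
$A_{ij} = \delta_{ij} a_i - m_i'\Omega m_j$,
$m_i = H_i C_i \Omega L$, $a_i = L'\Omega C_i H_i C_i \Omega L$. At 5
roughly equal clusters this gives $\hat d \approx 3.9$ rather than the
naive $\approx 5$; ignoring the cross terms leaves the test visibly
anti-conservative. `test = "z"` switches to the normal reference for
sensitivity analyses. Note one asymmetry that follows: the FG *test* is
$t$-based while its CI uses the same $t$ critical value, so test and CI are
dual here; published analyses that pair the corrected variance with a
±1.96 CI will show lower coverage than the test's size suggests.

## Estimands and scoring

Conditional-model estimates (random intercept, Mantel–Haenszel) are scored
against the true conditional odds ratio; marginal-model estimates
(unadjusted, both GEEs) against the marginal one,
$\beta_m = \beta_c/\sqrt{1 + c^2\sigma^2}$ with $c = 16\sqrt3/(15\pi)$.
At ICC 0.025 and 0.075 the divisors are 1.0145 and 1.0451 — a visible but
small attenuation. This rescaling is itself an approximation, accurate to
1–2% here, which the tests check against direct numerical averaging over
the random-effect distribution.

`summarize_fits()` reports, over converged replicates only: the rejection
rate of the two-sided 5% test, the mean odds ratio (exponentiated mean
log-OR), 95% CI coverage, and the convergence rate, each with a Monte
Carlo SE (binomial for proportions; delta method on the log scale for the
mean). A fit is "converged" unless the fitter failed or the estimated OR
or SE exceeds 1000 — the latter rule catches separation that optimizers
report as success. When fewer than 50 replicates converge (configurable),
estimates are reported as `NA`: a handful of surviving fits would be noisy
and survivorship-biased. The 50 cutoff is our reporting choice, picked so
that near-total convergence failure reads as "no estimate" rather than as
a number computed from a few dozen lucky replicates.

## Power calibration

`solve_or_for_power()` finds the conditional OR at which a chosen method
attains a target power, by bisection on the log odds ratio with
simulation-estimated power at each candidate (default 2000 replicates,
bisection tolerance 0.01 on the OR scale — the precision to which such
design values are usually quoted). Common random numbers across candidates
make the estimated power curve monotone, and a closed-form two-proportion
approximation brackets the root to keep the evaluation count small. Power
below the test size is rejected as a target, and a target unreachable at
OR ≤ 100 errors rather than extrapolating.

## Numerical choices, in one place

- GEE Fisher scoring stops when the coefficient step falls below 1e-8
  (max 100 iterations); $\rho$ is clamped to the positive-definite range
  of the exchangeable structure.
- The AGHQ posterior-mode search runs Newton steps to tolerance 1e-10
  (max 50); quadrature weights are computed by Golub–Welsch
  eigendecomposition and applied in log space to avoid underflow with
  rare events.
- `glm` is run with a deviance tolerance of 1e-12 so the unadjusted fit
  agrees with the closed-form 2×2 estimator to full reported precision.
- Ties and degenerate inputs: empty centers are dropped at generation
  (skewed mode only); single-subject centers are legal inputs everywhere
  except that they make the Mantel–Haenszel test unformable (declared
  non-convergence, see above).

## Problem sizes used in the shipped tests

The packaged acceptance tests reproduce published operating
characteristics at reduced Monte Carlo sizes — 2000 replicates for the
5-center null scenario, 1000 for the 100-center power scenarios, 500 and
300 for the large-$n$ checks — and compare at three combined Monte Carlo
SEs, combining the uncertainty of both the reduced run and the reference
values (themselves 5000-replicate estimates). These sizes keep a full test
run to minutes while leaving the comparisons sharp enough to detect a
miscalibrated test or a biased estimator.

## What the simulator does and does not establish

The generator produces exactly the world the random-intercept model
assumes: a normal center effect, no treatment-by-center interaction, no
covariates, 1:1 allocation, and blocks of 4. Conclusions therefore favor
the random-intercept analysis by construction, and say nothing about
non-normal center effects, unequal allocation, center-size/outcome
correlation, or covariate adjustment — all deliberately out of scope.
Within that scope the simulator reproduces the qualitative phenomena that
motivate the package: sandwich-variance anticonservatism with few centers,
its repair by the Fay–Graubard correction, Mantel–Haenszel subject loss
and convergence collapse with many small centers, and upward bias of the
random-intercept estimate with many tiny centers.
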
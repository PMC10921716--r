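---
title: "What cross-sectional aging clocks can and cannot recover: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{What cross-sectional aging clocks can and cannot recover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioagesim)
```

## The model

Cross-sectional biological-age predictors start from a panel of candidate
markers $X_1, \dots, X_m$ and chronological age $C$ measured at one time
point, build an age proxy $\widehat{B}$ from the markers, and interpret the
residual of $\widehat{B}$ regressed on $C$ — written $\widehat{\Delta}$ — as
an estimate of the age-independent *aging divergence* $\Delta$, where latent
biological age is $B = C + \Delta$.

Every predictor family implemented here relies, explicitly or implicitly, on
the *identical-association assumption*: a marker's strength of association
with $C$ mirrors its strength of association with $\Delta$. The
Klemera-Doubal model makes it explicit — each marker obeys
$x_j = q_j + k_j (C + \Delta) + \epsilon_j$ with the *same* slope on $C$ and
$\Delta$. Multiple linear regression of $C$ on the markers, and
principal-component scores built from age-preselected markers, inherit the
assumption implicitly. Crucially, the assumption is untestable from
cross-sectional data: a marker loaded on $\Delta$ and a marker loaded on an
irrelevant component $\Lambda$ with the same variance produce *identical*
joint distributions with $C$. This package exists to make that fact, and its
consequences, computable.

## The generators: a stated world

All empirical claims in the test suite refer to synthetic worlds in which
$\Delta$ is known. Three generators are provided.

**True/false marker pair** (`gen_example1`). Independent normals
$C \sim N(\mu, \sigma_c^2)$, $\Delta \sim N(0, \sigma_\Delta^2)$,
$\Lambda \sim N(0, \sigma_\Lambda^2)$, then
$X = \alpha + \beta(C + \Delta) + \epsilon$ and
$X' = \alpha + \beta(C + \Lambda) + \epsilon'$. Defaults: $n = 1000$,
$\mu = 50$, $\sigma_c^2 = 10$, $\sigma^2 = 2$,
$\sigma_\Delta^2 = \sigma_\Lambda^2 = 3$, $\alpha = \beta = 1$. With these
values $\mathrm{cor}(\widehat\Delta_X, \Delta) \to \sqrt{3/5} \approx 0.775$
while $\mathrm{cor}(\widehat\Delta_{X'}, \Delta) \to 0$, even though
$(X, C)$ and $(X', C)$ are observationally equivalent. The printed variance
symbols are read literally as variances; because that reading is not beyond
doubt, `sim_params1(values_are_sd = TRUE)` switches to the
standard-deviation reading. The default is variance-as-printed.

**Four coefficient scenarios** (`scenario_table`, `gen_example2`). Three
markers $X_i = \beta_{C,i} C + \beta_{\Delta,i} \Delta + \epsilon_i$ with
$n = 1000$, $\mu = 50$, $\sigma_c^2 = 10$, $\sigma_\Delta^2 = 5$ and the
coefficient grid

| scenario | $\beta_{\Delta,1}$ | $\beta_{\Delta,2}$ | $\beta_{\Delta,3}$ | meaning |
|---|---|---|---|---|
| A | 10 | 3 | 5 | identical association |
| B | -10 | -3 | -5 | inverted |
| C | 0 | 10 | -1 | unrelated |
| D | 9 | 5 | 5 | sign informative, size not |

with $\beta_C = (10, 3, 5)$ in every scenario.

*Noise equalization.* The exact per-scenario noise variances used in the
original realization of this design are not published, so they are
reconstructed from the stated requirement: the observable joint distribution
of (markers, age) must be identical across scenarios. Because $\Delta$ and
$\epsilon_i$ are independent Gaussians, only the total non-age variance
$\beta_{\Delta,i}^2 \sigma_\Delta^2 + \sigma_i^2$ is observable, so it
suffices to give marker $i$ a common budget
$T_i = \max_s \beta_{\Delta,i}^2[s]\, \sigma_\Delta^2 + \sigma_0^2$ and set
$\sigma_i^2[s] = T_i - \beta_{\Delta,i}^2[s] \sigma_\Delta^2$
(`derive_scenario_noise`). The floor $\sigma_0^2$ (`base_noise_var`,
default 25) keeps every marker noisy but informative; it is the minimal-noise
member of the feasible family. Any common inflation of $T_i$ would also
satisfy the indistinguishability requirement — see "known limitations".

**Survival-cohort emulator** (`lls_params`, `gen_lls_like`). A middle-aged
metabolomics-style cohort with registry follow-up: $n = 2267$ subjects, age
at inclusion $\sim N(59.2, 6.7^2)$ years, 59 continuous markers, and a
Gompertz mortality hazard on the age timescale,
$h(t) = a\, e^{bt}\, e^{\gamma \Delta + \beta_{sex} \cdot sex}$, with delayed
entry at the inclusion age and administrative censoring 16.3 years later.
Defaults chosen once and not revisited:

* $b = 0.095$/yr — a standard adult human log-mortality slope (mortality
  doubling time ~7.3 yr).
* $a$ — calibrated by bisection (`calibrate_gompertz_a`) against the
  *numerically integrated* expected event fraction so that the expected
  number of deaths is 309 of 2267 (~13.6%); at the defaults this gives
  $a \approx 8\times10^{-6}$/yr. The integration, not simulation, is the
  oracle, so the realized event count is an out-of-sample check (the suite
  requires it within ±25% of 309).
* $\gamma = 0.1$ per year of divergence and
  $\sigma_\Delta = 5$ yr, i.e. a hazard ratio of ~1.65 per SD of $\Delta$ —
  the order of magnitude reported for metabolomic mortality scores.
* $\beta_{sex} = \log 1.6$ for males (sex coded 0 = female, 1 = male,
  Bernoulli(1/2)).
* Marker architecture: each marker is age-only (share 0.25), age-and-
  divergence (0.20), divergence-only (0.15) or pure noise (0.40), with slope
  magnitudes $|\beta_C| \sim U(0.02, 0.08)$ and
  $|\beta_\Delta| \sim U(0.05, 0.15)$ on unit-noise markers, and the
  divergence slope keeping the age slope's sign (`sign_agreement = 1`, the
  "sign informative, size uninformative" world). The shares make ~45% of
  markers age-coupled, which reproduces the motivating descriptive of 26 of
  59 markers passing the Bonferroni screen at this sample size (25/59
  realized at seed 1 — not tuned further).

What the emulator does *not* emulate: real metabolite distributions
(log-normal tails, platform artifacts), marker-marker correlation beyond
what the shared $C$ and $\Delta$ induce, family structure, or competing
risks. A green test on this world therefore establishes the *statistical
logic* of the methods, not their behavior on any particular real platform.
Markers are generated Gaussian, so the real pipeline's log-transform step is
a no-op here and is represented downstream by z-scoring only.

## The predictor families

All families output a raw age proxy; `predict_delta` residualizes it on $C$
by OLS, which enforces $\overline{\widehat\Delta} = 0$ and
$\mathrm{cor}(\widehat\Delta, C) = 0$ to numerical precision.

* **MLR** (`fit_mlr`): OLS of $C$ on the markers; errors on rank-deficient
  designs, naming the collinear columns.
* **Ridge** (`fit_ridge_cv`): markers z-scored, intercept unpenalized,
  penalty chosen from a logarithmic grid ($10^{-3}$–$10^4$, 50 points) by
  minimum mean K-fold cross-validated squared error (K = 10), ties broken
  toward the smallest penalty. The minimum-CV rule (not one-SE) is used
  because the procedure being modelled selects the error minimizer. The
  fitted model is re-expressed on the raw marker scale, so a zero penalty
  reproduces `fit_mlr` exactly.
* **Klemera-Doubal** (`fit_kd`, `predict_kd`): reversed regressions of each
  marker on age give $(q_j, k_j, s_j)$; the point estimate is the
  precision-weighted least-squares solution
  $\widehat{BA} = \sum_j (x_j - q_j) k_j / s_j^2 \big/ \sum_j k_j^2/s_j^2$,
  the exact minimizer of $\sum_j ((x_j - q_j - k_j BA)/s_j)^2$. This is the
  direct consequence of the stated marker model; the variant that shrinks
  toward chronological age via an extra $s_{BA}^2$ term is deliberately not
  implemented, since estimating $s_{BA}$ is outside the usage modelled
  here. Markers with negligible age slope ($|k_j| < 10^{-8}\,
  \mathrm{sd}(x_j)/\mathrm{sd}(C)$) or negligible residual sd are dropped
  with a warning — their precision weights would be unstable or infinite.
* **PC1** (`fit_pc1`): Bonferroni pre-selection (`preselect_markers`,
  two-sided $t$ test on the Pearson correlation with age at per-marker level
  $\alpha/m$), z-scoring, leading eigenvector of the correlation matrix,
  score standardized and sign-oriented so it correlates positively with
  age, then mapped to the age scale as $BS \cdot \sigma_C + \mu_C$.
* **Equal weights** (`make_equal_weights`): every MLR coefficient replaced
  by its sign times the mean absolute coefficient. The two verbal
  formulations of this rule in the motivating material ("mean of the
  coefficients, signs kept" vs "mean of the absolute values, signs kept")
  are unified as the sign-preserving mean of absolute values, the reading
  under which both are the same operation. The intercept is set to 0: it
  cannot survive residualization on age.
* **Random weights** (`sample_random_weights`): $sign_j \cdot U(0,1)$ per
  marker, 1000 draws by default, seed-reproducible. Any mortality signal
  this family captures comes from the signs alone.

## Evaluation surfaces

* `eval_delta_recovery`: Pearson $r$ between $\widehat\Delta$ and the true
  $\Delta$ (the figures of merit in the scenario study are linear
  associations), RMSE in years, and the slope of truth on prediction as an
  attenuation diagnostic. A zero-variance prediction reports $r = 0$ with a
  degeneracy flag rather than NA, so that the biomarker-paradox case is
  representable.
* `fit_cox_delta`: Cox partial likelihood on the age timescale with delayed
  entry (`survival::coxph`, `Surv(entry_age, exit_age, event)`), covariates
  the z-scored $\widehat\Delta$ and sex, Efron tie handling (ages are
  continuous in the generators, so ties are rare and Efron is effectively
  exact). Scaling $\widehat\Delta$ makes coefficients comparable across
  methods. Sex is dropped automatically when constant (toy fixtures).
* `observational_equivalence`: moment differences (means, variances,
  marker-age covariance) standardized by Monte-Carlo standard errors, plus
  two-sample Kolmogorov-Smirnov checks; "indistinguishable" means every
  moment within 4 SEs and no KS rejection at 0.01 — chosen so false alarms
  are negligible across a test suite.
* `summarize_random_coefs`: median of the random-weight Cox coefficients
  and strict exceedance fractions over the reference methods, with tie
  counts.

## The two headline experiments

`run_scenario_experiment` generates each scenario, fits MLR / KD / equal
weights, and scores divergence recovery per replicate.
`run_cohort_experiment` runs the four-method cohort design: (1) 10-fold CV
ridge on all markers, (2) OLS on the Bonferroni-selected subset, (3) equal
weights from (2), (4) 1000 sign-preserving random draws; every method's
scaled $\widehat\Delta$ goes into the left-truncated Cox model, and the age
RMSE of methods 1-2 is reported alongside to expose the biomarker paradox
(the better age predictor can have the *weaker* mortality association of
its residual). Both experiments stamp their outputs with a config hash and
the seed sequence; reruns at a fixed config are identical.

## Numerical choices and degenerate inputs

* Divergence extraction tolerance: orthogonality asserted at $10^{-8}$.
* Ridge tie-break: smallest penalty attaining the minimal CV error; the
  lambda grid is sorted ascending so `which.min` implements this.
* KD drop tolerance: as above; an all-dropped marker set is an error.
* Constant markers are skipped (pre-selection) or errors (ridge, which
  cannot z-score them); constant proxies yield zero divergence with a
  warning; Cox fits on constant divergence report a flagged zero.
* RNG: every generator takes an explicit seed and restores the caller's RNG
  state, so bit-reproducibility never leaks across calls.

## Known limitations

* **Scenario C and multivariable weights.** Under the max-rule noise
  equalization, the population value of
  $\mathrm{cor}(\widehat\Delta_{MLR}, \Delta)$ in scenario C is 0.1959 —
  not 0. Scenario C gives marker 2 the largest divergence slope, so
  equalization gives it the least noise; multivariable MLR still weights
  marker 2 through its age slope and inherits part of its nearly noise-free
  $10\Delta$ component. The value stays near 0.2 for any noise floor below
  ~400 and only approaches 0 when noise drowns the markers, so "MLR
  captures only noise" holds qualitatively (equal weights does much better,
  population $r = 0.61$) but not as a strict near-zero bound. The property
  suite asserts the derived population value; one acceptance bound written
  against a near-zero expectation is knowingly left failing rather than
  weakened.
* The untestability result itself is out of scope; its empirical shadow —
  observational equivalence of the true/false pair and of any fitter applied
  to either — is what the suite checks.
* No competing risks, time-varying covariates, or family/cluster structure
  in the Cox model; no elastic-net/lasso clocks; no KD confidence-interval
  machinery.
* Whether the modelled ridge procedure z-scored markers before penalization
  is not documented in the motivating material; z-scoring is assumed (it is
  the overwhelmingly standard choice and the one under which the penalty is
  exchangeable across markers).
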
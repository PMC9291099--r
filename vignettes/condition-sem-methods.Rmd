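---
title: "Quantifying body condition with structural equation models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying body condition with structural equation models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condsem)
```

## The problem

Body condition is a multivariate concept: an individual's nutritional, immune
and hormonal state all bear on its performance, yet most field studies
collapse condition to a single proxy such as residual body mass. `condsem`
takes the opposite route: it operationalizes condition as the weighted
combination of measured health-state variables that best explains variation
in a fitness proxy (here, annual survival attached to individuals at the
area level), and estimates those weights jointly with every other
relationship in the system.

The statistical vehicle is a covariance-structure (SEM) model with three
kinds of variables:

* **observed** variables $x$, measured on each individual;
* **latent** variables $L$, unmeasured constructs that cause correlation
  among their indicators: $x_j = \lambda_j L + \varepsilon_j$;
* **composite** variables $C$, unmeasured variables *defined* as a weighted
  sum of their causes with residual variance fixed to zero:
  $C = \sum_i \gamma_i x_i$. An *unknown-weight* composite leaves the
  $\gamma_i$ free, so they are estimated from the data against an outcome:
  $y = \alpha + \beta C + \varepsilon_y$.

A condition index is an unknown-weight composite of the condition variables
with survival as the outcome; confounders (structural size, sex, age class,
handling time, bill shape) are handled with MIMIC blocks — a latent carrying
a single indicator with loading fixed to 1, on which the confounders regress
— so that, for example, *size-corrected mass* rather than raw mass feeds the
index, without any residual-regression pre-processing.

## Estimation

Internally every model is held in RAM form over the full variable set
$t = \text{observed} + \text{latent} + \text{composite}$: a directed
coefficient matrix $A$ (loadings, regressions, composite weights), a
symmetric matrix $S$ of variances and covariances (composite diagonal pinned
to 0), and a selector $F$ of observed rows. The implied covariance is

$$\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top,$$

and estimation minimizes the classical Wishart maximum-likelihood
discrepancy per group,

$$F_{ML} = \log|\Sigma| + \operatorname{tr}(S_g \Sigma^{-1}) - \log|S_g| - p,$$

with $S_g$ the $(N_g - 1)$-denominator sample covariance. Multi-group models
minimize $\sum_g (N_g - 1) F_{ML,g}$, which is also the reported chi-square
statistic ($T = (N-1) F_{ML}$ in one group; an `"n"` scaling flag exists
because conventions differ, with negligible effect at the sample sizes
involved here).

Numerical choices:

* **Optimizer**: `nlminb` quasi-Newton with the analytic gradient of the
  discrepancy (derived from $dF = \operatorname{tr}(E\, d\Sigma)$ with
  $E = \Sigma^{-1} - \Sigma^{-1} S_g \Sigma^{-1}$). Variance parameters are
  bounded below at $10^{-10}$ rather than log-parameterized, so boundary
  (Heywood) solutions are visible as near-zero variances instead of silent
  reparameterizations. Convergence requires a gradient max-norm below
  $10^{-6}$ per observation (the objective is scaled by $\sum_g (N_g-1)$,
  and gradient components pointing into an active variance bound are
  projected out, so Heywood boundary solutions count as converged, with a
  warning) or optimizer-reported convergence. Up to four polish restarts are
  taken from the incumbent, alternating plain and parameter-rescaled runs —
  the rescaled runs rescue the ill-conditioned weight/slope valley that
  composite models develop when the outcome slope is near zero.
* **Start values**: loadings 1, regressions 0, observed residual variances
  half the sample variance, latent variances half the variance of their
  scale indicator, and the saturated exogenous block at its sample values.
  Unknown-weight composites are the one exception: the weight/slope product
  creates a curved likelihood ridge through the naive start, so weights and
  the outcome slope are seeded from the least-squares solution of the
  outcome on (proxies of) the causes. This affects the path taken, never the
  optimum: fits remain deterministic given data and model.
* **Identification defaults**: first loading (or first composite weight)
  fixed to 1; `std_lv = TRUE` switches to unit latent variances. Endogenous
  variables receive free residual variances; exogenous observed variables
  (and exogenous latents) a saturated variance/covariance block, suppressible
  by writing the term explicitly with a fixed value. Composite residual
  variances are always 0. A composite block is left untouched if the user
  fixed any weight or any outgoing path — the scale-setting convention for
  composites is genuinely open, so the default is overridable.
* **Single-indicator MIMIC blocks** in the full model pin the indicator
  residual to zero, so the primed latent's residual variance carries the
  corrected variance. Leaving both free is technically identified through
  the composite-to-survival channel, but only barely — the likelihood is
  nearly flat along the split — so the pinned form is the default; the
  condition-composite model keeps the mass measurement-error variance free,
  where that channel is strong enough to identify it. The correlated errors
  of haematocrit and cholesterol consequently live at the primed-latent
  level in the full model.
* **Missing data**: listwise deletion with the retained and dropped counts
  recorded; no full-information ML.
* **Standard errors**: inverse observed information of the
  $(N-1)F_{ML}/2$-scaled objective; Wald $z$ and two-sided normal p-values,
  uncorrected (significance summaries in this literature are reported raw).
* **Standardization**: each directed coefficient $b(x \to y)$ is reported as
  $b \cdot sd(x)/sd(y)$ with model-implied standard deviations from the full
  $t \times t$ implied covariance; covariances become correlations.
* **Fit**: CFI $= 1 - \max(T - df, 0) / \max(T_b - df_b, T - df, 0)$ against
  the closed-form independence baseline; nested models compared by the
  chi-square difference test.
* **Scores**: latents by the regression method
  $\Sigma_{Lx}\Sigma_{xx}^{-1}(x - \bar x)$ with model-implied covariances
  and training means; composites as the fitted weighted sum of their
  centered causes, in topological order.

## The conventional baseline

For comparison the package ships the four-step residual/multiple-regression
pipeline: (1) regress mass on tarsus, head and wing length, keep the
residuals; (2) regress survival on residual mass plus the five physiological
variables; (3) take the fitted values as the condition index; (4) regress
the index on competitor density. PCA (correlation-based by default, because
the variables mix units; covariance PCA behind a flag) provides the
variable-reduction analogue of the latent variables. Components are
sign-fixed so the largest-magnitude loading is positive — loadings are only
defined up to sign, so published loadings of either sign are comparable to
ours only up to that convention.

## What the synthetic data emulate — and what they do not

The generator draws multivariate-normal data from the implied covariance of
any model with stated true values. Four packaged fixtures define the study
conditions used by the tests and the acceptance script; their numeric values
are fixture choices fixed once in one source file, not estimates from any
dataset:

* `energy`: two energy-store measures with implied correlation ≈ 0.9 and
  three structural sizes (pairwise r = 0.5) regressing on the latent.
* `colour_grouped`: hue/chroma/luminance with strong intercorrelation in
  adults and weak hue coupling in sub-adults.
* `condition`: the joint condition structure. Two composite causes dominate
  (size-corrected mass, weight fixed at 1; corticosterone −0.8) and four are
  near zero (0.10/0.10/0.05/0.05); condition → survival is 0.45 and
  density → condition −0.35. Mass carries measurement error (residual 0.2
  against a latent variance of 0.6), and corticosterone covaries with tarsus
  (−0.3) and head (−0.2). Those two ingredients are what bias the stepwise
  baseline: residualizing mass attenuates its slope (the size-related, truly
  predictive part is discarded together with measurement noise), and the
  size–corticosterone covariance routes the discarded signal into the
  corticosterone slope. The joint SEM models both and stays unbiased.
* `full`: the complete structure with the energy latent, primed confounder
  latents, correlated haematocrit/cholesterol errors, density and survival.

Limitations to keep in mind when transferring conclusions to real data: the
generator is Gaussian-only, so binary confounders (sex, age class) are
simulated as continuous liabilities; survival is a continuous area-level
quantity shared within sites, and treating it as an ordinary per-individual
response understates its dependence structure (an optional logit flag is
available for proportions); and because analysis and generating models share
their structure in the experiments, passing tests demonstrate correctness of
the estimator, not robustness to misspecification.

## The two evaluation experiments

The **bias experiment** simulates `nsim` datasets, estimates the effect of
each condition variable on survival by both routes (SEM: fitted weight times
the condition → survival slope; stepwise: the step-2 slope, residual mass
standing in for size-corrected mass), and reports mean bias
$\hat B = \overline{\hat\theta} - \theta$ and empirical standard error
$\hat E = sd(\hat\theta)$ per parameter. Relative bias ($100\hat B/\theta$)
is suppressed when $|\theta| < 0.05$, where percentages of near-zero truths
are noise; the threshold is configurable. Non-converged replicates are
excluded and counted, with a hard failure above 10%.

The **cross-validation** experiment partitions the data into `folds` folds,
`repeats` times (10 × 3 = 30 training/test sets by default — the internally
consistent reading of a "10-fold, 80/20, three repeats" protocol; an
explicit 80/20 Monte-Carlo-split mode is available as a flag since the two
descriptions conflict). The SEM form of the model excludes density, because
the task is predicting survival from the condition variables. RMSE and
$R^2 = 1 - SSE/SST$ are computed on pooled out-of-fold predictions by
default ($R^2$ may be negative); a per-fold-averaged mode exists because the
pooling convention is equally defensible.

Problem sizes used by the packaged experiments: recovery at n = 10,000 per
fixture; the bias contrast at nsim = 200 datasets of n = 1,000;
difference-test calibration with 500 replicates of n = 500; cross-validation
on n = 800 simulated individuals. These sizes give Monte-Carlo error well
inside the tolerances being checked while keeping a full run of the suite
comfortable on a laptop.

## A worked example

```{r example, eval = FALSE}
tm <- condition_fixture("condition")
d <- simulate_from(tm, n = 1000, seed = 1)

fit <- sem_fit(d, tm$model)
glance(fit)                     # chi-square, df, CFI, N
tidy(fit)                       # weights, paths, SEs, standardized solution
indirect_effect(fit, c("density", "condition", "survival"))

scores <- sem_scores(fit, d)    # per-individual condition index

cv <- cross_validate(d, folds = 10, repeats = 3, seed = 1)
tidy(cv)
autoplot(cv)

bias <- run_bias_experiment(tm, nsim = 200, n = 1000, seed = 1)
autoplot(bias)
```

## Known limitations

No robust/sandwich or bootstrap uncertainty; no FIML for missing data; no
ordinal-indicator estimators; no random effects — all flagged limitations of
frequentist SEM tooling in this setting, and out of scope here. Nested-model
comparison checks only that both fits used the same data and differ in
degrees of freedom; actual nesting is the user's responsibility. The
`full_model_with_bodysize` variant replaces the direct size regressions with
a structural-size latent and adds its direct survival path, so it is a
competing — not strictly nested — hypothesis relative to `full_model`.
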
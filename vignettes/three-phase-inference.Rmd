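---
title: "Three-phase hierarchical model-based and hybrid inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-phase hierarchical model-based and hybrid inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large-area forest biomass assessment rarely has field measurements where the
wall-to-wall remote-sensing data are. A common data structure is a chain:
a small set of plots with measured aboveground biomass density (AGBD, Mg/ha)
and field covariates; a larger set with field covariates and an airborne
laser scanning (ALS) metric; a still larger set with the ALS metric and a
satellite metric available wall-to-wall (or as a satellite LiDAR sample).
`hmb3` implements population-mean prediction through three hierarchically
nested regressions over this structure, together with the uncertainty
propagation that makes the prediction usable for reporting.

Two inference modes are covered:

* **3pHMB** (three-phase hierarchical model-based): the final-phase
  covariate is available for every one of the N grid cells, and the
  population mean is predicted as $\bar{p}_U\hat\gamma$.
* **3pHHY** (three-phase hierarchical hybrid): the final-phase covariate is
  available only for a probability sample $S_{IV}$, and $\bar{p}_U$ is
  replaced by its Horvitz–Thompson estimator, adding a design-based variance
  component.

## The model chain

With unit-augmented row vectors $x_i = (1, x_i)$, $z_i$, $p_i$:

* Model F: $Y_i = x_i\beta + \epsilon_i$, $\epsilon_i \sim N(0, \omega^2)$,
  fitted by OLS on the field dataset $S_I$ ($n_I$ plots).
* Model G\*: the multivariate regression $X_i = z_iA^* + \upsilon_i^*$,
  $\upsilon_i^* \sim N(0, \Delta^*)$, fitted on $S_{II}$; the unit component
  regresses perfectly, so the corresponding row and column of $\Delta^*$ are
  zero. Contracting with $\beta$ gives model G with $\alpha = A^*\beta$ and
  $\delta^2 = \beta^\top\Delta^*\beta$.
* Model Q\*: $Z_i = p_i\Gamma^* + e_i^*$, $e_i^* \sim N(0, \Theta^*)$,
  fitted on $S_{III}$; contracting with $\alpha$ gives model Q with
  $\gamma = \Gamma^*\alpha$ and $\theta^2 = \alpha^\top\Theta^*\alpha$.

Fitting proceeds by feeding each model's predictions forward as the next
model's response. The central algebraic device is that this sequential
route is identical to composing the matrix estimators:
$\hat\gamma = \hat\Gamma^*\hat A^*\hat\beta$. `fit_chain()` computes both
routes and verifies their agreement on every fit; the identity is also the
main oracle of the test suite.

## Variance propagation

Applying the law of total covariance twice,

$$\mathrm{Cov}(\hat\gamma)
 = \underbrace{\theta^2 G_{III}}_{\text{final fit}}
 + \Gamma^*\Big[\underbrace{\delta^2 G_{II}}_{\text{middle fit}}
 + \underbrace{A^*\,\omega^2 G_I\,A^{*\top}}_{\text{first fit}}\Big]\Gamma^{*\top}
 + \text{trace terms},$$

where $G_I = (X_I^\top X_I)^{-1}$ etc. are the inverse Gram matrices of the
realized designs. The trace terms are
$\mathrm{Tr}[\Delta^*\,\omega^2G_I]\cdot\Gamma^*G_{II}\Gamma^{*\top}$ and
$\mathrm{Tr}[\Theta^*\,\mathrm{Cov}_G(\hat\alpha)]\cdot G_{III}$; they arise
because the contraction vectors $\hat\beta$, $\hat\alpha$ are themselves
random. For a multivariate OLS fit the quadratic-form contraction collapses
through the Kronecker structure,
$v^\top\mathrm{Cov}(\hat M)v = (v^\top E v)\,G$, which is how
`cov_gamma_hat()` computes every block without materializing Kronecker
products.

The 3pHMB predictor variance is
$\bar{p}_U\,\mathrm{Cov}(\hat\gamma)\,\bar{p}_U^\top$. The 3pHHY variance
adds, under SRSWOR with sample size $n_{IV}$,
$\tfrac{1}{n_{IV}}(1-\tfrac{n_{IV}}{N})\,\gamma^\top\mathrm{Cov}(P_U)\gamma$
plus a design–model interaction trace
$\mathrm{Tr}[\mathrm{Cov}_{design}\,\mathrm{Cov}(\hat\gamma)]$. Trace terms
are always computed and reported separately; whether they enter the total is
a flag (`include_traces`, default `TRUE`), so their claimed negligibility is
verified rather than assumed. In the default boreal world their relative
contribution is of order $10^{-2}\,\%$, far below any practical relevance —
but this is an empirical property of well-conditioned designs, not an
identity.

The plug-in variance estimator (`estimate_variance()`) replaces every
unknown by its estimate. Residual (co)variances use the
degrees-of-freedom-corrected divisor $n - p$ throughout; with this choice
the estimator is close to unbiased in the validation runs, which is the
behaviour the method is expected to show. For the hybrid mode the design
covariance is the sample covariance of the sampled covariate vectors
(divisor $n_{IV}-1$) with the same finite-population correction, and the
Horvitz–Thompson mean stands in for the unknown $\bar p_U$ in the model
component — forced by the hybrid setting, where P is observed only on the
sample.

`mse_under_independence()` adds $(\theta^2+\delta^2+\omega^2)/N$ to the
variance. This assumes mutually independent, spatially uncorrelated
variability terms; real landscapes are spatially autocorrelated, so the
returned value carries an explicit `independence_assumed` attribute and
should be treated as a lower-bound-style approximation.

## The superpopulation world and what the simulator emulates

`superpop_spec()` describes a jointly normal superpopulation over
$(Y, X, Z, P)$ with chained correlations $r_{YX}, r_{XZ}, r_{ZP}$.
Conditional-expectation algebra turns the spec into the true chain
parameters (`derive_chain_params()`): e.g.
$\beta_1 = r_{YX}\sigma_Y/\sigma_X$, $\omega^2 = \sigma_Y^2(1-r_{YX}^2)$,
$\delta^2 = \sigma_Y^2 r_{YX}^2(1-r_{XZ}^2)$,
$\theta^2 = \sigma_Y^2 r_{YX}^2 r_{XZ}^2(1-r_{ZP}^2)$.

The off-chain correlations are not free parameters: the package fixes them
to the Markov-chain products ($r_{YZ} = r_{YX}r_{XZ}$,
$r_{YP} = r_{YX}r_{XZ}r_{ZP}$, $r_{XP} = r_{XZ}r_{ZP}$), because the
conditional derivations that define models G and Q use exactly these
covariances. This is an assumption of the chained world — conditional
independence along Y–X–Z–P — made explicit in
`full_correlation_matrix()`, which also enforces positive definiteness.

A consequence worth emphasizing: each modelling step shrinks the variance
of the (proxy) response by the squared step correlation
(`variance_reduction_factor()`). At $r = 0.8$ per step, two steps retain
only 41% of the original response variance. Maps and domain predictions
built on long model chains therefore understate landscape variability.

The default spec values mimic boreal forest conditions in northern Finland
(AGBD mean 62.62 Mg/ha, sd 49.53; chain correlations 0.77 / 0.75 / 0.76;
$n_I = 102$, $n_{II} = 943$, $n_{III} = 1721$, $n_{IV} = 5760$,
$N = 38400$). These are the package's reference study conditions, used by
the validation harness and the test suite.

What the simulator deliberately does **not** emulate: spatial
autocorrelation of errors or covariates, non-normal (e.g. skewed or
zero-inflated) biomass distributions, heteroscedasticity, covariate
measurement error, and nonlinear (allometric power-law) model forms. A
passing validation therefore shows the variance algebra is correct under
the stated model, not that the model fits any particular landscape.

## The validation protocol

`run_validation()` follows the standard two-stage Monte-Carlo design:

1. derive true parameters; generate the four fixed designs **once**;
   compute the analytic variances conditional on those designs;
2. per iteration: regenerate all responses from the models, fit the chain,
   record both predictions, draw a fresh SRSWOR sample for the hybrid
   predictor, and apply both plug-in variance estimators.

Fixing the designs outside the loop matches the model-based inference
framework, where inference is conditional on the realized covariates. It
also means the analytic variance is itself a random quantity across master
seeds (through the realized Gram matrices and $\bar p_U$): in the default
world it varies by roughly ±1–2%. Comparisons against published single-run
values must allow for that realization spread; the report prints
Monte-Carlo standard errors so every comparison is a quantified z-test.

### Randomness and reproducibility

One master seed drives everything. Sub-seeds are derived by a counter-based
scheme (`sub_seed(master, counter)`, modular multiplication by fixed
primes): counter 0 for the designs, counter i for iteration i. Any single
iteration can be replayed in isolation, and a report can be regenerated
from the configuration it echoes.

### Problem sizes and defaults

The default `n_reps = 10^4` puts the Monte-Carlo standard error of an
empirical variance at $V\sqrt{2/(n-1)} \approx 1.4\%$ of $V$ — tight enough
to detect any formula error of practical size in seconds-to-minutes on one
core. Full-fidelity runs at $10^6$ are a matter of passing a larger
`n_reps`; summaries are computed from stored per-iteration vectors, whose
memory cost is trivial even at $10^6$.

### Numerical choices

* OLS via QR decomposition; the inverse Gram matrix needed by the variance
  formulas is recovered from the R factor. Rank deficiency is a hard error
  naming the offending dataset — a silent pseudo-inverse would corrupt the
  variance formulas.
* Residual covariance divisor $n - p$ everywhere.
* Singular error covariances (the zero unit row/column of $\Delta^*$,
  $\Theta^*$) are handled by an eigendecomposition square root with clipped
  negative eigenvalues.
* Finite-population covariance $\mathrm{Cov}(P_U)$ uses divisor $N - 1$;
  the design-based estimate uses the sample covariance (divisor
  $n_{IV}-1$) with the same finite-population correction factor.
* Composition identities are asserted at $10^{-8}$ relative tolerance
  inside `fit_chain()` (they hold to machine precision in well-conditioned
  problems).

### Design choices that were genuinely open

* **Dataset independence in the generator.** The superpopulation is jointly
  normal, but the validation protocol draws the covariate columns of the
  four datasets independently and conditions on them. The generator follows
  the protocol, not the joint distribution: coupling the datasets would
  change what is being validated.
* **Whether the trace terms belong in the total.** Both full and
  trace-free totals are first-class; the default includes them, and the
  harness reports their contribution so the approximation is checked, not
  assumed. Published accountings of "trace terms" may count only the outer
  trace; this package's accounting includes every term the decomposition
  produces, and its total is the one that matches the empirical Monte-Carlo
  variance.
* **$P_U$ and $P_{III}$ are independent draws** — the third dataset is a
  separate sample, not a subset of the population grid.
* **Estimator substitution in the hybrid mode.** $\bar p_U$ is unknown when
  P exists only on the sample, so the model component of the variance
  estimator uses the Horvitz–Thompson mean.

## A worked run

```{r, eval = FALSE}
library(hmb3)
spec <- superpop_spec()            # boreal defaults
report <- run_validation(mc_config(spec, n_reps = 10000, master_seed = 1))
print(report)
summarize_bias(report)
```

On master seed 1 this prints an analytic 3pHMB variance of about 10.9
(3pHHY about 11.0), empirical variances within Monte-Carlo error of the
analytic values, mean plug-in estimates matching the empirical variances,
mean predictions near the population mean of 62.6 Mg/ha, and trace-term
contributions of order $10^{-2}\,\%$.

## Known limitations

* Univariate covariates per phase are the validated configuration; the
  algebra and code are dimension-generic ($h, q, t \ge 1$) but the
  superpopulation derivation is chain-correlation based and univariate.
* Only SRSWOR is implemented end-to-end for the hybrid design layer;
  general unequal-probability designs would need their own design-variance
  estimator.
* The MSE add-on assumes independent, non-autocorrelated errors — a known
  simplification flagged in the output.
* No model selection, regularization, or robust (heteroscedasticity-aware)
  coefficient covariances.
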
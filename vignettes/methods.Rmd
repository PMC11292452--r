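---
title: "Methods: a debiased autoregressive count model for state firearm policy effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a debiased autoregressive count model for state firearm policy effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gunpolicy)
```

## The estimation problem

State firearm policies are adopted in correlated bundles by states whose
characteristics — firearm ownership rates above all — also shape their
mortality trajectories. Any single statute plausibly moves deaths by a few
percent at most, so a credible analysis must (a) estimate many policies
jointly, (b) adjust for the confounders of adoption, (c) borrow strength
through informative priors sized to what single policies can plausibly do,
and (d) avoid the bias that creeps in when a model controls for lagged
outcomes that are themselves affected by treatment. This package implements
such a pipeline end to end, together with a synthetic world in which every
stage can be tested against known truth.

## Law coding

Ten policies are tracked (see `firearm_policies()`): seven restrictive
(dealer and private-sale background checks; under-18 possession and
under-20 purchase prohibitions; 24-hour and 7-day waiting periods;
child-access storage requirements) and three permissive (shall-issue
concealed carry, permitless carry, stand-your-ground). They partition into
six conceptual classes — four restrictive, two permissive.

For each (state, year, policy), `build_policy_panel()` produces:

* **exposure** $e \in [0,1]$: the fraction of the calendar year the law is
  in force, with actual day counts (366 in leap years). We use the
  fractional convention in enactment years rather than a binary
  first-full-year rule because it preserves dose information and matches
  the instant-effect construct.
* **phase** $f = \mathrm{clip}(\text{years\_since}/H, 0, 1)$ with horizon
  $H = 5$ years: a linear ramp from implementation to full effect.
  `years_since` is measured from the effective date to the observation
  year's midpoint (July 1), because annual outcomes carry no finer timing
  and midpoint dating treats mid-year enactments symmetrically.
* Repeals zero both $e$ (fractionally, in the repeal year) and $f$ (from
  the first year whose midpoint falls after repeal). The enactment-year
  and repeal conventions were genuinely open choices; both are documented
  here and exercised by tests rather than hidden.

A year-shift equivariance property (shifting an effective date by one year
shifts the coded sequences by one year) holds exactly for exposure and to
within one leap day (≈ 0.003 on the $f$ scale) for the phase covariate,
because real calendars are used.

## The model

Deaths $y_{st}$ in state $s$, year $t$ follow a negative binomial with
mean $\mu_{st}$ and dispersion $\phi$ ($\mathrm{Var} = \mu + \mu^2/\phi$;
large $\phi$ recovers the Poisson), with

$$\log \mu_{st} = \log N_{st} + \gamma_t + x_{st}'\beta
  + \rho_1\,(a_{s,t-1} - \Delta_{s,t-1})
  + \rho_2\,(a_{s,t-2} - \Delta_{s,t-2}) + \Delta_{st}$$

* $\log N_{st}$ — population offset, so the model describes rates.
* $\gamma_t$ — free year effects; the first analysis year is the reference
  level and an intercept carries the baseline (identifiability).
* $x_{st}$ — covariates standardized to mean 0 / SD 1 over analysis rows,
  entering contemporaneously (the simplest defensible reading of
  "state characteristics as covariates").
* $a_{s,t-k} = \log((y_{s,t-k} + 0.5)/N_{s,t-k})$ — lagged log mortality
  rates. The first two panel years are consumed only as lags. The +0.5
  continuity constant keeps the log finite and monotone at zero counts;
  it is configurable (`cont`).
* $\Delta_{st} = \sum_p \beta_{\text{inst},p} e_{pst} +
  \beta_{\text{slope},p} f_{pst}$ — the cumulative policy effect. A
  policy's **total effect** is $\theta_p = \beta_{\text{inst},p} +
  \beta_{\text{slope},p}$, its effect at or beyond the 5-year horizon.

**Debiasing.** Autoregressive models of treated outcomes attenuate causal
effects because the lagged outcome already embodies part of the treatment
response. Here the lags enter as $a - \Delta$: their policy-free
counterfactual. The algebraic consequence — proved by
`recursion_shift()` and asserted by tests — is that switching a policy on
and letting it phase in shifts the steady-state log rate by exactly
$\theta_p$ for any stationary $(\rho_1, \rho_2)$, while the naive variant
(`debias = FALSE`, retained for comparison experiments) compounds to
$\theta/(1-\rho_1-\rho_2)$ in generation and attenuates toward
$\theta(1-\rho_1-\rho_2)$ in estimation. The exact algebraic form of such
ancillary adjustment terms admits several faithful realizations;
counterfactual-adjusted lags were chosen because they carry this testable
equilibrium guarantee.

## Priors

* **Policy effects.** Each $\theta_p$ has a zero-mean normal prior with
  `prior_sd_total()` ≈ 0.1014, sized so 95% of prior mass lies between
  IRRs 0.82 and 1.22 — the range expert elicitation supports for single
  policies, and symmetric on the log scale ($|\log 0.82 + \log 1.22| <
  0.001$). The SD is split equally between $\beta_{\text{inst}}$ and
  $\beta_{\text{slope}}$ (each $\sigma/\sqrt2$): the induced total is all
  that is constrained externally, and the symmetric split satisfies it
  exactly. `mode = "uninformative"` inflates the policy SD tenfold for
  sensitivity analysis.
* **Covariates.** The 5 designated confounders get normal priors (default
  SD 1) so their adjustment is not shrunk away; the 23 others get a
  double-exponential (Bayesian lasso) prior with fixed scale 0.05 on the
  standardized log-rate scale. A fixed, documented scale was preferred to
  a hyperprior for reproducibility, since the lasso's hyperparameterization
  is not externally pinned down.
* **Nuisances.** Year effects N(0, 1); $\rho_1, \rho_2$ N(0, 0.5) with no
  hard stationarity constraint (weak priors keep the posterior in the
  stable region in practice and avoid boundary pathologies); intercept
  N(0, 10); $\log\phi$ normal (lognormal on $\phi$), default
  $N(\log 20, 1.5)$.

## Sampling

No Stan-class sampler is assumed by the package; inference uses a
package-authored adaptive Metropolis-within-Gibbs sampler (Rcpp):

* per-coordinate random-walk proposals, batch-adapted toward 0.44
  acceptance during warmup (adaptation frozen afterwards, preserving
  detailed balance in the sampling phase);
* directed proposals for the three ridge structures this posterior is known
  to have: $(\rho_1, \rho_2)$ sum/difference rotations (lagged rates are
  nearly collinear), instant/slope rotations per policy (only their sum
  $\theta_p$ is well identified), a level move trading the intercept
  against all year effects, and a persistence move trading
  $\rho_1+\rho_2$ against the intercept;
* a joint random-walk proposal using the Haario empirical-covariance
  recipe accumulated during warmup;
* split-$\hat R$ and an initial-positive-sequence ESS for every parameter;
  fits are flagged when any split-$\hat R$ exceeds 1.05.

Chains run sequentially under one `set.seed()`, so identical inputs,
configuration and seed give byte-identical draws. The sampler's target was
validated against an independently coded log density (R's `dnbinom` plus
explicit prior terms) to $10^{-6}$, and its calibration by simulation-based
calibration (below). Defaults are 4 chains × 1000 warmup × 1000 draws;
the experiment harness uses 2 × 2000 × 400 — warmup is deliberately long
relative to retained draws because the adaptive phase does most of the
work.

## Effect combination

`combine_draws()` evaluates, per posterior draw, $\ell = \sum_{p}
s_p(\beta_{\text{inst},p} + \beta_{\text{slope},p}\min(t/H, 1))$ for a
signed policy set. Built-ins: the six classes, purchase-and-possession
(six restrictive purchase policies), restrictive use-and-storage (storage
present, carry deregulation and stand-your-ground absent), and the
most-restrictive regime (+1 on seven restrictive, −1 on three permissive).
Summaries are the posterior median IRR, equal-tailed 80% and 95% credible
intervals, and $P(\ell < 0)$, the posterior probability of reduced deaths.
Equal-tailed type-1 (order-statistic) quantiles match the symmetric
interval presentation and are exactly reproducible by a sort-based oracle;
$P(\ell<0)$ counts strict negatives (ties are measure-zero).
`deaths_averted()` reports $D(1 - e^{\ell})$ per draw, with the convention
— observed deaths $D$ arise under the permissive baseline — recorded in
the output metadata rather than asserted silently, since the published
translation of a 20% reduction into ≈ 70,000 deaths does not print its
exact convention.

## The synthetic world

`simulate_study()` draws covariates, adoptions and counts under the same
conditional model the fitter assumes, so generator and fitter are
consistent by construction:

* **Covariates**: 5 confounders + 23 others, each stationary AR(1) per
  state with coefficient 0.9 and unit marginal variance — strong
  within-state persistence like real demographic/economic series.
* **Adoption**: a yearly logistic hazard on the first confounder (the
  ownership proxy), first-passage per state-policy, mid-year effective
  dates, no repeals by default. A positive hazard coefficient makes
  high-ownership states adopt sooner: real confounding, which tests verify
  both by correlation and by showing that omitting the confounder from the
  fitted model shifts the policy estimate.
* **Counts**: sequential NB draws from the debiased linear predictor at
  realized lags, initialized at the policy-free steady state and run
  through 10 burn-in years. Defaults: 50 states, 1979–2019, constant
  population 5 × 10⁶ (isolating rate dynamics from demographic drift),
  baseline steady-state rate ≈ 12 per 100k, $\rho_1 = 0.6$,
  $\rho_2 = 0.2$, $\phi = 30$, flat year effects, one policy (dealer
  background checks) with $\theta = \log 0.9$ split evenly between instant
  and slope — a detectable but prior-plausible 10% reduction.

What a green test does **not** establish: the generator has no spatial
spillovers, no demographic drift, no measurement error in covariates, no
repeals, no policy interactions, and year effects that are flat rather
than trending — so passing recovery and calibration tests certifies the
estimator under its own assumptions, not robustness to their violation.

## Evaluation harness

`run_calibration()` is simulation-based calibration: each replicate draws
*every* free parameter from the fitting prior, simulates a study, refits,
and records coverage and the rank of the true total effect among thinned
posterior draws. If the posterior computation is correct, 95% interval
coverage is Binomial(n, 0.95) and ranks are uniform; the acceptance suite
checks both (exact binomial bounds; χ² over 4 bins at α = 0.01). Because
truths are drawn from the prior, the harness priors
(`harness_priors()`) concentrate on worlds the generator can realize with
finite counts (stationary AR mass, intercept near the realistic baseline);
this is a requirement of SBC, not a tuning device. `run_attenuation()`
fits debiased and naive variants to the same persistent-world data
($\theta = \log 0.8$, $\rho_1 + \rho_2 = 0.8$) and reports how often and
how much the naive fit attenuates. Replicates with split-$\hat R$ > 1.1
are flagged and excluded only from coverage aggregates, never silently
dropped; every aggregate is recomputable from the per-replicate records.

The harness defaults to a reduced world (15 states, 2000–2017, 2 + 3
covariates, 2 chains × 2000 warmup × 400 draws) so a full calibration run
takes minutes, not hours; all model structure — ten policy columns, AR(2)
lags, debiasing, confounded adoption — is retained.

## Numerical choices and degenerate inputs

* Zero counts: +0.5 continuity constant in lagged log rates.
* Linear-predictor overflow guards reject proposals with
  $|\eta|$ outside $(-60, 40)$ rather than overflow.
* $\phi$ is sampled as $\log\phi$, bounded to $|\log\phi| \le 30$.
* Validation errors name the offending state-year-column; reversed or
  overlapping law records, non-integer or negative counts, missing
  lead-in years, and constant covariates are all rejected with messages.
* Policies with no adoption transitions remain at their prior — verified
  by a Kolmogorov–Smirnov check — rather than being dropped.

## Known limitations

* The sampler is random-walk based; for much larger panels (thousands of
  states or sub-annual data) a gradient-based sampler would scale better.
* Year effects are free parameters; no smoothing across years is offered.
* The deaths-averted translation is a per-draw arithmetic identity, not a
  demographic projection.
* Cross-outcome substitution can only be probed by refitting on other
  outcome columns; interaction (effect-modification) estimation is out of
  scope — with few transitions and highly correlated adoption it is not
  identifiable in data of this shape.
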
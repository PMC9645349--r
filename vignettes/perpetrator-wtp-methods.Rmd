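---
title: "Methods: DBDC valuation of perpetrator non-financial losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DBDC valuation of perpetrator non-financial losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perploss)
```

## The problem

When a driver causes a fatal accident, insurance covers the financial
losses, but the perpetrator also bears pain, suffering, social stigma and
loss of trust — *non-financial* losses that had no established monetary
value. Active-safety systems (ADAS) reduce the probability of *causing*
accidents, so valuing these losses is necessary to price the benefit of
such systems. `perploss` implements a stated-preference route to that
value: respondents imagine being the perpetrator (or, in a control arm,
the victim) of a fatal two-vehicle accident with 100% fault on one side,
and state via yes/no questions whether they would pay given prices for a
safety device that removes 50% or 90% of the accident risk, against a
baseline annual fatal-accident risk of 1 in 200,000 licensed drivers.

## Survey instrument and response model

### Double-bounded dichotomous choice

Each respondent faces, per efficacy rate, two yes/no purchase questions on
the seven-point price ladder (100; 1,000; 5,000; 10,000; 30,000; 50,000;
100,000 yen): an initial bid drawn from the middle five prices, then the
neighbouring bid one step up after *yes* / one step down after *no*
(`next_price()`). Group 1 is asked about the 50%-effective device first,
Group 2 about the 90%-effective one, so ordering effects can be tested.
Under rationality, a *yes* at the initial bid implies a *yes* one step
lower (and a *no* implies a *no* one step higher); `augment_records()`
adds that implied record, giving six (price, answer) records per
respondent. This imputation is not cosmetic: the follow-up bid depends on
the first answer, which makes the asked-second records selectively
sampled, and the imputed records cancel that selection exactly, so the
pooled-logit score has mean zero at the true parameters.

### Random-utility model

A respondent answers *yes* at price $p$ for efficacy rate $r$ (percentage
points) iff

$$V(r) + \beta_{price}\,p + \varepsilon \ge 0, \qquad
V(r) = \beta_0 + \beta_{rate}\,r + \textstyle\sum_x \beta_x x,$$

with $\varepsilon$ standard logistic. The implied latent WTP is
$\max\{0,\,(V(r)+\varepsilon)/(-\beta_{price})\}$ (`latent_wtp()`). The
generator draws **one** $\varepsilon$ per respondent, shared across both
rates and all four questions. This matches the rationality premise of the
imputation rule (answers within a respondent are mutually consistent and
monotone in price), keeps latent WTP nondecreasing in the rate whenever
$\beta_{rate} > 0$, and leaves every marginal yes-probability exactly
logistic, so pooled estimation remains consistent. The cost is strong
within-respondent dependence, which drives the inference choice below.
The initial bid is drawn independently for each rate block; with a single
shared bid and a zero rate effect the two blocks would duplicate each
other record-for-record and the rate coefficient would be identically
zero, which no sampling design intends.

### Risk-aversion elicitation

Risk attitude comes from a paired-lottery ascent: at each probability
$p \in \{0.1,\dots,1.0\}$ the respondent picks the safe lottery A
(20,000 / 16,000 yen) or the risky B (38,500 / 1,000 yen), stopping at
the first B. With CRRA utility $u(x) = x^{1-\gamma}/(1-\gamma)$ (log at
$\gamma = 1$), $EU_B - EU_A$ at fixed $p$ is decreasing in $\gamma$, so
the switch point identifies an *upper* boundary: `gamma_from_switch()`
returns the largest $\gamma$ on a 0.001 grid in $[-10, 10]$ at which B is
still weakly preferred — "the minimum $\gamma$ for which B beats A" is
not well-posed in this family, and the boundary reading is the one
consistent with later switches meaning more risk aversion (the map is
nondecreasing in the switch point, and round-trips: simulating choices
from the elicited $\gamma$ reproduces the observed switch point). Weak
inequality is used at the switch; at $p = 1$ B dominates for every
$\gamma$, so a first switch there carries no information and is top-coded
to the $p = 0.9$ value with the top-code dummy set — exactly how the
income ceiling (20.5 million-yen midpoint plus top-code dummy) is
handled.

## Estimation and inference

`fit_logit()` fits the pooled binary logit by maximum likelihood through
`stats::glm` (binomial link, gradient tolerance $10^{-10}$, 100-iteration
cap, explicit errors for constant responses, rank deficiency and
separation). The null model is intercept-only on the same rows. Fit
statistics: McFadden $R^2 = 1 - \ell/\ell_0$, Estrella
$R^2 = 1 - (\ell/\ell_0)^{-(2/n)\ell_0}$ with $n$ the pooled row count,
and the likelihood-ratio $\chi^2$ against the null.

Every fit carries two covariance matrices: the inverse observed
information (what plain pooled-logit output reports, and what the survey
analysis being reproduced used), and a per-respondent cluster-robust
covariance (`sandwich::vcovCL`). Because the six records per respondent
share one utility shock, the iid information matrix is not the sampling
covariance of the estimator: it *understates* the variance of
coefficients identified mostly within respondents (price) and grossly
*overstates* the variance of the rate contrast, whose within-respondent
noise cancels. The package therefore uses clustered inference wherever a
calibrated test or coverage statement is needed (the simulation checks
in the test suite), and naive inference where the goal is to mirror
reported tables. `run_scope_test()` takes the choice as an explicit
`inference` argument.

## Scope tests

Four subsets of the six-record dataset (`make_subset()`): Group-1
respondents (I) and Group-2 respondents (II) give internal scope tests;
the first-presented rate across everyone (III) and the second-presented
rate (IV) give external ones. I/II and III/IV each partition the record
set. Each test refits the reduced logit (intercept, price, rate) and
passes when the price coefficient is negative and the rate coefficient
positive, both significant at the two-sided 5% level; sign-only verdicts
are reported alongside, since the literal scope criterion requires only a
positive rate coefficient. Subset III — immune to ordering effects
because it holds only each respondent's first-asked rate — is also the
dataset behind the headline models, so the external scope-test fit *is*
the headline reduced fit. Imputed records stay in every subset (the
six-record dataset is constructed before subsetting, and dropping the
imputed rows would reintroduce the selection bias they cancel);
`read_responses()` in turn never trusts imputed rows from files and
re-derives them.

## WTP statistics and valuation

Under the model, WTP at rate $r$ is logistic with location
$V(r)/(-\beta_{price})$ and scale $1/(-\beta_{price})$, truncated at 0.
Hence (`median_wtp()`, `mean_wtp()`):

$$\mathrm{median} = \frac{V(r)}{-\beta_{price}}, \qquad
\mathrm{mean} = \frac{\ln(1+e^{V(r)})}{-\beta_{price}}
= \int_0^\infty \frac{dt}{1+e^{-(V(r)+\beta_{price}t)}}.$$

The truncated-logistic mean is the package's own closed form for the
reported averages; it agrees with numerical quadrature of the
yes-probability to $10^{-6}$ relative, and with all four published
average WTPs to within the $\approx 0.1\%$ wiggle that rounding the
published coefficients allows. For full-covariate fits both statistics
accept covariate values (typically `covariate_means()`); headline numbers
use the reduced fits only. Negative fitted medians are floored at zero
with a warning.

Two valuation routes are exposed (`loss_by_ratio()`, `loss_direct()`):

* **Ratio anchoring** (headline): multiply the established victim
  non-financial-loss value (537 million yen) by the
  perpetrator-to-victim median-WTP ratio at the same rate. Ratios enter
  at full precision — with the display-rounded 1.20 the 50%-rate answer
  would shift from 642 to 644 million yen. Rounding to integer millions
  (half-up) happens only in reports.
* **Direct risk division**: WTP divided by (reduction rate × baseline
  annual risk), the value-of-statistical-life construction. It yields
  magnitudes in the tens of billions of yen — orders beyond the anchored
  figures — and the two estimators are deliberately left unreconciled.

## Loss decomposition

Yearly accident losses obey the identity $S_n = D_n A_n L_n$ (total loss
= distance × accidents per km × loss per accident). `decompose()` turns
consecutive years into variation rates whose sum plus a residual equals
the total's variation rate exactly; the residual is the cross-term
shortfall of the first-order expansion and stays below 0.02 percentage
points when every factor moves by less than 1%. The default follows the
identity's literal current-year denominators
($\Delta X_n / X_n$); `denominator = "previous"` gives conventional
growth rates. The two conventions differ materially for large changes:
the canonical worked example (factors +9.7, +12.0, −18.9%, total −0.4%,
residual −3.2%) arises from a multiplicatively consistent series only
under previous-year denominators, which is how the pipeline test
reproduces it.

## What the generator emulates — and what it does not

Defaults (`population_config()`) encode the study conditions: 2,085
respondents, a 1040/2085 perpetrator-arm share, Group-1 shares of 50.7%
(perpetrator) and 50.05% (victim), published gender/age/coarse-income
marginals, and per-arm true coefficients at the published full-model
magnitudes. Where the survey report prints no marginal, a choice was made
once: binary covariates (accident experience, driving confidence,
10,000 km+ distance, ADAS experience) at 0.5; household income uniform
over the midpoint grid within each printed coarse bracket, giving the
top-coded 20.5 cell about 1.2% mass; the 70+ indicator drawn only inside
the 60+ age band with conditional probability 0.4; lottery switch points
uniform over the ten grid values; initial bids uniform over the five
permissible ladder prices. All are configuration-overridable.

The generator does **not** emulate protest zeros, inattentive or
"inappropriate" respondents (the original screening rule is not public),
item nonresponse, or any correlation between covariates and the utility
shock. Passing tests therefore demonstrate that the estimation and
valuation machinery is correct under the stated response model — not that
the model captures every behavioural feature of real survey data.

## Numerical choices and problem sizes

* Logit convergence: gradient tolerance $10^{-10}$, 100 iterations,
  explicit non-convergence error.
* $\gamma$ search: root bracketing on $[-10, 10]$ then snapping to the
  0.001 grid by direct expected-utility comparison; indifference resolved
  toward the larger $\gamma$ (weak inequality).
* Mean-WTP quadrature checks integrate to $(V+60)/|\beta_{price}|$, where
  the integrand is below $10^{-26}$.
* Money is handled in yen throughout; million-yen and two-decimal ratio
  formatting happen only at the reporting layer.
* The test suite sizes its simulations for tight-but-quick checks: single
  fits at 200–3,000 respondents; coefficient recovery with 20 replicates
  of 5,000 respondents against 3 clustered-SE bands; scope-test
  calibration with 400 replicates of 2,000 respondents against a
  3-binomial-SE band around the nominal 2.5% one-sided rate; marginal
  checks at 100,000 respondents and closed-form survival checks at
  $10^6$ draws.

## Known limitations

* The pooled logit is the reproduction target, not the efficient DBDC
  estimator; interval-data likelihoods would use both bounds jointly.
* Naive z-values on pooled records are miscalibrated by construction
  (see above); use `inference = "cluster"` for hypothesis tests on
  simulated or real clustered data.
* WTP confidence intervals (delta-method or Krinsky–Robb) are not
  provided.
* The victim reference loss (537 million yen) is an external input, not
  re-derived.
* The published Estrella values could not be reconciled with the
  standard formula (which this package implements); its McFadden values
  reproduce exactly.

## A worked example

```{r example, eval = FALSE}
cfg <- population_config(n_respondents = 2085, seed = 1)
out <- run_pipeline(cfg)
out$wtp                 # median/mean WTP per arm and rate, with ratios
out$scope$perpetrator   # scope-test verdicts, subsets I-IV
out$valuation[, c("statistic", "rate", "ratio", "loss_by_ratio_mn")]
```
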
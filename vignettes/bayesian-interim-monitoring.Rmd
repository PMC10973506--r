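---
title: "Bayesian interim monitoring with dynamic borrowing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian interim monitoring with dynamic borrowing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bayesinterim)
```

This vignette is the package's own account of its methodology: the
models, the priors, the sampler, what the synthetic data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## Setting

A phase III induction trial in adults (18-65) with newly diagnosed AML
randomizes an experimental against a standard arm 1:1 (about 390
patients per arm). The primary endpoint is event-free survival (EFS);
the design targets a hazard ratio of 0.76 with 82% power at the
two-sided 5% level, which requires 441 events — years of follow-up.
Four interim benefit-risk assessments are scheduled after 150, 300, 450
and 600 enrolled patients. A preceding trial contributes 426 historical
control patients whose induction treatment matched the current control
arm; 300 of them, matched 1:1 on age and ELN 2017 risk to concurrent
controls by propensity scores, reinforce the control arm through an
informative prior.

## Event-free survival model

EFS times follow a Weibull proportional-hazards model with cumulative
hazard $\Lambda(t) = t^{\nu} e^{\eta}$, so the log likelihood of subject
$i$ with time $t_i$ and event indicator $\delta_i$ is
$\delta_i(\log\nu + (\nu-1)\log t_i + \eta_i) - t_i^{\nu} e^{\eta_i}$.
The linear predictor is $\eta = \mu_c + \beta$ for the experimental arm,
$\mu_c$ for concurrent controls and $\mu_h$ for historical controls; the
hazard ratio is $e^{\beta}$. The shape $\nu$ is shared across all three
cohorts — the minimal commensurate structure in which borrowing acts
only on the log-rate intercept. Priors are $\beta,\ \mu_h,\ \log\nu \sim
N(0, 10^2)$ and the commensurate prior

$$\mu_c \sim N(\mu_h, \sigma_\tau^2).$$

The gap scale $\sigma_\tau$ governs borrowing strength. Three modes are
exposed (`borrow_config()`): `none` drops the historical cohort and
gives $\mu_c$ the vague prior directly; `fixed` uses a supplied
$\sigma_\tau$ (its limits are the testable contract: $\sigma_\tau \to
\infty$ reproduces the no-borrowing fit, $\sigma_\tau \to 0$ pools the
two control cohorts); `adaptive` places a half-normal hyperprior of
scale 1 on $\sigma_\tau$, so concordant historical data sharpen the
control posterior while conflicting data are discounted — dynamic
borrowing. The half-normal(1) form is this package's choice for the
hyperprior, made once and exposed as configuration (`hyper_scale`): on
the log-rate and logit scales a gap SD of 1 is already a very large
cohort discrepancy, so scale 1 is weakly informative without forcing
borrowing.

Binary endpoints (CR after two cycles, MRD-negative CR among CR patients
with an MRD assessment, 60-day mortality, grade 4-5 adverse events) use
the same structure on the logit scale: binomial likelihoods per cohort,
$p_{\text{exp}} \sim \text{Beta}(1,1)$,
$\operatorname{logit} p_h \sim N(0,10^2)$, and
$\operatorname{logit} p_c \sim N(\operatorname{logit} p_h,
\sigma_\tau^2)$. The report summarizes $\Delta = p_{\text{exp}} -
p_c$ by its posterior median, equal-tailed 95% credible interval and
$P(\Delta > 0)$; for the two safety endpoints the same convention is
kept and labelled as probability of excess harm. With `mode = "none"`
the model is fully conjugate and is sampled exactly (i.i.d. draws from
the two Beta posteriors) instead of by MCMC.

## Sampler

Posterior sampling is a self-contained adaptive random-walk
Metropolis-within-Gibbs: one Gaussian proposal per coordinate per sweep,
per-coordinate step sizes tuned in 50-iteration batches during warmup
toward a target acceptance rate (default 0.3) and frozen afterwards.
Defaults follow the analysis protocol: 3 chains of 50,000 iterations,
first half discarded. Convergence is monitored by the classical
Gelman-Rubin statistic per parameter; any $\hat R > 1.05$ (a
deliberately conservative cut — the diagnostic's originators used 1.1)
flags the fit with a warning rather than an error, since an interim
report with a flagged endpoint is still actionable.

Two reparameterizations matter for mixing, and both are internal — the
reported parameters are unchanged:

* **Non-centered gap.** The sampler works with
  $\mu_c = \mu_h + \sigma_\tau\,\delta$, $\delta \sim N(0,1)$, rather
  than $\mu_c$ directly. Centered coordinates cannot mix when
  $\sigma_\tau$ is small (the pooling limit), because $\mu_c$ is then
  glued to $\mu_h$ at a scale far below the likelihood's.
* **Time-scale centering.** Within `fit_weibull_borrow()` times are
  divided by the geometric-mean event time before sampling. The Weibull
  shape and intercepts are strongly correlated on the raw scale (months)
  and nearly uncorrelated on the centered one; the intercepts are
  shifted back by $\nu \log t_{\text{ref}}$ afterwards. The log hazard
  ratio and the commensurate gap are invariant to the shift. The same
  factorization motivates sampling the experimental arm's own intercept
  $\eta_e = \mu_c + \beta$ and deriving $\beta$.

Other numerical choices: survival times below 0.01 month are floored at
0.01 before likelihood evaluation (a zero event time otherwise has
undefined log density for $\nu \ne 1$); equal-tailed (not HPD) 95%
credible intervals throughout; per-interim and per-endpoint seeds are
derived from the master seed by a fixed affine hash (`interim_seed()`)
so any single interim can be re-run in isolation and reproduce the
scheduled run bit for bit.

## Propensity matching

Control-arm membership (current vs historical) is modelled by logistic
regression on standardized age and two ELN-risk contrasts against
"favorable"; fitted probabilities are the propensity scores. Matching is
greedy 1:1 nearest neighbor without replacement on the absolute score
difference, processing concurrent controls in decreasing score order
with exact ties broken by the lowest historical id — so the result is
deterministic and invariant to input row order. The pair count is a
required argument (300 in the motivating design) rather than inferred:
why 300 of the 392 available concurrent controls were used is not
derivable from first principles, so the choice is the caller's. No
caliper is applied by default (all 300 pairs were formed in the
motivating analysis); a `caliper` argument exists. Matching is done once
on the full dataset and the matched historical set is reused at every
interim, matching the study-design reading that the prior was
constructed once; `rematch_each = TRUE` recomputes it per cut. Optimal
(non-greedy) matching and weighting methods are out of scope.

## Synthetic trial generator

`generate_trial()` emulates the statistical structure the analysis
assumes, not the clinical course of AML:

* **Accrual** is uniform over the window implied by `accrual_rate`
  (default 22/month — roughly 780 patients over 2014-2017); recruitment
  calendars are otherwise unmodelled. Interim cuts
  (`cut_at_milestone()`) censor administratively at the enrollment time
  of the milestone-th patient, with zero data-cleaning lag.
* **EFS** is Weibull with shape 1.2 and per-group rates set from 4-year
  EFS of 44% (both concurrent arms) and 36% (historical), the published
  survival landmarks. The historical cohort is fully accrued
  (enrollment time 0) and censored at a 72-month horizon.
* **Binary endpoints** are drawn independently at the published rates,
  with two deliberate couplings: a 60-day death forces the EFS event
  into the first two months (the event time is resampled from the
  Weibull truncated to [0, 2]), and MRD status exists only for CR
  patients, missing at the published rates (22% current, 35%
  historical). Ages are uniform on 18-65 (only medians and the range
  are published); ELN risk is drawn from (0.36, 0.30, 0.34).

What this does *not* emulate — and hence what passing tests do not show
about real data: covariate-dependent hazards (age and ELN risk do not
affect the simulated outcomes, so matching corrects a selection
mechanism that the generator induces only through sampling noise unless
configured otherwise), post-remission treatment effects, crossover,
non-administrative dropout, and calendar drift between the historical
and current eras. One property worth knowing when designing experiments
with the generator: because 60-day mortality is configured separately
from the Weibull rates, a strong configured hazard ratio is attenuated
at short follow-up where forced early deaths dominate the event mix
(the package's own tests disable `p_death60` when they need a clean
Weibull signal).

## Interim orchestration

`run_interim_schedule()` cuts the data at each milestone, restricts the
historical cohort to the matched set, fits the EFS model and the four
binary models, and assembles a report per interim (posterior medians,
credible intervals, threshold probabilities, convergence flags, seeds).
A failing endpoint is recorded in the report without aborting the
others; an infeasible milestone aborts. No binding Bayesian stopping
rule is imposed — the output is advisory, in keeping with reporting to a
monitoring board — but a configurable advisory flag fires when
$P(HR < 0.76) < 0.05$. `run_without_borrowing()` repeats the schedule
with the historical cohort dropped, the standard sensitivity analysis
for the influence of external data.

## Group-sequential comparator

The conventional machinery is implemented against the same design
inputs. The Lan-DeMets O'Brien-Fleming spending function
$\alpha(t) = 2(1 - \Phi(z_{1-\alpha/2}/\sqrt{t}))$ allocates the
one-sided 2.5% type-I error across looks; efficacy bounds are solved so
each incremental null crossing probability equals the spend increment,
by the classical recursive numerical integration over the correlated
Gaussian increments (trapezoid rule, grid half-width 8 SD, 4001 points
by default; doubling the grid moves the five-look bounds by under
$10^{-3}$). Futility bounds are non-binding (efficacy bounds are
computed ignoring them) and use beta-spending of the same functional
form under the design alternative; the standardized drift is calibrated
so the futility bound meets the efficacy bound at the final look, and
the implied event count $\lceil(2\theta/|\log hr|)^2\rceil$ quantifies
the interim-monitoring inflation — 503 events for five equally spaced
looks at HR 0.76, 82% power, versus 440 for the fixed design by the
Schoenfeld formula. The commercial-software figure of 883 patients with
488 events for the same trial rests on accrual assumptions that are not
published, so it is treated as reference output to compare against, not
a number this package asserts. Only O'Brien-Fleming-type spending is
provided; information fraction is identified with event fraction, as is
standard for survival endpoints.

`simulate_logrank_operating_chars()` closes the loop empirically:
two-arm exponential trials with administrative censoring calibrated to
the design event count, tested by the two-sided log-rank test. At HR
0.76 with 441 expected events the empirical power over 10,000 trials is
82% (the design value); at HR 1.0 the empirical size is 5%.

## Problem sizes used by the tests

The shipped test suite runs the samplers at 2,000-30,000 iterations per
chain rather than the 50,000 default, and sizes its simulation
experiments (20-replicate parameter recovery and borrowing experiments,
10,000-trial operating characteristics, $10^6$-path boundary checks) so
the whole suite completes in a few minutes; these sizes were chosen so
that Monte-Carlo error is small against each assertion's tolerance. The
parameter-recovery experiment (true HR 0.76, shape 1.2, 800 per arm)
uses mature follow-up (accrual 10/month, ~85% events) — at interim-style
event fractions the log-HR standard error alone (~0.11) would exceed
the accuracy being asserted, so a recovery check there would measure
noise, not the model.

## Known limitations

* The commensurate hyperprior's published specification was not
  available; the half-normal form and the shared shape are this
  package's documented choices, both exposed as configuration.
* Borrowing acts on intercepts only; covariate-adjusted outcome models
  (and Cox semi-parametric fits) are out of scope.
* The sampler is a random-walk scheme: adequate for these 3-6 parameter
  posteriors, but iteration counts, not gradient information, buy its
  accuracy; the Gelman-Rubin flag should be respected.
* Matched historical patients enter the likelihood directly through the
  commensurate structure; no power-prior or weight-based alternatives
  are implemented.
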
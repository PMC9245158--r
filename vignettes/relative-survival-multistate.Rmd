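---
title: "Relative survival in non-parametric multi-state models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative survival in non-parametric multi-state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmsm)
```

## The model

A Markov multi-state process `X(t)` on a finite state space evolves with
transition hazards `lambda_hj(t)`; transition probabilities follow from the
product integral `P(s,t) = prod_(s,t] (I + lambda(u) du)`. We use the
clock-forward convention: `t` is always time since study entry, which is what
makes post-relapse transitions Markov even though subjects enter the relapse
state at different times (delayed entry).

When a transition ends in death and causes of death are unrecorded, we assume
the additive decomposition `lambda = lambda_E + lambda_P`: the observed death
hazard is the sum of an excess (disease-related) hazard and the population
hazard that a demographically matched member of the general population would
experience. The package's central operation replaces each death state by a
population and an excess counterpart and estimates, for each transition
`h -> death`,

* the population part as the risk-set-weighted average of the subjects'
  individual mortality-table hazards,
  `Lambda_hj,P(t) = int sum_i Y_hi(u) dLambda_Pi(u) / Y_h(u)`, and
* the excess part as the Nelson-Aalen estimate minus the population part.

Because the weighting follows the *actual* risk set, two features of real
cohorts are handled automatically: the changing demographic composition of a
state over time, and left truncation of post-relapse transitions. The same
extended hazard matrix drives the product integral, giving probabilities of
population and excess death before and after the intermediate event. Two
identities hold *exactly* by construction and are asserted in the tests:
population + excess hazards reproduce the observed hazard at every grid
point, and the pair of split-state probabilities sums to the unsplit death
probability at every time.

Assumptions worth stating: censoring is non-informative and shared across a
subject's competing transitions; the cohort is small relative to the general
population (so the life table is unaffected by removing it); and the additive
model itself. Where the cohort is *healthier* than the population the excess
hazard is genuinely negative; estimates then go negative too. They are
retained by default (an optional `clamp_negative` raises cumulative excess
hazards to zero with a logged count) because silently flooring them would
bias the split-sum identity.

## Time conventions and the evaluation grid

All internal time is in days, with one year = 365.241 days; this is the
convention of the established relative-survival ratetable ecosystem, and it
governs attained-age and calendar-year rollovers when matching subjects to
the table. A subject's population hazard is constant within each day;
`Lambda_Pi` is piecewise linear with daily knots. Population mortality is
accumulated on the daily lattice, each whole day a subject spends at risk
contributing that day's table hazard.

Estimates are *reported* on the pooled grid of observed event times (plus any
user-requested times). Daily population mass between two grid points is
lumped onto the later point, matching the right-continuous step convention of
the Nelson-Aalen estimator. This event-grid evaluation induces a small,
conservative discretisation relative to the daily reference; `split_hazards(
eval = "daily")` adds the full lattice when the difference matters. Partial
days at either end of a risk interval contribute no population mass (at most
one day's hazard, of order 1e-4, per subject).

## Variance options and confidence intervals

Two variance routes are implemented.

**Greenwood.** Hazards use `sum dN / (Y (Y - dN))`; when a risk set is
exhausted (`Y = dN`) the increment falls back to the Aalen form `1/Y` with a
warning. Probabilities use a forward covariance recursion of the product
integral in which each grid point contributes the multinomial covariance of
its hazard increments — a form chosen because it reproduces the classical
Greenwood Kaplan-Meier variance *exactly* in the pure-survival case (verified
against `survival::survfit` in the tests). Under this option the population
transitions are treated as fixed: zero variance and covariance, with each
excess transition inheriting its observed counterpart's variance. That
assumption is convenient but wrong in principle — the risk-set weighting
makes the population estimator random — and the simulations show its
consequences: zero-width intervals on population hazards and severe
undercoverage for population-state probabilities.

**Bootstrap.** Subjects are resampled with replacement (records and
demographic profile travel together; left-truncated records keep their entry
times), the entire pipeline is re-run per replicate, and the sample variance
over B replicates (denominator B − 1) is used. B = 100 by default.
Implementation note: a resample is represented by a multiplicity vector, so
each replicate reduces to weighted aggregations of precomputed per-subject
structures and is evaluated on the pooled original event grid — a superset
of the replicate's own event times, which leaves every cumulative quantity
at the target times unchanged while making 20,000 re-estimations affordable.
Replicates where a target is undefined are recorded as missing and excluded
with a logged count.

Six interval constructions are available: symmetric plain-scale with either
variance (`plain.G`, `plain.boot`), the delta-method log scale (`log.boot`),
empirical replicate quantiles (`q.boot`, type-7 interpolation — the
interpolated choice is configurable in spirit but fixed for
bit-reproducibility), and logit / complementary-log-log transformations.
Plain intervals are deliberately not clipped to [0, 1]. `log.boot` is the
recommended default: in the package's own simulations it restores near-nominal
coverage exactly where `plain.G` fails.

## The simulator and what it does (not) emulate

`simulate_cohort()` generates the illness-death cohort: uniform age, sex
Bernoulli(0.5), uniform entry date in [1990, 2000); latent relapse and
excess-NRM times from exponential or Weibull laws with optional log-linear
age effects (age centred at the middle of its range); population NRM from the
ratetable via exact inversion of the subject's piecewise-constant cumulative
hazard; after an observed relapse, population DaR from the ratetable
left-truncated at relapse and excess DaR from a left-truncated Weibull
conditioned on the relapse time (clock-forward, preserving the Markov
property). Only the minimum of the competing latent times is observed; cause
labels stay in a separate latent table. Exponential random censoring is
calibrated by bisection (common random numbers, so the censored fraction is
monotone in the rate) to leave about 20% of subjects randomly censored within
the 10-year administrative window; "censored" counts random censoring only,
not survivors of the full follow-up.

Five scenarios are bundled. Their exact rates are package choices, selected
once to satisfy the qualitative design constraints and kept in a single
constants block (`R/scenarios.R`): young cohorts (ages 25–45) where
population deaths are rare versus an old cohort (65–85, `exp.large`) where
population NRM is comparable to excess NRM; a Weibull variant; and two
covariate-effect variants with beta = ±0.03 per year of age on relapse,
+0.03 on excess NRM, and — by design — no age effect on excess DaR. The
bundled ratetable is *synthetic*: a Gompertz age profile with a female
advantage and a mild calendar trend, shaped like a Central European national
life table but generated in code. Consequences for interpretation: passing
tests demonstrate correctness of the estimators under ideal Markov sampling
with a smooth, exactly-known life table; they do not probe non-Markov
duration effects, covariates missing from the table, ties from coarsened
event times, or cohorts near the table's clamped edges.

## Exact truth by covariate integration

True hazards and occupation probabilities are obtained by integrating the
six-state process over the covariate law: a midpoint lattice over age (40
nodes), entry year (5) and both sexes. For each node the process has
piecewise-constant daily hazards, so the forward equations admit an exact
per-day solution (survival factors `exp(-sum of increments)`, competing-risk
allocation `(1 - e^-d)/d`, and a closed-form convolution for the relapse
pathway); no ODE solver is involved. The marginal true cumulative hazard
weights each node's hazard by its at-risk probability — the population
counterpart of the estimator's risk-set weighting — and censoring cancels
from the ratio because it is covariate-independent. Doubling the lattice
changes no reported truth by more than 1e-4 (asserted in the tests), and in
the constant-hazard, zero-table case the integrator agrees with the
closed-form competing-risks solution to 1e-6.

## Reproducibility and problem sizes

Replicate `i` of a performance run uses child seed `1000 * seed + i`, and its
bootstrap stream `10^9 + child`, so any single replicate can be reproduced in
isolation. The package's own validation uses scaled-down study sizes chosen
as the smallest that leave the Monte-Carlo error well below the effects being
checked: bias is assessed at n = 2000 over 200 replications (every estimand
within 3 Monte-Carlo SEs of its truth); SE agreement and coverage at
n = 1000, 200 replications, B = 100, where the 95% target has a binomial SE
of about 1.5 percentage points. The full-precision design (SE of the
coverage estimate 0.5%, hence 1900 — rounded to 2000 — replications, via
`nsim_for_cp_se()`) is what a production validation would use.

## Known limitations

* For left-truncated transitions both the Greenwood and the bootstrap SE
  understate the empirical SE of the *hazard* estimators; this is a known
  property of risk-set-based variance estimation under delayed entry, not
  specific to the relative-survival extension, and it is why coverage for
  the Relapse -> DaR hazards runs below nominal at early times.
* No closed-form variance exists for the population-part estimators; the
  bootstrap is the only honest option there.
* Covariates beyond the ratetable's matching variables are not modelled
  (no Cox/additive regression on excess hazards); transitions into
  intermediate states are never split, which would require event-specific
  population tables.
* Negative excess hazards are a model-violation signal and should be read as
  such rather than clamped away.
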
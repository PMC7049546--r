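---
title: "Dynamic health impact assessment of tobacco control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic health impact assessment of tobacco control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokehia)
```

## The model in one page

`smokehia` projects a national population forward in one-year steps under a
three-state smoking model (never / current / former smoker) and reports how
tobacco-control scenarios change life expectancy (LE), healthy life years
(HLY) and unhealthy life years (ULY) relative to a business-as-usual
reference. The chain is:

1. **Estimation.** From cross-sectional survey microdata, smooth the
   age-specific prevalence of each smoking state (fractional-polynomial
   logistic regression, fitted separately by sex and internally normalized so
   the three states sum to 100% at every age), the overall disability
   prevalence $\pi(a,s)$ based on the dichotomized activity-limitation item
   (GALI: any limitation counts as disabled), and odds ratios of disability
   for current and former smokers (reference: never), age-adjusted.
2. **Rates.** Combine prevalence $p_k(a,s)$, relative risks of death
   $RR_k(s)$ and baseline all-cause mortality $q(a,s)$ into state-specific
   death probabilities; derive the *net* start/quit/restart probabilities
   that hold the age-specific smoking prevalence exactly stationary over
   calendar time; invert the overall disability prevalence and odds ratios
   into state-specific disability probabilities $d_k(a,s)$.
3. **Projection.** Simulate the population under each scenario -- either by
   partial microsimulation (stochastic smoking histories, deterministic
   survival weights) or by the exact deterministic recursion that is its
   expectation -- with 2500 individuals per one-year age class (0--95) and
   sex, 480,000 in total, over a 30-year horizon with annual newborn cohorts.
4. **Summary.** Compute period (Sullivan) and cohort LE/HLY/ULY at age 15
   and report each scenario as a difference from the reference.

All models and projections are fully stratified by sex; age is integer with
class $a$ covering $[a, a+1)$ and 95 an open-ended "95+" class.

## Estimation

### Fractional-polynomial prevalence smoothing

Each binary outcome (e.g. "current smoker" vs rest) is regressed on
transforms of $u = \mathrm{age}/10$ drawn from the standard power set
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 denotes $\log u$), with all degree-1
and degree-2 combinations as candidates; a repeated power $p$ contributes
$u^p$ and $u^p \log u$. Within each degree the lowest-deviance fit is kept
(ties broken lexicographically). Between degrees we follow the standard
fractional-polynomial function-selection convention: the best degree-2 model
replaces the best degree-1 model only when it improves the deviance by more
than $\chi^2_{2,\,0.95} \approx 5.99$. A plain deviance argmin would always
prefer degree 2 (it nests degree 1), so a genuinely low-order
age-association could never be identified as such; the closed-test rule
recovers it while still allowing curvature where the data demand it.

Records are aggregated to binomial counts per observed age before fitting,
which makes the cost of the 44-candidate search independent of sample size
and allows non-unit survey weights (used as frequency weights; design-based
variance estimation is deliberately out of scope -- only point estimates
feed the projection).

The three per-state fits are made consistent by *internal normalization*:
predictions are divided by their per-age sum. Three binary fits plus
renormalization (rather than one multinomial fit) keeps each curve in the
standard FP family and matches how multistate prevalence inputs are usually
prepared; normalization preserves the ranking of the unnormalized fits at
every age. Ages below 15 -- below the survey's coverage -- are fixed at
(never, current, former) = (1, 0, 0).

### Disability inputs

Disability prevalence over age is smoothed with the same FP machinery. Odds
ratios come from a per-sex logistic regression of the disability indicator
on smoking state plus $u$ and $u^2$; the quadratic term captures curvature
in the age profile without interacting with sparse old-age strata.

## Rate derivation

### Mortality partition

With $RR_{\text{never}} = 1$,
$$q_{\text{never}} = \frac{q}{p_n + p_c RR_c + p_f RR_f}, \qquad
  q_k = RR_k \, q_{\text{never}},$$
so the prevalence-weighted mixture reproduces the baseline exactly
($\sum_k p_k q_k = q$). Values above 1 are capped with a warning (none occur
under the synthetic defaults). State-specific rates are computed once from
the reference prevalence and held fixed across scenarios: a policy changes
the population's composition, not the hazard attached to a state.

### Net transitions and stationarity

With three states, the two free prevalence constraints per age step identify
exactly two net flows. We attribute them to never$\to$current (*start*) and
a single signed current$\leftrightarrow$former flow (*net_cf*; positive =
quit probability, negative = restart probability), because never-smoker
status can only be left, which makes this the unique net parameterization.

Within a year, mortality acts first; flows then compose *sequentially*:
start first, then the quit flow acting on the post-start current pool (or
the restart flow on former). The sequential order matters at exactly one
place: where a cohort with no smokers yet (age 14, all never) must reach an
adult prevalence containing former smokers, only a start-then-quit
composition can produce them in a single step. With simultaneous flows that
step is infeasible and the stationarity property fails visibly. The closed
form is
$$s = 1 - \frac{p_n(a{+}1)\,T}{n_n}, \qquad
  c \text{ or } r \text{ from the current-state balance},$$
with $n_k = p_k(a)(1 - q_k(a))$ the survivor masses and $T = \sum_k n_k$.
Solutions outside $[0,1]$ are clipped with a warning naming the cells; under
the synthetic defaults no clipping occurs, and the deterministic reference
projection then reproduces the baseline age-prevalence at every year of the
horizon to floating-point accuracy (the defining property of net
transitions: the age distribution of smoking is assumed stable over time).

The open 95+ class is *not* given age-94's schedule: survivors of the pool
stay in it, so its flows are solved from the stationary self-map -- the same
balance with the class's own shares as the target under its own mortality.
Copying age-94's schedule would let the standing pool drift away from the
intended shares by roughly $10^{-3}$ per year, quietly breaking
stationarity at the top of the age range.

### Disability linkage

Given $\pi(a,s)$ and odds ratios $OR_k$, the baseline log-odds
$\beta_0(a,s)$ solves
$$\sum_k p_k \,\mathrm{logit}^{-1}(\beta_0 + \log OR_k) = \pi,$$
a strictly increasing function of $\beta_0$, by vectorized bisection on
$[-50, 50]$ to $10^{-12}$; then $d_k = \mathrm{logit}^{-1}(\beta_0 + \log
OR_k)$. The pairwise odds ratios hold exactly by construction and the
mixture reproduces $\pi$ to the bisection tolerance. $\pi = 0$ or $1$ map to
all-0 / all-1. This is a prevalence-odds cross-sectional attribution: the
package treats disability as an expected fraction of each lived year, not
as a simulated on/off state, since the summary measures only need expected
disabled person-years.

## Projection engines

The **partial microsimulation** draws stochastic smoking histories (initial
state from the scenario prevalence; one transition draw per individual-year)
but keeps survival deterministic: each individual carries an alive-weight
multiplied by $1 - q_{k}(a)$ each year, and no random death events occur.
This removes mortality noise from scenario comparisons while preserving the
risk-factor dynamics. A single uniform per individual-year encodes the
sequential flows ($u < s\,c$: start and quit within the year; $u < s$:
start; analogous thresholds for quit and restart), so scenario transforms
never desynchronize the draws. `common_random_runs()` reuses the same
individuals and uniforms across all scenarios, making differences nearly
noise-free; with equal risks in all states (RR = OR = 1) scenario
differences collapse to exactly zero.

The **deterministic recursion** propagates state-count vectors with the same
bookkeeping and is the exact expectation of the microsimulation; the test
suite verifies agreement within Monte-Carlo error and the
$n^{-1/2}$ shrinkage of the gap over `n_per_class` in {100, 400, 1600}.

Conventions, fixed and documented rather than configurable: survival update
first, then transitions; deaths mid-interval, so person-years are
$L = N - D/2$; newborn cohorts (all never smokers, age 0) enter every
projection year weighted by the newborn series; survivors of the 95+ class
remain in it; the class closes with the constant-hazard expectation $1/m$,
$m = D_{95}/L_{95}$.

## Scenarios

Nine registry entries: `reference` (identity), `smoking_free` (all never
smokers, start forced to 0), `zero_restart` (start 0 and restart flows 0),
`all_quit` (positive quit flows set to 1; restarts untouched, so a residual
current share can persist where the baseline net flow is a restart),
`zero_restart_all_quit` (start 0, quit 1 everywhere), `low_prevalence`
(swap in an alternative low-smoking table and re-derive transitions so the
alternative is itself stationary), `no_init_under_18` (zero smoking
prevalence and start below 18; 18+ untouched), `quit_x1_3` and `quit_x2`
(positive quit flows multiplied, capped at 1). Quit interventions are
sustained every projection year, not one-off. Prevalence transforms apply
once at baseline; transition transforms to the schedule used throughout.
Applying a scenario to its own output is a no-op, so transforms are
idempotent by construction (the multiplier scenarios would otherwise
compound).

## Summary measures

**Sullivan:** for a calendar year, $q(a) = D(a)/N(a)$ per cell (the
survival difference between adjacent years for closed cohorts),
cross-sectional disability prevalence $\pi(a) = $ disabled person-years /
person-years, a period life table with mid-interval deaths, $LE = \sum_a
L(a)/l(a_0)$, $ULY = \sum_a L(a)\pi(a)/l(a_0)$, $HLY = LE - ULY$.

**Cohort:** the baseline cohort is followed along its diagonal through the
horizon, summing person-years and disabled person-years; a 15-year-old
cohort is still alive after 30 years, so the remainder is closed by a
deterministic continuation under the final year's rates (a period table at
the final year applied to the survivors). The continuation's share of total
LE is attached as an attribute. On a stationary reference population the
Sullivan and cohort measures coincide, which the test suite checks to
$10^{-6}$; if a cohort reached the open class within the horizon its
identity would merge with the standing pool, so that configuration warns
and falls back to pooled open-class rates.

$HLY + ULY = LE$ holds by construction everywhere.

## The synthetic-data generator

The generator stands in for the real survey and demographic sources and is
itself first-class, tested code. Its defaults define the study conditions:

* **Smoking curves.** Parameterized per sex as a strictly decreasing
  logistic never-smoker curve and a decreasing logistic share of
  ever-smokers who still smoke (current ~16% of the population at age 40
  for men under the defaults, peaking in mid-adulthood). The monotone never
  curve is a deliberate choice: it guarantees nonnegative derived start
  probabilities at every age, so the stationarity property holds without
  clipping. Real cross-sections can violate this (cohort effects make
  never-prevalence rise with age among the old), in which case the solver
  clips and warns and stationarity holds only approximately -- passing
  tests on the synthetic defaults therefore do not certify clip-free
  behavior on arbitrary real inputs.
* **Disability.** Logistic baseline log-odds rising with age (about 1--2%
  disabled at 15, a third or more at 80+ when mixed over states), shifted
  by log odds ratios of 1.8/1.3 (men, current/former) and 2.0/1.4 (women).
  Disabled records split 70/30 into not-severe/severe; only the dichotomy
  matters downstream.
* **Mortality and population.** Gompertz one-year death probabilities
  $q(a) = 1 - \exp(-\text{level}\cdot e^{\text{slope}\,a})$ with defaults
  chosen so male life expectancy at birth falls in the high 70s under the
  deterministic life table -- the order of magnitude of a western European
  population, not calibrated to any published table. Population counts are
  the stationary population of that schedule; newborn counts decline 0.3%
  per year.
* **Relative risks of death.** 2.0/1.4 (men, current/former), 1.9/1.3
  (women), in the range reported for total mortality in European
  populations.
* **Survey sampling.** Ages 15+ drawn from the population age structure;
  all weights 1. No household clustering, nonresponse or missingness is
  emulated, so the generator validates the estimation-projection machinery,
  not survey-design handling.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200,000 survey records for
parameter-recovery checks (prevalence curves within 0.02 absolute on ages
20--80, odds ratios within 15%); the full 480,000-individual design for the
microsimulation-vs-deterministic comparison; 1000 random cells for the
inversion property tests (both solvers against `uniroot`-based
root-finders, 1e-10); replicated small runs (`n_per_class` 100--1600) for
the convergence law. Bisection tolerance for the disability inversion is
1e-12; prevalence rows are renormalized when within 1e-6 of summing to 1
and rejected otherwise; tables are written with 12 significant digits.

## Known limitations

No time-since-quitting gradient among former smokers (a single OR/RR per
state); no disease-specific pathway (disability attaches directly to
smoking state); no migration or secular mortality improvement; no
uncertainty quantification (point estimates only propagate); the Sullivan
method's usual caveat applies -- it assumes disability transition rates
change smoothly over the period.
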
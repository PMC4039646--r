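---
title: "An open-population model of GIST prevalence by treatment line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An open-population model of GIST prevalence by treatment line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistprev)
```

## The estimation problem

Gastrointestinal stromal tumour (GIST) patients with unresectable or
metastatic disease move through at most two licensed lines of systemic
therapy — imatinib, then sunitinib — before becoming *third-line
treatment-eligible*. The size of that third-line population decides whether
a candidate third-line treatment can be appraised under ultra-orphan rules
(prevalence below 2 per 100,000; the EU orphan boundary is 50 per 100,000).
No registry tracks patients by treatment line, so the quantity must be
modelled from what is observable: incidence, the proportion resectable at
diagnosis, and published survival/progression times per line.

## Model structure and assumptions

The model is an open-population compartmental chain. A fixed population
$Z_1$ produces $N = \Gamma Z_1$ newly diagnosed cases per year. A fraction
$p$ is resectable and enters the post-resection recurrence-free state $Z_2$;
the rest enter the imatinib state $Z_3$ directly. Relapses from $Z_2$ join
$Z_3$; imatinib failures move to the sunitinib state $Z_4$; sunitinib
failures to the third-line state $Z_5$; exit from $Z_5$ is death. Every
state also loses members to background mortality $\mu$.

Key structural assumptions, all deliberate simplifications:

- **Exponential times-to-transition.** Each state's dwelling time is
  exponential, so a published median $m$ maps to a rate $\ln 2 / m$
  (`median_to_rate()`). This is the only assumption consistent with a
  single-rate state, and it is what links the third-line median survival of
  0.77 years to the default exit rate of 0.904/yr. (The default table keeps
  the conventional printed value 0.904 rather than $\ln 2 / 0.77 = 0.900$;
  the 0.4% difference is immaterial to every output.)
- **No cure, no line-skipping, no re-resection.** Patients leave only by
  death; everyone progresses strictly down the line sequence. Both choices
  overstate prevalence slightly, which is conservative for a
  "below-threshold" claim.
- **Sequential adjuvant/neoadjuvant pathways are not modelled.**

### Annual cycle in probabilities, not rates

The difference equations advance in one-year cycles. Each per-year rate $r$
is converted to an annual transition probability $q = 1 - e^{-r}$
(`rate_to_annual_prob()`), and a state with disease-exit rate $\gamma$ loses
fractions $q(\gamma)$ and $q(\mu)$ per cycle (the *additive* formulation,
the plain reading of parallel exit arrows). The naive rate-based update is
unstable here because $\gamma_4 + \mu \approx 1.005 > 1$; the probability
formulation keeps every occupancy nonnegative across the whole plausible
parameter space. An *apportioned* variant — one combined exit probability
$1 - e^{-(\gamma + \mu)}$ split in proportion to the rates — is available
via `exits = "apportioned"` and changes equilibrium counts by under 2% at
default parameters; additive is the default.

Mass is conserved exactly at every step: incident cases equal the change in
total occupancy plus deaths. The test suite asserts this to relative
$10^{-9}$ along random trajectories.

### Equilibrium as the reporting mode

Prevalence is reported at the fixed point of the difference equations, where
each state's inflow balances its outflow:

$$Z_2^* = \frac{pN}{q(\gamma_2)+q(\mu)},\quad
Z_3^* = \frac{(1-p)N + Z_2^* q(\gamma_2)}{q(\gamma_3)+q(\mu)},\quad
Z_4^* = \frac{Z_3^* q(\gamma_3)}{q(\gamma_4)+q(\mu)},\quad
Z_5^* = \frac{Z_4^* q(\gamma_4)}{q(\gamma_5)+q(\mu)}.$$

`closed_form_equilibrium()` evaluates this directly;
`solve_equilibrium()` iterates `annual_step()` from the empty state until
the largest yearly change drops below $10^{-6}$ persons (cap 10,000
iterations; the update is a linear contraction, so convergence is geometric
and takes a few hundred iterations). The two agree to solver tolerance over
1,000 random parameter sets in the test suite. A transient mode
(`run_transient()`, or `predict()` on a fitted model) shows the build-up
from an empty population — relevant because imatinib and sunitinib only
entered use in 2001 and 2006, so a real 2010 snapshot sits somewhat below
equilibrium for the slow post-resection state.

```{r}
fit <- gist_model()
fit
round(fit$state, 1)
```

## Parameters

`default_parameter_table()` ships the seven-parameter configuration: base
value, standard error, min–max range for one-way sensitivity analysis, and
PSA distribution family.

```{r}
default_parameter_table()
```

Units: `incidence` per person-year; `p_resectable` a proportion; all other
parameters per-year rates. The population denominator defaults to the
mid-2010 UK estimate, 62,262,100. Two supporting computations mirror how
such a table is built from raw sources: `standardize_incidence()`
direct-standardizes age/sex-stratified registry counts onto a reference
population, and `weighted_background_mortality()` collapses an age-banded
life table under a patient age distribution. The weighting is done on the
rate scale ($-\ln(1-q)$), not the probability scale, because rates are what
the model adds to disease-exit rates; at these magnitudes the difference is
under 0.1%.

## Uncertainty analysis

**PSA.** All parameters are sampled independently (no correlation structure
is asserted by the inputs): gamma for the incidence, the transition rates
and background mortality; beta for the resectable proportion. Distributions
are method-of-moments matched to (base, SE) — `gamma_from_mean_se()`,
`beta_from_mean_se()` — the standard health-economics convention when only a
point estimate and standard error are available. Defaults: 5,000 draws, the
2.5th/97.5th percentile credibility interval (no smoothing or normal
approximation), and threshold probabilities as the fraction of draws below 2
and 50 per 100,000. Draws are bit-reproducible given the seed.

```{r}
psa <- run_psa(n_draws = 5000, seed = 1)
psa
```

**Scenario PSA convention.** Scenarios override the incidence
(1.5/100,000 p-y) and/or the third-line survival (median 1.5 years, entered
in years and converted). For the PSA around a scenario there are two
defensible conventions: pin the overridden parameters at their scenario
values and sample the rest, or keep them stochastic with the sampling mean
*recentred* at the scenario value. The package default is recentring, chosen
because the widths of the resulting scenario credibility intervals — in
particular the third-line intervals, which widen markedly when survival is
assumed longer — are only consistent with the overridden parameter remaining
stochastic; pinning it produces intervals roughly half as wide and scenario
threshold probabilities a factor of four smaller. `scenario_psa = "fix"`
selects the pinning convention.

**Tornado.** `one_way_sa()` moves one parameter at a time to its min and max
with the others at base, recording equilibrium third-line prevalence.
Incidence and third-line survival dominate; the imatinib and sunitinib
transition rates matter least (they shift *who* is in which upstream state
more than how many reach the third line).

```{r}
one_way_sa(gist_parameters())
```

## Threshold analysis

`threshold_incidence()` exploits the exact linearity of every equilibrium
count in $\Gamma$: the threshold is a single rescaling, verified by
re-evaluation (a bisection fallback agrees to $10^{-9}$ relative).
`threshold_thirdline_rate()` bisects on $\gamma_5$ (prevalence is continuous
and strictly decreasing in it) to $10^{-6}$ per-100,000, widening the
bracket automatically and failing explicitly — naming the attainable
supremum — if the target exceeds what $\gamma_5 \to 0$ allows. On direction:
third-line prevalence *exceeds* the boundary for exit rates at or **below**
the crossing, i.e. for median survival at or **above** the implied value;
the printed reports state this explicitly because the rate and the survival
move in opposite directions and are easy to misquote.

```{r}
threshold_incidence(gist_parameters())
threshold_thirdline_rate(gist_parameters())
```

## Synthetic fixtures

The registry extract and national life tables behind the default parameter
table are not redistributable, so the package generates synthetic stand-ins
(`generate_incidence_strata()`, `generate_life_table()`); both are labelled
synthetic and exist to exercise the standardization and weighting code, not
to add information. The incidence generator draws Poisson counts over fixed
person-years in nine 10-year age bands × two sexes, with a log-linear age
gradient (registry GIST incidence rises with age; the steepness is a config
knob since only the banding, not the gradient, is pinned down) calibrated so
the direct-standardized rate has expectation 1.053 per 100,000 person-years.
The life-table generator uses Gompertz-like mortality and an older-skewed
patient age distribution calibrated so the weighted mortality rate is
0.0314/yr. What these fixtures cannot show: real registries have
coding-uptake artefacts, unequal exposure across strata, and incidence/age
interactions by sex — passing tests on the synthetic fixtures validates the
arithmetic, not those data issues.

`random_parameter_set()` draws uniformly within the table's min–max box and
is the workhorse of the property tests.

## Numerical choices

- Equilibrium tolerance $10^{-6}$ persons, cap 10,000 iterations;
  non-convergence warns and is flagged, never silent.
- Bisection tolerances: $10^{-6}$ per-100,000 on the rate threshold,
  $10^{-12}$ on the incidence fallback; 200-iteration cap.
- The ultra-orphan comparison is strict (`< 2`), so a prevalence of exactly
  2.00 per 100,000 is *not* below the boundary.
- Degenerate inputs: zero SE or `family = "fixed"` collapses a parameter to
  a point mass; a beta SE with $se^2 \ge p(1-p)$, a unit annual mortality,
  and empty strata are rejected with errors.
- Problem sizes: the shipped analyses use 5,000 PSA draws; property tests
  use 1,000 random parameter sets for the equilibrium equivalence and
  $10^5$ draws for sampler moment recovery.

## Known limitations

- The equilibrium formulation reproduces external deterministic counts to
  within about 5%; the imatinib state is the most formulation-sensitive
  (inflow conventions for the two merged pathways can shift it by several
  percent). The additive/apportioned flag brackets this structural
  uncertainty only partially.
- Equilibrium overstates a calendar-year snapshot while treatment lines are
  still ramping up (see the transient mode).
- Independence of parameter draws is an assumption of convenience;
  correlated sampling is out of scope.
- The model pools prognostic subgroups (mitotic count, genotype) into single
  per-line rates, and excludes adjuvant/neoadjuvant use.
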
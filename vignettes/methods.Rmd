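---
title: "Valuing childhood lead exposure: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing childhood lead exposure: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadcost)
```

## The problem

Blood lead levels (BLLs) in children remain elevated across much of the
world, and childhood lead exposure damages cognitive ability. `leadcost`
converts country-level exposure summaries into an economic figure — the
share of lifetime earnings a young person can expect to lose, and the
annual dollar total across countries — using a human-capital
(cost-of-illness) approach. The focus on children aged 0–19 and on
cognition is deliberate: BLLs measured today are a better proxy for
cumulative exposure in children than in adults, and the cognition-to-
earnings link is the best-established channel for monetization. The result
is intentionally a conservative lower bound: behavioural effects, adult
cardiovascular disease, and returns for older and future cohorts are out of
scope.

## Exposure distributions from summary statistics

Country exposure data arrive as summaries, not microdata: a mean BLL with
an interval, and often the shares of children above 5 and 10 µg/dL. The
package represents the within-country BLL distribution parametrically:

* **degenerate** — a point mass at the mean. This is the baseline: the
  dose–response is evaluated at the country mean. It needs no distributional
  assumption and, because the default dose–response is concave, it
  *overstates* the loss relative to any spread-out distribution with the
  same mean (Jensen), so the baseline/log-normal gap is informative.
* **log-normal** — the standard right-skewed model for biomarker
  concentrations. Two fitters are provided, both closed-form:
  * from (mean *m*, exceedance *p* at threshold *t*): with
    *z = Φ⁻¹(1 − p)*, σ solves σ²/2 − zσ + ln(t/m) = 0 and
    μ = ln t − σz. The discriminant *z² + 2 ln(m/t)* is the feasibility
    margin; when it is negative no log-normal matches both summaries and
    the error message reports the admissible range of *p* for that mean.
  * from two exceedances (p₅, p₁₀): σ = (ln 10 − ln 5)/(z₁₀ − z₅),
    μ = ln 5 − σz₅.
* **normal** — provided for completeness; since BLL is non-negative the
  integration routines truncate at 0 and renormalize.

When the mean lies below the threshold the mean+exceedance quadratic has
two positive roots, i.e. two log-normals reproduce the same summaries. The
root policy is explicit: `smaller_sigma` (default for a bare fit — the less
dispersed, conservative choice under a concave dose–response),
`larger_sigma`, or `match_second_exceedance`, which picks the root whose
implied share above 10 µg/dL best matches the observed one. The `log-normal`
scenario uses `match_second_exceedance` whenever the second share is
available, since it resolves the ambiguity with data rather than
convention; every fit's chosen root and feasibility margin are written to
the run log.

Tail probabilities and quantiles are computed with the upper-tail forms of
`pnorm()`/`qnorm()` rather than `1 - p` arithmetic; this matters in the far
tail, where the complement loses about five significant digits and would
spoil the 1e-8 round-trip accuracy the fitters otherwise achieve.

## Dose–response

The IQ loss function `f` is pure configuration with three forms — linear,
log-linear `c·ln(1 + b)`, and piecewise linear — all continuous,
non-decreasing and zero at and below an optional no-effect threshold. The
default transcribes the concave pooled-analysis shape of the lead–IQ
literature: a loss of roughly 6.9 IQ points over the 2.4→30 µg/dL range
implies about 2.73 points per log-unit, so the central variant is
`2.73·ln(1 + b)` with no threshold. The `lower_bound` variant uses the
bottom of the pooled range (0.95 per log-unit) with a 2 µg/dL threshold.
Both are implementer-supplied encodings, visible and overridable in the
config file: the engine itself never hard-codes a coefficient. The `ln(1+b)`
form (rather than `ln b`) keeps the function finite and zero at zero
exposure.

The per-country quantity is the mean loss E[f(BLL)]. For a log-normal
exposure this is ∫f(e^{μ+σx})φ(x)dx, computed by Gauss–Hermite quadrature
in the log domain — the natural scheme because the weight is exactly the
standard normal density. The default is 128 nodes, doubled until two
successive estimates agree to a relative 1e-9 (ceiling 1024 nodes, with an
error raised if even that fails). For the smooth default integrands the
first doubling already agrees to near machine precision; the adaptive check
guards user-supplied piecewise forms, whose kinks slow convergence.
Truncated-normal expectations use adaptive quadrature on
[0, location + 12·scale].

## Monetization

Relative cost in percent: `min(cap, 100 · E[f] · e_us · ret_edu/r_us)`.
Parameters, with defaults:

| parameter | meaning | default | units |
|---|---|---|---|
| `e_us` | US lifetime-earnings loss per IQ point | 0.02 | fraction/IQ point |
| `r_us` | US returns to education | 0.10 | fraction/school year |
| `ret_edu` | country returns to education | data column | fraction/school year |
| `cap_pct` | ceiling on relative cost | 100 | percent |

The returns-to-education ratio is applied multiplicatively to `e_us` — the
most literal reading of "relative returns to cognitive skills" — and the
cap encodes that foregone earnings cannot exceed earnings. `e_us = 0.02`
and `r_us = 0.10` are round central values from the public EPA-style
valuation and Mincerian-returns literatures; they are deliberately
config-visible because the underlying sources quote ranges, not a single
number. Absolute cost is `rel/100 · gdp_pc · pop_0_19` (constant 2021
international dollars per year), summed for the global total. Continent
means are population-weighted by default (an unweighted switch exists and
the choice is recorded in every run manifest), since an unweighted mean
lets microstates dominate a continent row.

## Scenarios

The seven-column suite varies the inputs and assumptions of the exposure
and dose–response steps, never the final costs directly:

* `baseline` — degenerate at the mean. Treating the distributional
  integration (`log-normal`) as the deviation, not the baseline, follows
  from the suite's own structure: a sensitivity column labelled "log-normal" is
  only informative if the main estimate is something else.
* `lower_ci` / `upper_ci` — degenerate at the interval bounds (input-data
  variation).
* `increase_5` / `increase_10` — the BLL location multiplied by 1.05/1.10
  *before* the distribution and dose–response are applied; under a concave
  `f` this is not the same as inflating costs by 5%.
* `lower_bound` — the lower-bound dose–response variant above.

With a non-decreasing dose–response these definitions force
cost(lower_ci) ≤ cost(baseline) ≤ cost(upper_ci) and
cost(baseline) ≤ cost(+5%) ≤ cost(+10%) for every country — an invariant
the test suite checks across 100 random worlds.

## The synthetic world

`generate_countries()` emulates the structure the pipeline assumes: 199
countries (the size of a global exposure table), log-normal within-country
BLL distributions with country means log-normally dispersed around
3 µg/dL (clamped to 0.5–20 µg/dL, giving the right-skewed cross-country
pattern in which a minority of countries carries most of the exposure),
σ ∈ [0.4, 0.9], GDP per capita log-normal around $15,000 PPP, populations
0–19 log-normal around 3 million, returns to education uniform on 5–15%,
and interval bounds at mean ± 20%. These are one-time choices of plausible
magnitudes for a global panel, stated here and not tuned thereafter.

Emitted summaries are *analytic* functions of the true (μ, σ) — mean
= exp(μ + σ²/2), exceedances from the normal CDF — so fit-recovery tests
measure numerical error only; a separate noisy mode adds bounded relative
perturbation for robustness tests. `truth_costs()` values the truth through
an independent path (closed form for linear dose–response, fixed-seed
Monte Carlo otherwise) that shares no code with the quadrature engine.

What passing tests show — and do not show. End-to-end recovery on the
synthetic world demonstrates that the pipeline's fitting, integration and
aggregation are numerically correct *when the data really are log-normal
summaries with consistent exceedances*. Real exposure tables carry
measurement error, inconsistent summaries (a mean and exceedance no
log-normal can reconcile — handled by the two-exceedance fallback, but the
answer then depends on which summaries you trust), age aggregation, and
model error in the log-normal family itself. None of that is validated
here, and the published-scale totals depend on pinned external inputs
(exposure estimates, GDP, population, returns data) this package does not
ship.

## Numerical and degenerate-input choices

* Strict exceedance (P(BLL > t)): a point mass exactly at the threshold
  does not exceed it.
* Zero BLL is valid everywhere and yields exactly zero loss and cost —
  checked as an invariant, not an approximation.
* Exceedance shares of exactly 0 or 1 cannot be fitted (the quantile is
  infinite); the fitters reject them, and scenario code treats them as
  absent data rather than fabricating a distribution.
* Interval bounds equal to the mean are allowed (`lower_ci`/`upper_ci`
  then coincide with baseline).
* Optional columns are absent-as-`NA`, never 0: a zero exceedance is a
  meaningful observation.
* Results CSVs are written at full double precision; the round-trip
  guarantee is ≥ 10 significant digits.

## Problem sizes used in the test suite

Parameterized checks run at sizes chosen to exercise the mathematics, not
the hardware: 1000 random parameter sets for fit round-trips, a 10⁷-draw
Monte Carlo oracle for the quadrature cross-check, one 199-country world
(10⁶ Monte-Carlo draws per country in the truth path) for end-to-end
recovery, and 100 random 20-country worlds for the scenario-ordering
invariant. The whole suite completes in well under two minutes on a single
core.

## Known limitations

* No discounting or cohort projection: the total is an annual flow for the
  current 0–19 cohort only.
* No uncertainty propagation beyond the named scenarios; interval bounds
  enter as alternative point inputs, not as posteriors.
* The returns-to-education scaling is a proxy, and its multiplicative form
  is one defensible reading among several.
* Cartography is out of scope: `cmd_report()` emits a map-joinable table
  (`iso3`, `relative_cost_pct`) rather than rendering maps.
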
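---
title: "Methods: the aspirin primary-prevention Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the aspirin primary-prevention Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the decision model: what is
simulated, which conventions were chosen where several were defensible,
and what the tests do and do not establish.

## The decision problem

A hypothetical cohort of 60-year-old Chinese patients with type 2 diabetes
and no history of cardiovascular disease either takes low-dose aspirin
(100 mg daily) for life or does not. Aspirin shifts the odds of four
annual events — nonfatal myocardial infarction (MI), nonfatal stroke,
gastrointestinal (GI) bleeding, and all-cause death — and carries a drug
cost and a small taking-a-pill disutility. Outcomes are direct medical
costs (2019 USD, healthcare-system perspective) and quality-adjusted
life-years (QALYs), both discounted at 3% per year, accumulated over a
40-year horizon in yearly cycles.

## States and transitions

Five health states: *well*, *post-GI-bleeding*, *post-MI*, *post-stroke*,
*dead* (absorbing). Internally the engine uses seven compartments because
two kinds of duration dependence need one-cycle tunnels:

- entry into post-MI or post-stroke carries an elevated first-year
  mortality (0.188 and 0.144) before settling at the chronic annual
  mortality (0.07);
- post-GI-bleeding lasts exactly one year: the 3% case fatality is applied
  at the event itself, survivors spend one year off aspirin facing
  background mortality only, then return to *well*.

From *well*, the yearly event probabilities are the constant annual rates
converted by `p = 1 − exp(−r)` and treated as mutually exclusive competing
risks together with background age-specific mortality (a six-band life
table, 0.0133 at 60–64 rising to 0.2263 at 85+, with the last band open);
the remainder stays well. Recurrent events are not modelled: post-event
patients remain in their state until death.

## Strategy effects and the conventions behind them

Under aspirin every event probability is transformed **on the odds
scale**, `p₁ = OR·o/(1+OR·o)` with `o = p₀/(1−p₀)`. Odds ratios are what
the sources report; at these baseline risks the odds and risk-ratio
readings differ by well under 2%, but the odds-scale choice is exact to
the cited statistic.

Three semantics are not derivable from the model diagram alone; the
package resolves them as follows and the choices are pinned down by the
published totals that the acceptance suite checks:

1. **The all-cause-death odds ratio is 0.98** (95% CI 0.93–1.04), the
   diabetes-subgroup estimate of the source meta-analysis. The published
   input table also circulates a trials-restricted alternative (0.94 with
   range 0.85–1.04); the published base-case results, validation table and
   threshold analysis are only consistent with 0.98, so the fixture
   carries base 0.98 with the published sampling range.
2. **The death odds ratio applies wherever patients are on aspirin**: to
   background mortality in *well* and to the post-MI/post-stroke
   mortalities (the yearly management costs of those states explicitly
   include aspirin), but not in the post-GI-bleeding year, where aspirin
   is discontinued.
3. **Discontinuation (30%) gates costs, not effects.** The odds ratios
   come from intention-to-treat trial results that already embed
   non-adherence, so effectiveness is not reduced again. The drug cost is
   accrued by the adherent 70% of the well state. The taking-aspirin
   disutility (0.001) is charged to the whole well-state cohort — the
   published no-disutility scenario implies an ungated disutility while
   the published incremental cost implies a gated drug cost, and the
   package follows that arithmetic.

## Reward accounting

Costs and QALYs for cycle *k* (0-based) are computed on the **end-of-cycle
state occupancy** and discounted by `(1+0.03)^−k`; no half-cycle
correction is applied. One-time quantities — event costs for MI (4,346),
stroke (1,508) and GI bleeding (3,443, charged for all incident bleeds
including the fatal 3%, since the hospitalization occurs), and the
GI-bleed QALY decrement `0.25 × 15/365` — are charged in the cycle of
incidence at that cycle's discount factor. State rewards: utility 0.876
in *well* and the post-bleed year, 0.876−0.139 post-MI, 0.876−0.215
post-stroke; yearly management costs 500 (post-MI) and 556 (post-stroke)
for state occupants, with no separate drug cost there. End-of-cycle
counting was chosen over start-of-cycle because it reproduces the
published lifetime totals (start-of-cycle counting credits everyone alive
at a cycle's start with a full year and inflates discounted life-years by
about 5%); the difference nets out almost entirely in the increments.

## Validation

`validate_events()` accumulates undiscounted incident events over the
first seven cycles as a fraction of the initial cohort (the trial's mean
follow-up was 7.4 years; seven whole cycles is the closest the yearly
model can come) and takes all-cause death as the dead-state occupancy
after seven cycles, GI-bleed deaths included. The GI-bleeding and stroke
cells agree with the trial within ±10%. The MI and death cells do not:
the published validation table can be shown to mix conventions (its death
column equals the bare life-table product with no event-related excess
deaths, and its MI column matches a per-survivor denominator), so no
single honest accounting reproduces all eight of its cells. The
acceptance suite asserts the published ±10% claim as stated and the two
failing families are documented rather than patched.

## Sensitivity analyses

*One-way*: every non-fixed parameter is set to its range ends in turn.
Tornado ordering uses the span of incremental net monetary benefit at the
30,000 USD/QALY threshold, which remains defined where the ICER is
undefined or negative (dominance). The base object is never mutated
(copy-on-write), which the tests check for state leakage.

*Threshold*: bisection on the death odds ratio over [0.85, 1.10] to an
absolute tolerance of 1e−4 (the published threshold has three decimals),
locating both the ICER-crosses-WTP point and the dominance onset
(ΔQALY = 0). With an infinite WTP the two coincide, which is tested.

*Scenarios*: the no-disutility scenario sets the taking-aspirin
disutility to zero; its QALY shift must equal the removed disutility
times the discounted well-state exposure, and the tests verify that
identity against an engine rerun. The adjusting-factor scan multiplies
all four clinical event rates simultaneously — MI, stroke and GI bleeding
on the rate scale before probability conversion, background mortality on
the odds scale — over 0.5–2, emulating lower- and higher-risk (older)
cohorts; post-event transition mortalities are deliberately not scaled
(they are conditional prognosis parameters, not incidence). Factors large
enough to push a cycle's outgoing probabilities above 1 raise an error.

## Probabilistic sensitivity analysis

Published ranges are read as 95% intervals (z-width 3.92). Fitting
conventions, per family:

- **beta** (rates, probabilities): method of moments with mean at the
  base value and sd `(high−low)/3.92`; infeasible moments
  (`sd² ≥ m(1−m)`) are an error;
- **lognormal** (odds ratios, costs): median at the base value, log-sd
  `(ln high − ln low)/3.92` — the conventional parameterization for point
  estimates with asymmetric CIs;
- **uniform** (utilities, disutilities, hospitalization days): on
  `[low, high]`. Note the diabetes utility (base 0.876, range 0.701–1) is
  *not* centred on its base, so PSA mean QALYs sit about 3% below the
  base case by construction.

Parameters are drawn independently (only marginal distributions are
published); the adjusting factor and the mortality table are held fixed
(no distribution is given for them). Draws producing an invalid parameter
set would be redrawn and counted, but with the packaged ranges this never
occurs. The default run is 10,000 draws; each draw runs both strategies
through the cohort engine. CEAC probabilities use the highest net
monetary benefit per draw (ties to the comparator); the CE-plane is
reported as four fractions (dominant; more QALYs with ICER ≤ WTP; more
QALYs with ICER > WTP; fewer QALYs); 95% CIs are percentile-based on the
ranked per-draw differences; EVPI is `E[max NMB] − max E[NMB]`,
non-negative by construction.

Reproducibility: one seed set once before the draw matrix; the whole
result object is a pure function of (parameters, n_sims, seed).

The PSA's dispersion is wider than the published one: sampling the death
odds ratio from its published range width while honouring the
model's own threshold geometry (cost-effectiveness lost around OR ≈ 1.00)
yields a ΔQALY spread larger than the published interval
(−0.167, 0.286), which is itself narrower than any distribution fit of
the published ranges can produce. The probability-cost-effective and mean
ΔQALY land close to the published values; the published mean incremental
cost (352 USD, 32% above its own base case) and EVPI (744 USD) are not
reachable by independent sampling of the published inputs, and the
acceptance suite reports those misses rather than recalibrating toward
them.

## The random-parameter generator and the microsimulation

`random_parameter_set()` draws each non-fixed parameter uniformly within
its range — not from the PSA distributions — purely to generate valid,
diverse inputs for property tests. It emulates the plausible input space,
not any population: passing tests on these draws shows the engine's
invariants (conservation, absorbing death, monotonicity, microsimulation
agreement) hold across the input region, and nothing about real patients.

`microsim_oracle()` simulates individual patients through the same
transition probabilities and reward rules by sampling, sharing only the
per-cycle probability constructor with the cohort engine. Agreement
within Monte Carlo error (tested at 50,000 patients on the fixture and
10,000–20,000 on random inputs, with 3–4 SE bands sized to the number of
comparisons) checks the cohort recursion, reward wiring and discounting;
it cannot detect an error made identically in both implementations'
shared probability inputs.

## Numerical choices and degenerate inputs

- Occupancy conservation is enforced in tests at 1e−10; CEAC/quadrant
  normalization at 1e−12 (both are exact up to floating-point error).
- A zero discount rate makes discounted and undiscounted totals
  identical; a zero-risk parameter set (all rates and mortality zero)
  keeps the cohort 100% well and gives the closed-form annuity
  `0.876 × Σ 1.03^−k`, both used as exact test oracles.
- ICERs are reported only when ΔQALY ≠ 0; at ΔQALY = 0 preference falls
  back to cost, and a full tie goes to no-aspirin (no-intervention
  default). An ICER exactly at the WTP counts as cost-effective.
- Bisection assumes one sign change per bracket, which holds because the
  incremental NMB and ΔQALY are strictly monotone in the death odds ratio
  on the search interval; absent a sign change the threshold is reported
  as missing rather than extrapolated.
- Problem sizes (10,000 PSA draws, 50,000-patient fixture
  microsimulation, 200-draw property sweeps) were chosen so the whole
  suite runs in a few minutes on one core while keeping Monte Carlo
  standard errors well inside the asserted tolerances.

## Limitations

Constant annual event rates understate the age growth of ischemic and
bleeding risk (the adjusting-factor scan probes exactly this); transient
ischemic attack, cancer outcomes, and recurrent MI/stroke are outside the
state space; chronic post-event mortality is a flat 0.07, which beyond
age 84 is *lower* than background mortality — a structural simplification
inherited from the source inputs; indirect (societal) costs are excluded;
and all parameter draws are independent, so any real correlation between,
say, event rates and case fatality is ignored.
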
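---
title: "A decision-tree and Markov cohort model for BRCA1/2 testing with cascade screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree and Markov cohort model for BRCA1/2 testing with cascade screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brcacea` models the health economics of offering germline *BRCA1/2* testing
to high-risk breast-cancer patients, and targeted cascade testing to
first-degree relatives of carriers, in a resource-limited national health
system. This vignette is the package's own account of the model: its
structure, its assumptions, the numerical conventions it adopts where the
inputs under-determine the wiring, and what the results do and do not show.

```{r setup}
library(brcacea)
ps <- default_parameters()
ps
```

## The decision problem

Two strategies are compared from a societal, lifetime perspective:

* **Testing** — next-generation sequencing (NGS, \$666.88) for every
  eligible proband; carriers of a pathogenic/likely-pathogenic (P/LP)
  variant are counselled and, within a year, take up intensified
  surveillance, both risk-reducing mastectomy and salpingo-oophorectomy
  (RRM + RRSO), RRM only, or RRSO only. Relatives of carriers are offered
  targeted-variant testing (\$78.13).
* **No testing** — carriers remain undiagnosed and follow untreated
  natural history.

A decision tree converts each strategy into a probability allocation over
six management groups: M1 (carrier, intensified surveillance), M2 (both
surgeries), M3 (RRM only), M4 (RRSO only), M5 (non-carrier or variant of
uncertain significance), and M6 (undiagnosed carrier). VUS results carry
no management consequence and are pooled with M5; the VUS rate is retained
as a parameter so probabilistic analyses can perturb it, but in the base
case it affects nothing downstream. Testing redistributes carriers across
M1–M4 versus M6 but never changes carrier prevalence — an invariant the
test suite checks on random parameter draws.

```{r}
allocate_proband("testing", param_values(ps))
allocate_family("testing", param_values(ps))
```

## Markov model

Each group then runs through an annual-cycle Markov cohort model from
entry age 45 to a terminal age of 100 (56 cycles): states `Well`, active
breast cancer (`BC`), post-breast cancer (`PostBC`), metastatic breast
cancer (`MetBC`), ovarian cancer (`OC`, `PostOC`, `MetOC`), combined
breast + ovarian cancer (`BrOv`), and absorbing `Death`. Probands enter at
breast-cancer diagnosis (`BC`, year 1); family members enter `Well`.
Active `BC`/`OC` last exactly one treatment year before the post state
unless the cohort dies or progresses.

Recurrence and mortality vary with time since diagnosis, so each cancer
state carries a tunnel clock (1–16, saturating in the top band). Two
conventions matter:

* **Band values are within-band cumulative risks.** The published
  follow-up probabilities ("recurrence in 1–5 yr" 0.2432, "mortality in
  the 2–3 year" 0.1391, ...) are converted to per-cycle probabilities as
  $1-(1-q)^{1/w}$ for a band of width $w$ (open-ended top bands are
  treated as five-year blocks). Read instead as raw annual probabilities
  they would imply five-year survival near 50%, far below the survival
  curves such studies report.
* **Every new cancer event restarts the clock.** A recurrence is a new
  active cancer: the year of recurrence faces the first-year mortality
  band, and the survival curve restarts. Metastatic progression likewise
  enters `MetBC`/`MetOC` at clock 1.

### Where prevention acts

Each group's strategy-specific annual incidences (e.g. breast 0.0364 /
ovarian 0.0128 under intensified surveillance; 0.0037 / 0.0018 after both
surgeries) apply wherever a *new* primary can arise:

* from `Well` (family members) directly;
* from breast-history states, the group ovarian incidence adds to the
  sporadic ovarian-in-breast-patient rate (0.0007) while the ovaries are
  intact; after RRSO the group's post-surgical rate stands alone;
* from post-breast states, the group breast incidence adds
  contralateral/new-primary risk on top of the banded recurrence while
  breast tissue is intact; after RRM the literature post-RRM rate *is* the
  whole breast-event hazard — there is no tissue left for the recurrence
  band to act on.

This is the mechanism by which testing buys health: surgery groups
accumulate fewer new cancer events, each of which otherwise restarts a
high-mortality, high-cost episode.

### Mortality construction

The published combined-state (breast + ovarian) mortality values
(0.0195 in years 1–5, 0.0069 after) are treated as *excess* hazards added
to the banded cancer-survival curve. Taken alone they would place the
combined state far below post-breast mortality, making a second cancer
protective — in early prototypes the testing arm *lost* QALYs through
exactly this inversion. The same construction covers the ovarian-only
states, whose mortality the input table does not list separately; all
ovarian-side defaults are ordinary named parameters (`mort_oc_1_5`,
`mort_oc_6p`, `p_met_oc`) and can be revised in the configuration.

There is no background (non-cancer) mortality: cohorts die only through
cancer states. This follows the published parameter set, which lists
none, and inflates late-life state occupancy for everyone equally; a life
table hook would lower absolute QALYs (family members especially) but
barely moves the strategy deltas, which is what the comparison rests on.

### Costs and utilities

Cycle-start accounting with annual discounting at 3% for both costs and
outcomes (cycle 0 undiscounted), no half-cycle correction. Per cycle,
occupancy is charged:

* **annually**: outpatient care, the recurring out-of-pocket items
  (supplements, caregiver, private clinic), and direct non-medical
  per-visit costs (transport, meals, accommodation, a family member's
  opportunity cost) annualised at 12 visits/year in active-cancer states,
  4 in post states, 1 in `Well`;
* **on state entry**: inpatient care (an admission episode — charging the
  printed per-state annual inpatient figures to disease-free survivors
  every year for decades would make `PostBC` alone cost more per lifetime
  than the published totals for the whole strategy) and the first-year
  supportive-equipment/renovation items;
* **once at cycle 0**: the NGS panel (testing-arm probands), the targeted
  test weighted by uptake (testing-arm relatives), and the risk-reducing
  surgery fees (RRM \$1,239, RRSO \$631; M2 pays both).

Utilities are the interviewed EQ-5D-5L values per state (0.71–0.90), zero
for `Death`.

```{r}
run_base_case(ps, "proband")
run_base_case(ps, "family")
```

## Parameters, sampling, and sensitivity analyses

Every input is a `(mean, SE, family, role)` record. Probabilities and
utilities sample from Beta distributions matched exactly to mean and
variance ($\alpha = m(m(1-m)/se^2 - 1)$, $\beta$ analogous); costs from
Gamma ($k = m^2/se^2$, $\theta = se^2/m$ — shapes below 1 arise for the
heavy-tailed interview items and are valid). Degenerate rows (SE 0) stay
fixed; a Beta row with infeasible variance falls back to its mean with a
warning rather than aborting a full-set run. The three surgery uptakes
are drawn independently and rescaled proportionally in the rare draw
whose sum exceeds 1.

The PSA (`psa()`, default 2,000 iterations, single seed) reruns the whole
pipeline per draw; `ceac()` reports the fraction of draws with positive
incremental net monetary benefit, $\lambda \cdot \Delta QALY - \Delta
cost$, across willingness-to-pay values.

One-way analysis (`owsa()`) moves one parameter at a time to its range
ends. Probabilities and utilities use mean ± 1.96 SE clipped to [0, 1].
Costs use mean ± 25%: most interview cost SEs exceed their means, so a
normal-approximation interval would clip to
$[0, \sim\!3.6\times\text{mean}]$ and the tornado would only rank the
size of the SEs; ± 25% is the usual health-technology-assessment
convention for such items. Explicit per-parameter ranges override either
default. The outcome discount rate is varied over 0–6%.

## Budget impact

The five-year national projection compares no-testing with
testing-plus-prevention for the population the programme can actually
reach: 6,648 new high-risk patients per year (22,158 × 30%, ceiling) on
top of a 22,932-patient prevalent backlog, tested at the national
sequencing throughput of 3,500 samples in year 1 growing 55% annually and
capped by the remaining pool. Detected carriers (1,237/year at full
coverage) trigger cascade testing: 406 positive relatives in year 1,
scaling with the testing volume. Testing is charged in the year performed;
each year's tested cohort then accrues its strategy arm's undiscounted
per-person cost stream (nominal accounting, the budget-impact convention).
The budget impact is the strategy difference by year. The testing-outlay
lines reproduce the published arithmetic exactly; the care-cost lines are
the model's own streams, which are far larger than the published care
rows — those rows are not recoverable from the published per-state costs
under any accounting we could construct, and the package reports what its
own Markov streams imply.

```{r}
annual_budget(budget_epidemiology(), ps)
```

## Synthetic interview microdata

`synth_design()` / `generate_interviews()` emulate the 264-person
interview survey that produced the cost and utility inputs: for each of
the eight health states, the utility and the outpatient, inpatient,
first-year and recurring cost items are treated as true Beta/Gamma
distributions (moment-matched from the published mean/SE) and sampled
per subject. `estimate_parameters()` recovers means and standard errors
(SD/√n) and `update_parameters()` feeds them back into a parameter set,
closing the loop: generate → estimate → rerun.

The generator draws each quantity independently — it does not model the
within-subject correlation, zero-inflation, or visit-count structure real
interview data would show, nor EQ-5D-5L dimension-level scoring
(utilities are simulated directly on [0, 1]). Recovery tests therefore
demonstrate that the estimation stage is unbiased and that conclusions
are stable under resampling of inputs of this magnitude — not that the
original survey was adequate.

## Numerical choices and problem sizes

The expanded state space is 114 states (7 clocked states × 16 years +
`Well` + `Death`); a lifetime run is 55 vector–matrix products and takes
a few milliseconds, so the default analyses are exact cohort traces, not
approximations. Mass conservation holds to 1e-10 per cycle and `Death`
is monotone (both property-tested). The engine's independent oracle is a
count-level microsimulation of 100,000 walkers through the same
transition matrix, which must agree with the trace within three binomial
standard errors per state per cycle. Default problem sizes: 56-cycle
horizon, 2,000 PSA iterations, 500 interview records per state in
recovery tests, 100,000 walkers in the oracle.

## Known limitations

* The published model wiring is only partially recoverable; the
  conventions above are this package's documented reconstruction. The
  strategy *deltas* (QALY gain with testing, cost-saving cascade testing,
  ICER an order of magnitude below the \$5,000/QALY threshold) are robust
  across every wiring variant we examined, but absolute lifetime cost and
  QALY levels are not, and the package's levels differ from the published
  ones (which are themselves mutually inconsistent — no survival model
  can hold the published family QALY of 9.98 together with a 0.89 `Well`
  utility and a lifetime horizon from age 45).
* No background mortality, no age-dependent cancer incidence, no
  individual-level heterogeneity beyond the M1–M6 mixture, no
  reclassification pathway for VUS results, and no PARP-inhibitor or
  chemoprevention arms.
* Currency is 2021 USD throughout (32 THB/USD); no inflation adjustment.
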
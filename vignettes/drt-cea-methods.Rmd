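---
title: "Methods: a Markov model for the cost-effectiveness of pretreatment HIV drug-resistance testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov model for the cost-effectiveness of pretreatment HIV drug-resistance testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Since dolutegravir (DTG)-based regimens became the recommended first line
for people living with HIV (PLHIV), genotypic drug-resistance testing (DRT)
before treatment initiation is no longer routinely recommended: transmitted
resistance to integrase inhibitors is rare, and a test costs real money in
settings with constrained budgets. `drtcea` implements a decision model
that quantifies this trade-off for a low-to-middle-income setting: it
compares **testing every newly diagnosed person before treatment** (`TEST`)
against **empiric DTG initiation** (`NO_TEST`), in discounted USD and
quality-adjusted life years (QALYs), over a 40-year horizon.

## Model structure

Three clinical states — HIV stage, AIDS stage, death — evolve in annual
cycles. The engine expands them into an extended space that also tracks:

* **treatment state**: suppressed or failed on the first line (`S1`/`F1`),
  suppressed or failed on the second line (`S2`/`F2`);
* **first-line regimen** (DTG, or PI after an adverse-event switch);
* **transmitted resistance class** (none, NRTI, PI, INSTI);
* **opportunistic infection (OI)**, a within-cycle flag for AIDS-stage
  occupants.

Stage transitions come from a 16-row table (4 clinical contexts x 4 age
bands). The age bands start at 35–44; diagnosis ages start at 27, and ages
below 35 use the youngest band because no younger stratum is published.
The AIDS-with-OI rows embody roughly double the no-OI mortality
(0.14/0.16/0.22/0.32 vs 0.07/0.08/0.11/0.16); the separate 2.1x OI
mortality multiplier in the registry is applied only if a user supplies
custom AIDS rows without OI counterparts.

### Decision rules

* `TEST`: the test (1,181.14 USD, Sanger) is charged once at entry.
  Everyone starts DTG with the "tested" suppression probability (0.93)
  except people with transmitted INSTI resistance, who start a PI-based
  regimen (0.83).
* `NO_TEST`: everyone starts DTG; the suppression probability is governed
  by the true, unknown resistance class (none 0.93, NRTI 0.82, PI 0.93,
  INSTI 0.35).
* **Adverse events**: a one-shot 5% probability of DTG intolerance in the
  first cycle forces a switch to the PI line (informed effectiveness 0.83
  in `TEST`; class-specific in `NO_TEST`). The published input is a single
  probability, not an annual rate, so the event is modeled as first-cycle
  only.
* **Failure**: in *both* arms a first-line failure triggers a resistance
  test (same cost) and a switch to the PI line one cycle after the
  failure. An acquired-resistance class is drawn at the switch
  (NRTI 34%, PI 9%, INSTI 1%); the cohort engine uses the expectation over
  classes (0.7494 with the baseline inputs), the microsimulation draws a
  class. A failure of the second line is persistent: no third line is
  modeled.

### Suppression dynamics: a deliberate, conservative choice

Effectiveness values are *annual probabilities of viral suppression*. The
model evaluates them **once, at regimen initiation**: a suppressed person
stays suppressed on that regimen, a failing person remains failed until
the single permitted switch. The alternative — re-drawing suppression each
year — compounds effectiveness differences over 40 cycles and produces
much larger incremental QALYs. Because the published inputs do not state a
re-suppression or late-failure rate, the one-shot reading is the
assumption this package commits to. Consequences:

* the incremental QALY of testing is small (about 0.0014 at baseline) and
  the baseline ICER is far above the willingness-to-pay threshold;
* analyses that re-evaluate suppression annually (as some decision-tree
  software effectively does) will report several-fold larger QALY gains at
  a similar incremental cost. The package therefore promises the
  *direction and decision* of the comparison, not any externally printed
  absolute totals — indeed a 40-cycle annuity at utility 0.76 and 3%
  discounting caps the achievable discounted QALY total at 18.09, below
  some published totals for comparable models, so exact replication is not
  a meaningful target.

### Event order within a cycle

Adverse-event check (cycle 0 only) → failure-triggered switch (if failed
in a previous cycle) → OI draw (AIDS occupants) → reward accrual → stage
transition. OI status is redrawn every cycle (incidence is published per
suppression status; no carry-over information exists). A first-line
failure accrues the failed-context transition row in its failure cycle;
the switch takes effect the following cycle.

## Rewards and discounting

Utilities: HIV 0.76, AIDS without OI 0.67, AIDS with OI 0.58, death 0
QALY/year. Costs attach per regimen and stage, with separate first-year
(post-diagnosis) and subsequent-year rows; "first year" means the first
*model* cycle, not the first year of each new regimen. Death costs
nothing. Rewards are state-membership rewards credited at the start of
each cycle; cycle `t` is discounted by `(1+r)^-t` with `r = 0.03`, cycle 0
undiscounted. No half-cycle correction is applied by default (the
convention of the original analysis is unknown); `half_cycle = TRUE`
applies the standard correction (half weight on the first cycle plus a
discounted terminal half-cycle) to membership rewards only — one-time
test costs are events, never halved.

## The synthetic cohort and the microsimulation

`generate_cohort()` emulates the stated entry population of 1,000
hypothetical PLHIV: ages uniform on 27–45 (the published mean-age range;
mean 36 by symmetry — a truncated-normal alternative was considered and
rejected because no dispersion parameter is published), diagnosis stage
Bernoulli (17.7% AIDS), transmitted resistance NRTI 3%, PI 0.1%, INSTI
0.1% (the 0.1% values are the published floor substituted for point
estimates of zero). Each individual owns a random stream derived from
(master seed, id), so cohorts are prefix-stable under growth and the two
arms share random numbers when simulated from the same master seed
(common random numbers; the suite verifies the variance reduction).

The cohort engine and the microsimulation implement the same stochastic
process, so their means agree; the suite checks this at n = 10^5 within 3
Monte-Carlo standard errors. The engine fixes the start age at the cohort
mean (36) by design, so the equivalence check fixes the microsim ages
there too — with the full age spread, band-crossing times differ
nonlinearly in age and introduce a real (small, ~0.05 QALY) difference
that is a feature of the age distribution, not an engine discrepancy.

What a green suite does **not** establish: that the model reproduces any
real cohort's outcomes. All inputs are literature constants; the
synthetic cohort has no correlation structure (age, stage and resistance
are independent), no calendar-time effects, no loss to follow-up.

## Economic analysis

`icer()` computes `(C_TEST - C_NO_TEST) / (E_TEST - E_NO_TEST)`.
Degenerate quadrants (dominance, zero effect difference) are returned as
classifications rather than signed infinities, because tornado analyses
routinely cross them. The willingness-to-pay threshold is
`3 x GDP per capita = 3 x 2,746.4 = 8,239.2` USD/QALY; net monetary
benefit `wtp x E - C` gives the same decision whenever the incremental
effect is positive.

## Sensitivity analyses

* **Ranges.** Where a published range exists (effectiveness values,
  prevalences) it is used as printed. Utilities, OI probabilities, the
  adverse-event probability and the scalar transition probabilities have
  no published ranges and default to ±20% of the point value (clipped to
  [0,1]); costs have no ranges and default to a Gamma SD of 20% of the
  mean. Both conventions are registry entries, not hard-coded.
* **Distributions.** Beta for probabilities and utilities, Gamma for
  costs. A range is read as a 95% interval, `SD = (high - low)/3.92`;
  Beta shapes by method of moments (`alpha = m(m(1-m)/v - 1)`), Gamma by
  `shape = (m/sd)^2, scale = sd^2/m`. Infeasible Beta variances collapse
  to a fixed (degenerate) spec.
* **One-way DSA** re-runs both arms at each parameter's low and high,
  holding the rest at baseline; entries are sorted by ICER spread (an
  incremental-NMB metric is available because the ICER is unstable across
  dominance quadrants). Ties are ordered by parameter name.
* **PSA** (default 10,000 draws, seeded) samples every registry
  distribution, rebuilds the parameter set — scalar transition draws
  rewrite their table column and `p_remain` absorbs the change; a row
  driven infeasible is renormalized and counted, with >1% of draws an
  error — and runs both arms through the deterministic engine. The CEAC
  reports, per threshold, the fraction of draws with positive incremental
  NMB (default grid 0–100,000 USD/QALY by 1,000).
* Transition sampling is limited to the named scalar probabilities
  (HIV→AIDS by suppression status, AIDS→HIV); the 16 band-specific death
  probabilities have neither published ranges nor an obvious joint
  structure, and perturbing them independently would dominate the tornado
  with invented uncertainty.

## Numerical conventions and degenerate inputs

* Transition rows must sum to 1 within 1e-9; the shipped table satisfies
  this exactly as printed.
* Validation returns violations as data (a report), never exceptions;
  loading a config validates and names the offending parameter.
* Overriding a point value outside its recorded uncertainty range widens
  the range to keep `low <= point <= high` invariant.
* One published cost row carries an extra digit (5,195.051); the registry
  stores 5,195.05.
* Probabilities at band boundaries: ages in [45,55) map to 45–54, etc.;
  ages above the table clamp to 65+.

## Known limitations

Onward HIV transmission (a benefit of testing) is out of scope, as are
NNRTI-based regimens, third-line therapy, adherence, loss to follow-up,
and currency conversion or inflation adjustment. The model is a two-arm
comparison only; no efficiency frontier over more strategies is computed.
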
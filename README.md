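# drtcea

Cost-effectiveness analysis of **pretreatment HIV drug-resistance testing
(DRT)** versus empiric dolutegravir (DTG)-based first-line therapy, for
people living with HIV in a resource-constrained setting.

Should every newly diagnosed person get a genotypic resistance test before
starting treatment? Testing costs 1,181.14 USD per person and lets the
clinician tailor the first regimen to transmitted resistance; skipping it
risks starting an ineffective regimen in the small minority with
transmitted resistance, with more treatment failure, opportunistic
infection (OI), and death. `drtcea` answers this with a Markov model —
three clinical states (HIV stage, AIDS stage, death), annual cycles, a
40-year horizon, 3% discounting — run either as a deterministic cohort
(expected-value) engine or as a seeded microsimulation of 1,000
hypothetical individuals, plus the standard health-economics toolkit:

* **ICER**: `(C_TEST − C_NO_TEST) / (E_TEST − E_NO_TEST)`, with dominance
  classifications in degenerate quadrants;
* **decision rule**: cost-effective iff the ICER is below the
  willingness-to-pay (WTP) threshold, 3 × GDP per capita
  = 3 × 2,746.4 = **8,239.2 USD/QALY** (equivalently, positive
  incremental net monetary benefit `wtp·ΔE − ΔC`);
* **one-way deterministic sensitivity analysis** (tornado table);
* **probabilistic sensitivity analysis**: Beta distributions for
  probabilities/utilities, Gamma for costs, Monte Carlo propagation, and
  cost-effectiveness acceptability curves (CEAC).

Every model input (costs, transition probabilities, utilities, drug
effectiveness by resistance class, prevalences) ships as a validated,
JSON-serializable parameter registry; see the methods vignette
(`vignettes/drt-cea-methods.Rmd`) for the model's assumptions and the
reasoning behind every open design choice.

## Worked example

```r
library(drtcea)

P <- baseline_parameters()
res <- run_strategies(P)            # deterministic cohort, both arms
wtp <- wtp_threshold(P$gdp_per_capita, P$wtp_multiplier)
res$TEST
#> <ce_outcome> TEST: 100195.04 USD, 11.5179 QALY (discounted, 40 y)
res$NO_TEST
#> <ce_outcome> NO_TEST: 99014.03 USD, 11.5166 QALY (discounted, 40 y)
icer(res$TEST, res$NO_TEST, wtp)
#> <icer_result> dCost 1181.01 USD, dQALY 0.001364, ICER 865682.51 USD/QALY | WTP 8239.2: not cost-effective
```

Reading: testing the whole cohort costs about one test per person more
than not testing (the small offset is care-cost savings in the ~3.2% with
transmitted resistance), buys a small QALY gain concentrated in that same
minority, and the resulting ICER is far above the threshold — pretreatment
DRT is **not cost-effective** at baseline. The suite verifies this
decision, the engine/microsimulation equivalence (within 3 Monte-Carlo SE
at n = 10⁵), and the no-resistance limit in which the arms differ by
exactly one test cost and zero QALYs.

Note the absolute totals are conservative by construction: suppression is
evaluated once at regimen initiation rather than re-drawn annually (the
vignette explains why, and why published totals from models with other
conventions are larger).

Microsimulation and sensitivity analyses:

```r
coh <- generate_cohort(1000, seed = 42, P)
aggregate_trajectories(simulate_cohort(coh, "TEST", P))
#> <ce_summary> n=1000: cost 98770.48 (SE 1353.90), QALY 11.3697 (SE 0.1711)

tor <- one_way_dsa(P)               # tornado, sorted by ICER spread
psa <- run_psa(P, n_draws = 1000, seed = 42)
head(ceac(psa, seq(0, 2e6, 5e5)))   # acceptability vs WTP
```

## Command line

```sh
Rscript -e 'drtcea::cea_cli()' run --out out/            # results.json + traces
Rscript -e 'drtcea::cea_cli()' dsa --out out/            # dsa.csv
Rscript -e 'drtcea::cea_cli()' psa --ndraws 10000 --seed 1 --out out/
Rscript -e 'drtcea::cea_cli()' fixture --out params.json # dump baseline config
Rscript -e 'drtcea::cea_cli()' validate --config params.json
```

All flags: `--config PATH --mode cohort|microsim --n INT --horizon INT
--discount FLOAT --seed INT --wtp FLOAT --ndraws INT --metric icer|nmb
--half-cycle --out DIR`. Every output directory carries a `manifest.json`
(config hash, seed, mode, horizon, package version).

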
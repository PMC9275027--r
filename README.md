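# oncovalue

Value assessment of anticancer therapies from trial-level evidence, for
health-services researchers, HTA analysts and oncologists who want the two
major scales computed reproducibly instead of by spreadsheet: the **ASCO
Value Framework v2.0** (advanced disease) and the **ESMO Magnitude of
Clinical Benefit Scale v1.1** (non-curative forms 2a/2b/2c). The package
ships the six first-line metastatic renal cell carcinoma (RCC) phase 3
trials — COMPARZ, CheckMate 214, JAVELIN renal 101, Keynote 426, CLEAR and
CheckMate 9ER, all versus sunitinib — as fixtures whose published scorings
it reproduces cell for cell, plus a 28-day regimen drug-cost model and a
seeded synthetic trial generator so every stage is testable without
external data.

## The scores

**ASCO net health benefit.** For a trial scored on an endpoint with hazard
ratio *h* (point estimate):

    CB  = (1 − h) × 100 × w          w = 1 (OS), 0.8 (PFS); ORR: relative
                                     improvement × 100 × 0.7
    tox = 20 (s_c − s_t) / s_c       s_a = Σ weight × incidence_a over
                                     non-laboratory AEs; weights 0.5 (g1–2),
                                     2.0 (g3–4); clamped to ±20
    NHB = CB + tox + bonuses         flat 10-point QoL / palliation bonuses;
                                     tail-of-curve and TFI as config hooks

A statistically significant OS result outranks PFS and ORR;
non-inferiority designs omit CB entirely.

**ESMO-MCBS grade.** Form 2a (OS-primary) or 2b (PFS-primary) grades on the
*lower 95% confidence bound* of the hazard ratio together with the absolute
median gain in months, through a control-median-banded threshold table
(e.g. form 2a, control median > 24 months: grade 4 iff HR_lower ≤ 0.70 and
gain ≥ 9). Form 2c covers everything else, including non-inferiority
trials. At most one adjustment upgrade (early stopping/crossover, toxicity,
QoL, plateau) lifts the preliminary grade, capped at 5.

## Worked example

```r
library(oncovalue)
trials <- rcc_trials()          # the six RCC comparisons
asco_table(asco_score(trials), trials)
#>   treatment                  clinical_benefit toxicity quality_of_life net_health_benefit
#> 1 Pazopanib                               0        1               10               11
#> 2 Nivolumab + Ipilimumab                 37        4.9              0               41.9
#> 3 Axitinib + Avelumab                    24.8     -2.4             NA               22.4
#> 4 Axitinib + Pembrolizumab               47        1.7             NA               48.7
#> 5 Lenvatinib + Pembrolizumab             34        1.2             NA               35.2
#> 6 Cabozantinib + Nivolumab               40        0.8             10               50.8
```

Reading the rows: pazopanib, a non-inferiority trial, gets no
clinical-benefit score — its 11 points are toxicity (+1, slightly less
toxic than sunitinib) plus a 10-point QoL bonus. Axitinib + pembrolizumab
scores (1 − 0.53) × 100 = 47 on its significant OS hazard ratio;
axitinib + avelumab, with no OS reported yet, scores its ITT PFS result
(1 − 0.69) × 100 × 0.8 = 24.8. `NA` bonus cells mean "not assessable yet",
distinct from an assessed 0.

```r
esmo_table(esmo_score(trials), trials)
#>   treatment                  form       hazard_ratio gain  prelim adj  final
#> 1 Pazopanib                  2c         <NA>           NA    4    +/+    4
#> 2 Nivolumab + Ipilimumab     2a (>24mo) 0.44 (OS)    15.2    4    tox    5
#> 3 Axitinib + Avelumab        2b (>6mo)  0.56 (PFS)    5.4    3     -     3
#> 4 Axitinib + Pembrolizumab   2b (>6mo)  0.57 (PFS)    4.0    3     -     3
#> 5 Lenvatinib + Pembrolizumab 2b (>6mo)  0.39 (PFS)   14.7    3   early   4
#> 6 Cabozantinib + Nivolumab   2b (>6mo)  0.41 (PFS)    8.3    3   early   4
```

(abridged; the real table carries one column per adjustment flag).
Nivolumab + ipilimumab reaches preliminary grade 4 on form 2a
(0.44 ≤ 0.70, 15.2 ≥ 9 months) and the toxicity-improvement upgrade makes
it the only grade 5. Note the two scales disagree about pazopanib — lowest
NHB, but the best grade form 2c can give — which is a property of the
scales, not a bug.

Other entry points: `validate_trials()`, `read_trials()`/`write_trials()`
(versioned JSON interchange), `monthly_cost()`/`cost_report()` (28-day
regimen costs at 60 kg, synthetic default prices),
`trial_scenario()`/`generate_trials()` (seeded synthetic evidence),
`estimate_hr_logrank()` (one-step log-rank HR), `autoplot()`, `tidy()`,
`glance()`, and a CLI at `inst/cli/oncovalue` with `score`, `synthesize`
and `cost` subcommands:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","oncovalue",package="oncovalue"))')" \
  score --input inst/extdata/rcc_trials.json --out report.csv --framework both
```

## Caveats

The fixtures' adverse-event tables are synthetic aggregates calibrated to
the published toxicity points (per-event safety tables are not part of the
published summaries), and the default price list is synthetic; both are
labelled as such. See the vignette (`vignettes/value-frameworks.Rmd`) for
the full account of the models, defaults and limitations.
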
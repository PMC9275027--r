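---
title: "Scoring oncology trial evidence with ASCO VF v2.0 and ESMO-MCBS v1.1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring oncology trial evidence with ASCO VF v2.0 and ESMO-MCBS v1.1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncovalue)
library(dplyr)
```

Two scales dominate the value assessment of new anticancer drugs in advanced
disease: the ASCO Value Framework v2.0, which condenses a randomized
comparison into a *net health benefit* (NHB) in points, and the ESMO
Magnitude of Clinical Benefit Scale v1.1, which assigns a *grade* from 1 to
5 through rule tables. Both consume only trial-level summary statistics —
hazard ratios and their confidence intervals, median survival times,
adverse-event incidences, and a handful of qualitative flags — which makes
them mechanisable. This package implements both engines over a tidy
trial-evidence data model and ships the six first-line metastatic renal cell
carcinoma (RCC) trials (COMPARZ, CheckMate 214, JAVELIN renal 101,
Keynote 426, CLEAR, CheckMate 9ER, all versus sunitinib) as a worked,
fully reproduced example.

## The trial-evidence model

A trial set is a tibble with one row per randomized comparison. Endpoint
results and the adverse-event table nest as list-columns, so the whole
evidence base stays pipe-friendly:

```{r}
trials <- rcc_trials()
trials |> select(trial_id, treatment_label, design, assessed_population)
trials$endpoints[[4]] # Keynote 426
```

Three representation choices matter downstream:

* **Months are doubles; "not reached" is `Inf`, "not reported" is `NA`.**
  The distinction drives real behaviour: an unreached median blocks
  ESMO banding on that endpoint (immature data), while an absent median
  simply contributes nothing. The JSON interchange writes `Inf` as the
  sentinel string `"NR"`, never null.
* **Flags are tristate** (`"yes"`/`"no"`/`"unknown"`). An unknown flag never
  earns a bonus or an upgrade, and report tables render it as an empty cell,
  distinct from a 0 that was assessed and not earned.
* **Endpoints carry a population label** (`"ITT"`, `"PD-L1-positive"`,
  `"IMDC-intermediate/poor"`, ...). Scoring verbs take a target population
  and default to the record's `assessed_population`; JAVELIN renal 101 is
  scored on ITT although its co-primary endpoints were defined in the
  PD-L1-positive subgroup, because the regulatory approval rested on the
  ITT progression-free survival result.

`validate_trials()` checks every structural invariant (positive arm sizes,
ordered confidence bounds, incidences in $[0, 100]$, unique endpoint and
adverse-event keys) and reports violations as data rather than erroring, so
a batch of records can be triaged in one pass.

## ASCO Value Framework v2.0 (advanced disease)

The NHB is the sum of a clinical-benefit score, a toxicity score and four
bonus categories.

**Clinical benefit.** For a survival endpoint with hazard ratio $h$,

$$\mathrm{CB} = (1 - h) \times 100 \times w,$$

with $w = 1$ for overall survival (OS) and $w = 0.8$ for progression-free
survival (PFS); for response-rate endpoints the relative improvement
$(rr_t - rr_c)/rr_c \times 100 \times 0.7$ is used. The framework
prioritises OS: a statistically significant OS result is scored even when
PFS was the primary endpoint (CLEAR and CheckMate 9ER are scored on their
significant secondary OS), then significant PFS, then ORR. A
non-inferiority design earns no clinical-benefit score at all — the scale
measures superiority — which is why pazopanib's NHB consists of toxicity
and QoL points only.

**Toxicity.** Each non-laboratory adverse event contributes its incidence
weighted by grade band (0.5 for grades 1–2, 2.0 for grades 3–4) to a
per-arm burden $s_t, s_c$; the score is the relative difference scaled to
$\pm 20$ points:

$$\mathrm{tox} = 20 \, \frac{s_c - s_t}{s_c}, \quad \text{clamped to } [-20, 20].$$

Positive points mean the new treatment is *less* toxic. Laboratory-only
toxicities (isolated enzyme or blood-count abnormalities) are excluded by
the framework's convention — a debatable rule, since grade 4 neutropenia is
hardly trivial, but the engine implements the scale as defined and the flag
makes the exclusion auditable. Degenerate inputs are pinned down: both
burdens zero gives 0; a zero control burden against a non-zero treatment
burden returns the clamp floor $-20$ with an explanatory note. Note the
formula is *relative*: swapping the arms flips the sign but rescales the
magnitude by $s_c/s_t$, so the score is not symmetric in magnitude unless
the burdens tie.

**Bonuses.** QoL and palliation improvements earn flat 10-point bonuses
when their flag is `"yes"`. Tail-of-curve and treatment-free-interval
bonuses are accepted as rule hooks in `asco_config()` but default to zero:
no shipped scoring exercises them (follow-up data mature too late for
recently reported trials), and inventing magnitudes for unexercised rules
would be worse than leaving them configurable.

**Rounding policy.** Every component is rounded to one decimal, half away
from zero, and the NHB is defined as the *plain sum of the rounded
components*. The alternative (round the sum of unrounded components) gives
the same values on every shipped trial, but only the chosen policy makes
the reported decomposition additive to the last bit — an invariant the test
suite asserts on a thousand generated records, and the property a reader of
the output table will instinctively check by hand.

```{r}
asco <- asco_score(trials)
asco_table(asco, trials)
```

## ESMO-MCBS v1.1 (non-curative forms)

Form selection follows the primary endpoint: OS-primary trials use form 2a,
PFS-primary trials form 2b, and everything else — including non-inferiority
designs — form 2c. Two deliberate interpretations:

* **Grading basis is the lower 95% confidence bound** of the hazard ratio,
  not the point estimate (`hr_basis()`). This is the scale's own hedge
  against fragile point estimates and the single biggest numerical
  difference from the ASCO engine.
* **OS-primary trials whose control median OS is not reached fall back to
  form 2b on PFS.** Form 2a bands by the control arm's median OS (cut at 12
  and 24 months); an unreached median cannot be banded, and co-primary
  OS/PFS trials graded before OS maturity (Keynote 426 here) are graded on
  the PFS axis in practice. When no PFS fallback exists the engine demands
  an explicit `band_override` rather than guessing.

The preliminary grade is a threshold-table lookup: within a (form, band)
the highest grade whose row is satisfied, a row requiring
$h_{\mathrm{lower}} \le$ `hr_lower_max` **and** gain $\ge$ `gain_min`
months, floor grade 1, form 2b capped at 3. The shipped table
(`esmo_thresholds()`) marks each row's provenance in a `source` column: the
2a >24-month grade-4 row ($h \le 0.70$, gain $\ge 9$) and the 2b >6-month
grade-3 row ($h \le 0.65$, gain $\ge 3$) are verified against published
gradings; the remaining bands are framework-derived defaults a user can
edit and re-supply. One reading correction is baked in: the grade-4 rule is
sometimes misquoted as "HR $\ge$ 0.7"; every graded example (0.44 $\to$
grade 4) is consistent only with $\le$, and smaller hazard ratios must
never grade lower — the monotonicity the property tests enforce across the
whole table.

The survival gain is `derive_gain()`: an explicit override (used when a
median is immature but extended follow-up reports a gain, as for
nivolumab + ipilimumab's 15.2 months) takes precedence over the difference
of reached medians.

**Form 2c** has no hazard-ratio axis. Its default rule rows: demonstrated
non-inferiority plus improved QoL or toxicity earns grade 4 (pazopanib's
case); non-inferiority alone earns grade 2; failure to demonstrate it,
grade 1. Only the grade-4 row is verified against a published grading; the
rest is a documented default.

**Adjustments.** On top of the preliminary grade, at most one level of
upgrade, capped at grade 5. Candidate flags in precedence order: early
stopping/crossover (not applicable to form 2a, where interim-analysis
behaviour is part of the form itself), toxicity improvement, QoL
improvement, and optionally plateau of the curve (accepted but inert by
default — no shipped scoring exercises it). Because only one upgrade is
possible, the engine records the single flag *credited* with it; a
satisfied but uncredited flag (CheckMate 9ER's QoL improvement, pre-empted
by early stopping) is reported with a `"-"` mark, which is exactly how
published gradings annotate such rows. Form 2c takes no post-hoc upgrades;
its core rule already consumed the flags.

```{r}
esmo <- esmo_score(trials)
esmo_table(esmo, trials)
```

Note the two scales disagree by design: pazopanib is last by NHB (11.0, no
clinical-benefit score) yet reaches grade 4, the best a form 2c trial can
do, on "similar efficacy, better toxicity, better QoL". The engines make
the disagreement explicit rather than reconciling it.

## Drug-cost model

`monthly_cost()` expands a phase-structured dosing schedule over a half-open
day window and prices exact milligrams. "Monthly" means 28 days — four exact
weeks — with day 0 the first administration; half-open windows `[start, end)`
make costs additive over abutting windows, which the tests assert. Per-kg
and flat doses coexist (nivolumab 3 mg/kg vs 240 mg flat), defaulting to a
60 kg body weight. Vial rounding is deliberately not modelled: the engine
answers "what does the schedule dose", not "what does the pharmacy
dispense". The shipped price list (`prices_synthetic.csv`) is **synthetic**:
published cost summaries print totals but not unit prices, so regimen costs
here are verified by construction (linearity in prices, window additivity,
hand-enumerated administration calendars) rather than against published
totals. The phased nivolumab + ipilimumab regimen illustrates why a single
"monthly cost" can mislead: induction and maintenance windows price very
differently, so `cost_report()` keeps the per-drug breakdown attached.

## The synthetic generator

`trial_scenario()` fixes a truth — hazard ratio, control median, arm size,
censoring rate, adverse-event incidences, flags — and two simulators draw
from it, both seed-deterministic:

* `simulate_summary()` draws the estimated log hazard ratio from
  $\mathcal{N}(\log h, \, 4/E)$ where $E$ is the expected event count
  ($E = n \sum_{\text{arms}} \lambda/(\lambda + c)$ under exponential
  events and censoring), the standard two-arm approximation. Medians follow
  the exponential identity $m = \ln 2 / \lambda$, so the simulated
  treatment median is $m_c / \hat h$.
* `simulate_patient_level()` draws exponential event and censoring times
  per patient; `estimate_hr_logrank()` recovers the hazard ratio with the
  one-step log-rank estimator $\exp((O - E)/V)$ and CI
  $\exp((O-E)/V \pm z/\sqrt V)$.

Default study conditions mirror the fixture trials: control medians of
8–12 months, 200–600 patients per arm, a per-month censoring hazard of
0.02, and aggregate adverse-event incidences of 10–35%. Parameter-recovery
checks run at 2,000 patients per arm over true hazard ratios
$\{0.4, 0.6, 0.8, 1.0\}$, where the summary-level generator is unbiased to
well under 2%. The one-step log-rank estimator is held to looser bounds
($\pm 0.05$ around 1; $[0.45, 0.55]$ at a true 0.5): a score expansion
around $\beta = 0$ attenuates strong effects (measurably so at a true
hazard ratio of 0.4), which is a property of the estimator, not a defect of
the simulator — the Cox partial-likelihood cross-check in the test suite
shows the data themselves are unbiased.

What the generator does *not* emulate: non-proportional hazards (delayed
immunotherapy effects, crossing curves), cure fractions, informative
censoring, or correlated endpoints. Tests passing on generated records
therefore certify the *engines*' arithmetic and rule logic under the
frameworks' own summary-statistic worldview, not the behaviour of either
scale under pathological real-world survival shapes.

## Fixtures and their provenance

Endpoint numerics in `rcc_trials()` (hazard ratios, confidence bounds,
medians, follow-up, arm sizes) are the published summary statistics of the
six trials. The adverse-event tables are a different matter: published
value assessments print the resulting toxicity *points*, not the hundreds
of per-event incidences behind them. The fixtures therefore carry
**synthetic two-band aggregate AE rows calibrated to reproduce the
published toxicity points exactly**, plus one laboratory-only row each to
exercise the exclusion rule. They are labelled as such in the fixture file;
treat them as a faithful encoding of the published scores, not as trial
safety data. For CLEAR, the published grading lists 0.39 — the trial's
point estimate — as the graded "lower bound"; the fixture stores it as
given so the engine reproduces the published table (the grade is 3 from
either 0.32 or 0.39).

## Problem sizes used by the checks

The shipped verification runs at desk scale: the six fixtures score in
milliseconds; the rule-engine equivalence grid is $200 \times 200$ points
per exercised band; toxicity-oracle equivalence uses 1,000 random AE tables;
NHB additivity uses 1,000 generated records; and parameter recovery uses
400 replicates per hazard ratio at 2,000 patients per arm. These sizes were
chosen to pin each property with comfortable Monte-Carlo margin while
keeping a full run in the low tens of seconds.

## Known limitations

* The unexercised rule surfaces (tail-of-curve and TFI bonuses, plateau
  upgrades, several threshold bands, sub-4 form 2c rows) ship as labelled
  defaults, not verified rules; anyone grading trials that exercise them
  should review and, if needed, override the configuration.
* The engines score what the record says. Judgment calls that precede the
  record — which population to assess, whether a QoL instrument's change is
  an "improvement", whether stopping was "early" — are inputs, and two
  assessors can legitimately disagree on them.
* Costs depend entirely on the supplied price table; the synthetic default
  exists so the machinery is testable, not as a price reference.
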
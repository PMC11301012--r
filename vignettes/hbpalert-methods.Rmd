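---
title: "Methods: urgent-notification triage and co-occurrence analysis for home blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urgent-notification triage and co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpalert)
```

## The problem

A screening programme hands participants an automated sphygmomanometer for
14 days of home blood pressure (HBP) monitoring. Most results are returned
through the regular reporting channel weeks later, but severely elevated
averages amount to a critical value: the programme must decide — quickly
and reproducibly — who receives an expedited ("urgent") notification
letter, what that letter says, and afterwards whether the intervention
changed care-seeking behaviour. `hbpalert` implements that decision chain
and its two companion analyses (abnormality co-occurrence and
behaviour change) as a batch pipeline over CSV artifacts.

## Period averaging

The monitoring day is split into three clock windows: morning
04:00–11:00, midday 11:00–16:00, evening 16:00–04:00 of the next calendar
day. Published protocol descriptions give touching endpoints without
stating inclusion; we use half-open intervals `[start, end)` so the three
windows partition the 24-hour clock exactly — every minute belongs to
exactly one period, which the test suite checks minute by minute. A
reading between midnight and 04:00 is attributed to the *previous* logical
day's evening.

When a participant measures several times within one (day, period) cell,
only the chronologically first reading is retained; ties on identical
timestamps fall back to input order with a warning. The per-period result
is the arithmetic mean of the retained systolic and diastolic values with
the contributing count `n_used`; empty periods are reported with
`n_used = 0` and missing means rather than imputed. Readings outside a
participant's 14-day window are dropped with a warning — late readings
are an operational artifact, not data.

## Triage

Averages are graded in JSH2009 style: Grade I ≥ 140/90, Grade II
≥ 160/100, Grade III ≥ 180/110 mmHg, met when the systolic *or* the
diastolic criterion holds. Source texts mix "≥" and ">" at the band
edges; clinical grade bands conventionally include the threshold, so
comparisons use `>=` (configurable through `grade_thresholds()`). One
published footnote cites a diastolic cut of "> 95" that conflicts with the
100/110 mmHg bands in the running text; we implement the running text's
values and mention the footnote only here.

A period average is *eligible* only when built from at least
`min_measurements = 3` retained readings — an average over two or fewer
measurements never triggers a notification, however high. Two policies are
modelled explicitly rather than by date: `grade2_plus` (notify Grade II or
higher) and `grade3_only`; `policy_for_date()` maps a calendar date to the
phase a real programme used (stricter from 2014-07-01). Where one period
is Grade II and another Grade III, the participant's grade is the maximum
over eligible periods — the natural reading, though not the only one. The
human review step that a real notification office adds is out of
algorithmic scope; in its place every triage result carries a
per-period audit trail (`reasons`) that the pipeline writes to
`audit.log`.

Three properties are enforced by tests: no notification ever cites a
period with fewer than three retained measurements; the `grade3_only`
notification set is a subset of the `grade2_plus` set on identical input;
and raising a systolic mean never revokes a notification.

## Laboratory flags

Panels are flagged against inclusive reference intervals (a value exactly
at a bound is normal — the clinical convention for reference ranges), with
sex-specific bounds for hemoglobin, creatinine and uric acid. The
morphology rule is a strict OR: blast cells present, multiple atypical
cells, or *more than* 30 erythroblasts per 200 nucleated cells.

The five analysis categories roll up as: blood sugar ← the glucose value;
renal ← creatinine or BUN; liver ← AST or ALT; hematological ← hemoglobin,
platelets, leukocytes or the morphology rule; lipid is accepted as a
precomputed boolean because the screening panel's reference table carries
no lipid bounds. CRP, uric acid and sodium are flagged individually but
enter no category by default; the mapping is an argument
(`category_mapping()`) so alternatives are one edit away. A missing
analyte contributes *no* abnormality, with a note — absence is never
evidence of normality, and `flag_analyte()` reports it as `"missing"`.

## Association analysis

Within notified participants, the ten unordered category pairs form 2×2
tables tested at the Bonferroni-adjusted level α = 0.05/10 = 0.005.

*Yates-corrected chi-squared.* The statistic is
χ² = n(max(|ad − bc| − n/2, 0))²/(r₁r₂c₁c₂), referred to χ²₁. The
correction is clamped at zero, so a perfectly balanced table yields
statistic 0 and p = 1. The correction is kept on because it is what makes
the statistic track the exact conditional test at these sample sizes
(toggleable via `correct = FALSE`).

*Fisher exact.* Two-sided by point-probability summation: the p-value sums
hypergeometric probabilities of all tables with the observed margins whose
point probability is at most that of the observed table, with a 1e-7
relative tie tolerance — the dominant software convention, and the variant
confirmed by exhaustive enumeration in the test suite (all tables with
n ≤ 30 match a `choose()`-based oracle to 1e-9).

*Selection rule.* Published reports rarely state when the exact test was
used. The assignments in our worked example are consistent with "Fisher
iff the smallest observed cell is ≤ 5" (the two Fisher-marked tables have
min cells 5 and 3; every chi-squared table has min cell ≥ 10), so that
rule is the default, documented as reverse-engineered and overridable per
call (`method = "fisher"` or `"pearson_yates"`).

*Oracle for the corrected chi-squared.* A permutation check needs care:
the continuity correction approximates the *doubled one-sided*
hypergeometric tail, not the tail probability of the statistic itself.
Against the doubled one-sided conditional tail estimated from 1e5
hypergeometric draws, the corrected p-values agree to within 0.02 on
random tables of the sizes the analysis meets (the Monte-Carlo half-width
is ≈ 0.003 and the χ² approximation contributes ≈ 0.01); against the
statistic's own permutation tail the deviation can exceed 0.1, which is a
property of the correction, not an implementation defect.

A category with no variation makes its pairs degenerate; those results
carry p = 1 with an explanatory note instead of failing.

## Behaviour change

Questionnaire responses fall into five substantive categories (regular
treatment, discontinued follow-up, lifestyle precaution, follow-up without
medication, never pointed out) plus `no_answer`. Percentages are computed
over respondents only and rounded *half-up* to one decimal — base R's
round-half-even disagrees with printed clinical tables at ties, and
half-up reproduces every published percentage we checked. The paired
subgroup keeps participants with substantive answers in both waves.

McNemar's test dichotomises pairs as regular treatment versus the other
four behaviours (the mapping is an argument) and uses the
continuity-corrected statistic (|b − c| − 1)²/(b + c) on the discordant
counts, with an exact doubled-binomial companion p-value whenever
b + c < 25. With no discordant pairs the p-value is 1 with a note. The
corrected statistic is precisely the continuity-corrected normal
approximation of the doubled exact binomial tail, so the two converge
absolutely as b + c grows — except where the doubled tail saturates at 1
(b ≈ c) and in the deep tail, where only relative error is meaningful;
the test suite asserts agreement in exactly those terms.

One documented impossibility: for a published subgroup in which regular
treatment rose from 68 to 107 of 151 paired respondents, the discordant
counts must satisfy c − b = 39, and *every* feasible (b, c) gives a
corrected McNemar p below 0.01 — the p ≈ 0.08 printed alongside those
marginals cannot be reconstructed under the standard test. The package
implements the standard test and the acceptance suite demonstrates the
discrepancy computationally rather than matching the printed value.

## Synthetic cohort

The generator exists so every stage is testable end to end without data
access; its defaults describe the kind of cohort the analysis targets, not
claims about any particular study.

* **Demographics.** Sex is Bernoulli with female fraction 2/3; age is a
  two-component normal mixture (means 35 and 65, sd 7, equal weights),
  chosen so both published qualitative features hold: peaks in the 30s and
  60s and roughly 40% of participants above 60.
* **Blood pressure.** Each participant draws a latent grade
  (default prevalences 70/20/7/3% for none/I/II/III — hypertension-enriched
  relative to a general population, deliberately, so triage paths are
  exercised at test sizes) and a true pressure uniform inside the grade's
  systolic *and* diastolic band, so the latent grade is unambiguous.
  Readings add N(0, 8²) mmHg noise to systolic (0.7 × that to diastolic),
  the scale of within-person home BP variability; adherence is
  per-period Bernoulli per day (morning 0.90, evening 0.85, midday 0.20,
  matching "morning and evening required, midday appreciated" protocols);
  within-period repeats beyond the first are Poisson(0.1), an assumption —
  real repeat behaviour is undocumented. Sampled timestamps are
  de-duplicated to distinct minutes within a cell so CSVs are
  well-defined.
* **Category flags.** The five flags follow a pairwise log-linear (Ising)
  model. Because 2⁵ = 32 joint states are enumerable, flags are sampled
  *exactly* from the enumerated joint rather than by Gibbs sweeps: the
  exact sampler is deterministic given the seed, has no burn-in or mixing
  questions, and is faster; a coupled pair's sampled odds ratio equals the
  configured coupling whenever the pair is not embedded in a larger
  coupled component. Main effects are calibrated by a logit fixed-point
  iteration on the enumerated joint so marginal rates match
  `category_base_rates` (defaults 46.5/39.8/35.4/16.5/11.0%, the
  notified-cohort scale of our worked example) even under nonzero
  couplings.
* **Lab values.** A flagged category sets one mapped analyte (chosen at
  random) just outside its bound — uniform in a band of relative width
  0.3, starting 1% beyond the bound so CSV rounding cannot pull a value
  back inside; unflagged analytes are uniform inside their ranges. The
  abnormal side is "high" except hemoglobin (low, anemia-style); lipid is
  emitted directly as its boolean column. This makes flag recovery by the
  flagging stage exact, which the tests assert.
* **Questionnaires.** Pre-survey categories are drawn from configurable
  probabilities; the post wave moves a non-treated participant to regular
  treatment with probability 0.55 if the triage stage (run on the
  generated measurements under the configured policy) notified them and
  0.10 otherwise, and retains treated participants with probability
  0.95/0.90. Nonresponse is Bernoulli per wave (0.90 pre, 0.65 post,
  the response-rate scale of the worked example).

`recover_parameters()` closes the loop: triage sensitivity/specificity
against the latent grade, Woolf-CI odds-ratio estimates against the
configured couplings, and binomial-CI transition estimates against the
configured probabilities. In the noiseless, fully adherent limit, triage
sensitivity and specificity for the latent grade are exactly 1.

## Numerical and scale choices

Deterministic checks (printed-table reproduction) run in milliseconds.
The stochastic calibration sizes were chosen once as the smallest that
make the claims sharp: odds-ratio CI coverage uses 100 cohorts of
n = 2000 (binomially, true 95% coverage then fails a ≥ 90/100 bar with
probability < 0.02); the null calibration uses replicates of n = 2000
independent-flag cohorts, where each pair's false-significance count is
judged against the 99.9% binomial band around α = 0.005 — the band's lower
edge is 0, which matters because both tests are conservative at small
expected counts. The exhaustive Fisher oracle covers all ≈ 46,000 tables
with n ≤ 30. All randomness flows through a single seed; generation uses
only R's integer-stream RNG, so fixed config + seed gives byte-identical
CSVs across platforms.

## Limitations

Passing tests show the pipeline is internally coherent and recovers known
structure from data *generated by its own assumed model*; they cannot show
that real home-BP streams meet those assumptions (no device artifacts,
white-noise readings, missingness independent of pressure, lab
abnormalities exactly at category granularity). The generator does not
emulate any real cohort's absolute counts or notification rate —
prevalences are free parameters. The human review that precedes a real
letter, delivery logistics, and lipid thresholding are out of scope by
design.
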
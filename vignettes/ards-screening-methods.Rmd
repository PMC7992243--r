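---
title: "Methods: automated Berlin-definition ARDS screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Berlin-definition ARDS screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardscreen)
```

## The phenotype and its assumptions

`ardscreen` implements a retrospective computable phenotype for ARDS under
the Berlin definition: acute hypoxemic respiratory failure (PaO2/FiO2 ≤ 300
with PEEP ≥ 5 cm H2O), bilateral opacities on chest imaging, and edema not
fully explained by cardiac failure, in the presence of a recognized risk
factor. Because the phenotype runs on charted EHR data rather than
bedside assessment, several Berlin clauses are operationalized through
proxies:

* **PEEP during P/F determination.** Ventilator settings and blood gases
  are charted at different frequencies, so strict simultaneity of a PEEP
  record with each gas cannot be verified. The screen instead requires the
  qualifying P/F to occur *at or after* time zero, the first PEEP ≥ 5
  charted in an ICU area. This is the anchoring assumption of the whole
  algorithm: all imaging and ECG windows hang off time zero.
* **Bilateral opacities.** Radiology adjudication is a keyword rule, not
  NLP: lowercase, tokenize on non-alphanumerics, and accept a report when a
  token stemmed `bilateral` precedes a token stemmed
  `infiltrat*`/`opacit*`/`opacif*`/`edema` by at most `keyword_proximity`
  tokens within one period-delimited sentence. There is no negation or
  uncertainty handling; "no bilateral infiltrates" is a (known) false
  match, and findings split across sentences are (known) false non-matches.
* **Non-cardiogenic origin.** Berlin's objective assessment
  (echocardiography) is not available as structured data; the screen relies
  on structured cardiac-event flags (acute events during the index stay,
  any CAD/CHF history) and an ECG text query (new ST changes / LBBB within
  ±24 h of time zero).

A patient is screened positive only when all eight gates pass; evaluation
short-circuits at the first failure, but each result carries a trace of all
evaluated gates, and the first failing gate is the recorded exclusion
reason. A non-short-circuiting reference evaluation is kept in the test
suite and checked to agree with the pipeline on randomized small stores.

## Tunable parameters

All thresholds live in `screen_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `peep_threshold` | 5 | cm H2O | PEEP defining time zero |
| `pf_threshold` | 300 | — | maximum qualifying P/F (warned if changed: leaves Berlin) |
| `fio2_match_window` | 15 | min | half-width for matching vital-sign FiO2 to a PaO2 |
| `cxr_window` | 12 | h | half-width of the imaging window around time zero |
| `ecg_window` | 24 | h | half-width of the ECG query window around time zero |
| `risk_factor_window` | 72 | h | half-width of the risk-factor window around ICU admission |
| `min_vent_duration` | 12 | h | minimum total invasive ventilation |
| `vent_gap_merge` | 1 | h | maximum charting gap inside one ventilation episode |
| `keyword_proximity` | 3 | tokens | bilateral-to-finding distance in a report sentence |

Widening any permissive window (`pf_threshold`, `fio2_match_window`,
`cxr_window`, `risk_factor_window`) or relaxing `min_vent_duration` can only
add positives; narrowing the exclusion window (`ecg_window`) likewise. This
monotonicity is asserted property-style in the tests.

## Design choices where the rule was genuinely open

* **Imaging window anchor and sidedness.** "Within 12 h" does not name its
  anchor. Time zero is the algorithm's only defined anchor, so the window
  is centered there and applied symmetrically (the permissive reading);
  both are configurable.
* **Risk-factor window.** The documented miss mode — sepsis arising more
  than 72 h after ICU admission — implies a 72 h horizon; the screen uses a
  symmetric ±72 h window around admission so pre-admission diagnoses
  (trauma, aspiration) still count.
* **Ventilation duration.** The institutional duration algorithm is not
  reproducible from its description, so the package uses a transparent
  approximation: invasive records ≤ 1 h apart form an episode, episode
  spans are summed, and the boundary is inclusive (exactly 12.0 h is
  retained). An isolated record contributes zero.
* **Index stay.** The first ICU stay that yields a time zero governs:
  "first PEEP ≥ 5" implies the first qualifying event, and the acute
  cardiogenic exclusions are evaluated within that stay.
* **Severity.** The worst (minimum) qualifying ratio grades severity, the
  conservative clinical convention; boundaries are mild [200, 300],
  moderate [100, 200), severe (0, 100). If `pf_threshold` is widened
  beyond 300 (non-Berlin, warned), ratios above 300 grade at the mild edge.
* **FiO2 dialect.** Extracts mix fractions (0.21–1.0) and percentages
  (21–100); both are accepted and percentages divided by 100. Values in the
  gap (1, 21) are rejected as ambiguous rather than guessed, since a silent
  misread corrupts every downstream ratio.
* **Tie-breaks.** Equal-distance vitals FiO2 matches resolve to the earlier
  record (pre-draw settings better reflect the gas-draw condition); equal
  worst ratios resolve to the earliest; both make results deterministic.
* **Timestamps** are parsed as UTC (naive values assumed UTC) and the
  generator emits them on a 1-minute grid, which keeps nearest-match logic
  free of sub-minute ties and DST artefacts.
* **Dirty rows.** Loading rejects rows (with logged per-table counts)
  rather than aborting: orphan patient ids, timestamps before birth,
  non-positive PaO2, unknown enum categories, inverted or overlapping ICU
  stays. This mirrors real extract hygiene and keeps cohorts runnable.

## The synthetic cohort generator

No real ICU extract can ship with the package, so `generate_cohort()`
emulates one. Gold-positive patients are constructed to pass every gate
(PEEP 8 from six hours after admission, a qualifying gas with lab FiO2 and a
second gas exercising the vitals-matching path, a positive bilateral report
within the imaging window, 16 h of hourly invasive ventilation records, one
risk factor within 48 h of admission, benign comorbidities and ECG); the
worst ratio is drawn from a chosen severity stratum so the screened severity
must match the generating stratum. Gold-negative patients violate exactly
one named gate. Labels and archetypes are drawn per patient from a
patient-indexed RNG stream, so growing a cohort never perturbs earlier
patients and a fixed seed reproduces stores byte-identically.

Edge-case archetypes reproduce the documented disagreement modes between
the electronic screen and manual review:

* `missing_pf_and_cxr` — gold-positive, but no gas or imaging rows were
  captured; screened out at the qualifying-P/F gate.
* `late_sepsis` — gold-positive, but the only risk factor is sepsis
  recorded > 72 h after admission; screened out at the risk-factor gate.
* `home_bipap_no_peep` — gold-positive on home bilevel support whose PEEP
  was never electronically charted; screened out at time zero.
* `cardiogenic_mimic` — gold-negative with structured cardiac events; the
  exclusion catches it (true negative). Its `_defeat` variant carries the
  cardiogenic documentation only in free-text notes, which the structured
  search cannot see, producing a controlled false positive.
* `fibrosis_mimic`, `short_vent`, `unilateral_cxr` — gold-negative
  single-gate violators.

`staged_cohort()` fixes the composition exactly (cohort size, gold-positive
count, specific miss archetypes, false-positive count), emulating the
purposeful sampling used to enrich validation cohorts. Staging 50-patient
cohorts with 23, 22, and 18 gold positives and the corresponding one or two
miss archetypes yields confusion tables (21,0,2,27), (20,0,2,28), and
(17,1,1,31); the test suite and `scripts/acceptance.R` recompute the
resulting metrics end to end.

The generator emulates charting *structure*, not physiology: timestamps
jitter on a 1-minute grid, but there are no vitals waveforms, no disease
progression, no demographic realism, and report language is drawn from a
small template pool. Passing tests therefore demonstrate that the screen
implements its stated rules exactly and recovers constructed ground truth —
not that it would achieve any particular accuracy on another institution's
EHR, where documentation habits, report language, and charting density
differ.

## Metric arithmetic and table reconstruction

`diagnostics()` reports sensitivity, specificity, PPV, and NPV as
percentages rounded half-up to one decimal (base `round()` is banker's
rounding and would display 96.875 as 96.8; published tables use 96.9). Any
metric with a zero denominator is `NA`, explicitly undefined — never 0 or
100 — so small-cohort validations cannot silently corrupt.

`reconstruct_tables(n, fixed, targets)` exhaustively enumerates integer 2×2
tables summing to `n` and keeps those whose rounded metrics match the
targets; on `n = 50` the full enumeration is 23,426 tables and runs in well
under a second. It doubles as a consistency oracle: a published metric
quartet either pins down a unique table, or it does not — and one published
validation row is jointly consistent only with one false negative plus one
false positive, although its accompanying narrative describes two false
negatives. The package follows the printed metrics and stages its
validation-style cohort accordingly. Enumeration without any fixed cell is
capped at 5×10^7 candidate tables; larger problems must fix a cell.

## Problem sizes in the shipped checks

The test suite screens staged 50-patient cohorts, five clean 1000-patient
cohorts at prevalence 0.3, 200 randomized 20-patient stores against the
non-short-circuit reference, and 1000 random tables for the Bayes-identity
check (PPV odds = positive likelihood ratio × prevalence odds); these sizes
keep the full suite in the low minutes on a single core while exercising
every gate and archetype.

## Known limitations

* Keyword matching has no negation, uncertainty, or laterality-merge
  handling, and risk factors and cardiac history are taken from structured
  flags plus a fixed ECG phrase list — stand-ins for institution-specific
  note-search infrastructure.
* The ventilation-duration rule is an episode-merge approximation, not the
  published institutional algorithm.
* The screen is retrospective by construction (time zero requires the
  charted record to exist); it is not a real-time detector.
* Berlin's echocardiographic objective assessment is represented only
  through structured cardiac-event categories.
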
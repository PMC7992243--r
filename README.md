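# ardscreen

Rule-based, retrospective identification of acute respiratory distress
syndrome (ARDS) patients — per the Berlin definition — from flat-file ICU
electronic health record (EHR) extracts, together with a seeded synthetic
ICU cohort generator and diagnostic-accuracy validation against
gold-standard chart-review labels.

ARDS is frequently under-documented and ICD codes map poorly to it, so
retrospective cohort assembly usually requires laborious manual chart
review. `ardscreen` implements an automated electronic search strategy as a
deterministic computable phenotype: a sequence of screening gates applied to
structured EHR tables plus keyword adjudication of free-text radiology
reports.

## The screening algorithm

A patient is called ARDS only if every gate passes, evaluated in order:

1. **Eligibility** — research authorization on file and age ≥ 18 years at
   ICU admission.
2. **Time zero** — the first ventilator record with PEEP ≥ 5 cm H2O charted
   in an ICU area during an ICU stay (procedural areas excluded). Time zero
   anchors all downstream windows.
3. **Qualifying P/F** — a PaO2/FiO2 ratio ≤ 300 at or after time zero.
   Ratios pair each PaO2 with its lab FiO2, or, when that is missing, with
   the nearest vital-sign FiO2 within ±15 min. The worst (minimum)
   qualifying ratio grades severity: mild (200–300), moderate (100–199),
   severe (< 100).
4. **Chest imaging** — a chest X-ray within ±12 h of time zero whose report
   contains *bilateral* within three tokens before *infiltrates* /
   *opacities* / *edema* in the same sentence.
5. **Fibrosis exclusion** — no IPF / ILD / pulmonary fibrosis in the
   Charlson comorbidity search.
6. **Ventilation duration** — at least 12 h of invasive mechanical
   ventilation (records ≤ 1 h apart merge into episodes; episode spans are
   summed).
7. **Risk factor** — at least one ARDS risk factor (sepsis/septic shock,
   pneumonia, aspiration, pancreatitis, trauma, drug overdose, shock,
   multiple transfusion) within ±72 h of ICU admission.
8. **Cardiogenic exclusion** — no cardiogenic pulmonary edema, cardiogenic
   shock, or positive acute decompensated heart failure during the index
   stay; no CAD/CHF history; no new ST changes or left bundle branch block
   on ECG within ±24 h of time zero.

Validation against gold labels uses the standard 2×2 machinery:
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
NPV = TN/(TN+FN), displayed as percentages rounded half-up to one decimal.
`reconstruct_tables()` additionally inverts this arithmetic: given a cohort
size and published summary percentages, it enumerates all integer 2×2
tables and returns the ones consistent with them.

## Worked example

Stage a validation-style cohort of 50 patients with 18 gold positives, one
gold-positive patient whose P/F and chest X-ray are missing from the record
(a documented miss mode), and one cardiogenic mimic whose edema is
documented only in notes (a false positive for the screen):

```r
library(ardscreen)

coh <- staged_cohort(n = 50, n_positive = 18,
                     miss_archetypes = "missing_pf_and_cxr",
                     n_cardiogenic_fp = 1, seed = 7)
res <- screen_cohort(coh$store)
df  <- as.data.frame(res)
cm  <- confusion(setNames(df$ards, df$patient_id),
                 setNames(coh$gold$ards, coh$gold$patient_id))
cm
#>           gold
#> pred       positive negative
#>   positive       17        1
#>   negative        1       31
diagnostics(cm)
#> sensitivity 94.4%  specificity 96.9%  PPV 94.4%  NPV 96.9%
screen_funnel(res)
#>            gate n_passed
#>        screened       50
#>     eligibility       50
#>       time_zero       45
#>   qualifying_pf       38
#>    positive_cxr       36
#>        fibrosis       31
#>   vent_duration       25
#>     risk_factor       21
#>     cardiogenic       18
```

The funnel shows patients surviving each sequential gate; the two
disagreements are exactly the injected archetypes. Per-patient results
carry a full decision trace:

```r
screen_patient(coh$store, coh$gold$patient_id[2])
#> Patient SP00002 - ARDS (severe)
#>   time zero: 2017-03-12 07:56:00
#>   qualifying P/F: 80.1 (lab FiO2)
```

## Command line

A thin wrapper in `exec/ardscreen` exposes three subcommands over the same
functions (exit codes: 0 success, 1 validation failure, 2 bad arguments;
every run writes a JSON manifest):

```sh
ardscreen simulate --n 50 --prevalence 0.3 --seed 1 --out cohort/
ardscreen screen   --data-dir cohort/ --out results.csv --cxr-window 12
ardscreen validate --pred results.csv --gold cohort/gold.csv
```

All thresholds and windows are flag-overridable (flag > `--config` YAML
file > default).

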
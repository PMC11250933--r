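# berlinards

Automated, explainable detection of acute respiratory distress syndrome
(ARDS) from electronic-health-record extracts, for clinical informaticians
and ICU researchers who need a reproducible, rule-transparent phenotype
rather than billing codes or ad-hoc chart review.

ARDS diagnosis under the Berlin definition requires four findings to line up
in time: (1) acute onset, (2) hypoxemia — PaO2/FiO2 (P/F) ≤ 300 mmHg while
PEEP ≥ 5 cmH2O, (3) bilateral infiltrates (BI) on chest imaging, and (4)
respiratory failure not fully explained by heart failure or fluid overload
(HF/FO). `berlinards` implements that logic explicitly:

- **BI validity windows.** Each BI-positive radiograph at time `T_BI`
  validates hypoxemia within `T_BI ± δ_BI` (default 1 day); an intervening
  BI-negative radiograph truncates the window on its side. The candidate
  onset `T0` is the earliest qualifying P/F measurement inside any window.
- **HF/FO attribution.** With `T0_HFFO` the earliest HF/FO evidence
  (radiograph or echocardiogram), the admission is attributed to HF/FO —
  and not flagged — iff `T0 ≥ T0_HFFO − δ_HFFO` (default `δ_HFFO` 5 days).
- **Acuteness.** A tracheostomy within 7 days of admission, or an onset
  more than 7 days after the first PEEP ≥ 5 record, rejects the admission.
- **Ventilation minimum.** Under 48 h of mechanical ventilation rejects the
  admission unless the patient expired or went to hospice within 48 h of an
  intubation or extubation.
- Positive admissions get an onset time and a severity stratum from the
  minimum qualifying P/F within ±24 h of onset (≤100 severe, ≤200 moderate,
  ≤300 mild), plus a per-criterion evidence trace.

BI and HF/FO evidence come from trainable text classifiers (TF-IDF
bag-of-n-grams + grid-searched regularized linear models): sentence-level
for BI with an any-positive-sentence report rule, and keyword-anchored
2–3-sentence context documents for HF/FO. Evidence can also be injected
directly, which decouples the temporal logic from classifier quality.

The package also ships an ICD-9 comparator flag, confusion-matrix
evaluation with a 7×7 grid search over `(δ_BI, δ_HFFO)`, component
ablations, a seeded synthetic-EHR generator with known ground truth, a
single-admission timeline figure (the "ARDS graph"), and a CLI.

## Worked example

```r
library(berlinards)

co <- generate_cohort(generator_config(n = 50, seed = 42))
verdicts <- detect_cohort(co$admissions, evidence = co$evidence)
verdicts[[3]]
#> <ards_verdict adm00003: ARDS, onset 3686 min (day 2.6), mild>

pred <- vapply(verdicts, `[[`, logical(1), "ards")
compute_metrics(confusion_matrix(pred, co$labels$ards_label))
#> accuracy 88.0%  specificity 100.0%  recall 77.8%  precision 100.0%  F1 87.5%
```

Admission `adm00003` realizes the classic presentation: a BI-positive
radiograph, a qualifying P/F on day 2.6 inside its 1-day window, adequate
ventilation, and no HF/FO evidence — so the flag is positive with a mild
stratum (minimum qualifying P/F in (200, 300]). The cohort-level metrics are
computed against the generator's clinician-style ground truth; recall is
below 100% because the generator plants documented hard cases (unilateral
pneumonectomy-style disease, diuresis-refractory edema initially attributed
to HF/FO) that the rule set cannot flag by design.

The same pipeline from a shell:

```sh
inst/cli/berlinards simulate --n 50 --seed 42 --out cohort/
inst/cli/berlinards detect --cohort cohort/ --evidence cohort/evidence.csv --out verdicts.jsonl
inst/cli/berlinards evaluate --pred verdicts.jsonl --labels cohort/labels.csv
inst/cli/berlinards graph --admission adm00003 --cohort cohort/ --out ards_graph.png
```

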
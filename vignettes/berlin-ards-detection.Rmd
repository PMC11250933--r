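---
title: "Methods: Berlin-criteria ARDS detection with berlinards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Berlin-criteria ARDS detection with berlinards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berlinards)
```

## The detection problem

Acute respiratory distress syndrome is defined by the Berlin criteria as the
conjunction of four findings: acute onset; hypoxemia with PaO2/FiO2 (P/F)
≤ 300 mmHg while PEEP ≥ 5 cmH2O; bilateral opacities on chest imaging; and
pulmonary edema not primarily attributable to cardiac failure or fluid
overload. None of these is a single chart field. The imaging and cardiac
criteria live in free-text radiology and echocardiogram reports, and all
four must hold *near the same time*, which retrospective code-based
phenotypes ignore. `berlinards` makes the temporal alignment explicit and
auditable: every verdict carries a per-criterion trace naming the evidence
(note IDs, measurement counts, onset arithmetic) behind it.

## Temporal model

All times are minutes since admission (floating point). Absolute timestamps
exist only at the I/O boundary; internally a single admission is a set of
event series on a common relative axis, which removes timezone and DST
ambiguity.

**P/F measurements.** A P/F measurement exists for each PaO2 record that
has an FiO2 record at-or-before it within the pairing lookback (default
4 h; the most recent one is used). PEEP is last-observation-carried-forward
with a staleness limit (default 8 h); without a fresh PEEP the measurement
cannot qualify. The chart does not say which FiO2 was in effect at a blood
gas draw, so the lookback is a modeling choice; both limits are exposed in
`berlin_config()`. PaO2 records with no pairable FiO2 are skipped and
counted in the trace.

**BI validity windows.** Each BI-positive radiograph at time `T_BI`
contributes the interval `[T_BI − δ_BI, T_BI + δ_BI]` (default `δ_BI` =
1 day). A BI-negative radiograph truncates the interval on its side of
`T_BI`: the bound moves to the negative's time and the interval becomes
half-open there, so a qualifying measurement exactly at the negative
radiograph's time is *excluded* while one at an untruncated base endpoint
is *included*. Truncation-at-the-nearest-negative is the minimal reading of
"the window shrinks when a clear radiograph intervenes"; overlapping
intervals are merged (a shared endpoint merges unless both sides are open
there). An interval emptied by truncation is dropped.

**Onset.** The candidate onset `T0` is the earliest qualifying measurement
(P/F ≤ 300, fresh PEEP ≥ 5) lying inside any BI window; with none, the
admission is negative with reason `"no qualifying hypoxemia within a BI
window"`. The measurement timestamp itself is used as the onset time.

**Acuteness.** Two proxies: a tracheostomy within 7 days of admission
rejects the admission (an early tracheostomy implies pre-existing chronic
respiratory failure), and `T0` must fall within 7 days of the first
PEEP ≥ 5 record.

**HF/FO attribution.** With `T0_HFFO` the earliest HF/FO evidence time
pooled over radiographs and echocardiograms, the admission is attributed to
HF/FO iff `T0 ≥ T0_HFFO − δ_HFFO` (default `δ_HFFO` = 5 days). The formula
is applied exactly as stated, which has a deliberate, documented
consequence: HF/FO evidence that *postdates* the onset by up to `δ_HFFO`
still blocks the diagnosis. Whether later cardiac evidence should
retroactively negate an established onset is genuinely open; we apply the
rule verbatim rather than invent an asymmetry, and the ablation machinery
(`ablation_run(..., "no_hffo")`) quantifies its effect.

**Ventilation minimum.** Total ventilated time (open episodes run to
discharge) must reach 48 h. The exception preserves severe short courses:
admissions that expired or were discharged to hospice within 48 h of an
intubation *or* extubation still qualify, so death shortly after intubation
or terminal elective extubation is not mistaken for a trivial ventilation
episode.

**Severity.** The minimum qualifying P/F within ±24 h of `T0` sets the
stratum: ≤ 100 severe, (100, 200] moderate, (200, 300] mild. The ±24-h scan
window is our choice (severity is reported but not operationalized in the
standard definition); it is config-exposed.

The criteria are conjunctive, so evaluation order cannot change the
verdict; the engine evaluates the cheap ventilation rule first and a test
verifies flag-equivalence against independently evaluated component checks.

## Text classifiers

Evidence extraction is two classification tasks over prepared text.
Preparation lowercases; replaces `[** ... **]` de-identification
placeholders with per-class generic tokens; unifies variant phrases
("pls" → "please", "pna" → "pneumonia"); fuses common multi-word phrases
into unigrams ("pulmonary edema" → "pulmonaryedema", "consistent with" →
"consistentwith"); strips markup, digits and punctuation except question
marks (often the only marker of radiologic uncertainty); collapses
whitespace; and optionally applies a light rule-based suffix stripper
(off by default — the package bundles no stemming library, and on these
short reports stemming mostly merges distinct clinical terms).

**BI** is sentence-level: a deterministic rule-based segmenter (fixed
abbreviation list, blank-line boundaries, decimal-safe) splits the report
and each sentence is classified; the report is positive iff at least one
sentence is. **HF/FO** is document-level: sentences containing one of 14
trigger phrases (cardiac shock/arrest/failure, fluid/volume overload, heart
failure, CHF, hydrostatic, cardiogenic, hypervolemia, systolic/diastolic
dysfunction, LVSD, LVDD; matched case-insensitively before punctuation
stripping) anchor a previous/focal/next context document — two sentences at
report edges, one document per focal sentence. Report-level aggregation for
HF/FO defaults to any-positive-document, symmetric with the BI rule, with a
majority-vote switch in the config since the aggregation is a design
choice, not a requirement.

Vectorization is TF-IDF over uni+bigrams (smoothed idf, sublinear tf, L2
row norm, document-frequency bounds). The classifier family is a
regularized linear model: penalized logistic regression via `glmnet`
(default) with a linear SVM (`e1071`) as a grid alternative — the same
linear-decision-function class that wins on short clinical text, where the
signal is a handful of lexical markers. Training makes a stratified
train/test split (0.75 for BI, 0.80 for HF/FO), grid-searches
hyperparameters with stratified 5-fold cross-validation maximizing
positive-class F1, refits on the full training split and reports held-out
metrics. `replicate_evaluation()` repeats this over consecutive seeds and
summarizes min/max/mean with a Student-t 95% half-width — the t-interval
on replicate means is our choice of CI formula. Models serialize to a
single JSON archive (config snapshot, vocabulary, idf, weights at full
double precision); a round-trip test requires identical predictions on
probe texts.

## Synthetic data: what it emulates and what it does not

Every test runs without any external dataset. `generate_corpus()` builds
labeled units from slot-grammar templates, not a language model, so labels
are exact by construction: positive BI sentences always assert bilateral
involvement of a qualifying finding (infiltrate, opacity, consolidation,
airspace disease, aspiration, pneumonia); negatives are unilateral
findings, bilateral pleural effusions, atelectasis-only consolidation,
resolution phrasing or normal studies. Qualified *worsening/improvement* of
bilateral disease is positive; *resolution* is negative. Class balance uses
exact-count allocation (`round(n × rate)` positives, shuffled) at the
reference rates — 39.5% BI, 56.4% HF/FO radiology, 50.1% HF/FO echo — so
the balance contract holds at any n. Lexical noise applies label-preserving
abbreviation swaps, case flips and junk-token insertion at a configurable
token rate.

`generate_cohort()` realizes eight scenarios (classic presentation, HF/FO
confounding in three flavors, rapid radiographic resolution, early
tracheostomy, short ventilation with and without terminal exception, no
qualifying hypoxemia, unilateral disease) into full admissions:
observation trajectories, ventilation episodes, procedures and notes whose
text is generated consistently with the emitted evidence table. Each
admission carries both the engine-expected verdict (reproduced exactly by
`detect_ards()` in the closure tests) and a clinician-style label. The two
differ only for the documented hard cases: pneumonectomy-style unilateral
disease (clinically ARDS, never flaggable from bilateral-infiltrate text)
and the "masked" HF/FO flavor (initial cardiogenic picture, persistent
infiltrates after diuresis — clinically ARDS, attributed to HF/FO by the
rule). These encode the known failure modes of the rule set and keep
cohort-level recall honestly below 100%.

Scenario timing parameters are drawn from gap ranges chosen to straddle the
tuning grid {4 h, 8 h, 12 h, 1 d, 2 d, 5 d, 7 d}: classic cases place
hypoxemia up to 23 h after the radiograph (penalizing windows below 1 day),
rapid-resolution cases place it 25 h–7 d *before* a transient positive
radiograph (penalizing windows above 1 day), and HF/FO confounders place
cardiac evidence across (0, 5 d] after onset with a late-evidence flavor in
(5 d, 7 d] (penalizing HF/FO windows on either side of 5 days). A cohort
generated at the default windows therefore has its grid-search F1 uniquely
maximized at (1 d, 5 d), which the parameter-recovery check exercises
end-to-end. These ranges are the generator's study conditions, fixed in the
defaults.

What the generator does **not** emulate: real-report syntax diversity
(hedging, negation scope, section structure), correlated measurement
dropout, inter-annotator disagreement, realistic marginal distributions of
P/F or length of stay, or de-identification artifacts beyond the `[** **]`
placeholder style. Passing tests therefore demonstrate correctness of the
*logic* and the *pipeline mechanics* under controlled conditions — not
expected classifier accuracy on real clinical text, which must be
re-estimated on labeled reports from the target system.

## Numerical and design choices

- **Duplicate observations** at one timestamp keep the last-read value
  (with a warning): later chart writes usually supersede earlier ones.
- **FiO2 dialects**: values ≤ 1 are fractions, values ≥ 21 are percent;
  the open interval (1, 21) is physiologically meaningless in either
  dialect and is dropped with a warning rather than guessed. Results are
  clipped to [0.21, 1].
- **Mandatory input tables** are `admissions.csv`, `observations.csv` and
  `notes.csv` — the minimum the cohort filter needs; ventilation,
  procedure and diagnosis tables default to empty.
- **Tuning tie-breaks** go to the smaller `δ_BI`, then smaller `δ_HFFO`:
  smaller windows are the more conservative phenotype. Selection uses
  full-precision F1; one-decimal rounding is display-only.
- **Degenerate metric denominators** report 0 and are flagged in the
  `undefined` field instead of propagating NaN.
- **Window-grid problem sizes** used by the checks: 1,000 admissions for
  the brute-force equivalence, 400 for parameter recovery, 2,000 units ×
  5 replicates for classifier replication, 300 for ablations — sizes at
  which every stochastic property has been stable across seeds.

## Known limitations

- The HF/FO rule blocks diagnoses when cardiac evidence arrives after
  onset within `δ_HFFO`; patients with superimposed cardiogenic edema are
  systematically attributed to HF/FO (the masked scenario documents this).
- Bilateral infiltrates are read from report text, not images; unilateral
  anatomy (pneumonectomy) and radiologist phrasing outside the template
  space produce irreducible false negatives.
- Intubation and extubation times are inputs; the package does not infer
  them from device data.
- The sentence segmenter favors determinism over linguistic coverage; its
  abbreviation list is fixed and user-visible.
- The shipped stopword list and phrase maps are compact defaults and are
  user-replaceable in `text_pipeline_config()`; production use on a new
  EHR should revisit them.
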
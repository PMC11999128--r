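---
title: "Modelling diabetes progression: staging, note extraction and nested transition models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diabetes progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtransit)
```

## The disease model

`dmtransit` analyses type 2 diabetes progression as movement between four
stages defined by two clinical axes:

* **metabolic goal**: a patient is *ON* goal when HbA1c is strictly below a
  personalised target (6.5, 7.0 or 7.5 %), *OUT* otherwise;
* **chronic complications**: *NOT* before any of retinopathy,
  cerebrovascular disease or chronic kidney disease is coded, *YES* after.

The four stages, in the fixed order used for every matrix in the package, are
`ON-NOT`, `OUT-NOT`, `ON-YES`, `OUT-YES`. Goal transitions are bidirectional
(HbA1c moves both ways); complications are **absorbing** — once a staging
complication is coded the patient can never return to a `NOT` stage. Every
transition matrix therefore carries structural zeros in the
`YES`-row/`NOT`-column cells, and `transition_matrix()` treats an observed
recovery as a data-quality error rather than repairing it silently.

Two design choices here were genuinely open:

* **Strict threshold.** Goals are stated as "< target", so HbA1c exactly at
  the target is OUT of goal. The boundary case is tested explicitly.
* **Goal-policy table.** Published standards personalise the target but do
  not print a mapping. The default policy — under 45 without complications
  6.5 %, 45–64 7.0 %, 65+ or any complication 7.5 % — is a documented
  package assumption, fully replaceable via `goal_policy()` or a JSON file
  (`read_goal_policy()`). Thresholds outside {6.5, 7.0, 7.5} are rejected
  unless explicitly allowed.
* **Annual HbA1c.** One measurement per patient-year is assumed; if a source
  table has several, the caller should keep the chronologically last one, as
  it is the end-of-year status that drives the next transition.
* **1-year pooling.** With three study years, the 1-year matrix pools both
  adjacent-year pairs; the 2-year matrix uses the first-to-last pair. A
  pooled count matrix is exactly the sum of the per-pair count matrices
  (tested as a property).

## The synthetic cohort generator

No patient-level data are shipped or downloadable, so the generator is a
first-class module: every downstream stage is exercised against cohorts with
known ground truth. It is a discrete-time four-state Markov chain at 1-year
steps with stage-conditional emission:

* **Initial stages** default to the published 2018 stage occupancies
  (8685 / 6858 / 4375 / 3884 patients, i.e. roughly 36/29/18/16 %).
* **Dynamics** default to the published 1-year transition matrix. Because
  the published 2-year panel is *not* the square of the 1-year panel, an
  explicit 2-year matrix can be supplied; endpoints are then drawn from it
  directly and the intermediate year is a bridge draw from the 1-year row
  restricted to complication-compatible states (a `NOT` endpoint forbids a
  `YES` detour), preserving monotone complications.
* **Biomarkers** are drawn per patient-year from per-stage normal moments
  (age, sex, LDL, eGFR, creatinine, BMI, weight, height, blood pressures)
  matching the published per-stage baseline table; age is drawn once at
  baseline and increments deterministically.
* **HbA1c** is a truncated normal consistent with the true stage: ON stages
  draw strictly below the personal threshold, OUT stages at or above it,
  using the published per-stage means/SDs (about 6.4 (0.5) within goals and
  8.5–8.7 (1.5) outside). Truncation shifts the realised mean below the
  configured one when the threshold sits close to it (about −0.1 at a 7.0
  threshold); calibration tests therefore pin the goal policy at 7.5, where
  the shift is negligible.
* **Flags** (patient compliance, professional HbA1c/cholesterol guideline
  adherence, four lifestyle recommendations, analgesic/antacid use) are
  Bernoulli with the published per-stage prevalences, drawn once per patient.
  The published table reports a *compliance* prevalence but no rate of
  explicitly documented non-compliance; the generator states non-compliance
  in 10 % of notes (rest unstated), a value chosen once as realistic for
  physician notes.
* **Prescriptions** are counts (Poisson, capped at 3) with the published
  per-stage means, materialised as canonical drug names from the lexicon;
  insulin is more likely out of goal. A configurable fraction of truly
  prescribed drugs (default 30 %) is hidden from the structured field but
  still rendered in the note, emulating the incomplete structured EHR fields
  that motivate NLP backfill.
* **Planted effects.** For parameter-recovery experiments,
  `effect_params` shifts the per-step log-odds of goal loss and complication
  onset by per-flag coefficients (e.g. professional HbA1c-guideline
  adherence protective at −1.0, patient compliance at −1.2 on the
  complication axis). These are test-fixture magnitudes — clear effects a
  correct pipeline must recover — not estimates.

Notes are bilingual templated clinical shorthand (Spanish-flavoured with
English variants). Every ground-truth entity is rendered through a lexicon
surface form; noise dials control the rate of abbreviation surfaces
(`HBP`, `HTA`), single-character misspellings (guaranteed edit distance 1,
matching the extractor's correction radius), and distractor fragments.

What the generator does **not** emulate, and hence what passing tests do not
show about real data: free-text styles outside the templates, entity
mentions absent from the lexicon, OCR-like noise beyond one edit, mortality,
hospitalisation and dropout, within-year HbA1c trajectories, and per-year
drift of the emission distributions (the published table pools 2018–2020, so
emissions are held stationary).

## Dictionary NLP

The extraction pipeline is deliberately simple and fully specified:

1. **Preprocessing** — lowercase, URL removal, locale-independent accent
   folding, punctuation to spaces, digit removal (so `20mg` loses its
   numerals), tokens shorter than two characters dropped, stopwords removed.
   The stopword fixture includes EHR filler (`patient`, `visit`, unit tokens)
   but deliberately keeps negation tokens (`no`, `not`, `sin`) visible for
   the adherence patterns. Preprocessing is idempotent on its own output.
2. **Spelling correction** — a token not in the lexicon vocabulary is
   replaced by the unique vocabulary word within edit distance 1; exact
   matches always win, ties leave the token unchanged, and tokens shorter
   than four characters are never corrected (short tokens are mostly
   abbreviations, where a one-character edit is a different word).
   Lemmatisation/stemming is handled by surface-form enumeration in the
   lexicon rather than a language-specific stemmer — deterministic and
   bilingual-safe.
3. **Greedy longest-match search** — left-to-right n-gram scan (n ≤ 3, no
   overlaps), so multi-word entities (`metoprolol succinate`, combination
   products) beat their single-word prefixes. Equivalence with a brute-force
   enumeration of maximal non-overlapping matches is tested on randomised
   streams.
4. **Adherence classification** — rule-based, not a trained classifier:
   negative patterns (e.g. "no adherencia", a physician's special emphasis
   on adhering to treatment) that fire un-negated give `non_compliant`,
   otherwise positive patterns give `compliant`, otherwise `unstated`.
   Negation is a ±4-token window around the matched span.

The shipped lexicon's scope is deliberate: it covers exactly the drug set of
the worked extraction examples plus the drug classes of the analysis table,
so drugs outside it (plain aspirin, prednisolone) are *not* extracted —
lexicon scope, not extraction failure, explains those exclusions. One
printed derived name with an obvious typo is canonicalised to
`empagliflozin`.

Structured fields always win conflicts against extracted values
(extraction fills gaps and unions entity lists); conflicts are logged, and
the provenance of NLP-derived values is recorded. Whether the original
workflow resolved such conflicts the same way is unknown; this rule is a
package decision.

## Guideline adherence

`actual_treatment()` classifies prescribed hypoglycemic therapy
(insulin ≻ combined ≻ metformin ≻ none, combination products expanded
first), `ideal_treatment()` applies an ordered band table over HbA1c and
eGFR, and `cross_tab()` produces the 3×3 ideal-vs-prescribed table whose
diagonal is concordance. The default band table (HbA1c < 8 and eGFR ≥ 30 →
metformin; 8–9.5 → combined; > 9.5 or eGFR < 30 → insulin) is a declared
stand-in for institution-specific guideline algorithms and ships as an
editable JSON file. The LDL threshold for the cholesterol flag defaults to
100 mg/dL. NLP backfill can only move a patient *up* the treatment
precedence (never down), so insulin-row concordance is non-decreasing after
backfill — tested as a directional property, since the published
before/after percentages are properties of the proprietary cohort.

## The nested transition models

The four-class outcome is decomposed into two nested binary questions per
starting stage and horizon — out of goals at the horizon (all four stages)
and complication onset (only the two complication-free stages) — giving
twelve tasks over the 1- and 2-year horizons. For each task:

* stratified 80/20 train/test split (the held-out fraction is a package
  default; stochastic learners are seeded throughout, so every reported
  number is bit-reproducible given the data and seed);
* feature selection: variance filter, pairwise-correlation filter
  (|r| > 0.95 drops the later column), optional top-k by boosted-tree gain;
* stratified 10-fold cross-validation of every (family, hyperparameter)
  candidate, selected by mean fold F1 with AUC then accuracy as
  tie-breakers;
* optional SMOTE rebalancing — synthetic minority points are convex
  combinations of minority neighbours — applied to training folds only,
  either raising the minority to the majority count or moving both classes
  to an intermediate size. The default is no resampling, matching the
  preference for the unresampled models in the reference analysis;
* the winner is refit on the full training split and a **kappa-optimal
  cutoff** is chosen on the training predictions: Cohen's kappa is evaluated
  at every midpoint between adjacent distinct probabilities (plus 0 and 1),
  ties resolved toward the smallest cutoff. Test metrics and confusion
  rates are reported at that cutoff;
* **marginal effects**: binary features are toggled 0→1, continuous features
  shifted by +1 SD (the perturbation size is a package choice), and the mean
  change in predicted probability is reported in percentage points.

The default candidate grid is small and fixed: logistic regression, KNN
(k ∈ {5, 15, 31}), decision trees (depth {3, 5, 10}), random forest,
extremely randomised trees, and gradient boosting ({50, 200} rounds). The
feed-forward network — three 256-unit ReLU layers with inter-layer dropout
(default rate 0.2) and a sigmoid output, trained with Adam over a grid of
regularisation, learning rate and epochs on standardised features — is
implemented in-package and can be added to the grid (`families = c(...,
"mlp")`); it is excluded from the default grid because cross-validating it
dominates runtime without changing what the selection layer demonstrates.
No adaptive-boosting or light-gradient-boosting family is included;
gradient boosting covers that model class here. No multiple-testing
correction is applied across the twelve tasks — the metrics are
descriptive, as in the reference analysis.

The calculator, `predict_stage_probabilities()`, combines the two binary
models of the patient's current stage into a 4-stage probability vector
under an independence (outer-product) assumption — the combination rule is
not stated in the reference analysis and is a documented package decision.
For complication starters all mass stays on the two complication stages.
An alternative multinomial formulation is mentioned in the reference
analysis only as an inferior earlier attempt and is not implemented.

## Numerical and testing choices

* Transition-matrix rows must sum to 1 within 1e-9; printed reference
  matrices are renormalised from their ≤ 0.02-point rounding slack.
* AUC uses the rank statistic with mid-rank ties; single-class test sets
  report AUC as flagged-missing rather than a number.
* Degenerate inputs fail loudly: empty cohorts at the staging boundary,
  single-class training labels, non-exhaustive guideline bands, observed
  complication recovery.
* Test problem sizes: transition-recovery runs use 20 000 patients per
  initial stage (binomial SE < 0.4 points per cell), calibration checks use
  20 000 patients, extraction round-trips a few hundred notes, and the
  model-layer recovery experiments use 20 seeds of 1 500-patient cohorts
  with a reduced (logistic-only) grid plus one full-grid pass over all
  twelve tasks at 2 000 patients — sizes chosen so the whole suite stays
  desk-scale while keeping sampling error well inside the tested
  tolerances.

## Limitations

The package demonstrates methodology on synthetic cohorts whose generative
assumptions it controls; recovered transition matrices and model metrics
characterise the pipeline, not any real population. The published
performance tables of the reference analysis depend on a proprietary HMO
cohort and are intentionally not reproduction targets. Real clinical notes
are messier than the templated ones here; the extractor's guarantees
(zero-noise completeness, distance-1 correction) are statements about its
contract, not about arbitrary free text.
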
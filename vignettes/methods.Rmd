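---
title: "Methods: hybrid PPC risk prediction and rule-based surveillance recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid PPC risk prediction and rule-based surveillance recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modeling and design decisions behind
`ppcwatch`: what the pipeline computes, which choices were genuinely open
and how they were resolved, what the synthetic cohort generator does and
does not emulate, and what the shipped tests do and do not establish.

## Problem setting

The package targets binary surveillance classification: given one row per
postoperative patient — demographics, surgery and anesthesia descriptors,
window summaries of postoperative vitals (per-vital minima/maxima),
EMR-style abnormality flags, and nursing-note-derived symptom booleans —
predict whether the patient belongs to the group needing pulmonary
surveillance attention (the `ppc` label), and convert the prediction plus
the patient's abnormal findings into concrete nursing surveillance
actions. The label is a pragmatic "needs surveillance" indicator rather
than a confirmed diagnosis, which is why the downstream consumer is a
recommendation engine, not a diagnostic report.

## The feature schema and abnormality flags

`ppc_schema()` declares 41 features with semantic types, physiologic hard
bounds, and — for the vital summaries — normal ranges. Default adult
ranges are SBP 90–140 mmHg, DBP 60–90 mmHg, body temperature 36.0–38.0 °C,
respiratory rate 12–20 /min (inclusive at both ends), pulse 60–100 /min,
SpO₂ abnormal strictly below 95%, and pain (NRS) abnormal at 4 or above.
The SpO₂ cut-off is the one value with a firm external anchor; the others
are conventional adult ranges chosen so that a reference case (SBP 151
abnormal; BT 37.1, RR 20, SpO₂ 95, NRS 2.125 all normal) is classified the
way a clinician would read it. All ranges are configurable through
`ppc_schema(normal_ranges = ...)`.

A judge flag is true iff *any* of its source summaries violates the range
(e.g. `SBP_judge` looks at both `SBP_max` and `SBP_min`). Flags are always
derivable from the vitals, so `derive_judge_flags()` is idempotent and
`validate_schema()` treats a flag/vital disagreement as a reportable
inconsistency. Derived bins (`Age_1` in decades, `BMI_1` as the WHO
classes, `Anesthesia_time_1` in hourly bins) are regenerated from their
numeric sources and never trusted from input — the source data carries no
definition for them, so regeneration is the only way to make them
consistent. Missing values are rejected, never imputed: the modeling
contract is a complete analytic table.

## Synthetic cohort generator

Real cohorts of this type are access-restricted, so `generate_cohort()`
is a first-class module, not a test fixture. Design choices:

* **Labels first.** Exactly `round(n × prevalence)` positives (default
  prevalence 0.2) are assigned before any feature is drawn. This makes
  prevalence deterministic and lets tests assert exact counts.
* **Numerics** are truncated normals (inverse-CDF sampling) inside the
  physiologic hard bounds, with additive case shifts: the PPC group is
  older (+6 y), has longer anesthesia (+22 min), higher maximum pulse
  (+7 /min), lower minimum SpO₂ (−0.8 %), lower hemoglobin, and slightly
  worse blood pressure, temperature, respiratory-rate and pain profiles.
  Weight is derived from BMI and height rather than drawn independently.
* **Categoricals** come from class-conditional multinomials tilted toward
  open approach, emergency admission, stomach/liver/pancreas sites,
  hepatobiliary-pancreatic malignancy, smoking, limited activity, L-tube
  and multimorbidity in the case group.
* **Flags and symptoms.** Judge flags are computed from the sampled
  vitals via `derive_judge_flags()` — never sampled — preserving the
  causal direction vitals → flags and keeping generated data
  internally consistent (a conforming cohort must validate cleanly).
  The three symptom booleans are threshold functions of the vitals with a
  small label-dependent Bernoulli flip (scale 0.05), so they stay
  informative without being copies of the vitals.
* **Calibration.** The default (`"paperlike"`) effect sizes were chosen
  once so that the full pipeline reaches a test AUROC around 0.8 — the
  regime reported for real cohorts of this kind — by a normal-theory
  separation calculation (the summed squared standardized shifts put the
  oracle AUC near 0.84) followed by a direct check. The `"separable"`
  preset triples the numeric shifts for smoke tests (AUROC > 0.95).

What the generator does *not* emulate: feature correlations beyond the
shared label (vitals are conditionally independent given the class, except
flags/symptoms/bins), missingness, longitudinal trajectories (the window
is already collapsed to min/max summaries), and site-specific coding
idiosyncrasies. Tests passing on this generator therefore demonstrate
pipeline correctness and the direction of methodological effects, not
clinical performance on any real population.

## SHAP importance and input weighting

A preliminary random forest (100 trees, depth 6, balanced class weights —
deliberately small, since only a ranking is needed) is fit on the
index-encoded training features. Per-feature importance is the mean
absolute SHAP value, computed by path-dependent TreeSHAP implemented in
C++ (`src/treeshap.cpp`): node covers come from routing the training data
through each tree, and the attribution satisfies local accuracy (SHAP sums
plus the base value reproduce the forest probability) to machine
precision. Both properties are tested, including against a brute-force
subset-enumeration Shapley oracle on small trees.

Importance is normalized by its maximum — this makes the weight bound
exact — and mapped to input scales

\[ w_i = 1 + \lambda\,\mathrm{imp}_i^{\gamma}, \]

with tuned defaults λ = 0.27, γ = 0.82, so w ∈ [1, 1.27]: important
features are amplified at the encoder input, nothing is dropped. Two
choices were open and are fixed here: importance is computed on the
training split only (never the holdout), and when several fold models are
supplied the per-fold importances are averaged *before* normalization.
λ = 0 reproduces the unweighted input exactly, which is what the ablation
arms rely on.

## Encoder and imbalance handling

The encoder is a two-hidden-layer MLP (256 → 64, ReLU, dropout 0.43)
written directly on R's matrix operations; categorical *and* boolean
features enter through learned embeddings (default width 8 — the tuned
value is not public, so this is a package default) scaled by their
feature weight, numerics as weighted z-scores. Training uses Adam
(batch 256, peak learning rate 2.16 × 10⁻³) for up to 50 epochs with:

* a linear warm-up from a tenth of the peak rate over 5 epochs;
* early stopping on validation AUROC with patience 10 and best-weight
  restoration (the stopping criterion was open; validation AUROC matches
  the optimization target used everywhere else);
* a positive-class weight on the logistic loss, `"auto"` = negative
  count / positive count (4 at 20% prevalence);
* an inverse-frequency weighted sampler drawing with replacement, giving
  an expected 50% positives per batch ("a minimum proportion of positive
  cases" is not a number anywhere, so expected balance is the default);
* optionally focal loss, `−α_t (1−p_t)^γ log p_t` with α multiplying the
  positive-class term only, so γ = 0, α = 1 reduces exactly to plain
  cross-entropy (whether an α term was used at all in the source work is
  unstated; this convention keeps the reduction limit exact and α
  behaves like `pos_weight`).

The latent representation is the *post-activation* hidden-2 output
(pre- vs post-activation was open; post-activation makes the latent the
same object the classifier head would see during encoder pre-training).
Everything is seeded: sampler, dropout masks, initialization; two runs
with the same seed produce bit-identical weights.

## Forest head and decision threshold

The 64-d latents feed a 200-tree, depth-10 probability forest with
inverse-frequency class weights; probabilities are the standard mean of
per-tree class fractions. The decision threshold is calibrated on the
internal validation split: candidates are the midpoints between
consecutive sorted unique validation probabilities plus 0.5 (exhaustive
over achievable confusion matrices), scored by positive-class F1 ("an
F1-like score" is interpreted as positive-class F1; an Fβ and a balanced
sensitivity/specificity criterion are also implemented), ties broken
toward the larger threshold (favoring specificity). Classification is a
strict inequality: a case is positive iff its probability *exceeds* the
threshold. With imbalance handling disabled the threshold is fixed at
0.5.

## Evaluation, search and ablation

The seven-metric panel (precision, recall, accuracy, macro-F1, ROC-AUC,
PR-AUC, specificity) is implemented from the definitions: ROC-AUC as the
tie-aware rank statistic (trapezoidal equivalent), PR-AUC with step-wise
precision interpolation (average precision — interpolation conventions
differ, so the choice is recorded here and tested against a brute-force
oracle). Confidence intervals are percentile bootstrap with 1000 case
resamples, keeping each patient's (label, prediction, probability) triple
paired; a resample that loses a class is redrawn. The CI method was not
specified externally; the percentile bootstrap is the assumption and is
labeled in outputs. Coverage is verified empirically in the acceptance
tests (200 simulated datasets of n = 500 against the generator's
population AUC under a fixed a-priori risk score).

Hyperparameter search is seeded random search over the declared space
with a 5-fold stratified cross-validated AUROC objective; the fold
assignment is fixed per search so all trials are comparable. (The
original tuning used Bayesian optimization over ≈ 500 trials; no such
optimizer is part of this package's dependency set, and random search
keeps the contract — argmax over a logged trial sequence, deterministic
under seed — intact at desk scale, default 50 trials.)

The ablation (`run_ablation()`) trains four arms on identical splits per
seed: `full`; `no_shap` (all weights 1); `no_imbalance` (plain loss,
plain sampler, unbalanced forest, fixed 0.5 threshold); `baseline` (both
removals — the fourth row is read as the simultaneous removal). Metrics
are averaged over seeds.

## Recommendation engine and validation

The rule engine replaces a fine-tuned language model with a deterministic
mapping — by design, not as an approximation: the action space is a fixed
12-item ontology, the evidence relation is tabulated, and determinism is
what makes the validator's soundness provable. The admissible-evidence
map is not tabulated anywhere authoritative, so it is anchored to the
ontology semantics: respiratory actions (1–2) accept respiratory-rate,
SpO₂ and respiratory-symptom evidence; sputum (3) the secretion symptom;
the general monitoring actions (4–5) any abnormal vital; temperature
actions (6–7) temperature and infection symptoms; pain actions (8–9) the
pain score; early ambulation (10) is the basic tier requiring no
evidence; physician escalation (11–12) accepts any abnormal finding. It
ships as data (`action_ontology()`), editable without touching code.

For each abnormal finding the engine emits every admissible action as an
action–evidence–rationale record; high predicted risk adds the monitoring
defaults (4, 5) justified by the risk itself when no finding already
covers them, and the basic action (10) is emitted for every patient. The
validator labels a record `unnecessary_action` if its cited value is in
range, `evidence_mismatch` if abnormal but inadmissible for that action,
`correct` otherwise; risk-justified records are correct iff the action
tier matches the risk. By construction the engine only emits records its
own validator accepts — the tested soundness property. Per-patient scores
average the 5/1 record scores and round half-up into bins 1–5 (the
rounding rule for the averaging step was open; half-up is the assumption
recorded here), and `summarize_scores()` tabulates the five bins.
Rationale strings come from fixed per-action templates and are
deliberately outside the validation contract, which checks
action–evidence consistency only. `build_llm_prompt()` renders the
deterministic prompt (role instruction, itemized patient bullets, JSON
directive) so an external generative model can be slotted in and its
outputs pushed through the same validator and scoring; the package itself
performs no language-model inference.

## Numerical and degenerate-input conventions

* Stable softplus forms for both losses (finite up to |logit| = 100).
* Precision is 0 when nothing is predicted positive; a per-class F1 with
  an empty denominator is 0; AUCs are `NA` under single-class labels.
* An all-equal probability vector makes the threshold optimizer fall back
  to 0.5 with a warning.
* An all-zero importance vector normalizes to all zeros (no division)
  with a warning, and yields unit weights.
* Zero-variance features fail normalization by name; unseen categorical
  levels are errors, never silently bucketed.

## Problem sizes in the shipped tests

The test-suite simulations use the sizes at which each property is
stable and the whole suite stays comfortably re-runnable: ranking
recovery at n = 2000 over 20 seeds; imbalance benefit at n = 2000,
prevalence 0.1, 10 seeds; pipeline sanity at n = 2000 (separable) and
n = 5000 over 10 seeds (paper-like); ablation at n = 2000 over 5 seeds;
bootstrap coverage over 200 datasets of n = 500 with 1000 resamples. The
acceptance script reruns the pipeline at n = 5000.

## Known limitations

Conditional independence of most features given the class means the
generator cannot probe collinearity-driven failure modes; the encoder has
no GPU path and no learning-rate schedule beyond warm-up; probabilities
are not calibrated (no Platt/isotonic step — none is part of the modeled
pipeline); and the recommendation engine's clinical content is exactly as
good as its configured ontology and normal ranges, which are package
defaults, not institutional protocol.
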
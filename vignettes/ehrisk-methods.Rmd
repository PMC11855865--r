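---
title: "Risk sequence models and relative contributions for longitudinal EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk sequence models and relative contributions for longitudinal EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ehrisk)
```

## The problem

Patients with Alzheimer's disease frequently develop psychosis (hallucinations
and delusions) in the years after diagnosis, and that transition carries a
sharply worse prognosis. Given a patient's longitudinal electronic health
record (EHR) — dated diagnosis codes, medication orders, and abnormal
laboratory flags — we want to (1) predict whether psychosis onset (a psychosis
diagnosis or a first antipsychotic order) will occur within the next three
months, and (2) rank the clinical features the model relies on as risk-raising
or protective, at both the drug level and the drug-target (protein) level, the
latter as a screen for repurposing candidates.

`ehrisk` implements that full pipeline: cohort construction from an event
stream, sequence encoding, four risk-model families, perturbation-based
feature contributions, and the relative-contribution (RC) statistic with
Wilcoxon testing and multiplicity control. Because real hospital EHR streams
cannot be redistributed, the package also contains a first-class synthetic
generator with planted ground-truth effects, and every downstream claim in the
test suite is validated against that ground truth.

## Cohort construction

An *index date* anchors each sample: model inputs are the events in the
look-back window `[index − 365 d, index)` and the outcome is sought in the
window `(index, index + 90 d]`. Both windows are half-open and exclude the
index date itself, so the anchoring encounter can never leak the label, and an
outcome on the index date disqualifies that candidate anchor. "Three months"
is fixed at 90 days and "one year" at 365 days; calendar-month arithmetic was
rejected as ambiguous (is 3 months after Nov 30 = Feb 28 or Mar 2?).

A patient is eligible at an encounter date when (i) an anchoring dementia
diagnosis precedes it strictly, (ii) at least a full look-back of record
exists before it, and (iii) no psychosis diagnosis or antipsychotic order
occurred before it. A *case* is anchored at the latest eligible encounter with
an outcome event in its outcome window; a *control* at the latest eligible
encounter with none. Ineligible patients are reported with machine-readable
reasons (`NO_AD`, `INSUFFICIENT_HISTORY`, `PRIOR_PSYCHOSIS`,
`PRIOR_ANTIPSYCHOTIC`, `NO_ELIGIBLE_ENCOUNTER`) — counts always partition the
input. Psychosis diagnoses dated the same day as a delirium diagnosis are
masked up front: transient delirium is easily mis-coded as psychosis onset.

Two decisions here were genuinely open and are this package's own:

* **Case anchor.** The control rule ("latest encounter") is mirrored for
  cases: the latest eligible pre-outcome encounter anchors the primary case
  sample. Earlier eligible encounters are used only for augmentation.
* **Augmentation.** Case augmentation is realized as multi-anchor resampling —
  up to `augmentation_max_per_case` additional samples anchored at distinct
  earlier eligible encounters of the same patient. This adds no fabricated
  events and preserves patient identity, which matters because splitting is
  *patient-level*: an 8:1:1 train/validation/test partition of patients, never
  of samples, so augmented copies cannot leak across splits.

## Encoding

Each sample becomes an ordered sequence of visits; a visit is the deduplicated
set of integer code indices on one encounter date plus the day gap to the
previous visit. The vocabulary is built from training-split patients only:
laboratory codes are ranked by patient-level frequency and capped at the top
89 (the most frequently tested labs), all codes are ordered by frequency with
a lexicographic tie-break, and one index is reserved for out-of-vocabulary
codes — unseen codes map to that shared token rather than vanishing, which
preserves visit structure at prediction time. Laboratory features are binary
abnormal flags keyed by test identifier; normal results are not tokens.
Diagnosis codes can be normalized to 3-character ICD-10 groups through a
user-supplied ICD-9→ICD-10 lookup (a small synthetic lookup ships in
`inst/extdata/` for tests and examples). The overall vocabulary cap (30,000)
is honoured as a maximum, not a target.

Ablations (`ablate_codes()`) remove one code type from encoded sequences,
drop visits that become empty, and recompute day gaps — used to measure how
much each data modality contributes to discrimination.

## Models

Four families share one training harness (`train_risk_model()`):

* **LR** — logistic regression on the binary presence bag-of-codes.
* **RNN** — stacked tanh recurrent layers over visit embeddings.
* **TLSTM** — an LSTM whose long-term memory is discounted between visits by
  `g(Δt) = 1/log(e + Δt)` (days): the previous cell state is decomposed
  through a learned projection, its short-term component discounted by
  `g(Δt)`, and the result recombined before the usual gate updates. `g(0)=1`,
  strictly decreasing, always positive.
* **RETAIN-style** — two-level attention computed in reverse time: one GRU
  yields per-visit attention (softmax over visits), a second GRU yields
  per-coordinate code-level attention (tanh), and the prediction is a
  logistic read-out of the attention-weighted sum of visit embeddings.

No deep-learning framework is involved: forward and backward passes are
hand-derived batched matrix algebra (BLAS), optimized with Adam plus decoupled
weight decay, with inverted dropout on visit embeddings during training. The
test suite verifies every architecture's gradients against central finite
differences at tolerance 1e-7. Training is deterministic given the
configuration seed. Early stopping monitors validation AUROC and halts after
`patience` epochs without improvement, restoring the best-epoch weights; the
decision threshold for precision/recall/F1 is the max-F1 point on the
validation split, frozen before the test split is touched.

Defaults follow the published recipe for this model family — embedding 128,
hidden 128, dropout 0.2, two layers, input cap 30,000, patience 3. The
optimizer settings that recipe leaves unstated (learning rate 1e-3, batch 64,
weight decay 1e-3) are exposed in `model_config()`. For the desk-scale
synthetic studies shipped in the acceptance suite we use a protocol tuned for
those problem sizes (see "Synthetic study protocol" below); hyperparameters
are study choices, not constants of the method.

## Contribution analysis

The importance statistic is perturbation-based, not attention-based (the
RETAIN attention weights are available but deliberately unused as the primary
importance — perturbation is model-agnostic and comparable across families):

1. **Occlusion FC.** For one occurrence of a feature — one (visit, code)
   instance — the feature contribution is `p(full sequence) − p(sequence with
   that occurrence removed)`; emptied visits are dropped and day gaps
   recomputed. A patient's FC for a feature is the **sum over its
   occurrences**, each occluded independently from the intact sequence.
   Under an LR bag model this reduces to the closed form
   `σ(z) − σ(z − w)` for a singly-occurring feature, which the tests assert
   to 1e-10. Note an edge: a feature present in several visits of a binary
   bag survives any single occlusion, so its LR contribution is 0 — sequence
   models do not share this degeneracy.
2. **Normalization.** Per patient, `fc_normalized = fc_raw / Σ_features
   |fc_raw|`: absolute shares sum to 1 per patient, so patients with many
   encounters (hence many occurrences) do not dominate. This is also where
   the "balanced and fair" scaling lives; it is isolated in
   `normalize_fc()` so alternatives can be plugged in.
3. **RC.** For each feature with at least `min_support` exposed patients per
   group (default 10 — medians and rank tests are unstable below that),
   `RC = median(fc_normalized | events) / median(fc_normalized |
   non-events)`. Medians, not means: FC distributions are heavy-tailed.
   `RC > 1` flags a risk association, `RC < 1` protective. A zero
   denominator median yields an explicit `UNDEFINED` flag; opposite-sign
   medians yield `INDETERMINATE_SIGN`; nothing is silently dropped.
4. **Testing.** Per feature, a two-sided Wilcoxon rank-sum test on the
   normalized FCs (exact enumeration when the pooled n ≤ 12 with no ties,
   tie-corrected normal approximation otherwise), then Benjamini–Hochberg
   (reported as `q_fdr`, cutoff 0.05) and Bonferroni across the features
   actually tested in the run — Method 1 and Method 2 families are corrected
   separately, since they are reported separately.

## Drug-target layer

A many-to-many drug→protein map drives two complementary analyses.
**Method 1 (drug-focused)** trains on drug tokens; afterwards each patient's
drug FCs are pooled *additively* onto targets (`pool_fc_by_target()`).
Additivity is forced by consistency: FC is already a per-patient sum over
occurrences, and under a one-to-one map the pooled table must equal the drug
table exactly (a property the tests assert). **Method 2 (target-focused)**
replaces each mapped drug token by its protein tokens *before* vocabulary
construction, so patients taking different drugs with a shared target pool
into one feature, raising the sample size behind the target-level test.
Direction of modulation (agonist vs antagonist) is deliberately ignored — a
known limitation of the underlying map. Both the drug-level and the
target-pooled reports are emitted for Method 1, labelled distinctly.

## The synthetic generator

`generate_cohort_stream()` emulates the *shape* of a dementia-cohort EHR
stream, not its clinical semantics:

* Each patient has `2 + Poisson` encounters (floor 2, so every patient has a
  usable sequence) over an observation span, default 550 days with a mean of
  20 encounters — roughly the monthly-contact cadence of an elderly memory-
  clinic population. One early visit carries the anchoring dementia
  diagnosis; one visit is guaranteed anchor-eligible.
* Codes occur independently per visit at catalog prevalences (default 0.05
  per visit across 12 diagnosis, 12 medication, 6 lab codes).
* One anchor encounter is drawn uniformly among eligible visits; the outcome
  probability there is `plogis(baseline_logit + Σ planted β over codes in the
  look-back)`, default baseline 0.2. Cases get a psychosis diagnosis or an
  antipsychotic order (50/50) uniformly within the 90-day window. Optional
  *order effects* add β only when code A first occurs before code B —
  a signal invisible to any bag-of-codes model.
* A drug-target map can be generated jointly (every drug ≥ 1 target;
  shared targets guaranteed by pigeonhole when drugs outnumber targets).

One seed drives everything via a single vectorized draw, so an identical
configuration regenerates a byte-identical stream. What the generator does
*not* model — real ICD semantics, numeric lab values, visit-type and
insurance structure, confounding by indication, code co-occurrence
correlation — bounds what passing tests mean: they validate the machinery and
the statistic's operating characteristics, not clinical transportability.

## Synthetic study protocol and numerical choices

The packaged studies (test suite and `scripts/acceptance.R`) run at desk
scale: cohorts of 600–5,000 patients, 30-code catalogs, planted effects of
|β| = 1–2. At those sizes the published 128-dimensional settings are heavily
overparameterized, so the studies train the sequence models with the
dimensions scaled to the problem (embedding/hidden 32), a learning rate of
5e-3, weight decay 0.03, up to 40 epochs with patience 15. For contribution
analyses, occlusion FCs are averaged over three independently trained model
replicates (different initialization and shuffle seeds on the same split):
single-model attributions carry initialization noise that the averaging
removes, while genuine planted effects are stable across replicates.

Two opposing failure modes motivated these choices, and neither can be
fully eliminated: an undertrained model yields attribution noise that
swamps real effects, while a sharply trained one acquires small but
systematic weights on uninformative codes — partly in-sample chance
associations that any faithful model learns, partly coupling introduced by
occlusion itself on an attention architecture (removing any token perturbs
the softmax visit-attention normalizer and thereby re-weights every other
visit). Because the per-patient Wilcoxon on model attributions is
considerably more powerful than a marginal association test on the same
data, those systematic micro-weights can reach nominal significance in
sufficiently sharp models. In our simulations the planted-effect power and
the null-code false-positive rate rise together with attribution sharpness;
the protocol above sits at the balance point we judged most defensible.
Users should read the RC q-values as evidence about what *the model* relies
on, and treat borderline discoveries (q near the cutoff, RC near 1) with
corresponding caution.

Other numerical choices: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8); early-stopping
improvements must exceed 1e-6; Wilcoxon switches from exact to approximate
beyond pooled n = 12 or at the first tie; all randomness flows from declared
integer seeds, with per-stage sub-seeds derived by a fixed affine map kept
below 2³¹.

## Known limitations

* The RC statistic characterizes the *model's* reliance on a feature; with
  confounded real data that is association, not causation — no propensity or
  indication adjustment is attempted.
* The RC significance test is anti-conservative with respect to ground
  truth: it tests whether the model systematically uses a feature, and
  models legitimately use chance associations present in their training
  sample. Expect some nominally significant features with small true
  effects, especially alongside strong signals (the BH threshold adapts to
  them).
* Binary-presence LR makes multi-occurrence features invisible to occlusion
  (see above); interpret LR-based FCs accordingly.
* The drug-target layer treats all targets of a drug equally and ignores
  modulation direction and affinity.
* The generator's independence assumptions (codes independent given the
  visit; visits homogeneous) make the synthetic calibration results a lower
  bound on the difficulty of real data.
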
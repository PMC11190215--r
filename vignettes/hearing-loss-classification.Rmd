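---
title: "Classifying hearing-loss types from pure-tone audiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hearing-loss types from pure-tone audiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiotype)
```

## The problem

Pure-tone audiometry measures a patient's hearing threshold, in dB HL, for
air conduction at the octave frequencies 125–8000 Hz and for bone conduction
at 250–4000 Hz (the two extremes are not tested by the bone vibrator). The
relationship between the two curves determines the *type* of hearing loss:

* **conductive** loss — elevated air thresholds with normal bone thresholds
  and a positive air–bone gap (outer/middle-ear pathology);
* **sensorineural** loss — both curves elevated together, no gap
  (cochlear/neural pathology);
* **mixed** loss — both curves elevated *and* a gap;
* **normal** hearing — both curves below the loss cutoff, no gap.

`audiotype` implements this determination twice, deliberately: once as a
deterministic diagnostic **rule engine**, and once as a trainable
**sequence classifier** (a bidirectional LSTM) that learns the mapping from
raw threshold sequences. Because the rule engine provides exact labels for
any complete audiogram, the two routes check each other: on synthetic data
the classifier's held-out accuracy is bounded above only by its own
capacity, and the package's tests exploit this.

## Validity screening

Clinical exports contain malformed and physiologically impossible records.
Before any labelling, every audiogram passes five independent checks
(`apply_qc()`), after Margolis and Saly's audiogram-validity rules:

1. **completeness** — air thresholds at 250–8000 Hz and bone thresholds at
   500–4000 Hz must all be present (125 Hz air and 250 Hz bone are optional);
2. **air range** — air thresholds must lie in −10…110 dB HL, with a reduced
   90 dB maximum at low frequencies;
3. **air steps** — adjacent-octave air thresholds may differ by at most
   30 dB;
4. **bone range** — bone thresholds must lie in −10…60 dB HL, reduced to
   40 dB at 250 Hz;
5. **air–bone relation** — wherever both conductions were measured, the
   signed gap AC − BC must lie in −10…50 dB.

Two of the published clauses are ambiguous, and we chose defaults rather
than guessing silently. The reduced air/bone maxima ("when the limit is
90/40 dB") are applied **at and below 250 Hz**, because audiometer output
limits are lower at low frequencies; `qc_config(low_freq_strict = FALSE)`
selects the opposite reading. The step rule is applied **symmetrically**
(|Δ| ≤ 30 dB, bounds inclusive): a literal one-sided 0–30 dB reading would
reject every audiogram that improves toward high frequencies, which
contradicts the existence of rising conductive-loss configurations; the
bounds are configurable as a signed interval. QC is a pure filter — records
are never repaired or imputed.

## The diagnostic rule engine

Labelling (`classify_audiograms()`) uses three quantities per ear, all
compared unrounded:

* **PTA4** — the mean threshold at 500, 1000, 2000 and 4000 Hz, per
  conduction. The WHO normal-hearing criterion is PTA4 < 20 dB HL; 20 dB
  exactly classifies as loss.
* **high-frequency means** — air over 4000 and 8000 Hz; bone over the grid
  frequencies within 4–6 kHz. Since bone conduction is never measured above
  4 kHz, the bone criterion reduces to the 4000 Hz threshold alone; the
  frequency lists are configurable (`rule_config()`).
* **air–bone gap presence** — gaps are AC − BC at the four PTA frequencies;
  a gap is *present* when at least three gaps reach 10 dB or any single gap
  reaches 15 dB (bounds inclusive). Negative gaps never count.

The four class predicates follow the standard rule table (normal /
conductive / sensorineural / mixed as sketched above). Combinations matched
by no row — e.g. a normal PTA4 alongside a single large gap, or an elevated
air PTA4 with normal bone but no gap — return **indeterminate**. A clinical
dataset labelled by audiologists has no such class, because experts resolve
edge cases by judgment; an automatic engine must instead be explicit about
them. Indeterminate records are reported and excluded from training.

## Synthetic audiograms

The generator (`generate_audiograms()`) stands in for confidential clinical
data. Class membership is multinomial with configurable proportions,
defaulting to a large clinical archive's mix: 17.17% normal, 4.37%
conductive, 26.71% mixed, 51.69% sensorineural. (These printed percentages
total 99.94%; the generator renormalizes them exactly.)

Each audiogram is drawn from a parametric curve family: a *bone-level*
curve `L(f) = base + slope · octave(f) + jitter(f)`, quantized to the 5 dB
clinical step, with the air curve sitting `gap(f)` above it. Per-class
priors: normal and conductive use base ∈ [−5, 12] dB; mixed base ∈
[25, 50]; sensorineural base ∈ [25, 55] with a non-negative slope bias;
gap ∈ [15, 40] dB (±5 per-frequency) for the gap classes and below 10 dB
for the others; jitter is Gaussian with σ = 2 dB. The bone curve is
generated *first* and air derived from it, so clipping bone into its
audiometer range can never manufacture a spurious air–bone gap. The
optional thresholds are recorded with probability 0.9 (125 Hz air) and 0.5
(250 Hz bone, where its level permits).

Candidates are then **rejection-sampled against the package's own
oracles**: a draw is accepted only if it passes all five validity checks
and the rule engine returns exactly the intended class. The priors
therefore only shape realism; label correctness is guaranteed by
construction, and two invariants hold for every generated set — QC rejects
nothing, and `classify_audiograms()` reproduces the stored labels exactly.

What the generator does **not** model: patient age/sex structure, bilateral
correlation between ears, test–retest measurement noise, and whatever
threshold-shape regularities distinguish real pathology beyond the rule
criteria. Passing tests on synthetic data therefore demonstrate that the
pipeline learns and evaluates the *diagnostic mapping* correctly — not that
the reported accuracy transfers to any clinical population.

## Feature encoding and normalization

Each audiogram becomes a 7-step sequence ordered by frequency, with two
features per step (air, bone) and a bone-presence flag
(`encode_sequences()`). Four feature-scaling schemes are available
(`fit_normalizer()`): z-score (population sd), min–max, robust
(median/IQR, linear-interpolation quantiles) and max-abs. Statistics are
estimated **per channel over observed values only, from training data
only** — inside cross-validation the normalizer is refitted on every
training fold, never globally, so no test-fold information leaks into the
transform. Unmeasured thresholds are filled with 0 *after* the transform
(the channel centre under z-score); the presence flags can be added as a
third input channel (`model_config(use_mask_channel = TRUE)`), off by
default to match the two-feature encoding.

Class imbalance is corrected by weighting the training loss with the
balanced heuristic `w_c = N / (4 n_c)` (`compute_class_weights()`), which
conserves `sum(n_c w_c) = N`; no published formula exists for this step, so
the standard one is used and custom weights can be passed instead.

## The sequence classifier

The classifier (`train_sequence_model()`) is a recurrent network written
directly in vectorized R — forward pass, backpropagation through time and
the Adam optimizer, with correctness pinned by finite-difference gradient
checks in the test suite:

* layer 1: LSTM over the 7 steps, bidirectional by default (64 units per
  direction, outputs concatenated), unidirectional for the `"lstm"`
  variant;
* dropout 0.2;
* layer 2: LSTM (32 units), final hidden state only;
* dropout 0.2; dense layer; softmax over the four classes.

Training uses class-weighted cross-entropy, Adam at 1e-3, mini-batches of
32, at most 150 epochs with early stopping (patience 10 on the loss of an
internal 10% validation split), restoring the best-validation weights. The
hidden sizes and rates are conventional defaults for a 7 × 2 input and are
all exposed in `model_config()`. Every stochastic element — initialization
(Glorot uniform, forget-gate bias 1), shuffling, the validation split,
dropout — is driven by one seed through a private RNG stream, so a fixed
(data, config, seed) triple reproduces the model bit-for-bit in this
single-threaded implementation.

Numerical choices: softmax is computed with max-subtraction; cross-entropy
clamps probabilities at 1e-12; a non-finite loss aborts training rather
than continuing silently. Argmax ties at prediction resolve to the first
class in the fixed order (normal, conductive, mixed, sensorineural).

The comparison baseline (`train_tree_baseline()`) is a C4.5-style decision
tree: binary splits at midpoints of consecutive distinct feature values,
chosen by **gain ratio** (information gain over split information, in
bits), majority leaves, no pruning by default. It consumes flat
12-dimensional vectors (7 air + 5 bone thresholds); unmeasured bone values
take the paired air threshold (gap 0) and a missing 125 Hz air value is
carried from 250 Hz — sentinel choices, documented rather than hidden.
Error-based pessimistic pruning is deliberately out of scope; on this
problem the unpruned gain-ratio tree already sits within a point of its
ceiling, and pruning would not change the directional comparison.

## Evaluation protocol

`run_cv_experiment()` performs stratified K-fold cross-validation (default
K = 10): per class, indices are shuffled (seeded) and dealt round-robin, so
per-class fold counts differ by at most one. Within each fold the
normalizer and class weights are computed on the training part only. Fold
metrics (`metrics_from_confusion()`) follow the standard confusion-matrix
family — per-class one-vs-rest precision, recall and F1, overall accuracy —
with aggregate precision/recall/F1 **support-weighted** by default (macro
selectable). Fold summaries report the arithmetic mean and the population
(ddof = 0) standard deviation. Predictions are pooled across folds into a
single confusion matrix and a pooled micro-averaged one-vs-rest ROC AUC:
the four binary one-vs-rest problems are flattened into one set of
(indicator, score) pairs and the AUC is the normalized Mann–Whitney rank
statistic with ties counting one half — equal to exhaustive pair counting,
which the tests verify. Whether a published single confusion matrix
represents pooled CV predictions or one representative fold is often
unstated; pooling is chosen here and stated.

Paired classifiers are compared with McNemar's test
(`mcnemar_compare()`): from per-sample correctness, the discordant counts
n01 and n10 give a chi-square statistic with 1 df, with Edwards' continuity
correction by default (the classical uncorrected statistic is a flag away);
with no discordant pairs the test is degenerate and reports statistic 0,
p = 1 rather than an error. At small discordant counts the corrected
chi-square tracks the exact binomial test, which the suite checks.

## Problem sizes in the shipped tests

The test-suite and acceptance-script runs use 10,000 synthetic audiograms
(8,000 train / 2,000 held out) for the end-to-end learnability checks,
~1.3 × 10⁵ grid points for the rule-engine truth table, and smaller seeded
sets elsewhere; these sizes give stable statistics (e.g. the conductive
count at 4.37% has a binomial sd of ≈ 20 at n = 10,000) while keeping a
full run to a few minutes. Because the labels are a deterministic function
of the thresholds, the expected held-out accuracy ceiling is 100%; the
shipped check requires ≥ 98%.

## Known limitations

* Synthetic audiograms are rule-consistent but not distribution-matched to
  any clinical population; no claim about clinical accuracy follows from
  them.
* The rule engine implements the rule table literally; expert labellers may
  deviate from it on edge cases, and such disagreements are unobservable
  here.
* The bone high-frequency criterion nominally spans 4–6 kHz but is
  evaluable only at 4 kHz on the measured grid.
* Severity grading, audiogram-shape configuration and inter-ear symmetry
  are out of scope: the package classifies type only.
* Exact reproducibility is guaranteed for single-threaded runs; under a
  multi-threaded BLAS, floating-point reduction order may perturb results
  at machine precision.
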
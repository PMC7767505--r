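---
title: "Methods: cascaded CNN classification of sigma-factor promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded CNN classification of sigma-factor promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcascade)
```

## The problem

Bacterial promoters are short DNA regions upstream of a transcription start
site (TSS) where RNA polymerase initiates transcription. In *E. coli* the
sigma subunit of the holoenzyme recognizes the promoter, and the sigma type
(σ70, σ54, σ38, σ32, σ28, σ24) defines the promoter subclass. Canonical σ70
promoters carry the hexamer TATAAT centered near −10 and TTGACA near −35
relative to the TSS, both heavily degenerate in real sequences.

`promcascade` solves two nested tasks over fixed 81-nt windows: decide
whether a window is a promoter at all, and if so assign its sigma subclass.
Both tasks are solved by the same small binary convolutional network applied
in a cascade.

## The cascade

Rather than a 7-way softmax over heavily imbalanced classes, classification
is an ordered elimination of one-vs-pool binary decisions:

| stage   | positive class | negative pool            |
|---------|----------------|--------------------------|
| ProMN   | any promoter   | non-promoter             |
| Sigma70 | σ70            | σ54, σ38, σ32, σ28, σ24  |
| Sigma24 | σ24            | σ54, σ38, σ32, σ28       |
| Sigma28 | σ28            | σ54, σ38, σ32            |
| Sigma38 | σ38            | σ54, σ32                 |
| Sigma32 | σ32            | σ54                      |

At prediction time stages run in this order with *first-accept* semantics:
a ProMN probability below the threshold ends the cascade with
`NON_PROMOTER`; otherwise the first sigma stage whose probability reaches
its threshold assigns its label, and a record rejected by all five sigma
stages receives the residual label σ54 (which, being last, needs no
classifier of its own). Stages after the first acceptance are not evaluated;
their reported probabilities are `NA`.

Design choices that were genuinely open:

* **Decision threshold.** No published threshold exists for the stages; we
  use 0.5 everywhere and expose it per stage
  (`cascade_model()$thresholds`).
* **Sigma38's negative pool.** A literal reading of the published stage
  table would make σ38 its own negative, which is inconsistent with the
  elimination scheme; the pool is {σ54, σ32}.
* **Short-circuiting.** Whether downstream stages were evaluated for
  reporting in the original tool is unknowable from the description; we
  short-circuit, and the test suite pins that behavior via call-counting
  stub classifiers.
* **No resampling.** Class imbalance is handled purely by the cascade
  structure; synthetic minority oversampling is deliberately absent (it
  invites overfitting on sequence windows this short).

## The binary CNN

Each stage is the same architecture on one-hot input. A sequence is encoded
with channel order A, T, C, G — A=(1,0,0,0), T=(0,1,0,0), C=(0,0,1,0),
G=(0,0,0,1) — giving an 81 × 4 matrix. The layer pipeline is

```
conv1d(32 filters, kernel 7, ReLU) → batchnorm → avgpool(2, stride 2)
→ dropout(0.35) → conv1d(32 filters, kernel 5, ReLU) → avgpool(2, stride 2)
→ dropout(0.30) → flatten → dense(16, ReLU) → dense(1, sigmoid)
```

trained with binary cross-entropy,
\(H_p(q) = -\tfrac{1}{N_{pos}+N_{neg}}\big[\sum \log p(y_i) + \sum \log(1-p(y_i))\big]\),
and SGD with momentum 0.95 and learning rate 0.007. L2 regularization
(default λ = 1e−3) is applied to both convolution and both dense weight
matrices. Batch normalization follows the first convolution only; this
asymmetry is intentional and preserved.

Settings that had to be fixed here because no published value exists:

* **Padding.** Convolutions use "same" padding, so positions are preserved:
  81 → pool → 40 → pool → 20, giving a flattened width of 20·32 = 640 and
  dense-layer weight count (640+1)·16 = 10 256. Average pooling is unpadded
  and drops the trailing element at odd lengths (81 → 40).
* **Batch-norm placement.** The default order is conv → ReLU → batchnorm;
  the alternative conv → batchnorm → ReLU is switchable
  (`arch_config(batchnorm_before_relu = TRUE)`).
* **Schedule.** 50 epochs of mini-batches of 32, chosen for desk-scale
  runs; both are exposed in `train_config()`.
* **Initialization.** Fan-in-scaled normal ("He") weights from a seeded
  stream; biases zero; batch-norm gamma 1 / beta 0. Running batch-norm
  moments use exponential smoothing with factor 0.9 and ε = 1e−5.
* **Loss clipping.** Probabilities are clipped to [1e−7, 1−1e−7] before
  logarithms.
* **Determinism.** `fit()` re-initializes weights from `train$seed`, and
  shuffling and dropout draw from the same seeded stream, so (data, seed)
  fully determines the final weights. `train_cascade()` derives stage seeds
  as `seed + stage_index − 1`. Inference disables dropout and uses running
  batch-norm moments, so predictions are deterministic and independent of
  batching.

The trainable parameter counts are closed-form and audited in the tests:
conv1 (7·4+1)·32 = 928, conv2 (5·32+1)·32 = 5152.

## Sequence handling

Input FASTA is parsed with Biostrings; sequences are uppercased, and any
character outside A/C/G/T — including N and other IUPAC codes — is rejected
(matching the alphabet contract of the original web tool). Labels travel
either in headers as `id|LABEL` or in a two-column TSV.

Redundancy removal is a greedy first-seen-wins filter on ungapped identity
(matching positions / length) for equal-length sets, with the conventional
0.8 cutoff. This is a transparent approximation of word-based greedy
clustering tools such as CD-HIT, not a reimplementation: it is exact about
*which* pairwise identity it uses, at the cost of ignoring gaps and
clustering heuristics. It is idempotent, and its edge behavior (threshold
above 1 keeps everything, 0 keeps only the first record) is pinned by tests.

## The synthetic benchmark generator

Real benchmark promoters (RegulonDB-derived) are external data, so the
package ships a generator that makes every pipeline testable offline.
Windows are 81 nt with the TSS placed at position 61, so the window spans
−60..+20; the −10 hexamer TATAAT occupies positions 49–54 and the −35
hexamer TTGACA positions 24–29 (1-based, inclusive). This registration is a
package convention — configurable in `synth_config()` — since window
anchoring conventions differ between curated datasets.

Promoter records are uniform background with the two hexamers plus one
class-distinguishing 6-mer (positions 10–15, a distinct motif per sigma
class) planted, after which every planted position is independently
substituted by a *different* base with probability `mutation_rate`
(default 0.1, a moderate degeneracy). Non-promoters are pure uniform
background. `table1_counts()` reproduces the benchmark composition
(2860 non-promoters; 1694/94/163/291/134/484 for σ70/σ54/σ38/σ32/σ28/σ24),
optionally scaled.

What this emulates: window length, class imbalance, positionally anchored
degenerate motifs, and a motif-free negative class. What it does not:
positional jitter of real TSS annotation, composition bias of genomic
background, correlated motif degeneracy (real promoters deviate from
consensus in structured ways), any true sequence determinant of sigma
class, and the near-promoter hardness of negatives drawn from a real
genome. Consequently, passing the learning checks shows the implementation
can extract planted positional signal through the full pipeline — it does
not certify benchmark-level accuracy on real data, where class boundaries
are far softer. Held-out metrics on the synthetic benchmark (≈98–99%
promoter accuracy) sit well above the ~90% reported on curated data, as
expected for separable planted motifs.

## Evaluation

From TP/TN/FP/FN: Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = (TP+TN)/(TP+TN+FP+FN), and
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A zero factor in
the MCC denominator is reported as MCC 0 with an explicit
`mcc_undefined` flag rather than silently; Sn/Sp are `NA` when their class
is absent. The test suite checks all four formulas against an independent
brute-force implementation on 1000 random confusion matrices at 1e−12.

Cross-validation is stratified 5-fold (per-class fold sizes differ by at
most one), deterministic given its seed; an unstratified mode exists.
ROC/AUC uses the Mann–Whitney rank formulation, so ties between a positive
and a negative score count one half; this equals brute-force pairwise
concordance, which the tests verify on random score sets. Stage-level CV
metrics are computed as standalone one-vs-pool binary tasks (the cascade
conditional variant can be assembled from `cascade_predict()` output, whose
per-stage probabilities are reported for exactly this purpose). For
promoter-only independent test sets, per-class performance is reported as
TP/FN pairs, since no negative class exists.

The hyper-parameter grid spans filters {8,16,32,64,128}, kernels
{3,5,7,9,11}, pooling {2,4}, dropout {0.15..0.45 by 0.05} and dense units
{8,16,32,64}. By default one value per field is drawn and applied to both
convolutions / both dropout layers (1400 configurations); an untied mode
draws them independently. Ranking is by cross-validated mean MCC with
deterministic tie-breaking on grid order.

## Problem sizes used in the shipped checks

The test suite trains at benchmark scale only where the property needs it:
the learning-sanity checks use 500+500 promoter/background records at
mutation rate 0.1 (50 epochs) for the binary task, and 360 non-promoters +
120 per sigma class for the full 7-way cascade; structural and determinism
checks use a reduced architecture (4 filters, kernel 3, 4 dense units) and
a few epochs. The acceptance script runs the full pipeline on the standard
composition at half scale (a 2860-record promoter/background core plus
subclasses) with an 80/20 stratified split. These sizes are the package's
desk-scale defaults; nothing prevents running the full-scale composition
via `table1_counts(scale = 1)`.

## Known limitations

* The synthetic generator's class motifs are fictions; results on it upper-
  bound nothing about real promoters.
* The identity filter ignores gaps and is quadratic in the worst case;
  it is intended for benchmark-sized sets (thousands), not genome-scale.
* The CNN is CPU-only, single-threaded R; it is sized for 81-nt windows and
  would need compiled kernels for much longer inputs.
* Calibration of stage probabilities is raw sigmoid output; no isotonic or
  Platt scaling is applied before thresholding.
* σ54 is only ever assigned by elimination, so its precision is bounded by
  the specificity of the five sigma stages above it.
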
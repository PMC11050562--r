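---
title: "Predicting adverse drug reactions from SMILES: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adverse drug reactions from SMILES: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serious idiosyncratic adverse drug reactions (ADRs) — QT-interval
prolongation, teratogenicity, rhabdomyolysis — are rare, mechanistically
murky, and catastrophic when missed. The datasets available for modelling
them are small tables of marketed drugs (one to a few hundred molecules)
with binary risk labels distilled from regulatory labelling text. adralert
implements a chemical-language-model pipeline for this setting: molecules
enter as SMILES strings, a transformer encoder turns each token into an
embedding, a small CNN head predicts the binary risk, and the encoder's
attention maps are pooled into per-atom importance scores that are compared
with a catalog of structural alerts (SMARTS patterns for toxicity-associated
functional groups such as amines, ethers, aromatic halides, carboxylic
acids, imide N–H and sulfonamides).

## Pipeline and model

**Canonicalization.** Every molecule is reduced to its largest covalent
fragment (salts lose their counter-ion), stripped of stereo descriptors by
default (the printed SMILES of the drugs this method is applied to carry no
stereo marks, even for chiral drugs such as quinidine; `keep_stereo = TRUE`
preserves them), and canonicalized with Open Babel. Unparseable rows are
dropped, counted and reported — attrition is never silent, because the
curated ADR datasets themselves show unexplained losses between selection
and retrieval.

**Tokenization.** A regex tokenizer splits SMILES into atom tokens
(including bracket expressions like `[nH]` and two-letter halogens) and
non-atom tokens (bonds, ring digits, parentheses), with an exact
token-to-atom map. The map is what lets attention over tokens become scores
over atoms.

**Encoder.** The encoder is a transformer with rotary positional embeddings
and linear (kernelized) attention using the elu(x)+1 feature map. Linear
attention computes outputs in O(length) through the factorization
φ(Q)(φ(K)ᵀV) / (φ(Q)φ(K)ᵀ1) and never forms an attention matrix; because
attribution needs one, the package materializes the exact kernelized
attention (row-normalized φ(Q)φ(K)ᵀ) at encode time, which is O(n²) only at
analysis time and exact, not an approximation. Two encoder kinds satisfy
one contract: a self-contained *reference encoder* (2 layers, 4 heads,
d_model 64, deterministically initialized from a seed, frozen) and an
adapter for locally converted pre-trained checkpoints. The reference
encoder is a random-feature encoder: it makes the full pipeline runnable
and testable offline, and its token embeddings are informative enough for
the classification head to learn from, but its attention weights are not
trained (see "Limits" below).

**Classification head.** Two 1-D convolutions over the token dimension —
d_in → 3·d_in then 3·d_in → d_in, kernel 3, padding 1 so sequence length is
preserved, each with batch normalization and ReLU — followed by a masked
mean-pool over non-pad positions, a hidden fully connected layer with
dropout, and a softmax output; trained with AdamW on cross-entropy.
The sequence-to-vector reduction is a masked mean-pool: it is
length-invariant and ignores padding, and the batch-norm statistics are
computed over valid positions only and frozen at evaluation, which makes
inference batch-size invariant and metrics deterministic. Hyperparameters
not dictated by the architecture are defaults, all overridable and all
recorded in the fitted model: learning rate 1e-3, batch size 32, weight
decay 1e-2, dropout 0.2, hidden width = d_in, early stopping on an internal
stratified validation split (15%) with the best-epoch weights restored.

**Augmentation.** SMILES enumeration writes the same molecular graph under
random atom orderings; every variant canonicalizes back to its source,
which is both the correctness invariant and the guard the implementation
enforces. Augmentation is applied *after* fold splitting and only to
training folds; evaluation always scores one canonical SMILES per drug.
The alternative — augmenting before splitting — leaks a drug across folds
and inflates test metrics with correlated copies, so it is not offered.

**Evaluation.** Stratified group fivefold cross-validation over drugs
(never variants), reporting nine metrics: accuracy, recall rate, precision,
MCC, balanced accuracy, F1, AUROC, AUPRC and specificity, aggregated as
mean ± sample (n−1) standard deviation across folds. AUROC uses the
rank-sum statistic with midranks for ties; AUPRC uses step interpolation
(no linear interpolation between PR points). Degenerate denominators are
defined to 0 with a logged warning — MCC with any zero marginal is 0.

**Attribution.** Attention tensors are averaged over layers and heads, then
over the receiving axis (column means), giving one nonnegative score per
token; boundary tokens are excluded; atom tokens pass their score to their
atom. The pooling axis is configurable (`received`, `emitted`,
`symmetric`) because "average-pooled attention" does not pin down an axis;
`received` is the default and every report records the policy used.
The top 30% of atoms by score are selected (ties broken by score then atom
index), the selection is expanded to complete any overlapping catalog
group, and every catalog SMARTS is matched against the whole molecule with
an overlap fraction against the selection — near-misses stay visible
rather than being dropped.

## The synthetic benchmark

Real ADR datasets require external downloads, so the package ships a
generator that emulates their shape: a few hundred molecules, imbalanced
classes (defaults mirror 155:39), positives carrying a planted alert
substructure (default: an aryl fluoride grafted onto a random scaffold of
8–20 heavy atoms over C/N/O/S chains, branches and rings), negatives
rejection-sampled against the alert SMARTS, and a configurable fraction of
labels flipped. The alert SMARTS is therefore a perfect class oracle on
noiseless data, and the planted atom indices are known ground truth for
attribution tests. A "hard negatives" option plants a decoy (an aliphatic
halide) to probe attribution specificity.

What the generator does *not* emulate: pharmacologically realistic
property distributions, multiple interacting pharmacophores, activity
cliffs, or assay noise structure. Passing the synthetic benchmark shows the
pipeline machinery is correct and can recover a planted signal under label
noise; it does not certify performance on real drug datasets.

## Study conditions and problem sizes

The package's own end-to-end study, used by the test suite and
`scripts/acceptance.R`, is fixed at: 100 positives / 100 negatives, 5%
label noise, scaffolds of 8–20 heavy atoms, aryl-fluoride alert, reference
encoder (2 layers / 4 heads / d_model 64), augmentation multiplicity 3,
AdamW for at most 40 epochs with patience 6. Multiplicity 3 and the epoch
cap were chosen because the planted-alert task converges well within them;
raising either changes runtime, not conclusions. Under these conditions
fivefold CV reaches mean MCC ≈ 0.87 and recall ≈ 0.94, and a
label-permuted control sits at MCC ≈ 0.

## Numerical choices

* Linear-attention feature map: elu(x)+1, strictly positive, so attention
  rows normalize without clamping; factorized and naive computations agree
  to 1e-6 and materialized rows sum to 1 within 1e-5.
* Rotary embeddings rotate (even, odd) coordinate pairs with frequencies
  10000^(−2k/d); the transform is an isometry and inner products depend
  only on position offsets (checked to 1e-8).
* Batch-norm epsilon 1e-5, running-statistics momentum 0.1 with unbiased
  variance; He initialization for convolution and FC weights.
* All randomness flows through one master seed via a fixed integer
  derivation (stage-salted linear congruential map kept inside 32-bit
  range), so every stage is independently reproducible and repeated runs
  are byte-identical.
* Duplicate canonical SMILES with agreeing labels merge (first-seen
  metadata kept); with conflicting labels the load aborts — a silent
  coin-flip on a label would poison both training and evaluation.
* OOV tokens are an error, not an UNK: attribution integrity requires that
  every scored token be a real vocabulary member.

## Design decisions that were genuinely open

* **Pooling axis** (`received` default): neither "attention received" nor
  "emitted" is canonical; both are offered and recorded per report.
* **Top-fraction 0.3** for substructure selection: circled substructures in
  published attention analyses cover roughly a third of each molecule's
  atoms; configurable.
* **Class weights off by default**: the reported low specificity on the
  most imbalanced task (0.432) suggests the original training did not
  reweight classes; inverse-frequency weights are available as an option.
* **Final-layer embeddings feed the head**; which layers a pre-trained
  encoder should expose is unstated upstream, and the adapter contract
  leaves room for alternatives.
* **Checkpoint format**: the adapter reads a directory of `config.json` +
  `weights.rds` in the reference layout. Converting a public pre-trained
  checkpoint into this layout is a user-initiated offline step; nothing is
  downloaded, and the pipeline falls back to the reference encoder with a
  warning when no checkpoint is available.

## Limits

* The reference encoder's attention is untrained. Its materialized
  attention maps are exact and the pooling arithmetic is verified against
  naive loops, but per-atom scores from a randomly initialized encoder do
  not preferentially land on the planted alert: measured across encoder
  seeds, planted-atom enrichment ranges from ~0.3 to ~0.9 — a coin flip
  driven by token salience, not signal. Meaningful attribution requires a
  pre-trained (or fine-tuned) encoder; the package keeps the encoder
  frozen during head training by design, so attribution quality is a
  property of the supplied encoder, not of the head.
* The SMARTS matcher implements the subset needed by the shipped catalog
  (elements, aromaticity, X/D/H/R/charge primitives, logical operators,
  recursive environments). It is cross-checked against Open Babel on every
  catalog entry, but it is not a complete SMARTS engine.
* Aromaticity is read from the SMILES string (lowercase atoms), not
  re-perceived; the pipeline canonicalizes through Open Babel before any
  graph work, so this is safe for its own outputs but means Kekulé input
  must pass through canonicalization before SMARTS matching.
* The nine-metric report on the synthetic task is not comparable to
  numbers obtained on the real curated datasets with a pre-trained
  encoder; reproducing those requires external downloads and is
  deliberately outside the offline test surface.
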
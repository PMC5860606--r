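---
title: "Ontology-structured deep learning for protein function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-structured deep learning for protein function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proteins are annotated with classes of the Gene Ontology (GO), a directed
acyclic graph of tens of thousands of terms in three branches — biological
process (BP), molecular function (MF) and cellular component (CC) — linked by
subclass (`is_a`) relations. Annotation obeys the true-path rule: a protein
annotated with a class is implicitly annotated with every superclass.
Predicting GO annotations from sequence is therefore a large-scale,
multi-label, hierarchical classification problem, and predictions should be
*consistent*: a specific class must never be believed more strongly than its
own generalisations.

`deepgo` implements an end-to-end neural approach to this problem, together
with everything needed around it: OBO parsing and annotation propagation,
evidence-code filtering, a BLAST-style best-hit baseline, a
sequence-identity-based train/test split, the CAFA evaluation metrics, and a
synthetic-data generator that makes the whole pipeline testable offline.

## The model

A protein sequence (20-letter alphabet, 3 to 1002 residues) is decomposed
into overlapping amino-acid trigrams — there are $20^3 = 8000$ of them — and
encoded as a vector of 1000 trigram indices, zero-padded at the tail, so a
maximum-length sequence fills the vector exactly. The network is:

1. **Embedding.** Each index selects a learned 128-dimensional vector
   (8001-row table; row 0 belongs to the padding symbol), giving a
   $1000 \times 128$ matrix per protein.
2. **Convolution.** One 1D convolution, 32 filters of length 128, unit
   stride, no padding ($1000 - 128 + 1 = 873$ positions), ReLU.
3. **Temporal max-pooling.** Window 64, stride 32:
   $\lfloor(873 - 64)/32\rfloor + 1 = 26$ windows per filter; flattened to a
   feature vector of length $26 \times 32 = 832$. The arithmetic is asserted
   at model-spec construction; with length-preserving convolution padding
   the same hyperparameters would give 960, not 832, so the valid (no
   padding) convolution is forced.
4. **Fusion.** Concatenation with a 256-dimensional protein network
   embedding (a knowledge-graph embedding of a protein interaction/orthology
   network, consumed as a precomputed table; proteins without one get the
   zero vector), yielding 1088 features.
5. **Shared dense layer.** 1024 ReLU units, dropout afterwards.
6. **Per-class sigmoid layers with max-merge.** One small sigmoid layer per
   selected GO term. For every internal term (one with a selected
   descendant) a merge layer outputs the maximum of the term's own score and
   its selected children's merged scores, recursively; leaves pass through.
   The model output is the concatenation of leaf classification layers and
   internal merge layers, reported in term-set order.

The recursive merge makes the output exactly the maximum of the raw scores
over each term's selected-descendant closure, which guarantees
$\mathrm{score}(C) \ge \mathrm{score}(D)$ whenever $C$ is an ancestor of
$D$ — for any weights, trained or not. Thresholding therefore always yields
upward-closed prediction sets that never need post-hoc propagation.
Gradients flow through the merge (and the pooling) via their argmax, so the
hierarchy participates in training.

Three variants are exposed: `deepgo` (sequence + network features,
hierarchical), `deepgoseq` (sequence only, hierarchical) and `deepgoflat`
(both inputs, one flat sigmoid output layer, no merge — consistency is not
guaranteed, and `check_hierarchy()` can quantify the resulting inversions).

### Training

Multi-output binary cross-entropy, averaged over terms and samples, is
minimised with RMSprop (learning rate 0.01, decay 0.9, batch size 128). The
samples are shuffled once under the configured seed; 80% train the model and
20% form a validation split monitored after every epoch, and the weights of
the best-validation epoch are the ones kept. Dropout (rate 0.2) is applied
after the shared dense layer during training only. One model is trained per
ontology branch.

### Design choices where the architecture description is open

Several details are not fixed by the published description of this family of
models; the package fixes them as follows and exposes the knobs:

* **Activations.** ReLU after the convolution and the shared dense layer
  (the per-class layers are sigmoid by definition).
* **Hierarchy wiring.** By default every class layer reads the shared
  1024-dimensional features (`shared-input`). A `cascade` wiring is
  available in which a class layer additionally reads its induced parents'
  activations, and `class_layer_units` can widen the per-class layer with a
  hidden ReLU stage; the default width is 1, i.e. the class layer *is* its
  output neuron.
* **Merge depth.** The merge is recursive (children before parents), not
  single-level: a single-level maximum over raw child scores does not give
  transitive consistency, the recursion does.
* **Initialisation.** Fan-scaled uniform (Glorot) for convolution and dense
  weights, small uniform $(-0.05, 0.05)$ for the embedding table, zero
  biases; all draws are seeded.
* **Padding row.** The embedding row of the padding index is fixed at zero
  rather than trained. Padding then contributes nothing to any convolution
  window, which also lets the implementation evaluate the convolution only
  over windows that touch real sequence — an exact shortcut, not an
  approximation.
* **Epoch budget.** 12 epochs by default, with best-epoch weight restoration
  standing in for explicit early stopping.
* **Tie-breaks.** Equal annotation counts at the term-selection cutoff
  resolve by ascending lexicographic term id; equal best alignment scores
  resolve toward the lexicographically smallest reference id. Both make
  reruns reproducible.
* **Minimum sequence length.** 3 residues (one trigram); sequences are
  uppercased before validation, and post-padding (zeros at the tail) is
  used.

## Data handling

**Ontology.** OBO 1.2 `[Term]` stanzas; only `is_a` edges are used (other
relationship types are ignored — no cross-branch or parthood reasoning).
Alternate ids are rewritten to their canonical term before propagation.
Annotations to obsolete classes are an error by default; a lenient mode
drops them with a warning, since how such annotations were historically
handled is not documented anywhere authoritative.

**Annotations.** GAF 2.x or 3-column TSV, filtered to experimental evidence
codes (EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC) by default. Propagation
upward-closes every protein's term set and is idempotent.

**Term selection.** After propagation, the terms of one branch are ranked by
annotation count and the `top_k` most annotated terms meeting `min_count`
are kept (the published models used 932/589/436 terms for BP/MF/CC with
minimum counts 250/50/50). Annotations to unselected terms still contribute
through their selected ancestors, because propagation happens first.

**Sequences.** Accepted iff length is within [3, 1002] and only canonical
residues occur; ambiguous codes (B, O, J, U, X, Z) are rejected with the
offending position.

**Identity split.** Pairwise identity is the BLAST `pident` convention —
identical positions over the alignment length of the best local alignment
(BLOSUM62, gap open 11 / extend 1), maximum over both directions, 0 when no
alignment passes the backend's reporting threshold. The split builds a graph
with an edge at ≥ 50% identity and assigns whole connected components to the
training side, largest first, until the training fraction is met. Connected
components are the weakest construction that still guarantees no test
sequence reaches the threshold against any training sequence, even through
chains of similarity. The built-in backend is Smith–Waterman via
`Biostrings::pairwiseAlignment` with a raw-score reporting threshold
(default 40) standing in for BLAST's significance cutoff — without one, any
two random proteins share some tiny perfect-identity local match; an
optional `blastp` backend shells out to BLAST+ with an e-value cutoff
(default $10^{-3}$, the documented default where the original choice is
unknown).

## The synthetic benchmark

Real inputs at publication scale (SwissProt, STRING-derived embeddings, GPU
training) are out of scope; the package instead generates a fully
self-contained benchmark whose ground truth is known by construction:

* a rooted, single-namespace toy DAG — 13 terms by default: a root, four
  internal terms with 1–2 parents each, and exactly 8 leaf classes;
* one distinct 8-residue motif per leaf. Each protein joins each leaf with
  probability 0.3 (resampled until it carries at least one leaf, mirroring
  the requirement that trained and evaluated proteins have at least one
  annotation); for each joined leaf its motif is written into the sequence
  with probability 0.9, at a position that avoids previously planted motifs
  when possible. Background residues are i.i.d. uniform; sequences are
  50–100 residues long. Annotations are the joined leaves, propagated;
* network embeddings built as the sum of fixed Gaussian prototype vectors of
  the protein's terms plus isotropic noise (sd 0.1) — embeddings that carry
  class signal, the regime where fusing them should help.

Default sizes are 2500 proteins (2000 training / 500 held out). Rationale
for the package's own choices: motif length 8 is far below the kernel length
128, so leaf membership is learnable by a single convolution layer by
construction; 50–100-residue sequences keep the benchmark at desk scale
while leaving room for several non-overlapping motifs; the 10% of positives
without their motif behave as label noise and bound achievable recall for
the sequence-only variant. All randomness derives from one integer seed
through R's Mersenne–Twister generator, so every artefact is reproducible.

What the generator does *not* emulate: real amino-acid composition, real GO
topology statistics, protein-network degree distributions, or motifs with
positional/compositional structure. Passing the recovery run shows the
implementation can learn planted sequence signal and exploit informative
network features end to end; it says nothing about accuracy on real
proteins.

## Evaluation

The CAFA-style metric suite, all computed over the selected term set:

* **Protein-centric $F_{\max}$.** For threshold $t$, a protein's predicted
  set is every term scoring $\ge t$. Precision is averaged over the $m(t)$
  proteins with at least one prediction, recall over all $n$ proteins;
  $F_{\max}$ is the maximum harmonic mean over the grid
  $t \in \{0, 0.01, \dots, 1\}$ (the CAFA convention; the smallest
  maximising threshold is reported). Thresholds where nothing is predicted
  contribute $F = 0$; proteins without a true term in the universe are
  excluded (recall would be undefined — evaluated proteins are expected to
  carry at least one annotation).
* **Term-centric AUC and $F_{\max}$** per term, across proteins. AUC is
  computed as the tie-corrected rank statistic (the probability that a
  random positive outscores a random negative, ties counting ½), which
  equals trapezoidal integration of the step ROC curve while avoiding
  curve-ordering bugs; terms lacking a positive or a negative are reported
  missing and excluded from averages.
* **Global AUC** over all (protein, term) pairs pooled into one binary
  problem.
* **MCC** from the pooled confusion matrix at the $F_{\max}$-maximising
  threshold, with the usual zero-denominator → 0 convention.

A grouped mode evaluates any partition of the proteins (per organism, per
family) independently. The baseline (binary scores: transferred terms score
1) is evaluated with the same machinery; it has no score gradation, so its
AUC is not meaningful and only threshold metrics are comparable.

## Numerical and degenerate-input behaviour

The network is single precision; losses are accumulated in double precision
and predictions clamp to $[10^{-7}, 1 - 10^{-7}]$ inside the loss only. A
non-finite loss aborts training with a diagnostic rather than continuing. An
all-padding sequence with a zero network vector is valid input and produces
finite scores (every pooling window then sees only the convolution bias).
Prediction runs sample by sample, so batched and single-sample execution are
bit-identical. Training with the same seed twice yields identical histories
and weights.

## Worked example

```{r, eval = FALSE}
library(deepgo)

ds <- make_synthetic_dataset(synthetic_spec(seed = 11))
samples <- encode_dataset(ds$proteins, ds$termset, ds$annotations,
                          ds$embeddings)
tr <- subset_samples(samples, samples$ids[1:2000])
te <- subset_samples(samples, samples$ids[2001:2500])

model <- build_model(model_spec(), ds$termset, ds$dag)
model <- train_model(model, tr, train_config(seed = 101))

pred <- predict(model, te)
evaluate_predictions(pred, ds$annotations[te$ids])
check_hierarchy(pred, ds$termset, ds$dag)   # zero rows, by construction
```

At this problem size (2000 training proteins of 50–100 residues, 13 terms,
12 epochs) training takes on the order of two minutes per model on one CPU
core; these are also the sizes exercised by the test suite and the
acceptance script.

## Known limitations

* Only `is_a` semantics; no part-of/regulates reasoning, no OWL.
* The knowledge-graph embedding method itself is out of scope — embeddings
  are an input, and the synthetic generator fabricates them for testing.
* No information-content-weighted metrics (e.g. $S_{\min}$) and no bootstrap
  confidence intervals.
* The per-class-layer design scales linearly in selected terms; the package
  is written for hundreds to a thousand selected terms per branch, not the
  full ontology.
* Desk-scale defaults are deliberately small; reproducing published-scale
  benchmark numbers requires the original data volumes and is not a goal of
  this package.
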
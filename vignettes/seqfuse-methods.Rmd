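---
title: "seqfuse: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqfuse: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`seqfuse` classifies protein sequences into two classes -- a disease-associated
positive class (labelled `CML`, for chronic myeloid leukemia) and a `Control`
class -- from the amino-acid string alone. The classifier is a hybrid of a
learned sequence encoder and handcrafted composition descriptors:

1. **Token stream.** Residues are integer-encoded and embedded
   (128-dimensional trainable lookup table). Two parallel 1-D convolutions
   (kernel sizes 3 and 7, 128 filters each, stride 1, "same" zero-padding,
   ReLU) scan the embedded sequence at two receptive-field scales -- short
   motifs versus broader context. Each branch is max-pooled (size 2, stride
   2) and regularized with dropout 0.5, the branches are concatenated
   channel-wise, and a bidirectional LSTM (64 units per direction) models
   long-range dependencies in both directions. Global average pooling (GAP)
   over the time axis yields a fixed 128-vector.
2. **Descriptor stream.** Per sequence we compute a fused 382-dimensional
   vector: the pooled residue embedding (128), type-I pseudo amino acid
   composition (PseAAC, 25 = 20 residue frequencies + 5 sequence-order
   correlation factors), and a dipeptide composition (DPC) block reduced
   from 400 to 229 dimensions. Each dimension is z-score normalized with
   statistics fitted on the training split only.
3. **Head.** The GAP vector and the fused vector are concatenated (late
   fusion), passed through a dense layer (128, ReLU), dropout 0.5, and a
   2-class softmax. Training minimizes categorical cross-entropy with Adam
   (beta1 0.9, beta2 0.999, initial learning rate 1e-3), batch size 32, up
   to 100 epochs, reduce-on-plateau scheduling and early stopping (patience
   10 on validation loss, best weights restored).

Upstream of the model the package provides FASTA ingestion with strict
residue validation, greedy redundancy filtering at a sequence-identity
threshold, and a stratified 70/15/15 split.

## Key parameters

| parameter | default | meaning / why |
|---|---|---|
| identity threshold | 0.90 | pairs at or above it are redundant; identity = matches / shorter length |
| alignment scoring | match 1, mismatch 0, gap open -5, extend -1 | unspecified upstream; conservative identity-style scoring, configurable |
| PseAAC lambda, w | 5, 0.05 | realizes the 25-dim descriptor; classic weight factor |
| PseAAC properties | hydrophobicity, hydrophilicity, side-chain mass | the canonical type-I triplet, standardized over the 20 residues |
| DPC keep | 229 | the published descriptor width; realized as variance-ranked selection from the 400 dipeptides (ties broken lexicographically) because no natural alphabet yields 229 |
| max_len L | 512 | token-stream truncation; covers nearly all inputs in the default corpus (200-600 residues) |
| split rounding | floor + remainder to train | reproduces the published 1,120/240/240 split of a balanced 1,600-sequence corpus exactly |
| dropout | 0.5 | after each pooled branch and after the dense layer |
| bootstrap | B = 1000, percentile 95% | resamples lacking a class are redrawn and counted |

## Numerical and design choices

* **Alignment semantics.** Identity filtering needs "matches in the optimal
  alignment". We use an exact Needleman-Wunsch/Gotoh affine-gap global
  aligner over the lexicographic objective (maximize score, then maximize
  identities among co-optimal alignments), so the reported match count is
  deterministic. A provable composition bound (matches cannot exceed the
  summed per-residue count overlap) lets the greedy filter skip hopeless
  pairs exactly; we deliberately do not implement lossy k-mer prefilters.
  Because exact all-pairs alignment is quadratic in both corpus size and
  sequence length, the experiment pipeline leaves the dedupe stage off by
  default (the synthetic corpus is duplicate-free by construction); it is
  a one-flag opt-in for real corpora.
* **z-scores** use the population standard deviation; constant dimensions
  map to 0 rather than dividing by zero. Transforms (normalizer, DPC
  selector) are fitted on training rows only and applied frozen; the ids
  they saw are recorded so leakage is testable.
* **Late fusion.** The source architecture describes both a per-residue
  input to the CNN and a per-sequence 382-vector. The only reading that
  uses both without contradiction is to concatenate the fused vector after
  GAP, before the dense head; it is toggleable to express ablations. The
  fused vector's 128-dim embedding slice is computed from the *frozen*
  backend table (mask-weighted mean over real positions) at featurization
  time, while the token stream trains its own copy of the embedding --
  a static descriptor cannot track jointly trained weights.
* **Masking.** Sequences are processed at their true length everywhere
  (conv "same"-padding, pooling floor(T/2), GAP over real steps), so padded
  positions can never influence the output -- the property is tested, not
  assumed.
* **Initialization.** Glorot-uniform weights, per-gate orthogonal
  recurrent matrices (the usual LSTM default), zero biases except the LSTM
  forget gate (1.0), and a standard-normal embedding table. The embedding
  scale matters: with a tiny uniform(-0.05, 0.05) init the convolutional
  activations are ~0.03 in magnitude and the sequence stream barely trains
  at the fixed learning rate; N(0, 1) residue vectors give the conv
  branches a usable signal from the start.
* **Gate order** in the LSTM parameter blocks is [input | forget |
  candidate | output]; both directions share the layout. Gradients for
  every stage are validated against finite differences in the tests.
* **Integrated gradients** attribute the pre-softmax logit of the target
  class (default `CML`) with a midpoint-rule Riemann sum from the all-zero
  (padding) embedding baseline; channel attributions are aggregated per
  position by signed summation so the completeness identity holds.
  Positions beyond the true length are excluded by construction.
* **Degenerate statistics.** Zero-denominator metrics return 0 with a
  warning; paired t-tests on zero-variance nonzero differences are flagged
  as deterministic differences (p reported as 0) rather than erroring;
  singleton silhouette clusters score 0.
* **Projection to 2-D** defaults to centred principal components with a
  deterministic sign convention; any nonlinear method can be plugged in as
  a function.

## The synthetic corpus: what it emulates and what it does not

The original study corpus (UniProtKB entries for four disease-associated
gene families plus controls) is not deposited, so the package ships a
planted-motif generator as its test-bed. The default world: 1,600
protein-like sequences, exactly balanced, lengths uniform on 200-600,
backgrounds i.i.d. from a per-dataset residue distribution drawn from a
symmetric Dirichlet (concentration 10 -- mild, realistic compositional
bias, avoiding the artifacts an exactly uniform composition creates in
PseAAC/DPC). Positives carry one width-3 and one width-7 consensus motif
(`WCH`, `KFWPYMC` -- fixed, arbitrary choices made once) at uniform
non-overlapping positions, optionally mutated per position; negatives are
pure background. The two widths match the two convolutional receptive
fields by design, and ground-truth placements are returned so attribution
can be scored against them.

What a green test on this corpus establishes: the pipeline is leak-free,
deterministic, and the architecture can discover planted local structure
end-to-end. What it does not establish: performance on real proteomes --
real families share phylogenetic correlation, domain structure and length
biases the generator deliberately omits, and the published benchmark
numbers depend on an unavailable corpus.

A property worth knowing when interpreting end-to-end results: on the
noise-free corpus the descriptor stream is informative but imperfect,
while the token stream alone can learn the planted motifs essentially
perfectly (the `dual_no_handcrafted` ablation demonstrates this). With
both streams active, optimization first exploits the descriptor shortcut
-- the z-scored dipeptide block doubles as a set of near-unique
per-sequence fingerprints, so training loss collapses before the
convolutional stream has discovered the motifs -- and early stopping with
the published patience then snapshots the model mid-race. The end-to-end
acceptance test runs the stated protocol and documents the behaviour
actually achieved, including this shortfall; it is a finding about the
optimization dynamics of descriptor fusion on weakly-informative
descriptors, not a missing capability of the architecture.

## Ablation grid

`cnn_only` (branches -> concat -> GAP -> head), `bilstm_only` (embeddings
-> BiLSTM -> GAP -> head), `single_cnn_bilstm` (k = 3 branch only),
`dual_no_handcrafted` (late fusion off), `dual_pseaac_only` /
`dual_dpc_only` (one handcrafted block fused), `full`. Baseline variants
run without late fusion, mirroring how such baselines are conventionally
named; the per-variant fused width is derived and recorded in the run
manifest. `run_ablation()` repeats each variant over seeds, summarizes
mean and percentile-bootstrap CI per metric, and reports paired two-tailed
t-tests against `full` (pairing by seed).

## Known limitations

* The exact aligner is for desk-scale corpora; no heuristic accelerations.
* The pre-trained 1024-dim protein-language-model backend is an interface
  (`embedding_backend("table", ...)`), not a bundled model; offline runs
  use the trainable lookup backend.
* Binary classification only; the evaluation module does not generalize to
  C > 2.
* `history` reproducibility is exact on a fixed BLAS/backend; bit-level
  reproducibility across different BLAS builds is not guaranteed.
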
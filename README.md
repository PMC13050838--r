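# seqfuse

Binary classification of protein sequences with a dual-branch CNN–BiLSTM
and handcrafted descriptor fusion.

## The problem

Given amino-acid sequences labelled as disease-associated (`CML`, for
chronic myeloid leukemia — e.g. members of implicated families such as
BCL2, HSP90, PARP, RB) versus `Control`, learn a classifier from the
sequence alone. Two signal scales matter: short conserved motifs and
broader contextual patterns, plus global composition. `seqfuse` is aimed
at computational biologists who want a tested, fully offline,
desk-reproducible implementation of this kind of hybrid pipeline —
including the unglamorous parts (validation, redundancy filtering,
leak-free featurization, seeded training, honest statistics).

## The model

Token stream: residues → trainable 128-d embedding → two parallel 1-D
convolutions (kernel sizes **3** and **7**, 128 filters, "same" padding,
ReLU) → max-pool(2,2) + dropout 0.5 per branch → channel concat →
**BiLSTM** (64 units/direction) → global average pooling.

Descriptor stream: per-sequence fused vector of **382** dimensions =
pooled embedding (128) ⊕ type-I **PseAAC** (25 = 20 + λ, λ = 5) ⊕
variance-selected **DPC** (229 of 400 dipeptides), z-scored with
train-split statistics.

Head: `[GAP ; fused] → dense(128, ReLU) → dropout 0.5 → softmax(2)`,
trained with categorical cross-entropy, Adam (lr 1e-3, β₁ 0.9, β₂ 0.999),
batch 32, reduce-on-plateau, early stopping (patience 10, best weights
restored). Upstream: FASTA validation, greedy redundancy filtering at 90 %
identity (`sim = matches / min(|a|,|b|)` under exact global alignment),
stratified 70/15/15 split.

Everything numerical (forward pass, backpropagation, Adam, the aligner) is
implemented in the package (RcppArmadillo core) — no Python or deep
learning framework required.

## Worked example

```r
library(seqfuse)

# a planted-motif corpus: 200 protein-like sequences, positives carry a
# width-3 and a width-7 consensus motif
cfg <- experiment_config(
  generator = generator_config(n_total = 200L, length_range = c(80L, 160L),
                               seed = 0L),
  train = train_config(max_epochs = 10L, early_stop_patience = 9L),
  seed = 0L)
res <- run_experiment(cfg)
print(res$report)
```

Output from this exact run:

```
Evaluation on 30 sequences (positive class: CML)

               precision    recall  f1-score   support
Control            0.789     1.000     0.882        15
CML                1.000     0.733     0.846        15
accuracy                               0.867        30
macro avg          0.895     0.867     0.864        30
weighted avg       0.895     0.867     0.864        30

ROC-AUC 0.987 | PR-AUC 0.988
accuracy 95% CI [0.733, 0.967] | ROC-AUC 95% CI [0.947, 1.000] (B = 1000)
```

Reading: after ten epochs on a 140-sequence training split the model
ranks positives above negatives almost perfectly (ROC-AUC 0.987); the
default 0.5 threshold is conservative here (CML precision 1.000 at recall
0.733 — four positives score just under it). The bootstrap intervals
(1,000 resamples of the test set) show the uncertainty expected of a
30-sequence test split.

Where the model looks in the sequence:

```r
id <- res$splits$test[res$test_labels == 1][1]   # a positive test sequence
i  <- match(id, res$features$ids)
ig <- integrated_gradients(res$model, res$features$tokens[[i]],
                           res$features$fused[i, , drop = FALSE])
top_k_positions(ig, 10)      # 1-based positions driving the CML logit
#>  [1] 25  7 87 75  5 27  9  8 57 30
res$motif_truth[[id]]        # where the motifs were actually planted
#>     motif start end
#> 1     WCH    75  77
#> 2 KFWPYMC     3   9
```

Five of the ten highest-attribution positions fall inside the two planted
motifs (positions 3–9 and 75–77 of a 100-plus-residue sequence).

Other entry points: `read_fasta()` / `write_fasta()`,
`filter_redundant()` (greedy identity clustering with a JSON report),
`featurize_dataset()` (TSV-able feature table), `run_ablation()`
(variant grid with bootstrap CIs and paired t-tests),
`silhouette_score()` + `project_2d()` (latent-space separation), and a
thin CLI at `inst/cli/seqfuse.R`
(`Rscript seqfuse.R simulate|dedupe|split|featurize|run ...`).

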
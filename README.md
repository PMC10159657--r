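# tcrbind

Prediction of T-cell receptor (TCR) – peptide binding from sequence alone,
with a random forest over positional BLOSUM62 encodings.

## The problem

Cytotoxic T cells recognise infected or malignant cells when the TCR binds
a short peptide (8–11 aa) presented by a class-I HLA molecule. Predicting
which CDR3β sequences recognise which epitopes is a key step in
neoantigen-based immunotherapy, and a hard one: curated databases
(IEDB, VDJdb, McPAS-TCR, TBAdb, 10X) yield collections in which only a few
percent of TCR–peptide pairs are binders, and a handful of high-frequency
"dominant" epitopes distort both training and evaluation.

`tcrbind` implements this prediction pipeline end to end for R users:

* **Encoding.** Each residue of the CDR3β (padded to 19 positions) and of
  the peptide (padded to 11 positions) is embedded as its 20 BLOSUM62
  log-odds scores, giving a flat vector of
  `20×19 + 20×11 = 600` features. In pMHC mode the HLA molecule is added
  as its 34-residue NetMHCpan-style pseudo-sequence (the peptide-contact
  positions of the heavy chain), `20×34 = 680` more features,
  `1280` in total.
* **Classifier.** A probability random forest (`ranger`) fit on the
  encoded pairs; binding is called when the predicted probability reaches
  the 0.5 threshold. Class imbalance is handled by keeping every binding
  pair and downsampling non-binders to a 1:10 ratio before training.
* **Curation.** Merging with deduplication, removal of label-conflicted
  pairs, disjoint peptide-stratified subset construction, unseen-peptide
  splits with generated wild-type negatives.
* **Evaluation.** AUC (Mann–Whitney, ties half-credited), accuracy,
  sensitivity, specificity; stratified reports; per-peptide false-positive
  attribution with a dominant-peptide criterion; binding-ratio titration;
  peptide-specific models; Levenshtein-similarity clustering and
  label-proportion RMSE by similarity bin.
* **Synthetic data.** A repertoire generator with a planted, exactly
  checkable motif-compatibility rule, so the whole pipeline is testable
  with known ground truth and no external downloads.

## Worked example

```r
library(tcrbind)

# a synthetic repertoire at the realistic 3.27% binding composition
rep <- generate_repertoire(synthetic_config(n_pairs = 5000, seed = 42))
rep
#> Synthetic TCR-peptide repertoire: 5000 pairs, 166 binding (3.32%)
#> Planted rule rows: 4  (k = 3 )

# curate, rebalance to 1:10, split, fit
curated  <- remove_conflicts(merge_and_deduplicate(list(rep$records)))$records
balanced <- sample_negatives(curated, ratio = 10, seed = 42)
set.seed(42)
idx   <- sample(nrow(balanced), round(0.7 * nrow(balanced)))
train <- balanced[idx, ]; test <- balanced[-idx, ]

fit <- tcrbind(train, n_trees = 200, seed = 42)
fit
#> TCR-peptide binding random forest (pair mode, 600 features)
#>   trees: 200   seed: 42
#>   training: 113 binding / 1165 non-binding (1:10.3)
#>   OOB Brier score: 0.0158

prob <- predict(fit, test)
metrics_report(prob, test$label)
#>   stratum auc accuracy sensitivity specificity threshold n_pos n_neg
#> 1    <NA>   1    0.989       0.887           1       0.5    53   495
```

The report reads: on 548 held-out pairs (53 binders, 495 non-binders) the
forest ranks binders above non-binders perfectly (AUC 1 — the planted rule
is fully learnable), calls 88.7% of true binders binding at the 0.5
cutoff, and produces no false positives here. On real curated data the
same pipeline operates at AUCs near 0.98 only because dominant epitopes
are plentiful; `fp_attribution()` and `ratio_titration()` quantify exactly
that effect.

A command-line wrapper is installed as `exec/tcrbind` inside the package
library (subcommands `simulate`, `curate`, `split`, `encode`, `train`,
`predict`, `evaluate`, `analyze-peptides`, `compare-models`).

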
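---
title: "tcrbind: model, conventions and synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcrbind: model, conventions and synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbind)
```

## The model

`tcrbind` treats TCR–peptide recognition as a binary classification
problem over sequence pairs. An observation is a CDR3β amino-acid
sequence (8–19 residues — the hypervariable loop chiefly responsible for
peptide contact), a peptide (8–11 residues), optionally the presenting
class-I HLA allele, and a binary label (1 = binding). The classifier is a
probability random forest on a fixed-length positional encoding:

* each sequence position contributes the 20 BLOSUM62 log-odds scores of
  its residue against the amino-acid alphabet (order `AA_ALPHABET20`,
  the conventional substitution-matrix order A, R, N, D, …);
* sequences are right-padded to the maximum valid length with all-zero
  blocks — zeros, never the scores of a gap symbol, so padding is inert
  for tree splits;
* flattening is position-major: entries `(j-1)*20 + 1 … j*20` belong to
  position `j`. The order is frozen because serialized models are only
  exchangeable if every encoder agrees on it;
* pair mode: `20×19 + 20×11 = 600` features. pMHC mode appends the
  encoding of the 34-residue HLA pseudo-sequence (`680` values) for
  `1280` features in total.

The pseudo-sequence is the NetMHCpan-style compact MHC representation:
the residues at 34 fixed peptide-contact positions of the mature heavy
chain (positions shipped in `inst/extdata/pseudo_positions.txt`). The
model does **not** re-evaluate peptide–MHC binding; the pMHC complex is
assumed confirmed, the HLA block only lets the forest condition on the
presenting molecule.

Key modelling assumptions, stated plainly: binding is decidable from the
CDR3β alone on the TCR side (no α chain, no V/J context); positional
BLOSUM62 scores are an adequate residue embedding (no learned embedding);
and the heavily imbalanced label distribution is better handled by
resampling than by reweighting.

## Tunable parameters

| parameter | default | where | why |
|---|---|---|---|
| `n_trees` | 300 | `tcrbind()` | enough for stable probability estimates at these feature counts; fit time grows linearly |
| `mtry` | `floor(sqrt(p))` | `tcrbind()` | the standard forest heuristic; p = 600 or 1280 |
| `threshold` | 0.5 | `classify()`, reports | the conventional operating point; ties (`p == threshold`) classify as **binding** (`>=`), the permissive choice for a screening tool |
| `ratio` | 10 | `sample_negatives()` | training at 1:10 binding:non-binding keeps enough negatives for specificity while letting the forest see every binder; the raw composition is ~1:30 |
| `share_cutoff` | 0.95 | `fp_attribution()` | "dominant" made explicit: the smallest peptide set absorbing 95% of false positives; `top_n` overrides it |
| `bin_width` | 0.1 | `similarity_bin_rmse()` | ten bins over Levenshtein similarity in [0, 1] |
| `train_peptide_fraction` | 0.8 | `unseen_peptide_split()` | 80% of peptides (not observations) train; the rest are never seen in training |

All randomised operations take an integer `seed` and are bit-reproducible
under it; the package never touches the caller's RNG stream.

## Numerical and procedural conventions

* **AUC** is computed from midranks — exactly the Mann–Whitney
  probability that a random binder outranks a random non-binder with ties
  counted half, and exactly the trapezoidal area under the ROC curve. It
  is invariant under monotone transforms of the scores and is checked
  against a brute-force pairwise oracle in the tests.
* **Single-class strata** report threshold metrics with AUC marked
  unavailable (`NA`), never zero.
* **Conflict removal** drops *both* sides of any (CDR3β, peptide[, HLA])
  key observed with both labels. The alternative — keeping a majority
  label — silently injects noise; dropping is conservative and the
  removed keys are reported.
* **Deduplication keys** include the HLA allele only in with-MHC mode;
  source tags of collapsed duplicates are concatenated in first-seen
  order.
* **Subset construction** stratifies on peptide identity: each peptide's
  records are dealt round-robin across subsets (with a rotating offset),
  then subsets are trimmed to a common target size. This keeps peptide
  diversity near-uniform across subsets without an explicit optimisation.
* **HLA names** normalise to 2-field (protein-level) nomenclature;
  synonymous/noncoding suffixes are truncated because the pseudo-sequence
  is identical at protein level. Non-standard residues (X, B, Z, U, `*`)
  anywhere in a sequence cause rejection, not imputation, which keeps the
  encoding well defined.
* **Levenshtein similarity** is `1 − d/max(|a|,|b|)` with unit-cost edit
  distance; normalising by the longer sequence keeps the value in [0, 1]
  and makes identity the unique similarity-1 case.
* **Peptide clustering** is PAM (medoid partitioning) on `1 − similarity`;
  the representative is the medoid, i.e. the member with maximal mean
  within-cluster similarity. PAM is deterministic for a given matrix; the
  seed is still pinned for defence.
* **Similarity-bin RMSE** compares the (binding, non-binding, mix) label
  proportions of the training peptides in each bin with the
  representative's predicted-label proportions, taken as (share of its
  pairs predicted binding, share predicted non-binding, 0): a single test
  peptide has per-pair predictions, not a mix category of its own. Empty
  bins are flagged `empty`, never zero-filled.
* **Ratio titration** resamples only the chosen peptides' records (all
  positives kept; negatives down-sampled without replacement, or
  up-sampled with replacement when the pool is short); the other
  peptides' records pass through untouched, so differences across ratios
  are attributable to the chosen set alone.

## The synthetic-data generator

Real curated collections cannot be redistributed with the package, and
re-downloading them is out of scope, so every claim the test suite makes
is made on synthetic repertoires with known ground truth.

The generator plants a *positional k-mer compatibility rule*: a table of
(peptide 3-mer, CDR3β 3-mer) rows with fixed anchor windows (peptide
positions 3–5, CDR3β positions 5–7 by default). A pair binds iff some row
matches both windows. Anchoring at fixed positions keeps the rule exactly
checkable (`rule_fires()` is exported and used as the label oracle) and
learnable by a forest on positional features — a floating motif would
smear the signal across position blocks and make "the model should learn
this" an ill-posed test. Binding pairs are constructed from
motif-carrying pool members; non-binding pairs are random pool
combinations rejection-sampled so the rule does not fire. The number of
binders is drawn Binomial(n, `binding_fraction`) with the default
fraction 0.0327, matching the composition of the large multi-database
collections this pipeline targets. Optional label noise flips labels
after rule evaluation (flipped rows are tagged), and
`inject_dominant_peptides()` adds high-frequency peptides whose labels
are coin flips at a chosen rate — the synthetic analogue of dominant
epitopes, and a positive control for the false-positive attribution and
titration analyses.

What the generator does **not** emulate: V(D)J recombination statistics
(CDR3β sequences are uniform over the alphabet, save the planted motifs),
peptide processing/presentation biases, shared public TCRs across
donors, and database-specific curation artefacts. Consequently, passing
tests demonstrate that the pipeline's machinery is correct and that the
forest can recover a learnable signal at realistic imbalance — not that
any particular AUC will be achieved on real repertoires.

The bundled HLA lookup (`inst/extdata/hla_pseudo_synthetic.tsv`) is a
**synthetic** demonstration panel: allele names in the fictitious
`HLA-A*90:xx` range with random pseudo-sequences. Real analyses should
derive pseudo-sequences from IMGT/HLA heavy chains via `read_hla_fasta()`
or supply a curated map via `read_pseudo_map()`.

## The permutation null

The negative control for "the forest learned the planted rule" is the
standard permutation design: permute the labels of the sampled dataset
once, then rerun the entire split/train/evaluate procedure. Its held-out
AUC concentrates at 0.5.

A tempting variant — shuffle only the *training* labels and score against
the true held-out labels — is biased below 0.5 on rare-positive data and
is deliberately not used: the permuted forest's probability estimates for
the small positive-feature regions are right-skewed (most such regions
receive zero permuted positives), so true binders systematically score
below the base rate. The bias is a property of that test design, not
evidence of (anti-)signal.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
16 000 generated pairs (≈ 5 800 after 1:10 downsampling, 60/40
train/test) with 200-tree forests, and smaller configurations (400–2 000
pairs) for the component tests. These sizes give stable metrics — the
held-out AUC of the planted rule is ≥ 0.99 and the permutation null lies
within a few hundredths of 0.5 — while keeping a complete run in seconds
to minutes on a single core. Subset construction is exercised at a scaled
size (hundreds of records per subset); the 70 000–75 000 defaults of
`make_subsets()` reflect full-scale collections.

## Known limitations

* Only CDR3β is modelled on the TCR side; α-chain and V/J-gene
  information is not represented.
* The bundled allele panel is synthetic; shipping real pseudo-sequences
  would require the IMGT/HLA reference, which users must supply.
* `cross_validate_models()` stratifies folds on the label, not on the
  peptide; peptide-disjoint evaluation is a separate, deliberate step
  (`unseen_peptide_split()`), mirroring how model selection and
  generalisation analysis are kept apart.
* Forest hyperparameters are deliberately plain (no tuning harness);
  the documented defaults are overridable but no search is performed.
* With very few distinct peptides the unseen-peptide split can leave a
  category (e.g. mix) unrepresented in training; the split reports its
  category counts so this is visible.
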
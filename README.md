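# mhcbind

Peptide–MHC binding prediction in R: a hybrid CNN–BiLSTM network with
channel/spatial attention (CBAM), a semi-supervised curation pipeline for
mass-spectrometry eluted-ligand data, 5-fold ensemble training, and a
neoantigen candidate-peptide pipeline.

## Who this is for

Immunoinformaticians who need an end-to-end, inspectable, pure-R
implementation of the modern peptide–MHC prediction workflow: training a
binding predictor from IC50 affinity tables and eluted-ligand
immunopeptidomics, then ranking tumour-mutation-derived candidate peptides
against an HLA panel. Everything runs offline on a single CPU at desk
scale, with a synthetic-data generator that plants recoverable anchor
motifs so the whole pipeline is testable without external datasets.

## The model

A peptide is middle-padded to a fixed length, concatenated with the
allele's pseudo-sequence (contact residues), and one-hot encoded over the
20 residues + padding. The score is produced by fusing:

* a **2D convolution** over the pair "image" with **CBAM** attention —
  channel gate `M_c = σ(MLP(AvgPool F) + MLP(MaxPool F))`, then spatial
  gate `M_s = σ(Conv([AvgPool F'; MaxPool F']))`, each applied
  multiplicatively — followed by global pooling;
* a **1D convolution + bidirectional LSTM** over the residue sequence
  (standard gates `f_t, i_t, o_t`, candidate `tanh` cell update);
* dense **skip connections** from the BLOSUM62 peptide encoding and the
  raw one-hot pair encoding;

into an MLP head. Regression pre-training targets the affinity transform

```
score = 1 − ln(IC50) / ln(50000)        (IC50 in nM)
```

with MSE loss; classification uses weighted cross-entropy on the strict
`IC50 < 500 nM` binder rule, AdamW, and cosine learning-rate annealing.
The curation stage uses the pre-trained regressor to assign each
multi-allele eluted peptide to its argmax allele and to remove sampled
decoy negatives the model scores as binders, before merging all sources
into one training table. Forward and backward passes are hand-implemented
in vectorised base R (no deep-learning framework is required) and verified
against finite differences and scalar oracles in the test suite.

## Worked example

Train a small regression ensemble on synthetic affinity data and evaluate
on held-out pairs:

```r
library(mhcbind)

ic50_to_score(c(1, 500, 50000))
#> [1] 1.0000000 0.4256252 0.0000000

world <- make_world(n_alleles = 2, seed = 42)   # planted anchor motifs
ba <- sample_ba(world, 4000, seed = 43)
head(ba, 3)
#>     peptide allele      ic50_nM
#> 1 MARVYIIRF SIM-02 30582.139835
#> 2 NYKTPPAVI SIM-02     2.281601
#> 3 KHAHICELQ SIM-02 30089.388245

ba$score <- ic50_to_score(ba$ic50_nM)
cfg <- tiny_config(task = "regression", seed = 44, epochs = 4, t_max = 4)
ens <- fit_fold_ensemble(ba, world$pseudo, cfg, k = 2)

test <- sample_ba(world, 1000, seed = 45)
pred <- ensemble_predict(ens, test$peptide, test$allele, world$pseudo)
evaluate_predictions(label_by_threshold(test$ic50_nM), pred)
#> PR-AUC 0.9172 | ROC-AUC 0.9287 | TOP20%-PPV 0.9650 | r 0.7288 (n+ 490, n- 510)
```

The peptides in row 1 and 3 miss the planted anchors of allele SIM-02 and
sit near the 30 µM baseline; row 2 matches both anchors and binds at
~2 nM. Four epochs of a deliberately small model already rank held-out
binders with ROC-AUC 0.93; the full benchmark below trains longer on more
data and reaches ≈ 0.99.

A command-line interface wraps the same functions
(`exec/mhcbind simulate | pretrain | curate | train | predict | evaluate |
neoantigen`); every run writes a manifest JSON with its configuration,
seed, and input checksums. See the vignette
(`vignettes/mhcbind-methods.Rmd`) for the model, pipeline, and design
notes.

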
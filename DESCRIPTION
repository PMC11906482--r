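Package: mhcbind
Title: Peptide-MHC Binding Prediction with a Hybrid CNN-BiLSTM-CBAM Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts peptide-MHC (class I and II) binding from sequence.
    Peptides and MHC allele pseudo-sequences are one-hot and BLOSUM62
    encoded and scored by a hybrid network combining a 2D convolutional
    branch with channel/spatial attention (CBAM), a 1D convolution plus
    bidirectional LSTM branch, and a BLOSUM62 skip connection. Supports
    IC50 regression pre-training, semi-supervised curation of
    mass-spectrometry eluted-ligand data (multi-allele deconvolution and
    decoy filtering), 5-fold cross-validated ensemble training,
    ranking-based evaluation metrics, and a neoantigen candidate-peptide
    pipeline with panel scoring and sequence-logo motif summaries. A
    synthetic-data generator with planted anchor motifs makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    pROC
Config/testthat/edition: 3
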
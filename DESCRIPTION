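Package: tfsnr
Title: Single-Nucleotide Resolution Prediction of Transcription Factor
    Binding Sites with a k-mer Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Labels every nucleotide of a DNA sequence as transcription-factor
    binding or not. Sequences are tokenized into overlapping k-mers, embedded,
    and passed through a configurable multi-layer bidirectional self-attention
    encoder trained from scratch with a multi-task objective that couples a
    sequence-level head (does the sequence contain a binding site?) with a
    token-level head (which k-mers lie inside it?). Includes balanced dataset
    construction with dinucleotide-frequency-preserving shuffled negatives,
    planted-motif synthetic data generation, nucleotide- and sequence-level
    evaluation metrics, cross-factor transfer matrices, attention-weight
    aggregation, and a motif-discovery post-processor that turns per-nucleotide
    probability tracks into position weight matrices in MEME minimal format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
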
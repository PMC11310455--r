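---
title: "Single-nucleotide TFBS prediction with tfsnr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-nucleotide TFBS prediction with tfsnr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tfsnr)
```

## The problem

Most sequence-based models of transcription factor (TF) binding answer a
coarse question: *does this window contain a binding site?* `tfsnr` answers
the fine-grained one: *which nucleotides are inside the site?* Every position
of a DNA sequence is classified as binding or background, which is the
resolution needed to annotate individual promoter elements, compare called
sites against database motifs, or count distinct sites in a regulatory
region.

The framing borrows from named-entity recognition: the sequence is a
sentence, overlapping k-mers are words, and a binding site is a contiguous
entity span to be tagged. A bidirectional self-attention encoder reads the
whole window, and two prediction heads are trained jointly — one scoring the
sequence ("is a site present?") and one scoring each k-mer token ("is this
token inside the site?").

## Dataset construction

Supervised data come from binding-site intervals (ChIP-seq derived, BED-style
0-based half-open coordinates). For every site we extract a 100-bp window in
which the site is placed at a uniformly random offset, and label each
nucleotide 1 inside the site span and 0 outside (`extract_window()`). Random
placement prevents the model from learning a positional shortcut ("sites
live in the middle").

Negatives are not random genomic windows: each positive is paired with a
**dinucleotide-frequency-preserving shuffle** of itself (`dinuc_shuffle()`),
carrying all-zero labels. The shuffle is the Euler-path construction of
Altschul and Erickson: the sequence is an Eulerian walk on the 4-vertex
dinucleotide multigraph; we draw a uniformly random last-exit edge set
forming an arborescence into the terminal vertex, permute the remaining
out-edges, and re-walk the graph. The dinucleotide count multiset — hence
GC content, CpG density, and both terminal bases — is preserved *exactly*,
so the classifier cannot separate classes on low-order composition and must
learn the actual site pattern.

The resulting dataset is balanced 1:1 at the sequence level, but heavily
imbalanced at the nucleotide level: with 100-bp windows and site lengths
around 10–15 bp (mean 12.5), the pooled background:binding label ratio is
`(2 * 100 - 12.5) / 12.5 = 15`, i.e. about fifteen background labels per
binding label. This is why area under the precision–recall curve (AUPR),
not AUC, is the headline nucleotide-level metric.

Two choices here are deliberately stricter than strictly necessary:

* **Pair-aware splitting.** A positive and its shuffled twin always land in
  the same train/test partition (`split_dataset()`, `cross_validate()`,
  and the validation carve-out in `tfsnr_fit()`). Splitting twins across
  partitions would leak the positive's composition into the other side.
* **N handling.** Sequences containing `N` are excluded from pair
  construction (with a warning): the shuffle is undefined off the ACGT
  alphabet and the k-mer vocabulary does not cover ambiguity codes. At
  tokenization time stray `N`s map to `[UNK]`, which keeps its real 0/1
  label and stays in the loss — `[UNK]` positions are real nucleotides, and
  dropping them would silently shrink the evaluation set.

## Tokenization and the label interchange

A sequence of length $L$ yields $L-k+1$ overlapping k-mers (k = 3 by
default; 3–6 supported, matching the conventional DNA language-model range).
The vocabulary is all $4^k$ k-mers plus five special tokens
(`[CLS]`, `[PAD]`, `[UNK]`, `[SEP]`, `[MASK]`), $4^k + 5$ entries in all —
69 for k = 3 — in a fixed order (specials first, then lexicographic k-mers)
so that vocabularies and checkpoints are portable.

Nucleotide labels and token labels interconvert by two asymmetric rules:

* **AND (nucleotide → token):** a token is 1 only if *all* k covered
  nucleotides are 1. Partial overlap with a site does not make a token
  positive.
* **OR (token → nucleotide):** a nucleotide is 1 if *any* covering token is
  1.

The pair is a Galois-style adjunction, not an inverse pair: round-tripping
erases exactly the 1-runs shorter than k (the AND can never fire inside
them) and is the identity otherwise. The test suite checks this law against
a brute-force oracle over random label vectors. At prediction time the
continuous analogue of OR is the **max** over covering tokens
(`expand_token_probs()`): unlike the mean, max-expansion commutes with
thresholding, so binarizing nucleotide probabilities at any threshold
equals OR-expanding binarized token labels.

`[CLS]` is prepended and `[SEP]` appended (whether an end marker is used for
single sequences is a convention choice; we follow the BERT default), and
both carry an ignore marker (-1) that excludes them from the token loss.

## The encoder

Input embeddings are the sum of a learned token embedding and a position
embedding, followed by LayerNorm and dropout. Positions default to fixed
sinusoidal tables; BERT-style learned absolute embeddings are a config
option. The choice matters more here than in the pretrained lineage this
architecture comes from: recognizing a motif through overlapping k-mers is
an *adjacency* pattern (token i must agree with tokens i±1, i±2 wherever
the site sits), and sinusoidal tables represent relative offsets the same
way at every position, so one attention pattern generalizes across the
window. Learned absolute embeddings must acquire that position arithmetic
from data — cheap when fine-tuning a pretrained genome-scale model, but
data-hungry when training from scratch on a few thousand sequences, where
we observed it is the difference between learning the motif's context and
plateauing at per-k-mer base rates. The trunk is a stack of
post-norm transformer layers, each

$$\mathrm{LayerNorm}(x + \mathrm{Sublayer}(x))$$

with two sub-layers: multi-head scaled dot-product self-attention

$$\mathrm{head}_i = \mathrm{softmax}\!\left(\frac{X W_i^Q (X W_i^K)^\top}{\sqrt{d_k}}\right) X W_i^V,
\qquad \mathrm{MultiHead}(X) = \mathrm{Concat}(\mathrm{head}_1, \ldots, \mathrm{head}_n)\, W^O$$

and a position-wise feed-forward network with GELU activation. We use
$\sqrt{d_k}$ (the per-head width) as the score scaling factor, the standard
choice. Padding slots are excluded from the softmax support: their key
columns receive $-10^9$ before normalization, so attention rows over
unmasked slots sum to 1 and padding can never influence real tokens (a
property the tests assert by re-encoding the same sequence with different
amounts of padding).

Two sigmoid heads sit on the shared trunk: a linear layer on the final
`[CLS]` state for the sequence task (we read the raw `[CLS]` state rather
than adding a BERT-style pooler — one less layer to train and nothing in
the task needs it), and a linear layer on every k-mer state for the token
task. The training objective is

$$\mathcal{L} = \lambda\,\mathrm{BCE}_{\mathrm{sequence}} + (1-\lambda)\,\mathrm{BCE}_{\mathrm{token}}$$

with $\lambda \in [0,1]$ (default 0.5, weighting the tasks equally; the
token term averages over each sequence's real k-mer tokens). Probabilities
are clamped to $[10^{-7}, 1-10^{-7}]$ inside the BCE so the loss stays
finite at saturated predictions.

The entire network — forward pass *and* analytic backward pass — is
implemented in vectorized base-R matrix algebra. The test suite verifies
the backward pass against central finite differences on a 2-layer toy model
to a relative error of $10^{-4}$ (observed agreement is ~$10^{-8}$), which
pins down every gradient path: embeddings, LayerNorm, attention softmax,
GELU, both heads and the multi-task loss.

### Desk-scale and full-scale configurations

`model_config()` defaults to 2 layers, 4 heads, d_model 64, d_ff 256,
k = 3, dropout 0.1 — about 160k parameters, trainable in minutes on one
core. `model_config_full()` mirrors the 12-layer, 768-wide, 12-head
BERT-base geometry of the DNA language-model lineage (learned positions,
0.02 init) for users with the hardware to train it. Both run exactly the
same code.

An optional checkpoint hook (`read_checkpoint()`) restores any previously
trained weights; nothing in the package depends on external pretrained
weights — the encoder trains from scratch.

## Training protocol

`tfsnr_fit()` optimizes with AdamW (β₁ = 0.9, β₂ = 0.999, decoupled
weight decay 0.01 on weight matrices, global gradient-norm clipping at
1.0) under a linear learning-rate warmup followed by linear decay to zero
over the scheduled epochs, the standard recipe of this model family. A
pair-aware validation subset (10% by default) is carved from the training
data; after each epoch the validation loss is computed, the best weights
are retained, and training stops early after `patience` (default 2)
non-improving epochs, up to 10 epochs by default. Training is exactly
reproducible: a single integer seed drives named substreams for weight
initialization, data order, dropout, and the validation split, and two runs
with equal inputs produce bit-identical weights.

Training from scratch (rather than fine-tuning a pretrained language model)
is a different optimization regime, and three defaults reflect that. The
initialization scale is 0.1 rather than BERT's 0.02: with the tiny classic
value a small encoder sits at base-rate predictions for hundreds of steps
before symmetry breaks (we verified this directly on overfitting probes).
The batch size defaults to 16 so a 10-epoch budget yields a few thousand
parameter updates — the shuffled negatives force the model to discover
*compositional* patterns (the exact k-mer order of the motif), which emerge
later in optimization than low-order statistics. And sinusoidal positions
(above) remove the need to learn position arithmetic from scratch.

`cross_validate()` implements the hyperparameter search protocol: pairs are
partitioned into 5 folds (twins together), every candidate configuration is
trained on 4 folds and scored on the fifth, and the candidate with the best
mean validation nucleotide-level AUPR is selected — the held-out test set
plays no role in selection.

## Evaluation

`evaluate()` reports accuracy, precision, recall, F1, AUC and AUPR at both
levels. Nucleotide-level metrics pool all positions of all sequences
(micro-averaging; per-sequence macro-averaging is available via
`average = "macro"` — whether published nucleotide-level numbers micro- or
macro-average is rarely stated, so both are exposed). AUC is the
Mann–Whitney rank statistic; AUPR is average precision with tied scores
processed as threshold groups. Single-class ground truth yields `NA`, never
a silent 0. The implementations are cross-checked in the tests against pROC
and a brute-force precision–recall sweep.

`cross_tf_matrix()` evaluates each factor's model on every factor's test
set. Factors whose motifs are shared (as within a TF family) transfer —
off-diagonal scores close to the diagonal — while disjoint motifs do not;
the acceptance suite demonstrates both regimes on synthetic factors.

## Interpretation

`attention_maps()` exposes the per-layer, per-head row-stochastic attention
matrices. `aggregate_attention()` reduces them to a per-position profile:
the attention *received* by a token is the column mass of the map (how much
all queries attend to that key), averaged over heads, distributed to the
nucleotides the k-mer covers (averaging over covering tokens), and averaged
over sequences. The attention direction is a definition choice — maps can
be aggregated over queries or keys — and column mass is the natural notion
of "how much the model looks at this position". On synthetic data with
sites pinned at the window center, a trained model's profile peaks over the
site span.

`cls_correlation()` computes Pearson correlations between the final-layer
`[CLS]` vectors of a sequence set, ordered by average-linkage hierarchical
clustering for display; trained models separate positive from negative
sequences (higher within-class than between-class correlation).

## Motif discovery

`discover_sites()` post-processes a per-nucleotide probability track: a
window of length `window` (default 10 bp) slides with stride 1 and is
positive when its **mean** probability reaches `threshold` (default 0.5).
One consequence of the mean statistic deserves emphasis: a site of width
$w$ inside a window of length $W > w$ can reach a window mean of at most
$(w/W)$ times its per-base probability, so a scan window much wider than
the expected site silently raises the effective threshold. Match `window`
to the expected site width (as the recovery experiments in the test suite
do, scanning at the planted motif's width);
maximal runs of positive windows are merged and the central `window`-length
region of each run's span is called as one site. The mean was chosen as the
window statistic because it is smooth and monotone under the threshold
(raising the threshold can never create new sites, a property the tests
assert); `stat = "max"` is available. For even-length slack the central
region resolves to the left-of-center start. Defaults for window length,
threshold and the central-region length are declared package choices — the
upstream description of this post-processing fixes none of them — and all
are exposed on the CLI.

`collect_sites()` extracts the called substrings (all of length `window`,
so center-alignment is the identity), `build_pwm()` stacks them into a
position weight matrix with an additive pseudocount
(`(count + c) / (n + 4c)`, default c = 0.01 so single-base columns stay
finite under log-scoring without visibly distorting frequencies), and
`write_meme()` emits MEME minimal format for downstream comparison tools.
Only positive-prediction tracks contribute sites; negatives contribute
nothing.

## Synthetic data: what it emulates and what it does not

`generate_synthetic()` reproduces the *statistical geometry* of
ChIP-seq-derived training data: fixed-length windows, exactly one site per
positive at a uniform offset, per-nucleotide labels, background drawn from
a mononucleotide (or first-order Markov) model, and sites drawn from a
consensus string, a PWM, or the background (when only label geometry
matters). The generator emits its ground-truth PWM so recovery experiments
can close the loop. It is deterministic for a fixed spec.

What it does **not** emulate: genomic background heterogeneity (repeats,
CpG islands), cooperative or homotypic site clustering, multiple sites per
window, chromatin effects on ChIP-seq peak boundaries, and label noise from
imprecise peak calls. Passing the recovery tests therefore demonstrates
that the architecture, losses, and post-processing are implemented
correctly and can extract a planted signal at realistic imbalance — not
that the desk-scale model matches published performance on real ChIP-seq
corpora, which requires the full 12-layer pretrained configuration and the
external datasets.

## Reference experiment sizes

The test and acceptance suites use problem sizes chosen to exercise the
full pipeline on a single CPU: the main recovery experiment plants a 6-bp
consensus (`CAGCTG`, an E-box) in 2000 positive 100-bp windows (4000
sequences after pairing, 80/20 split), trains the desk-scale encoder for at
most 10 epochs, and asks for nucleotide-level AUPR ≥ 0.8 and
sequence-level AUC ≥ 0.95 on the held-out pairs, plus recovery of the
planted PWM (mean central-column Pearson r ≥ 0.8) from
`discover_sites()` → `build_pwm()`. Transfer experiments train two further
600-pair factors (one sharing the motif, one disjoint, `TTTAAA`).
Distributional properties (offset uniformity, shuffle exactness, label-map
laws) are property-tested with seeds fixed in the suite.

## Numerical choices

* LayerNorm ε = 10⁻¹², BERT's value; softmax rows are max-shifted before
  exponentiation.
* Masked attention scores use −10⁹ rather than −∞ so that all-masked rows
  (padding queries) stay NaN-free; stored maps zero those rows explicitly.
* BCE probability clamp 10⁻⁷; gradients flow through the unclamped sigmoid
  (exact except in the saturated tail the clamp guards).
* Weight init N(0, 0.02²); LayerNorm gain 1, bias 0; head biases 0.
* Ties in `discover_sites()` central regions resolve left; ties in AUC use
  midranks; tied scores in AUPR are one threshold group.

## Known limitations

* Pure-R training is practical to roughly 10⁵–10⁶ parameters and 10³–10⁴
  sequences; the full-scale configuration is provided for completeness but
  wants a GPU implementation for realistic corpora.
* Masked-language-model pretraining is out of scope; the encoder trains
  from scratch, so it needs labeled data volumes that a pretrained model
  would not.
* One site per positive window is assumed by the generator and by the
  label geometry of `extract_window()`; multi-site windows work at
  prediction time but are not part of the training construction.
* The motif post-processor reports fixed-width (`window`) sites; true site
  length is recovered only through the PWM's information profile, not the
  called interval width.
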
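---
title: "Modeling protein sequences with a bidirectional language model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein sequences with a bidirectional language model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

A protein sequence can be read as a sentence whose words are single amino
acids. A language model trained to predict the next residue from all
previous ones (and, independently, the previous residue from all following
ones) has to internalize the statistical regularities of protein
sequences — residue propensities, local segment structure, longer-range
composition. The internal states of such a *bidirectional language model*
(biLM) then provide, for every residue, a vector that depends on the whole
sequence context. These contextual embeddings can be transferred to
supervised tasks: per-residue secondary-structure and disorder prediction,
and — after averaging over residues — per-protein localization and
membrane classification. `protlm` implements this transfer-learning
pipeline end to end, together with the classical input encodings it is
compared against, the downstream predictors, and an evaluation suite.

## The language model

Tokens are the 25 residue letters (20 standard, U, O, B, Z, X) plus three
special tokens (padding, sequence start, sequence end) — 28 in total, in a
fixed documented order. The architecture per token is:

1. **Character encoder.** Each token is rendered as a short character
   sequence (begin-of-word, the symbol, end-of-word, padding) and passed
   through a bank of character convolutions of increasing window size,
   max-pooled over positions and concatenated over filters, then through
   highway layers and a linear projection to the per-direction word
   dimension. Because every word is one amino acid, this encoder reduces
   to a learned, context-independent table with one row per token, which
   the implementation computes once per step — an exact optimization, not
   an approximation.
2. **Recurrent layers.** Two LSTM layers per direction, with a projection
   back to the word dimension and a residual connection between the
   layers. The forward and backward directions are trained independently
   (the forward objective conditions only on tokens to the left of the
   target, the backward one only on tokens to the right), so no
   information leaks across the prediction boundary; causality is verified
   by perturbation tests.
3. **Softmax head.** A shared softmax over the 28 tokens. Training uses a
   sampled softmax with 20 negative samples; evaluation always uses the
   full softmax.

Two presets are built in. The `"paper"` preset is the full-scale
architecture — convolution windows 1–7 with 32…1024 filters, two highway
layers, projection 512, hidden dimension 4096 — whose
forward+backward-concatenated layer outputs are 1024-dimensional and whose
free-parameter count comes to about 93.6 million. It is used for
architecture arithmetic and dimensionality checks; training it is a
GPU-cluster undertaking far outside an R session. The `"mini"` preset
(windows 1–3, 16 filters each, one highway layer, projection 32, hidden
64, ~83 k parameters) is the desk-scale analog on which all training
experiments and behavioral tests run.

Design choices worth recording:

- **Weight sharing between directions.** The character encoder, highway,
  projection and softmax are shared; each direction owns its recurrent
  layers. Sharing the recurrent layers as well is exposed as
  `share_directions = TRUE`, but the default follows the reference
  convention, which is also the only variant consistent with the ~93 M
  parameter total.
- **Negative-sampling proposal.** The NLP convention is a log-uniform
  proposal over frequency-sorted vocabulary ranks. Amino-acid frequencies
  are near-uniform and our vocabulary is not frequency-sorted, so the
  default proposal here is uniform; with 20 negatives out of 28 tokens
  this makes training nearly exact, which we verified by comparing against
  full-softmax training on an i.i.d. corpus (both converge to the entropy
  bound; the log-uniform proposal converges noticeably slower and is kept
  as an option).
- **Truncated backpropagation.** Length-sorted batches are processed in
  contiguous unroll-length windows (default 20 for `mini`, 100 for
  `paper`) with recurrent state carried across windows and reset between
  batches. Each window takes one optimizer step; the gradient is
  normalized by the target count of a *full* window, not the realized
  one — otherwise the short terminal window, populated almost entirely by
  end-of-sequence targets, is weighted up per target and the model
  systematically over-predicts the end token (we observed exactly this
  failure before fixing the normalization).
- **Optimizer.** Adam at learning rate 0.003 by default; Adagrad at 0.2
  (the reference biLM default) is available but converges poorly at the
  mini scale we train at.
- **Dropout** (rate 0.1) is applied to the recurrent layers' inputs during
  training only.

All forward/backward passes are hand-written in vectorized base R; every
layer's analytic gradient is checked against central finite differences in
the test suite (relative agreement at `1e-4` or better on sampled
coordinates of every parameter group).

## Embedding extraction

Three layers are extracted per residue: the word-encoder output (duplicated
across the two direction halves so all layers share one width), and the two
recurrent layers with forward and backward halves concatenated. The default
combination is the element-wise **sum** of the three layers (1024
dimensions at full scale), the variant all downstream models consume;
horizontal concatenation (3 × 1024 = 3072) is retained for research use.
No fine-tuning and no learned layer weighting is applied. Per-protein
vectors are the arithmetic mean over residue rows. Inference batches are
packed by sorting proteins by length and greedily filling batches of at
most 15,000 residues; embeddings are verifiably independent of batch
placement.

## Baseline encodings

- **One-hot** (20 channels; rare/ambiguous/unknown residues become zero
  rows).
- **BLOSUM65 rows** (23 channels: 20 standard + B, Z, X), raw integer
  scores from the bundled NCBI-format matrix. U and O, absent from
  substitution matrices, are looked up as C and K respectively (their
  closest biochemical parents); the aliasing is recorded on the encoding.
- **Evolutionary profiles** (50 channels: one-hot 20, substitution profile
  20, 7 alignment-HMM transition features, 3 diversity features), read
  from TSV; the synthetic generator provides consistent profile fixtures.
- **3-mer skip-gram** (100 dimensions): overlapping 3-mers trained with
  skip-gram negative sampling. The mapping is context-free by
  construction — one vector per distinct 3-mer — which is precisely the
  property the contextual embeddings are contrasted against. Per-residue
  encoding uses the 3-mer centered at each position with edge replication;
  there is no established convention for assigning overlapping 3-mers to
  individual residues, so this choice is ours and documented here.

## Downstream predictors

The **per-residue model** is a two-layer CNN: window-7 convolution from X
input channels to 32 filters, ReLU, dropout 0.25, then a second window-7
convolution to 13 outputs presented as three softmax heads (3-state
structure, 8-state structure, binary disorder). A single 13-channel output
convolution is parameter-identical to three separate head convolutions and
matches every printed parameter count: X·7·32+32 + 32·7·13+13 gives 232 k
(X = 1024), 14 k (50), 244 k (1074), 25 k (100), 7 k (20), 8 k (23). The
three tasks are trained jointly with summed per-head cross-entropies
(each averaged over its scored residues); residues with undefined labels
are masked out of loss and metrics. Adam, learning rate 0.001, batches of
128 proteins, ~5% random held-out split for early stopping with patience
5. Whether the original per-residue system shared one trunk across the
three tasks or trained them separately cannot be decided from parameter
counts (they are identical); we default to the shared trunk.

The **per-protein model** compresses the pooled embedding to 32 features,
then applies dropout 0.25, batch normalization and ReLU — in exactly that
order — followed by two linear softmax heads (10-class localization,
2-class membrane). Parameter count d·32+32 + 64 + 330 + 66, i.e. 33,260
("33 k") for d = 1024. For the 100-dimensional k-mer input the same
closed form gives 3,692.
Proteins with unknown membrane annotation contribute zero membrane loss
but still train the localization head. Batch-normalization statistics are
running means/variances updated during training and frozen at inference.

## The synthetic study conditions

No real protein corpus ships with the package; everything is testable on a
generator whose latent structure mirrors what the analysis assumes:
sequences whose local context predicts structural class.

Proteins are emitted by a hidden-state Markov grammar with ten states
(helix H, 3₁₀-helix G, π-helix I, strand E, bridge B, turn T, bend S, coil
C, disordered D, membrane-helix M). Each state has a peaked emission
distribution built from classical residue propensities (preferred residues
weighted 6:1 — e.g. A/L/E/M/Q/K for helix, V/I/F/Y/W/T for strand,
L/I/V/F/A/W for membrane segments), and a self-transition probability
setting realistic segment lengths (means of roughly 3–14 residues).
States map onto DSSP letters for the 8-state labels; the disordered state
maps to coil *and* is flagged in a separate mask, mirroring the convention
that disorder is missing coordinates rather than a DSSP class. The
three-state reduction is the standard [G,H,I]→H, [B,E]→E, rest→O.

Per-protein labels: each of ten localization classes (named after the
DeepLoc convention) biases the transition-target mixture over states —
nuclear proteins are disorder-rich, extracellular ones strand-rich,
membrane classes carry membrane-helix states, and so on. The mixtures are
sharpened by an exponent (`mixture_contrast`, default 2) chosen once so
that the classes are actually recoverable from state composition at
typical protein lengths: with the default settings a classifier given the
*true* state composition reaches roughly 60% ten-class accuracy, leaving
meaningful headroom between chance (10%) and perfection for the encodings
under comparison. A protein is labeled "membrane" exactly when its hidden
path contains a membrane-state run of at least 15 residues (an
independent run-length scan reproduces the label in tests); 8% of
membrane annotations are masked to "unknown". Lengths are log-normal with
median 150, clipped to [30, 2000].

What the generator does *not* emulate: real residue co-occurrence beyond
first-order state structure, homology between proteins, alignment noise in
real evolutionary profiles, 3-D geometry, and class-imbalanced
localization priors. Passing tests therefore demonstrate that the
implementation learns and transfers the latent structure it was given —
not that it attains any particular accuracy on natural proteins.

The standard study conditions used by the behavioral tests and the
acceptance script are: 400 training and 120 held-out test proteins, the
mini biLM trained for 8 epochs, residue predictors trained for up to 12
epochs and protein predictors for up to 40 (early stopping usually halts
sooner), and the 3-mer skip-gram trained for 2 epochs — matched budgets
across the encodings being compared. These sizes were chosen as the
smallest at which the expected orderings are stable across seeds.

Under these conditions the pipeline reproduces the qualitative results of
full-scale transfer learning: the mini biLM's held-out perplexity falls
well below the 20-residue entropy bound on grammar corpora while
converging to that bound from above on i.i.d. corpora (a model trained on
an i.i.d. uniform corpus cannot statistically beat perplexity 20 on held
out data — an analytic anchor the tests assert); contextual embeddings
beat one-hot encodings for secondary structure; and pooled contextual
embeddings beat pooled context-free 3-mer vectors for localization.

## Numerical choices and degenerate inputs

- Probabilities in all softmax layers are computed with max-subtraction;
  cross-entropies clamp probabilities at `1e-12`.
- The binary Matthews correlation returns 0 with a degeneracy flag when a
  contingency marginal is zero; the Gorodkin RK does the same when a
  marginal variance vanishes. Per-protein disorder MCC macro-averages over
  proteins and excludes (but counts) proteins whose true labels contain a
  single class; a residue-pooled variant is also reported.
- Bootstrap standard errors use 1000 resamples of the item set drawn with
  replacement; per-residue metrics bootstrap the per-protein score
  distribution.
- Empty sequences, unknown tokens, mismatched feature/label lengths,
  mismatched store modes and checkpoint hashes are all hard errors — the
  package refuses to guess.

## Limitations

Disorder transfer is weak at the mini scale: the disorder head learns a
clear ranking signal (disordered residues receive several-fold higher
probabilities than ordered ones) but, with ~6–8% positives and the
standard unweighted cross-entropy, its calibrated probabilities rarely
cross the argmax threshold within the desk-scale training budget, so the
macro-averaged disorder MCC stays near zero even though the
residue-pooled MCC is positive. Both variants are reported; this mirrors
disorder being the hardest of the transfer tasks rather than a defect of
the labels (an independent windowed-composition classifier on the same
fixtures attains a pooled MCC of only ~0.34).

The R implementation is single-threaded and CPU-bound; training the
full-scale preset is out of reach by design (the preset exists so that the
architecture arithmetic is checkable). The sampled-softmax machinery is
exercised with a 28-token vocabulary, where it is nearly exact; its
behavior with large vocabularies is untested here. The t-SNE projection
delegates to scikit-learn through a subprocess and therefore requires a
Python installation with scikit-learn at run time.
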
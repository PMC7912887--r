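---
title: "mirtarnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtarnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

MicroRNAs (miRNAs) are ~22-nt regulatory RNAs that repress genes by
hybridizing to short sites, typically in 3'UTRs. Canonical targeting is
driven by Watson–Crick pairing of the miRNA *seed* (positions 2–7 or 3–8
from the 5' end); non-canonical sites tolerate G–U wobbles and a single
bulged or mismatched nucleotide. `mirtarnet` classifies a (miRNA,
candidate site) pair as target / non-target directly from raw sequence,
with no hand-crafted features.

The classifier is a six-layer hybrid network:

1. **Embedding** — each residue of the 5-letter alphabet {A, U, G, C, N}
   maps to a trainable 5-dimensional vector. N (the padding letter) is a
   first-class vocabulary item with its own trainable row, not zeros.
2. **1D convolution** — 320 kernels of width 12, ReLU, *valid* boundary
   mode (no implicit zero padding: the convolution sum
   $\mathrm{Conv}(X)^n_m = \mathrm{ReLU}\big(\sum_{i=0}^{I-1}\sum_{j=0}^{J-1}
   w^n_{i,j}\, x_{m+i,j}\big)$ only covers in-bounds positions, so the
   output length is $L - I + 1$).
3. **Max pooling** — window 2, stride 2 (the minimal dimensionality
   reduction; the published description requests pooling but does not fix
   its size, so both are exposed in `model_spec()`).
4. **Bidirectional LSTM** — 32 hidden units per direction, standard gate
   equations ($i_t, f_t, o_t$ gates, candidate $\tilde c_t$, cell $c_t$,
   output $h_t = o_t \cdot \sigma_{out}(c_t)$). Per the source method the
   output nonlinearity $\sigma_{out}$ is **ReLU** rather than tanh;
   `rnn_activation = "tanh"` is the fallback flag. The final time-step
   states of the two directions are concatenated (64 features) — a
   classification head needs a fixed-width vector.
5. **Dense** — 16 ReLU units (width is a package choice; unspecified in
   the source description).
6. **Dense** — 1 sigmoid unit: the target probability.

Dropout (default rate 0.2, tunable over the grid) is applied at four
sites: after the convolution, after pooling, after the BiLSTM, and between
the dense layers. The source text is internally inconsistent here (its
prose says "after every layer except the first and last", its figure
lists the four sites); the figure placement is implemented.

Loss is binary cross-entropy and the optimizer is Adam (β₁ = 0.9,
β₂ = 0.999) — the description fixes learning rates but not the optimizer;
this choice is recorded here and in the model artifact.

### Input encoding

A pair is encoded as `pad(reverse(miRNA)) ++ pad(site)`:
the mature miRNA (always written 5'→3') is reversed to 3'→5', each
sequence is right-padded with N to its slot, and the two are concatenated.
Slot layouts are fixed by a `pair_schema`: (26, 53) → 79 total for
DeepMirTar-style site tables, (26, 40) → 66 for miRAW-style trimmed
sites. Whether padding precedes or follows reversal is not specified by
the source; `mirtarnet` pads *after* reversing, so the miRNA 3' end sits
at position 1 and the site 5' end at a fixed offset — fixed positional
semantics for the convolution. The letter→code map A=0, U=1, G=2, C=3,
N=4 is frozen for artifact stability.

## The engine: why the network is hand-implemented

No deep-learning framework is available in the target R environment, and
the network is the method's core contribution, so forward and backward
passes are implemented natively in R as a small number of large BLAS
operations (one im2col GEMM for the convolution, batched input
projections for all LSTM time steps). Backpropagation is verified in the
test-suite against central finite differences of the loss — on the full
graph and on every ablation variant — to a relative tolerance of 1e-4,
which is the engine's independent correctness oracle.

### Initialization

Weights are Glorot-uniform, biases zero except the LSTM forget gate
(bias 1). The embedding deserves a note: with the customary tiny uniform
start (±0.05), signal reaching the output through six layers is so small
that Adam can idle at the trivial loss (ln 2) for a seed-dependent number
of epochs — some seeds never escape within a desk-scale epoch budget.
Because `embed_dim == vocab_size`, the embedding can instead start at the
identity plus N(0, 0.05) noise, i.e. *one-hot encoding as the starting
point of a trainable embedding*. This preserves the design (a trainable
dense embedding) while making takeoff reliable; it was adopted after
observing dead-start seeds at the default scale.

## Training protocol

* **Splits** — 64 % train / 16 % validation / 20 % test, stratified by
  label, sizes `round(0.2 N)` / `round(0.16 N)` / remainder per stratum.
  At the published dataset sizes this reproduces every printed
  test/validation count exactly; the published split table's own rows sum
  to one less than its totals, so printed *training* counts can differ by
  one pair.
* **Grid** — learning rates {0.2, 0.1, 0.05, 0.01, 0.005, 0.001}, dropout
  {0.1 … 0.5}, batch sizes {10, 30, 50, 100, 200}, epoch cap 1000. Ties
  in validation accuracy break deterministically toward the lowest
  learning rate, then dropout, then batch size.
* **Early stopping** — training halts when validation accuracy fails to
  improve by ≥ 0.1 % (absolute) within the patience window (100 epochs at
  publication scale); the best-validation weights are restored. The
  monitored set is validation (the source says only "the accuracy of the
  model"; monitoring test would leak).
* **Repeats** — `repeated_runs()` re-splits with derived seeds and
  reports per-metric means with 2.5/97.5 empirical percentile intervals
  (linear interpolation between order statistics), the repeated-resplit
  protocol (30 repeats at publication scale).
* **Unified dataset** — `compose_unified_dataset()` draws, per class,
  `floor(0.9 × min(class counts))` pairs from the smaller source and caps
  the larger source at 3× that, returning the leftovers as held-out test
  sets. At the published class counts this yields 3,465 + 10,395 pairs
  per class (27,720 combined) and leftover sets of 443/385 and
  21,265/20,598. (The drawn count is anchored on the *smaller* class so
  the combined set stays balanced; an alternative reading — a fraction of
  each class separately — contradicts the published leftover counts.)

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the method
assumes, so training, scanning and ablation are testable offline:

* miRNAs 19–26 nt, uniform composition, drawn from a **finite pool**
  (default 64 distinct miRNAs). Real interaction catalogs reuse a finite
  set of mature miRNAs across thousands of pairs; with a fresh random
  miRNA per pair the shuffled-negative task becomes pure relational
  matching ("does this site complement this never-seen-before seed?"),
  which this architecture — like any sequence classifier without an
  explicit pairing mechanism — cannot learn at desk scale.
* positives carry a planted motif: the reverse complement of the seed
  (2–7 or 3–8 register, 70 % canonical / 30 % non-canonical by default;
  non-canonical sites allow G–U wobbles and exactly one bulge or
  mismatch), at a random offset, with uniform i.i.d. flanks — the
  simplest null for 3'UTR context absent a stated background model.
* negatives follow the curated-set construction: the mature miRNA is
  shuffled (multiset preserved, identity permutations redrawn) and the
  site is kept. Note the consequence: *the site distribution is identical
  between classes*, so models trained on shuffle-negatives discriminate
  on the miRNA slot. This mirrors the real construction and is exactly
  why such a model cannot rank gene windows. For scanner work the
  generator therefore offers `negative_mode = "resample_site"` (same
  miRNA, motif-free random site), which forces the model to read the
  site. The scanner acceptance experiment uses this mode.
* provenance (seed mode, register, planted offset, motif) is retained per
  pair so every planted structure is re-verifiable by the independent
  complementarity checker `verify_planted_site()`.

What a green synthetic test establishes: the pipeline encodes correctly,
gradients are exact, the optimizer recovers a planted signal, the scanner
localizes it. What it does not establish: the published accuracies on the
curated human datasets (thermodynamics, conservation, site-context biases
and miRNA family structure are absent here), which are out of scope.

## The scanner

Long genes are split into overlapped windows of the model's site-slot
length (default step = window/2, so any site up to window/2 + 1 nt lies
wholly inside some window); when the final stride overshoots, one extra
window is anchored at `gene_len − window_len`, avoiding artificial
N-runs mid-sequence. Genes shorter than a window become a single
N-padded window. A window is a binding site when its probability ≥ the
site threshold (default 0.5); a gene is a target when its positive-window
count ≥ `min_sites_per_gene` (default 1). Offsets are 0-based half-open,
sense strand only (inputs are transcript/3'UTR sequences). Positive
windows can be written as FASTA with gene, offset and probability in the
header.

## Ablation harness

`variant_spec()` removes one component while keeping everything else
fixed: the pooling layer (conv feeds the BiLSTM), conv + pooling
(embedding feeds the BiLSTM), the BiLSTM (pooled map flattened into the
dense head), the hidden dense layer, or all dropout sites. Parameter
counts change exactly as the reconciled shapes dictate, which the tests
assert in closed form. `compare_variants()` trains all variants on
identical (seed-matched) re-splits so accuracy deltas reflect
architecture only. Re-optimizing the grid per variant is available by
running `grid_search()` with a variant spec.

## Numerical and scale choices

* Sigmoid pre-activations are clamped to ±30, so reported probabilities
  are strictly inside (0, 1); BCE uses an eps of 1e-12.
* A non-finite training loss (divergence at aggressive learning rates)
  aborts the run with epoch/batch diagnostics; grid search records such
  cells as failed and continues.
* Zero-denominator metrics (e.g. PPV with no positive calls, or
  specificity on a positives-only set) are `NA`, mirroring the
  "cannot be calculated" treatment, never 0.
* Acceptance-scale training uses the published early-stopping *rule* with
  a scaled patience (8 within ≤ 18–25 epochs) and n = 2,000 pairs so the
  whole suite fits a single CPU; the package defaults remain
  patience 100 / 1000 epochs. Thresholds were fixed from the stated
  world before measurement and are not tuned to runs.

## Known limitations

* No thermodynamic (ΔG), accessibility or conservation modelling — by
  design, the classifier sees raw sequence only.
* The synthetic world has no site-context or expression realism; green
  tests validate the machinery, not biological performance.
* Training at publication scale (tens of thousands of pairs, patience
  100, 30 repeats, the full 150-cell grid) is supported but takes CPU
  hours, as the original implementation did.
* No reverse-complement scanning and no multi-miRNA co-targeting scores.
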
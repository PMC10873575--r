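---
title: "The nanocon model: contrastive hybrid methylation calling from nanopore signal features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nanocon model: contrastive hybrid methylation calling from nanopore signal features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocon)
```

## The problem

Nanopore sequencing reads DNA by measuring the ionic current as a molecule
transits a protein pore. 5-methylcytosine (5mC) perturbs that current, so
the methylation status of a cytosine can in principle be read directly from
the signal — no bisulfite conversion required. In practice the perturbation
is small, noisy, and spread over the several bases that occupy the pore at
once, and genome-wide the two classes are badly imbalanced: depending on
the organism and sequence context, methylated sites can be rarer than
unmethylated ones by a factor of fifty, or can outnumber them.

`nanocon` classifies candidate cytosines from per-read, per-site feature
records: a 13-base motif centered on the cytosine, and three 13-long signal
tracks — the per-base current mean, its standard deviation, and the number
of raw signal samples per base. Ground truth comes from bisulfite
sequencing, treated as the gold standard.

## Data model and labeling

An instance (`methyl_set` row) is one read's view of one candidate site.
Bisulfite cytosine reports are reduced to per-site calls by
`label_sites()`: a site is **positive** when its coverage is strictly above
5 reads and its methylation rate strictly above 90%, **negative** when its
rate is exactly 0%, and **excluded** otherwise. Two readings of that rule
were genuinely open and are worth recording:

* *Does the coverage filter apply to negatives?* The defining rule states
  it only for positives. We apply it to both by default
  (`negative_coverage_filter = TRUE`): a 0%-rate call on a single read is
  not a credible negative, and the point of the rule is credible examples.
  The flag restores the literal reading.
* *Strictness.* "Above 5" and "over 90%" are read as strict inequalities;
  coverage exactly 5, or a rate of exactly 0.9, is excluded.

Sites with zero coverage have an undefined rate and are excluded, never an
error. Instances at excluded sites are dropped by `attach_labels()`.
Datasets are split 8:1:1 into train/validation/test by a seeded shuffle;
validation and test sizes are floored and the remainder goes to training.

The imbalance statistic used throughout is `class_proportion()`, the ratio
of positive to negative instances (about 0.02 for *A. thaliana*-like data,
about 1.85 for human NA12878-like data).

## The network

Two branches encode an instance, and a recurrent layer fuses them.

**Sequence branch.** The 13-base motif is tokenized into its 9 overlapping
5-mers (`tokenize()`), a window size chosen to match the ~5-base pore
footprint. The vocabulary is the 1024 ACGT 5-mers in lexicographic order
plus an unknown token (any window containing `N`) and a pad token; ids are
a pure function of the alphabet, so tokenization is stable across machines.
Token embeddings plus learned positional embeddings over the 9 positions
feed a stack of Transformer encoder layers built on scaled dot-product
self-attention,

$$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right)V,
\qquad Q = XW_Q,\; K = XW_K,\; V = XW_V,$$

with multi-head projection, residual connections, layer normalization and
a position-wise feed-forward block — the standard encoder layout.

**Signal branch.** The 39 per-base statistics (13 means, 13 standard
deviations, 13 signal lengths on a `log1p` scale, to tame their count
nature) pass through a fully-connected ReLU network.

**Fusion.** The paper-level description of fusion — concatenate the two
feature sets, then run a bidirectional GRU — leaves the geometry open. We
concatenate the (single) signal vector onto *each* of the 9 sequence steps
and run the Bi-GRU over those 9 composite steps, because this preserves the
sequential structure the recurrent layer exists to exploit; the alternative
(flattening everything into one step) would reduce the GRU to an expensive
dense layer. The final forward and backward hidden states concatenate into
the fused representation (`repr_dim = 2 * gru_hidden`, 128 by default).
Dropout (default 0.2) is applied to this representation during training. A
two-layer softmax head produces class probabilities.

Widths and depths are not dictated by the method and were fixed once at
small values adequate for a 9-token problem: embedding 64, 2 encoder
layers, 4 heads, signal encoder 39→64→64, GRU hidden 64. All are
configurable via `nanocon_config()`.

Everything — forward pass, reverse-mode gradients, Adam — is implemented in
base-R matrix algebra on a per-batch tape; attention over a batch is
computed as one blocked matrix product with a block-diagonal mask.
Gradients are validated against central finite differences in the test
suite, and training is bit-reproducible given a seed on a single CPU
thread.

## The contrastive objective

Each training batch is split at random into two equal halves; the i-th
members of the halves form a pair, with indicator $y=1$ when they share a
class. With $D(x_i, x_j)$ the cosine similarity of the two fused
representations, the contrastive loss over $N$ pairs is

$$L_{\mathrm{con}} = \frac{1}{2N}\sum \left[(1-y)\,D^2 + y\,\max(m - D,\, 0)^2\right],
\qquad m = 2 .$$

Two properties of this form, implemented exactly as defined, deserve
comment. $D$ is a *similarity* even though the loss is written in distance
form; the term structure is nevertheless coherent — different-class pairs
($y=0$) are pushed toward $D=0$, same-class pairs toward high $D$. And
because the margin $m=2$ exceeds the maximum cosine similarity of 1, the
same-class term never saturates: it contributes at least $(2-1)^2$ per pair
and the loss cannot reach zero on a batch containing a same-class pair.
This is a documented consequence of the definition, not a defect we
correct; the gradient direction, which is what matters, still pulls
same-class pairs together (a property the test suite checks directly).

The classification objective is mean binary cross-entropy
$L_{\mathrm{CE}} = \frac{1}{N}\sum -[y_i \log p_i + (1-y_i)\log(1-p_i)]$
(probabilities clamped at $10^{-7}$), and the combined objective is

$$L = \alpha\, L_{\mathrm{con}} + (1-\alpha)\, L_{\mathrm{CE}}, \qquad \alpha = 0.8 .$$

**Alternating freezing.** Training alternates two phases: in the
contrastive phase the classifier head is frozen and the encoder minimizes
$L$; in the classification phase the encoder is frozen and the head
minimizes $L_{\mathrm{CE}}$. "Encoder" here means everything upstream of
the head — the contrastive term itself has no parameters, so the encoder is
the only coherent counterpart to freeze. Alternation is per-epoch by
default (`per_batch` is available); frozen parameters are verifiably
bit-identical across their frozen phase. Optimization is Adam with an
exponential per-epoch learning-rate decay (default 0.95 from $10^{-3}$).
When a validation set is given, the returned model is the epoch snapshot
with the best validation AUPRC — the natural selection criterion under
imbalance; ties go to the later epoch, whose classifier head has seen the
most training (AUPRC is rank-based and can saturate before the
probability scale is calibrated).

## Metrics

`confusion_and_metrics()` reports the confusion counts at a 0.5 threshold
(configurable) and ACC, Precision, Recall and F1 computed from those counts
by their defining formulas, plus AUROC as the Mann–Whitney rank statistic
with midranks for ties, and AUPRC as average precision — step integration
of the precision–recall curve with tied scores grouped into a single
threshold, so the value does not depend on tie order. Average precision and
trapezoidal PR integration differ; we use the former. When a test set
contains a single class, rank metrics and recall/precision are reported as
0 with a `degenerate` flag and a warning rather than an error.

## The simulator

`simulate_dataset()` generates labeled instances with the statistical
structure the method assumes, so every stage is testable without
sequencing data. Per-base current means are drawn from
$\mathcal{N}(\mu(\mathrm{base}) + \ell\,\delta\,\mathbb{1}[|i-c| \le w],\ \sigma)$
where $\ell$ is the label, $c$ the center position, $w$ the effect
half-width (default 2, emulating the pore footprint), and
$\mu(A,C,G,T) = (0.5, -0.3, 0.3, -0.5)$ a fixed, arbitrary base-level
table. Standard deviations are folded normals ($|\mathcal{N}(0,0.5)|+0.1$)
and signal lengths shifted Poissons ($1+\mathrm{Pois}(8)$); the class
effect can be confined to any subset of the three tracks
(`effect_tracks`), which gives the ablation protocol a ground truth — if
only the means carry signal, masking the means must hurt. Motifs are
uniform random bases with the center fixed to `C` and the context
constraints applied (CpG: following `G`; CHG: `H` then `G`; CHH: two
`H`s). Class imbalance is set by `proportion` (positives per negative,
covering the ~0.02–1.85 regimes of real datasets) with
`n_pos = round(n·p/(1+p))`.

The defaults (`n_instances = 4000`, `proportion = 0.25`, `delta = 3`,
`noise_sigma = 1`) describe a *strongly separable* regime: a 3-sigma mean
shift over five positions. What the simulator does **not** emulate:
k-mer-dependent pore current models, basecalling errors, alignment
artifacts, inter-read covariance at a site, or the long-tailed dwell-time
distributions of real pores. Passing the recovery tests on simulated data
therefore demonstrates that the architecture, losses and training loop
work as specified — not that the model attains any particular accuracy on
real sequencing runs.

`simulate_bisulfite_report()` completes the loop for the labeling stage:
per-site coverage is Poisson (so some sites legitimately fall below the
coverage filter) and methylated counts are binomial at rates 0.97 / 0.01 /
0.5 for methylated / unmethylated / ambiguous truth.

## Numerical and design notes

* **Problem sizes.** The recovery analyses in the tests and the acceptance
  script use 4,000 instances for the separable and null regimes and 1,500
  for the ablation pair, each trained for 4–6 epochs at batch size 64 —
  sizes at which the separable regime saturates and a single-CPU run stays
  comfortable. The per-epoch alternation means half the epochs train the
  head; for very small budgets, keep `epochs` even.
* **Determinism.** All stochastic steps (initialization, shuffling,
  pairing, dropout, simulation) derive from explicit seeds through R's RNG;
  repeated fits with one seed agree bit-for-bit, which the suite asserts.
* **Ties and degeneracies.** Odd contrastive batches drop one instance;
  batches of size 1 are skipped in the contrastive phase; zero-coverage
  bisulfite sites are excluded, never errors; zero vectors are rejected by
  cosine similarity rather than silently returning 0.
* **`no_gru` ablation** replaces the Bi-GRU with a dense ReLU layer over
  the flattened 9-step concatenation at the same output width, matching
  the "replace fusion with a fully-connected layer" variant.
  **`mask_sequence`** zeroes the sequence branch's contribution (the
  context sequence becomes a zero matrix); **`no_contrast`** sets
  $\alpha = 0$, so the contrastive phase degenerates to encoder
  cross-entropy training. The remaining flags zero one signal track before
  encoding.
* **Site-level aggregation** across reads is deliberately left out of the
  model: predictions are per read. Averaging per-read probabilities per
  site is a reasonable downstream utility but a separate decision from the
  classifier itself.

## Limitations

The contrastive margin of 2 over a cosine similarity bounded by 1 means the
contrastive loss has a constant floor; monitoring its absolute value across
runs of different batch composition is uninformative (its *decrease* is
meaningful). Training cost grows quadratically in batch size through the
blocked attention product, which is why the default batch is 64. The
simulator's additive-shift effect model makes the positive class linearly
separable in the means track at large `delta`; it cannot probe the model's
advantage over simpler baselines, only its correctness.
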
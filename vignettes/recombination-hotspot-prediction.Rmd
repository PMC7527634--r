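---
title: "Methods: composition-based prediction of recombination hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based prediction of recombination hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recspot)
```

## The problem and the model

Meiotic recombination events concentrate in hotspots and avoid coldspots.
The predictor implemented here treats hotspot-vs-coldspot as a two-class
problem on raw DNA sequence and rests on one modelling assumption: the two
classes differ in local base composition — the joint frequencies of short
(1–5 nt) words and of base pairs at short gapped offsets — strongly enough
that a classifier over fixed-length composition vectors can separate them.
No alignment, position weight matrix or chromatin information is used.

The pipeline is: encode each sequence into per-block feature vectors, rank
each block by SVM-RFE, cut the blocks to fixed selected sizes, concatenate
weighted ranked prefixes into one hybrid vector, and classify with a
feed-forward network under stratified 10-fold cross-validation.

## Encodings and their parameters

**Gapped dinucleotide composition** (`gdc_features`). For each gap
$\kappa$ (number of interposed bases) and each of the 16 ordered base
pairs, the fraction of the $L-\kappa-1$ positions $(i, i+\kappa+1)$
carrying that pair. The per-gap 16 values sum to 1. The gap range is a
tunable set; the default $\kappa \in \{0,\dots,7\}$ is the smallest
conventional range that yields the customary 128-dimensional block
($16 \times 8$). Whether gaps are counted from 0 or 1 is a convention
choice; this package counts interposed bases starting at 0 (so
$\kappa = 0$ is plain dinucleotide composition).

**Reverse-complement composition** (`rcc_features`). Window counts of
k-mers for $k \in \{3,4,5\}$, pooled by canonical class (a k-mer and its
reverse complement are one feature) and divided by $L$. Pooling makes the
block strand-invariant: a sequence and its reverse complement get
identical vectors, which is appropriate because hotspot annotations are
not stranded. Division by $L$ rather than by the window count $L-k+1$ is
deliberate — it matches the formulation this block descends from; a
`per-window` option provides the statistically conventional alternative.
The class counts are 32, 136 and 512 (even-length k-mers admit
reverse-complement palindromes, odd-length ones do not), hence the fixed
680 dimensions.

**Pseudo trinucleotide composition** (`psetnc_features`). The 64
trinucleotide frequencies $f_v$ augmented with $\lambda$ correlation
tiers
$$\theta_j = \frac{1}{L^*-j}\sum_{i=1}^{L^*-j}\Theta(T_i, T_{i+j}),
\qquad L^* = L-2,$$
all jointly normalized:
$d_v = f_v / (\sum f + w \sum\theta)$ for $v \le 64$ and
$d_{64+j} = w\,\theta_j / (\sum f + w \sum\theta)$. The inner pairwise
function is taken as the mean squared property difference
$\Theta(T_i,T_j) = \frac{1}{\mu}\sum_u (P_u(T_i)-P_u(T_j))^2$ — the usual
pseudo-composition convention; the source formulation leaves it implicit,
so this is an explicit design choice of the package. Defaults:
$\lambda = 2$ (pinned by the customary 66-dimensional block,
$64 + \lambda$) and $w = 0.1$ (a free default; $w$ only needs to be small
enough that composition dominates). Increasing $w$ strictly increases the
mass on the tier features whenever $\sum\theta > 0$.

The per-trinucleotide property table is user-replaceable. The default
ships three *generic composition descriptors* (G+C, purine and keto
fractions), standardized to mean 0 / variance 1 over the 64
trinucleotides. They are deliberately not presented as physicochemical
scales: no specific property set is canonical for this block, so the
default exercises the mathematics while documenting its arbitrariness;
users with a preferred dinucleotide/trinucleotide scale should supply it
via `psetnc_params(property_table = ...)`.

**Composition bank** (`kmer_bank_features`). Plain k-mer compositions for
$k = 1..5$ (1364 features, per-k window-normalized). The 425-feature `H`
block is the SVM-RFE-selected top of this bank. This block is an honest
stand-in: the engineered 425-feature set it replaces is not
reconstructible from published information, so the package preserves the
block's size and role while generating its content from first principles.
A precomputed external matrix can be substituted wherever a block matrix
is accepted.

## Selection and the hybrid rule

`svm_rfe_rank` standardizes features, fits a linear SVM (cost 1 by
default), scores features by squared weight and removes the worst `step`
per iteration — 1 for blocks of ≤ 200 features, 10% of the remainder
above (a speed compromise for the 680- and 1364-wide blocks). Ties in
squared weight break by original column order, which makes the ranking
deterministic; duplicated columns receive exactly equal weights and end
up adjacent.

The hybrid rule $F = aG + \lambda(R + \mathrm{PseTNC}) + (1-\lambda)H$ is
interpreted as *ranked-prefix concatenation*: a block contributes its top
`round_half_up(weight × size)` features. This is the only reading under
which the nine catalogued group dimensions (425, 78, 430, 83, 428, 252,
255, 81, 257) are reproducible from the selected block sizes
(5, 12, 66, 425); exact halves round up (5 × 0.5 → 3, 425 × 0.5 → 213),
verified against all nine groups. $\lambda$ is applied to R and P
separately (6 + 33 at $\lambda = 0.5$) rather than to their pooled 78;
both give the same totals, and per-block application composes better.
Note the symbol collision: the mixing weight $\lambda$ (`lam_mix`) is
distinct from the PseTNC tier count (`lam`).

## The classifier

`train_dnn` implements a plain feed-forward network: Xavier-initialized
weights (variance $2/(\mathrm{fan_{in}}+\mathrm{fan_{out}})$, zero
biases), tanh/ReLU/sigmoid hidden activations, a 2-unit softmax output
(class 0 = hotspot; exact probability ties predict 0 for determinism),
and softmax cross-entropy with a small L2 penalty (default $10^{-4}$)
minimized by full-batch backpropagation. The updater combines Adagrad
per-parameter scaling with momentum 0.9 — the convention of the deep
learning framework this architecture descends from, where "SGD optimizer",
"Adagrad updater" and "momentum 0.9" co-exist; plain SGD-momentum is
available as an option. Training runs a fixed iteration count (no early
stopping); minibatches and inverted dropout are available but off by
default. Gradients are verified against central finite differences in the
test suite (at a perturbed-bias point for ReLU, whose kink at exactly zero
pre-activation makes one-sided differences there meaningless).

The default geometry (430 inputs, hidden 413-318-251-182-96, learning
rate 0.1, 1000 iterations, seed 6) is the published tuned configuration
for the G3 hybrid input. The surrounding description of that
configuration is internally inconsistent about depth ("five hidden
layers" vs a count of 4); the explicit width list 430-413-318-251-182-96-2
is taken as authoritative — five hidden layers. For the synthetic-scale
experiments in this package (83-feature G4 input, 400 samples) a compact
64-32 network trained for 300 iterations is used instead: a five-layer,
~400 000-parameter network is disproportionate to an 83-dimensional input
and would dominate runtime without changing the conclusion. That choice
was made on problem-size grounds when the experiment was designed.

## Evaluation

Metrics use the hotspot-centric notation ($H^+$, $H^-$ totals; $H^{-+}$
hotspots predicted coldspot; $H^{+-}$ coldspots predicted hotspot):
$\mathrm{ACC} = 1 - (H^{-+}+H^{+-})/(H^{+}+H^{-})$,
$\mathrm{SN} = 1 - H^{-+}/H^{+}$, $\mathrm{SP} = 1 - H^{+-}/H^{-}$, and
$$\mathrm{MCC} = \frac{1 - (H^{-+}/H^{+} + H^{+-}/H^{-})}
{\sqrt{(1 + \frac{H^{+-}-H^{-+}}{H^{+}})(1 + \frac{H^{-+}-H^{+-}}{H^{-}})}}.$$
These are algebraically identical to the standard TP/TN/FP/FN
formulations (the test suite checks every confusion table with class
totals up to 20). Degenerate cases never produce silent NaN: a zero MCC
denominator factor (an all-one-class prediction) yields MCC = 0 by the
usual convention, and an absent class makes SN or SP `NA` with a warning.

Cross-validation is stratified (each fold's class ratio within one sample
of the overall ratio) and seeded. The default `leakage_mode =
"fold-internal-selection"` re-fits the SVM-RFE rankings and the feature
standardization inside each training fold — the statistically correct
protocol; `"whole-dataset-selection"` ranks once on all data, which is
optimistic but mirrors how such benchmarks have often been run, and is
provided for replication. Reported metrics are pooled over the union of
held-out predictions; per-fold values are also returned. ROC curves sweep
all unique scores (ties as one step) and AUC is the trapezoidal area,
equal to the normalized Mann–Whitney U statistic.

## The synthetic generator

`generate_synthetic_dataset` builds sequences as concatenations of i.i.d.
trinucleotide tokens. Coldspots draw tokens from an independent-base
background; hotspots place exactly `effect` excess probability mass on a
planted 3-mer set (uniformly across the set) with the non-planted
background renormalized, so the between-class difference in expected
planted-token frequency equals `effect` exactly — which is what makes the
generator testable against its own stated probabilities
(`token_distributions`). `gc_shift` moves the hotspot background G+C mass.
Defaults mirror the historical benchmark's class sizes (478/572) and a
plausible 200–3000 nt length range (the real benchmark's length
distribution is unpublished; this is a recorded guess, not a fact).

What the generator does *not* emulate: genomic sequences are not i.i.d.
token streams — real hotspots carry positional motifs, GC skews,
repeats and long-range structure. Passing the synthetic recovery test
therefore demonstrates that the pipeline's plumbing is correct and that it
can extract a compositional signal of known strength; it does not certify
the published accuracy on real yeast data, which requires the external
benchmark download described in the README.

The packaged experiment uses 200 + 200 sequences of 500 nt with
`effect = 0.15` on {AAA, TTT} — a signal strength at which the planted
words shift roughly 15% of token mass, comfortably learnable yet far from
degenerate — with the G4 hybrid (83 features; it omits the expensive
1364-feature bank and exercises all three formula-defined encodings).
The label-shuffled control on the same data must fall at chance level.

## Numerical choices and degenerate inputs

* Sequences are uppercased on read; residues outside {A,C,G,T} are
  rejected (or dropped with `strip_ambiguous = TRUE`) because every
  extractor assumes the 4-letter alphabet.
* Internal coordinates are R's 1-based vectors; the feature definitions
  above are stated in 1-based positions to match.
* Sequences too short for a gap or k yield zero-filled features with a
  warning (keeping matrices rectangular) rather than an error.
* Normalization identities (per-gap GDC sums, TNC/PseTNC sums to 1) hold
  to 1e-12 and are tested at that tolerance.
* Zero-variance columns are left unscaled during standardization (divisor
  1), so constant features pass through as zeros rather than NaN.
* All RNG use is localized: generator, fold assignment, initialization
  and training restore the caller's RNG state.

## Known limitations

* The `H` block approximates, not reproduces, the external engineered
  feature set; published results that depend on its exact content are out
  of reach by construction.
* The PseTNC property defaults are placeholders; biological conclusions
  about sequence-order terms require a real property table.
* Published benchmark accuracies are not asserted anywhere in this
  package: they depend on an external download, a partially specified
  selection protocol and stochastic training. The README documents the
  replication path and the expected range instead.
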
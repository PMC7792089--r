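---
title: "Modelling circRNA-binding protein specificities with a capsule network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circRNA-binding protein specificities with a capsule network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-binding proteins (RBPs) recognise short sequence elements on circular
RNAs (circRNAs). CLIP-derived binding-site collections give, per RBP, a
set of bound sequence fragments of varying length. `capsRBP` turns such a
collection into (i) a classifier scoring whether a fragment is a binding
site, (ii) position frequency matrices describing the motifs the
classifier exploits, and (iii) ranked candidate binding positions on
full-length circRNAs, including windows that cross the back-splice
junction — a circRNA has no free ends, so a junction-spanning site is as
legitimate as any other.

## Dataset construction

**Encoding.** Fragments are one-hot encoded as $L \times 4$ matrices with
columns in A, T, C, G order; `N` (and only `N`) encodes as an all-zero
row, so padded positions contribute nothing to any convolution sum. `U`
is normalised to `T` on input; motif logos are rendered back with `U`
because the molecules are RNA.

**Length standardisation.** Observed sites vary in length while the
network wants a fixed $L$. The threshold is the Tukey upper fence
$Q_3 + 1.5\,\mathrm{IQR}$ of the site-length distribution, with quartiles
by linear interpolation (type-7 quantiles) and the fence rounded half-up.
Shorter sites are centred and N-padded — an odd remainder goes to the 3′
side, a fixed convention chosen for reproducibility — and longer sites
are discarded as length outliers rather than truncated, to avoid
injecting flanking sequence the experiment never observed.

**Negatives.** One negative per kept positive, produced by a
dinucleotide-preserving shuffle: an Euler-path (Altschul–Erikson style)
construction on the base-transition multigraph with seeded randomisation
of edge orderings. All 16 adjacent-pair counts and the terminal bases are
exactly conserved, so the classifier cannot separate the classes on
low-order composition (CpG content and the like); it must learn
order-dependent structure. If a randomised path reproduces the input —
possible for low-complexity sequences with a unique Eulerian path — the
construction is retried up to 10 times and then accepted as is.

**Redundancy.** Exact duplicate positives are removed. When genomic
coordinates are available, an optional greedy Jaccard-overlap filter
(default cutoff 0.8) additionally drops heavily overlapping sites; no
published overlap cutoff exists for this filtering step, so the value is
configuration-exposed.

## The classifier

For a one-hot matrix $M$:

1. $K$ convolution filters of width $h$ (ReLU) produce feature maps
   $conf_i = \mathrm{ReLU}(\sum_{j=1}^{h} w_j x_j + b)$ of length
   $L-h+1$.
2. Global max pooling keeps one scalar per filter (leftmost argmax on
   ties, retained for motif discovery).
3. The $K$ pooled values reshape into $n = K/8$ primary capsules of
   dimension 8; each is squashed:
   $\mathrm{squash}(v) = \frac{\lVert v\rVert^2}{1+\lVert v\rVert^2}
   \frac{v}{\lVert v\rVert}$. We evaluate this as
   $v\,\lVert v\rVert/(1+\lVert v\rVert^2)$, an algebraically identical
   form that never divides by the norm: the zero vector maps exactly to
   the zero vector and the norm law holds to machine precision (the
   backward pass keeps a $10^{-12}$ guard).
4. Per (input capsule $i$, digit capsule $j$) affine matrices
   $W^{ij} \in \mathbb{R}^{16\times 8}$ give votes $u^{ij} = W^{ij} v^i$.
   Separate matrices per output capsule are required — with a single
   $W^i$ the two digit capsules could never differ.
5. $T = 2$ rounds of dynamic routing per digit capsule: starting from
   zero logits, each round sets couplings $c = \mathrm{softmax}(b)$,
   aggregates $a = \sum_i c_i u^i$, squashes $v = \mathrm{squash}(a)$,
   and updates $b_i \mathrel{+}= v\cdot u^i$. With zero initial logits the
   first round is exactly the squashed mean of the votes.
6. The two digit-capsule norms are the class scores; training minimises
   the summed margin loss
   $T_c\max(0, m^+ - \lVert v_c\rVert)^2 +
   \lambda(1-T_c)\max(0, \lVert v_c\rVert - m^-)^2$ with $m^+=0.9$,
   $m^-=0.1$, $\lambda=0.5$. There is no reconstruction/decoder branch.

**Routing softmax axis.** The coupling softmax is taken over the $n$
input capsules, independently per digit capsule, so each round's
couplings are positive and sum to one per digit capsule. The original
capsule-network convention instead softmaxes each input capsule's logits
across the output capsules; both readings are implemented
(`routingSoftmax = "inputs"` / `"outputs"`) and verified against
finite-difference gradients, with `"inputs"` the default. On the
benchmark below the choice is immaterial.

**Optimisation.** Mini-batch Adam (default learning rate $10^{-3}$,
standard moment decays 0.9/0.999, batch 64, switching to 512 above
100,000 instances), at most 30 epochs by default. A stratified 10%
validation split is scored after every epoch; training stops once the
validation loss has not improved for `patience` epochs and the
minimal-validation-loss checkpoint is returned, so the selected
checkpoint never has a higher validation loss than any earlier epoch. A
non-finite loss aborts with a diagnostic. All randomness (initialisation,
validation split, batch order) flows through R's RNG, so a fixed seed
reproduces training bit-for-bit; checkpoints store every weight plus the
full configuration and reload to bit-identical scores.

**Pooling ablation.** With `maxpool = FALSE` the pooling stage is
removed and every feature-map position of each group of 8 filters
becomes a primary capsule ($n = (K/8)(L-h+1)$), as in the original
capsule network. On the synthetic benchmark (single 80/20 split,
$n_{pos}=1000$, identical training budget) the pooled model reaches AUC
$\approx 0.97$ while the unpooled variant stays near chance under every
initialisation scale and both routing-softmax conventions we tried — a
strong form of the observation that max pooling improves this
architecture's performance. The unpooled path is therefore an ablation
control, not a recommended configuration.

## Cross-validation and evaluation

`crossValidate()` performs stratified $k$-fold CV (default $k=5$, i.e.
each fold is a 20% test set): per fold a fresh model is trained on the
remaining folds (with its own inner validation split for early stopping)
and scored on the held-out fold. AUC is computed from the Wilcoxon rank
statistic with ties contributing one half — exactly the probability that
a random positive outscores a random negative — and is checked against an
independent ROC implementation in the tests.

## Motif discovery

Convolution filters act as motif detectors. For each detector and each
positive test fragment, if any position responds ($conf_i > 0$) the
width-$h$ subsequence at the argmax (leftmost on ties) is extracted;
stacked subsequences give a position frequency matrix in which `N`
characters contribute to no column. Detectors contributing fewer than 10
subsequences (configurable; no published minimum exists) are dropped.
Counts are kept raw; conversion to probabilities for MEME export adds a
0.25 pseudocount per cell, which also makes all-`N` columns uniform.
Per-column information content is $2 + \sum_b p_b \log_2 p_b$ bits.
Motifs are written in MEME minimal format so they can be aligned to
reference motif collections with external tools such as Tomtom; the
package's responsibility ends at the export (conventional significance
cutoffs for such comparisons are E ≤ 0.05 against a reference database
and E ≤ 0.001 for positive-vs-negative contrasts). Logos are drawn with a
minimal base-graphics stacked-letter renderer.

## Scanning full-length circRNAs

A window of the training fragment length $W$ slides at stride 1 (default)
over the sequence. In circular mode (default) the first $W-1$ nt are
appended so every rotation of the circle is a window start: rotating the
input rotates the hit coordinates and leaves scores unchanged, which the
tests verify. Coordinates are 1-based inclusive; a junction-crossing
window keeps its start on the original sequence, reports the
modulo-length end and sets `wrapped = TRUE`. Hits are ranked by score
with ties broken by earlier start, and `reportTopHits()` greedily selects
non-overlapping hits. BED export converts to 0-based half-open
coordinates at the writer, splitting wrapped hits into their two arcs.

## The synthetic study

Real circRNA–RBP collections require external downloads, so the package
ships a generator that reproduces the *statistical structure* the
classifier assumes: positives are i.i.d. background sequences (default
uniform base frequencies) of fixed length $L = 50$ with one motif
instance planted at a uniformly random offset (default consensus
`ACTAAC`, the DNA form of the canonical QKI motif `ACUAAC`; plant
probability 1), and negatives are dinucleotide shuffles of the positives
— the same construction used for real data. A GC-rich background preset
exists to confirm that the shuffled negatives, not raw composition, carry
the classification difficulty. `simulateFullCircRNA()` plants
non-overlapping (possibly junction-wrapping) motif occurrences on
circular background sequences for end-to-end scan testing.

The benchmark configuration used in the tests and the acceptance script
is $n_{pos} = 2000$, $L = 50$, $K = 64$ filters ($8\times 8$ primary
capsules), $h = 9$, $T = 2$, batch 64, learning rate $3\times 10^{-3}$,
at most 15 epochs with patience 3. These sizes were chosen as the
smallest study at which the task is comfortably learned (per-fold CV AUC
0.96–0.99; a label-permutation control sits at chance); the package
default of $K = 128$ filters ($16\times 8$ capsules) performs equally
well here and is the configuration intended for real datasets, which are
larger and noisier.

**What passing the synthetic benchmark does and does not show.** The
generator has no CLIP noise, no overlapping or mislabelled sites, no
exon/intron architecture, a single fixed-length motif and an i.i.d.
background. Success on it demonstrates that the pipeline's machinery —
encoding, shuffling, optimisation, routing, motif read-out, scanning —
works end to end, not that any particular accuracy will be reached on
experimental data.

## Numerical choices and degenerate inputs

* Squash evaluated without dividing by the norm (exact at zero); backward
  guard $10^{-12}$.
* Coupling softmax is computed with max-subtraction for overflow safety.
* Global max pooling and motif argmax both break ties to the left.
* All-zero feature maps (a detector that never fires) propagate zero
  gradient through the ReLU gate and contribute no motif subsequences.
* `lengthThreshold()` rejects empty input; shuffling rejects length-1
  sequences and sequences containing `N` (the shuffle operates on raw
  sites before padding).
* AUC computation rejects single-class inputs; CV rejects datasets with
  fewer than $k$ instances of either class.
* Adam with learning rate 0 leaves parameters exactly unchanged (used as
  a determinism check in the tests).

## Known limitations

* Binary heads only (bound / unbound); no multi-class digit layer.
* The unpooled ablation does not train to a useful optimum at desk
  scales (see above); it exists for the comparison, not for use.
* Scanning scores every window independently; no smoothing or peak
  merging beyond greedy non-overlap selection.
* Checkpoints are R-native RDS archives; bit-identical reload is
  guaranteed on the same platform only.
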
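---
title: "Modelling TF-family binding from DNA sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TF-family binding from DNA sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Transcription factors (TFs) recognise short, degenerate DNA motifs, and
families of related TFs often share very similar binding preferences (the
palindromic G-box `CACGTG` is bound by bZIP, bHLH, BES1 and BZR factors
alike). Large in-vitro binding compendia (DAP-seq and related assays)
provide genome-wide peak sets for hundreds of TFs, but training one binary
classifier per TF scales poorly and starves rare factors of data.
`tfbinder` instead models binding at the *family* level as a single
multi-label problem: a 250 bp genomic window is mapped to a vector of
per-family binding probabilities. One model annotates every family at once,
shares sequence features between related families, and can afterwards be
interrogated for *why* it predicts binding — motifs, their sequence
context, and their syntax (co-occurrence, positional robustness) — and
applied to tasks the training assay never saw: annotating untargeted
footprint peaks, predicting the regulatory impact of single-nucleotide
variants, and grouping genes by their predicted regulatory profile.

# Data model

* **Windows and labels.** The genome is tiled into fixed-length windows
  (250 bp; non-overlapping by default). A window is labelled positive for a
  family when it covers at least 70% of the length of one of that family's
  peaks. All coordinates are 0-based half-open (BED convention)
  internally; GFF3 input is converted on read. Windows with no positive
  label are kept — unbound sequence is something the classifier must
  learn. Peak sets of the member TFs of a family are merged (union) before
  labelling.
* **Cross-validation.** Splits are by chromosome: each fold holds out one
  whole chromosome for validation, which prevents leakage between
  overlapping or adjacent windows.
* **Baselines.** Mono- and dinucleotide shuffles of the training sequences
  (labels kept) give the s- and d-baseline models. The dinucleotide
  shuffle is an exact Euler-path construction: dinucleotide counts are
  preserved exactly, destroying motifs while keeping local composition.

# The classifier

The network is a 1-D convolutional stack: four blocks of
convolution → batch normalisation → ReLU → max-pooling, a flatten, two
dense blocks (dense → batch normalisation → ReLU → dropout), and a sigmoid
output with one unit per family. Training minimises the sum over families
of binary cross-entropy (optionally class-weighted), with Adam at learning
rate 0.002 and early stopping once the validation loss has not improved
for 5 consecutive epochs (the parameters of the best epoch are restored).
The early-stopping monitor is always the *unweighted* validation loss, so
weighted and unweighted protocols are stopped on a comparable signal — a
weighted monitor is dominated by rare-family noise and stops the weighted
protocol long before the rare families are learned.
The engine is implemented in the package itself — im2col/col2im and fused
batch-norm/ReLU/pooling kernels in C++, the matrix algebra on BLAS — and
its gradients are verified against finite differences in the test suite.

Reference defaults (all overridable through `model_config()`):

| parameter | default | notes |
|---|---|---|
| window length | 250 bp | fixed model input |
| conv filters | 64, 64, 64, 64 | |
| conv kernels | 12, 8, 8, 8 bp | first layer spans a whole core motif |
| pooling | 2, 2, 2, 2 | 250 → 9 positions at the flatten |
| dense units | 128, 64 | dropout 0.25 |
| learning rate | 0.002 (Adam) | constant |
| patience | 5 epochs | monitors total validation loss |
| batch size | 64 | |
| max epochs | 50 | |
| `augment_rc` | TRUE | random orientation per window per epoch |

Two defaults deserve explanation. **Reverse-complement augmentation**:
binding sites occur on both strands, so each training window is presented
in a random orientation each epoch (labels unchanged; inference is always
on the forward strand as given). Without it the model must learn every
motif twice from half the examples, and at desk-scale training-set sizes
(thousands of windows rather than hundreds of thousands) it overfits
before that happens. **First-layer kernel of 12 bp**: family core motifs
are 6–13 bp; letting the first layer span a full core accelerates feature
discovery markedly at small sample sizes. Batch size 64 likewise trades
BLAS efficiency for update count, which is what minority families are
starved of.

## Class imbalance

Family supports are long-tailed. Two mitigations are built in, separately
switchable because their interplay is the object of study: inverse-
frequency class weights `w_f = N/(F * n_f)` (N = total positive labels,
renormalised to mean 1, zero-support families capped) multiply the
per-family loss terms; and offset-augmented training windows (step 75 or
125 bp instead of 250) densify the sampling of labelled regions. Family
subsets (top-k / bottom-k by training support) are built by column-
subsetting the label matrix before training.

# Explainability stack

* **Attribution**: gradient × input by default — the exact gradient of the
  family's output probability with respect to the one-hot input, times the
  input. A sampled Shapley-style alternative (random position reveal over
  dinucleotide-shuffled references, seeded) is available where
  gradient-free attribution is wanted; the pipeline only requires faithful
  localisation, which the planted-motif tests verify directly.
* **IPMs** (interaction predictive motifs): per family, attribution maps
  of correctly predicted windows are thresholded (smoothed |score| above
  1.5 SD of the window mean) into seqlets of 4–25 bp, greedily clustered
  by best-offset, strand-aware correlation, and summarised as
  position-frequency matrices with pseudocount 1. This is a deliberately
  small re-implementation of the seqlet-to-motif idea; no metaclustering.
* **Motif similarity and trees**: best-offset Pearson correlation of
  aligned PWM columns, maximised over the reverse complement (required for
  palindromic cores), then average-linkage clustering.
* **Scanning**: log-odds against a uniform 0.25 background, both strands,
  `N` scoring 0; hits at ≥ 85% of the motif's maximum possible score.
* **Syntax metrics**: offset independence (mean run length of positive
  calls across a 10 bp-stride sliding window, normalised by the 24-window
  ceiling — the number of 250 bp windows that can fully contain one
  motif); weighted co-occurrence (count-weighted mean number of other
  families called in a family's windows); IPM context importance
  (fraction of motif-containing windows the model does not call bound; its
  reciprocal complement is the IPM predictability); a co-enrichment
  Z-score network under a binomial independence null (validated by
  simulation in the tests); and model-vs-motif-occurrence FDR comparison.
  The occurrence-ratio form of context importance printed by some sources
  is numerically inconsistent with a window-level reading (a ratio of
  windows to total occurrences is not a probability), so the window-level
  complement is the primary definition and the literal occurrence ratio is
  always reported alongside.

# Downstream applications

* **Gene regulatory profiles**: per gene, positive calls are counted per
  family over the promoter (1 kb upstream + 0.5 kb downstream of the TSS)
  and terminator (0.5 kb + 1 kb around the TTS), both 1.5 kb, strand
  aware. Profiles are embedded in 2-D and clustered with a density-based
  clusterer that has an explicit noise class. Both stages are pluggable
  functions; the defaults are a scaled PCA embedding and a direct DBSCAN
  implementation (eps 0.25 on the embedding scaled by the leading
  component's SD, minPts 5). Cluster–category enrichment uses two-sided
  Fisher tests with BH correction over the full cluster × category grid;
  cluster co-expression coherence uses a permutation test (n = 1000,
  seeded) on standardised logit co-expression scores with the
  `(r + 1)/(n + 1)` empirical p-value and BH across clusters.
* **Variant effects**: 250 bp windows centred on the variant; per family
  the pair (p_ref, p_alt) is classified gain / loss / retained / unbound
  at θ = 0.5; events with |Δp| > 0.2 pass the shift filter (strictly
  greater). The control null re-applies the same ref→alt substitution at
  30 random positions of the window that carry the same reference base
  (never the variant position), classifying each control as expected /
  de-novo / none relative to the real variant's gain-loss set.
* **Footprint peak annotation**: peaks are standardised to 250 bp around
  their midpoint (edge-clipped peaks flagged), annotated by the model, and
  compared to overlap-derived experimental family sets (≥ 1 bp overlap by
  default). Condition response is modelled by L2-regularised logistic
  regression (fixed λ = 0.01, standardised features) from per-family
  probabilities to the fold-change sign, with stratified 5-fold CV and
  permutation importance over 30 within-column permutations.

# The synthetic test bed

Every component is testable without external data through a generator that
emulates the study conditions: a 5 × 200 kb genome (i.i.d. background, GC
0.36), eight family PWMs of which three share a central `CACGTG` core with
distinct flanks, per-family site counts log-spaced from 1500 down to 30
(the long-tailed imbalance regime), sites planted on random strands
without overlap, peaks of 100 bp around each site midpoint (so the 70%
labelling rule is attainable within one window), one co-occurrence rule
(family 4 sites recruit a family 5 site within 250 bp with probability
0.6), synthetic gene models whose promoters carry archetype-specific
sites, SNPs at the highest-information position of planted sites (ref →
least-probable base) and background SNPs ≥ 10 bp from any site, and a
condition dataset in which peaks of two designated responsive families
receive positive and negative log fold changes respectively.

Design choices of the generator worth stating: planted PWM columns are
sharp (dominant base probability 0.92–0.99), emulating high-affinity
consensus sites — with soft columns the information ceiling of the task
(measured by a PWM-scan oracle that knows the true motifs) drops below
what end-to-end recovery tests can meaningfully probe. The shared-core
trio is the exception: its flanking columns are moderately informative
(dominant base 0.75–0.90, sharp core), as in real family motifs, so that
the trio's mutual similarity is carried by the core it shares; and
outgroup motifs are redrawn until they are dissimilar (best-offset
correlation ≤ 0.45 over ≥ 8 aligned columns) from every core member —
without this constraint, chance alignments between unrelated sharp
matrices regularly exceed the trio's own mutual similarity and the
library does not encode the motif-family structure it is meant to test.
Motif-tree clustering likewise requires alignments of at least 8 columns
for the same reason. Condition-response
strength is bimodal (half the peaks respond at the full effect size, half
at a quarter of it): differential binding magnitude varies across loci in
real data, and it keeps both the mild (|lfc| < 1) and extreme response
classes populated while the sign stays family-driven — with a single
effect size of 3 and noise 0.5 the mild class would be essentially empty.

What the generator does *not* emulate: chromatin context, methylation,
peak-strength heterogeneity, sequencing noise, overlapping sites, and the
true genomic background of repeats and low-complexity sequence. Passing
the end-to-end tests therefore demonstrates that the machinery recovers
planted structure under controlled conditions, not that real-genome
performance will match.

# Problem sizes and expected behaviour

The packaged protocols run at desk scale: the default bundle yields 4,000
non-overlapping windows, and offset-75 training windows give roughly
10,700 training examples per chromosome fold; a fold trains in a few
minutes on one core. Three behaviours are worth knowing.

First, the *reference* protocol at this scale uses the 75 bp offset
training windows (labelling and evaluation stay on non-overlapping
windows). With plain non-overlapping training windows the model has only
~3,200 examples per fold: it learns the abundant families and then
overfits before the minority families are learned, and its held-out
weighted auPR plateaus far below what the same architecture achieves with
offset sampling. Offset windows are not an optional extra at desk scale —
they are what makes the training set large and translation-diverse enough
for the architecture to work, which is precisely the role the offset
strategy plays in the imbalance-mitigation experiments.

Second, the dinucleotide-shuffle baseline is not a chance-level
predictor: shuffling preserves per-window composition, and planted-motif
windows are compositionally biased, so the d-baseline reaches a weighted
auPR around 0.26 against a weighted prevalence of 0.18. Comparisons
against it measure how much the model learns *beyond* composition.

Third, minority families (under ~100 planted sites) are not learned by
the unweighted protocol — per-family MCC correlates positively with
abundance — and the class-weighted loss (with the unweighted
early-stopping monitor) recovers them at a small cost to the overall
weighted auPR. This is the imbalance phenomenology the family-level
approach is designed to study, and it appears at desk scale exactly as it
does genome-wide.

# Numerical choices

* Threshold conventions: probability ≥ 0.5 is a positive call; the
  variant shift filter is strictly `>` 0.2; mild response is |lfc| < 1.
* auPR is step-wise (no interpolation), ties grouped; auROC is the rank
  statistic with half credit for ties; the MCC of a constant predictor is
  0 by convention.
* Early stopping counts epoch 0 as the pre-training validation
  evaluation; improvement must beat the best loss by more than 1e-8.
* Batch-norm uses ε = 1e-5 and running-statistics momentum 0.9; inference
  is deterministic (dropout off, statistics frozen), and chunked
  prediction matches unchunked to float tolerance.
* The dinucleotide shuffle retries its random last-edge tree until it is
  connected; for 4-letter alphabets this terminates quickly with
  overwhelming probability.
* Degenerate inputs: all-N windows one-hot to zeros and get finite
  probabilities; empty peak sets give all-zero label columns with a
  warning; families with zero positives are excluded from metric
  aggregates rather than imputed.
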
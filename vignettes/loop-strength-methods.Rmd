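---
title: "Predicting cohesin-mediated interaction strength: models, evaluation and the synthetic fixture"
author: "loopStrength package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cohesin-mediated interaction strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopStrength)
```

## The problem

Cohesin (RAD21)-mediated chromatin loops connect pairs of anchor peaks
and can be mapped directly by ChIA-PET, which reports each loop's
strength as a paired-end-tag (PET) count.  The assay is expensive and
unavailable for most cell types.  This package predicts the PET
strength of the interaction between any two anchor peaks from features
that are cheap to obtain:

1. the linear genomic distance between the two peak centers, in kb;
2. RAD21 ChIP-Seq signal at both anchors (per-chromosome RPKM);
3. H3K27ac signal at both anchors (active chromatin);
4. H3K27me3 signal at both anchors (repressive chromatin);
5. the GC percentage of both anchor sequences;
6. a CTCF motif convergence flag: 1 when the leftmost anchor carries a
   forward-strand motif and the rightmost a reverse-strand motif, and 0
   in every other configuration (divergent, tandem, or motif absent in
   either peak).

The full schema has 10 columns (paired features contribute one column
per anchor).  The *minimal* schema keeps RAD21, distance, GC and the
flag (6 columns), so a usable model needs a single ChIP-Seq experiment.

Three regressor variants are trained on the same examples: a deep
neural network, a random forest, and gradient boosting.  The target is
the observed PET count; predictions are continuous, non-negative
strengths, and a prediction is called *strong* at the conventional
threshold of 3 PETs.

## Conventions and feature definitions

All files use BED conventions (0-based, half-open); internally ranges
are GRanges (1-based, closed) and conversion happens only at the file
boundary, so write/read round-trips are exact.  Arithmetic rules are
defined on BED coordinates:

* peak center `= floor((start + end) / 2)`; the distance feature is
  `|center1 - center2| / 1000` kb;
* a read belongs to a peak when its midpoint lies in `[start, end)` —
  the midpoint rule is symmetric in read orientation and robust to
  fragment length (whether the original counting used full overlap or
  5' ends is not decidable from the method description; the midpoint is
  our fixed choice);
* RPKM is per chromosome: count / (chromosome total / 1e6) / (length
  in kb).  Reads are never deduplicated;
* GC percent counts G and C over the full interval length; ambiguous
  bases count in the denominator only;
* one motif hit is retained per peak (highest score, midpoint inside
  the peak, ties to the leftmost start);
* anchors are stored leftmost-first, so "first anchor" is well defined
  for the convergence flag and the shuffled-loop null;
* inter-chromosomal records are dropped at parse time (with a logged
  count): all models are defined on intra-chromosomal interactions.

## The regressors

**Random forest** and **gradient boosting** use the field-standard
implementations (`randomForest`, `xgboost`) with pinned parameters so
behavior cannot drift across library versions: 100 trees with bootstrap
resampling and mean aggregation for the forest; 100 stages, shrinkage
0.1, depth-3 trees and squared-error loss for boosting.  Tree
predictions are clipped at zero.

**The deep neural network** is implemented in the package (base R
matrix operations): three hidden layers of 128 rectified-linear units,
a rectified-linear output so predictions are non-negative by
construction, inverted dropout at rate 0.2 on the hidden layers,
mini-batches of 32, Adam at learning rate 1e-5, mean-squared-error
loss, at most 750 epochs with early stopping when the validation MSE
has not improved for 50 epochs.  The validation slice is the last 10%
of the shuffled training rows (the monitoring split size is our
choice).  Two numerical choices matter in practice:

* **Input standardization (on by default).**  With the small fixed
  learning rate, Adam moves each weight by at most ~1e-5 per step;
  on raw feature scales (distances up to thousands of kb, RPKM in the
  thousands) hidden activations reach 1e4 and the epoch budget is far
  too short for the optimizer to traverse that scale — training either
  collapses to a dead rectified output or oscillates at enormous loss.
  z-scaling on training-set statistics (folded into the stored model,
  so prediction is transparent) makes the configuration trainable;
  `dnnConfig(standardize = FALSE)` restores raw-value training.
* **Output-bias initialization at the target mean.**  A rectified
  output unit initialized at zero can start in its dead regime, where
  no gradient flows; starting it at `mean(y)` guarantees training
  begins in the active region.

Splits: the main models use a random 75/25 train/test partition
(`splitRandom`; whether the original split was stratified is unknown —
ours is fully random).  The feature-importance experiments train on
odd-numbered autosomes and test on even-numbered ones
(`splitByChromosomeParity`); chrX/chrY/chrM are excluded from parity
splits.

## Evaluation stack

**Negative-binomial controls.**  Observed PET counts are overdispersed
and well described by a negative binomial, so the null for "does the
model predict anything" is a vector of draws from an NB moment-matched
to the sample mean and variance of the observed strengths
(`p = m/v`, `r = m^2/(v - m)`); when `v <= m` the sampler falls back to
Poisson with a warning.  A useful model must beat the control
correlation by a wide margin.

**Contact maps and SCC.**  Peak-level interactions are binned by
anchor center (`floor(center / binSize)`, the unambiguous rule when a
peak straddles a boundary); the map value of a bin pair is the summed
strength, so total map mass equals total PET strength exactly.  The
stratum-adjusted correlation coefficient between two maps smooths both
with a (2h+1)-wide truncated mean filter (in-bounds cells only; the
upstream border convention is not restated anywhere, truncation is our
choice), splits them into diagonal strata up to a maximum genomic
distance, computes a Pearson correlation per stratum and averages with
variance-stabilized weights
`w_k = N_k * sqrt(var(rank(X_k)) * var(rank(Y_k)))`, excluding
zero-variance strata.  Defaults follow the published settings: `h = 2`
and 25 Mb maximum distance.

**Loop capture and its null.**  A reference loop is *captured* when a
predicted interaction with strength >= 3 overlaps it on both anchors
(respective anchors, >= 1 bp, after coordinate ordering — the simplest
reproducible matching rule).  The null shuffles the first-anchor
coordinates of the reference loops within each chromosome
(derangement-preferred; singleton chromosomes stay unshuffled with a
warning), and pairs whose permuted first anchor lands right of the
second are re-ordered so the leftmost-first invariant survives.

**Feature importance.**  Permutation importance permutes one feature
column of the test matrix and reports the mean increase in the error
metric (MAE by default) over 10 repeats (repeat count is our choice).
Ablation importance retrains without a feature — paired features drop
both columns; `"histones"` drops H3K27ac and H3K27me3 jointly — and
reports the test-MAE increase over the full model on the
odd-train/even-test chromosome split.

**CTCF occupancy and the overlap test.**  Interactions are classified
by whether CTCF ChIP-Seq peaks overlap both, one or neither anchor
(>= 1 bp).  The empirical overlap test draws, 10,000 times, a random
subset of the interaction universe of the same size as the target set
(without replacement), counts its intersection with a comparison
class, and reports `p = #(simulated > observed) / n_sim` (strict
inequality, so ties do not count) and the mean simulated intersection
as the expected overlap.

**Shuffled-input controls.**  For map-level comparisons, a control
prediction permutes whole feature rows jointly before predicting: every
marginal feature distribution — in particular the distance
distribution — is preserved while the row-to-target pairing is
destroyed.

## The synthetic fixture

The generator (`simulateDataset`) emulates the structure of the real
inputs at desk scale, with every parameter in `simConfig()`:

* **Genome**: 2 chromosomes of 2 Mb with isochore-like 100-kb blocks
  whose GC targets are uniform on 30--70%.
* **Peaks**: 80 non-overlapping 2-kb anchor peaks per chromosome on a
  jittered grid (2 kb is the typical anchor-peak size).
* **Reads**: 50,000 reads per track and chromosome; uniform background
  plus in-peak excess giving 10-fold mean enrichment.  RAD21
  enrichment varies per peak (gamma multiplier, mean 1, CV 0.5);
  H3K27ac and H3K27me3 follow a per-peak activity level `a` and
  `1 - a`, making the two marks anti-correlated across peaks, as in
  real chromatin.
* **Motifs**: present in 35% of peaks (chosen so that ~10% of sampled
  interactions have motifs in both anchors, the prevalence reported
  for real cohesin interactions), strands equiprobable.  CTCF ChIP
  peaks co-locate with 90% of motif-bearing and 50% of motif-free
  peaks: occupancy is common even where no high-confidence motif is
  detectable, which reproduces the observed gap between motif
  prevalence and occupancy.
* **Interactions**: 5,000 distinct same-chromosome peak pairs; each
  strength is drawn from NB(mean mu, dispersion k = 4) with

  `mu = mu0 * exp(-d_kb / lambda) * (1 + beta * meanRad21Rpkm) * (1 + gamma * ctcfFlag)`

  using `mu0 = 10`, `lambda = 150` kb, `beta = 5e-4` (scaled to the
  fixture's RPKM magnitudes), `gamma = 1` (convergent loops about
  twice as strong, matching the direction of the real effect).  Only
  an inverse distance dependence is established empirically; the
  exponential form is chosen for a closed-form decay scale.  The mean
  uses the *realized* RPKM and flags computed from the simulated
  reads and motifs, so a model trained on extracted features can in
  principle recover `mu`.  All randomness flows from one seed through
  named substreams (`subSeed`), so components regenerate in isolation.

What the fixture does *not* emulate: fragment-length and read-quality
structure, replicate variability, trans-chromosomal contacts, mappability
and blacklist artifacts, and the genome-scale correlation structure of
real chromatin.  Tests passing on the fixture demonstrate that the
implementation recovers a planted signal of the assumed form — not that
the models attain any particular accuracy on real genome-scale data.

## Problem sizes used by the test suite

The suite and the acceptance script run the full pipeline on the
default fixture (5,000 interactions, two 2-Mb chromosomes).  The DNN is
trained with a 200-epoch cap in these runs; at the fixture's size the
validation loss is still creeping downward at 200 epochs but the
test-set Pearson correlation is within ~0.02 of a 750-epoch run, so
the cap is a sensible profile for routine testing.  SCC oracle checks
use 50 x 50 maps; the empirical-test uniformity check uses 200
meta-replicates at 200 simulations each.

## Known limitations

* The DNN is intentionally plain (no batch normalization, schedules or
  regularization beyond dropout) to stay faithful to the fixed
  architecture; it trails the tree models slightly on the fixture.
* SCC weighting follows the rank-variance-stabilized form; published
  implementations differ in minor variants, which agree on all cases
  we test but are not guaranteed identical on degenerate strata.
* `captureRate` matching is interval overlap only; it does not weight
  by distance or strength of the match.
* Per-chromosome RPKM makes signals comparable within a chromosome but
  inherits any chromosome-scale coverage bias of the input track.
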
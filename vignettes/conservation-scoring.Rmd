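---
title: "Scoring cross-species conservation at the functional genomics level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-species conservation at the functional genomics level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sequence alignment tells us *where* two genomes correspond; it does not tell
us whether the corresponding regions still do the same job. Two regions can
align at the sequence level while only one of them carries regulatory
activity, and regulatory elements can retain their function while their
sequence drifts. `lecifr` scores a complementary notion of conservation: for
every pair of sequence-aligning regions in two species (the reference
species "A", e.g. human, and a query species "B", e.g. mouse), it estimates
the evidence that the pair is conserved *at the functional genomics level*,
using only functional genomic annotations — peak calls, chromatin-state
segmentations, and continuous signal — as input. This is the LECIF score.

The trick is in how the supervision is set up. Positive examples are pairs
of regions that align at the sequence level; negative examples are random
re-pairings of those same regions ("mismatch" negatives). Because negatives
reuse exactly the regions that appear in positives, every individual
feature has an *identical marginal distribution* in the two classes. No
classifier that looks at features one at a time — logistic regression being
the canonical example — can beat chance on this task. Whatever signal a
classifier does extract must come from the *joint* structure of the two
species' feature vectors, i.e. from cross-species concordance of activity.
The score is therefore usable as evidence of shared function even though
alignment, not function, provided the labels.

## The classifier

Each base model is a two-branch ("pseudo-Siamese") feed-forward network:
one branch embeds the species-A feature vector, a second, independently
parameterised branch embeds the species-B vector, and a final subnetwork
combines the two embeddings into a probability. The two branches share no
weights — the species have different annotation compendia and different
feature dimensionalities, so a true Siamese architecture is not applicable.

Training minimises class-weighted binary cross-entropy with weight 1 for
positives and `w_neg = 50` for negatives. The heavy negative weight pushes
scores toward 0 unless the evidence for conservation is strong, so a high
score is a conservative claim; it changes calibration, not ranking. After
each epoch the AUROC on a held-out validation set is computed (unweighted —
validation selection uses the balanced validation sample directly);
training stops when validation AUROC has not improved for 3 epochs, at 100
epochs, or at a wall-time cap, and the weights from the best epoch are
kept.

The final score is the mean of an ensemble of `K` such networks, each
trained on its own random subset of `n_pos` positive and `n_neg` negative
examples from the training pool. The reference-scale protocol uses `K =
100` members with 10^6 examples per class each, after a 100-candidate
random hyperparameter search; the shipped `"desk"` profile (`K = 10`,
2×10^4 per class, 10 candidates, 30 epochs) keeps the full pipeline in
laptop range. Genome-wide scores come from *two* ensembles trained on
complementary chromosome splits: a pair is always scored by the ensemble
that never saw its chromosomes.

Numerical choices the text above leaves open are fixed as follows, and
recorded in the model object: Adam optimisation, rectified-linear hidden
activations, He-style Gaussian initialisation under a per-member seed,
predictions clamped to `[eps, 1-eps]` with `eps = 1e-12` inside the loss,
and inverted dropout during training only.

## From alignment to examples

The pairwise alignment arrives in axt format. Each gapped record is split
at every gap column into maximal ungapped blocks, within which bases
correspond 1:1 (antiparallel when the query is on the reverse strand —
reverse-strand coordinates are converted to forward-strand at load, which
requires the query chromosome sizes, and downstream code is
strand-agnostic). Where several query segments map to overlapping reference
segments, the highest-scoring one is kept; remaining ties break by query
chromosome name and start, for determinism. Blocks are tiled into
non-overlapping 50-bp windows from the block's first base, the final window
truncated at the block end, so regions of 1–50 bp result.

Mismatch negatives are built per chromosome-split role as a random
permutation of the B regions over the A regions, with fixed points (and,
defensively, any re-creation of a truly aligning combination) repaired by
rotations — a derangement with respect to the alignment relation. One
negative per positive keeps counts balanced; class imbalance is expressed
through the 50:1 loss weight instead of through example counts. A
genome-background variant samples both members uniformly from their
genomes, for the LECIF-GB-style score.

Chromosome splits are whole-chromosome: a pair belongs to train, validation
or test only when *both* of its chromosomes are in that role's sets, the
three sets are disjoint within each species, and pairs matching no role are
kept for prediction only. The default carves chromosomes by parity (odd
minus one reserved chromosome for training, the reserved odd chromosome for
validation, even for test); the exact sets are configurable because the
appropriate partition depends on the genomes at hand.

## Features

A region is represented by the annotations overlapping its *first base*
(regions are at most 50 bp; this trades a little resolution for an
order-of-magnitude cheaper featurisation, and a base-resolution mode exists
for checking the effect). Each peak track contributes one binary feature;
each chromatin-state segmentation contributes a one-hot block with one
binary feature per (state, epigenome); each signal track contributes one
continuous feature, min–max normalised by the species-wide extremes
computed once over all signal tracks jointly and clipped to `[0, 1]` at
prediction time. Bases outside any segmentation interval encode all-zero
for that epigenome rather than erroring — real segmentations have gaps.
Feature order is fixed by manifest order (then state order) and persisted
with the schema, so matrices are reproducible byte for byte.

## The score track and its variants

Scoring the genome applies the split-complementary ensembles to every tiled
window of every block; the window's score annotates all its bases, and
output goes to bedGraph (reference genome) plus a paired TSV carrying both
species' coordinates, at 6 decimal places, without merging adjacent
equal-scoring windows. The region-neighborhood variant re-scores a pair
against 50-bp query windows stepped at 50 bp from the aligning query
region's first base in both directions within a neighborhood of `W` bases,
and takes the maximum; `W = 0` reproduces the plain score bit for bit, and
the result is non-decreasing in `W`. The step is 50 bp rather than 1 bp:
the windows mirror the tiling convention, and a 1-bp slide would mostly
re-score near-identical feature vectors at 50× the cost.

## Evaluation statistics

The package implements the full set of statistics used to characterise
such scores, each as a small tibble-in/tibble-out function with an
independent oracle in the test suite:

* **Class-weighted AUROC/AUPRC** (`weighted_auc()`), where each negative
  carries weight `w_neg`; a uniform negative weight cancels from AUROC but
  not from AUPRC, whose random-scorer expectation under equal counts is
  `1/(1+w)` — `1/51 ≈ 0.02` at the default weighting. A bootstrap wrapper
  reports mean ± SD over resamples.
* **Weighted Jaccard similarity** of tissue-grouped peak activity
  (`tissue_activity_vectors()`, `weighted_jaccard()`):
  `Σᵢ min(hᵢ, mᵢ) / Σᵢ max(hᵢ, mᵢ)` over per-group overlap fractions;
  pairs with a zero denominator are flagged and excluded. The tissue
  grouping is evaluation-only metadata — it never enters training features.
* **Chromatin-state frequency correlation** per state across pairs, for
  segmentations from a jointly learned state model; undefined (constant)
  states are reported missing, not zero.
* **Score binning** by equal width or percentile rank, **variant
  enrichment** per equal-width bin against the uniform background of all
  scored regions with one-sided exact binomial p-values (no
  multiple-testing correction is applied inside the enrichment — the
  conventional raw thresholds are left to the caller),
  **annotation comparisons** via two-sided Mann–Whitney U tests, two-level
  **per-state mean scores** (state×epigenome mean, then across epigenomes),
  **windowed means** with the half-coverage rule (windows with *strictly
  less* than half their bases annotated are dropped, so exactly-half
  windows are retained — the literal reading of the rule), and **windowed
  two-track correlations** (50-bp windows, 10-bp steps, a minimum-annotated
  threshold per track, with the two tracks free to annotate different
  bases).

## The synthetic data generator

Real compendia (thousands of experiments over mammal-scale genomes) are far
outside a test suite's budget, so the generator plants the *structure* the
method exploits into toy data. Each genome is tiled into 200-bp segments
carrying a latent categorical activity state (six states, promoter-like
through quiescent, frequencies 0.05–0.45) plus a continuous activity level.
Within aligned blocks, the query genome's latent intervals are exact images
of the reference segments through the alignment; each image copies the
reference state and level with probability `rho`, the planted concordance,
and is drawn independently otherwise. Observed tracks are noisy emissions:
peak tracks fire per segment with state- and tissue-group-specific
probabilities, segmentations mislabel a segment with probability 0.1 per
epigenome, and signal tracks add Gaussian noise (sd 0.05) to the activity
level. Variants are placed at a background rate, multiplied in
high-activity aligned segments when the planted enrichment effect is on.
An audit (`concordance_audit()`) re-reads a fixture and recovers `rho`
after correcting raw agreement for chance under the marginal state
frequencies.

The alignment side emulates the real input surface: gapped axt records
with reverse-strand queries, non-overlapping placements, and a synteny
bias (the query partner falls on the same-numbered chromosome with
probability 0.8) so that chromosome-parity splits retain a usable share of
pairs, as real synteny does. Default scale is 4 chromosomes × 1 Mb per
species with ~2,000 alignment records, which runs in minutes; the test
suite and the acceptance script use 4 × 400 kb with 1,000 records, giving
roughly 20,000 aligning 50-bp pairs — enough for the chance-level and
signal-recovery checks while keeping a full run within a coffee break. The
desk-scale model settings there are `K = 10` members at 2,500 examples per
class, which suffices on fixture-scale data.

What the generator does *not* emulate matters for interpreting green
tests: there is no sequence evolution, no assay-specific noise structure,
no covariance between annotations beyond the single latent state, no
uneven chromosome sizes, and two orders of magnitude fewer features than a
real compendium. Passing tests demonstrate that the machinery is correct
and that the method recovers planted cross-species dependence; they say
nothing about biological conclusions on real genomes.

## Degenerate inputs and edge conventions

Coordinates are 0-based half-open throughout (axt's 1-based inclusive
coordinates converted on read, BED interoperability on write). Applying the
reverse-strand flip twice is the identity. An alignment record whose gapped
sequences differ in length is a parse error naming the record; a mismatch
negative set cannot be built from a single positive (no derangement
exists) and requires an explicit seed; a validation set with one class has
no defined AUROC and is rejected; signal normalisation with equal global
min and max is rejected; neighborhood windows running off a chromosome end
are dropped rather than erroring; empty score bins report missing folds.

## Limitations

The score is only defined where the two genomes align (scoring arbitrary
non-aligning pairs is supported only through the neighborhood operation,
and is expected to cost specificity). A low score conflates absence of
conserved activity with absence of evidence — sparse annotation in either
species drags scores down. And the ensemble's seeds, initialisation and
member subsets are recorded, so runs are reproducible on fixed hardware,
but bit-level reproducibility across BLAS implementations is not
guaranteed.
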
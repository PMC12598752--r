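---
title: "Methods: coelution-based interaction and complex inference in cfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coelution-based interaction and complex inference in cfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Co-fractionation mass spectrometry (CF-MS) separates native protein
assemblies across tens of chromatographic fractions and quantifies each
protein in each fraction. Proteins that belong to one complex co-elute, so
their intensity profiles are correlated. `cfnet` turns a CF-MS experiment,
the protein sequences, and a reference complex catalog into (i) per-pair
interaction scores, (ii) predicted protein complexes, and (iii) structural,
functional and spatial quality scores for those complexes. Every stage can
be exercised offline against a seeded synthetic generator, so the whole
pipeline is testable without any external download.

## Input representations

**Elution profiles.** Profiles are loaded from TSV/CSV, missing cells are
imputed to zero, all-zero rows dropped, and each surviving row is divided
by its sum so it integrates to 1 (tolerance 1e-9, which makes the contract
testable in floating point). Profiles are then zero-padded at the end to a
fixed 200 fractions so experiments with 27-61 fractions share one input
width. Normalization precedes padding by construction - the object refuses
the reverse order - because appended zeros must not dilute row sums.

**Sequences.** Each protein sequence is encoded as a frequency-matrix chaos
game representation (FCGR). The 20 canonical amino acids are placed, in
alphabetical order, at evenly spaced vertices of the unit circle starting
at angle 0 (counterclockwise); the trajectory starts at the origin and each
residue moves the point a fraction `scale = 0.863271` of the way to its
vertex. That scale keeps the 20 attractor basins from overlapping. Points
are binned on a 16 x 16 grid over [-1,1]^2 (half-open cells, last cell
closed), flattened row-major to length 256, and divided by the maximum bin
count so every vector lies in [0,1]. The vertex layout and start point are
package conventions, fixed and documented here because the chaos-game
literature admits several; all results in this package are internally
consistent under this convention. Non-canonical residues (X, U, B, Z, *)
have no vertex and are dropped before encoding; an all-non-canonical
sequence is an error naming the protein.

**Pair labels.** Pairs sharing a reference complex are positive; pairs
whose proteins are both catalog members but share no complex are negative;
everything else observed is "experimental" (scored, never trained on).
A positive is demoted to negative when it lacks any coeluting fraction:
the maximum over fractions of the product of the two normalized profiles
must exceed 0.01, evaluated on the un-padded region. The tie (exactly
0.01) demotes, because the rule requires the product to be strictly
greater. Proteins in several complexes are positive with all their
co-members; "different complexes" only applies when no complex is shared,
otherwise the positive and negative definitions would contradict each
other. Negatives are then down-sampled uniformly at random (seeded) to a
1:1 ratio with positives, and the balanced set is split into 5 stratified
cross-validation folds (or a single 70/30 split).

## The classifier

Each protein's input row is `[elution (200) | FCGR + embedding (256)]`,
456 values in [0,1]. The embedding matrix is a trainable parameter with
one row per protein, initialized uniformly in [-0.01, 0.01]: small, so the
measured signals dominate early training, while backpropagation gradually
writes complex-label context into the protein representations. It is
*added* to the FCGR block and the result *concatenated* to the elution
block, preserving the raw coelution signal.

The network applies a length-preserving 1-D convolution (F = 32 filters,
kernel width 5, stride 1, zero padding) along the 456-long axis of each
protein row, a ReLU, and then re-adds the raw input row to every filter
channel (a residual reinjection; placed after the nonlinearity, one of two
defensible orders). Because convolution operates per protein, its cost is
N convolutions for N proteins rather than one per pair - with M input
positions that is N x M work instead of 2 N(N-1) M for a pair-stacked
design, and the kernel parameter count (5 x 32 weights + 32 biases) is
half what the same filters would need on stacked pair rows.

For a pair (i, j) the head takes the elementwise *absolute* differences
|H_i - H_j| (456 x F) and |X_i - X_j| (456 x 1), concatenates them along
the channel axis (F + 1 channels), flattens, and applies three fully
connected layers (456*(F+1) -> 64 -> 16 -> 1) ending in a logistic unit.
The absolute difference is a deliberate choice: interaction labels are
symmetric, a signed difference is not, and the absolute value makes
score(i, j) = score(j, i) an exact identity rather than an approximation
(a signed-difference variant with both-order augmentation could be added
behind a flag, but symmetry by construction is easier to reason about and
test).

Training minimizes binary cross-entropy with Adam (learning rate 1e-3),
dropout 0.2 on the two hidden layers, and weight decay 1e-4 on weight
matrices, for 40 full-batch epochs per fit; all initialization, dropout
and shuffling derive from one seed, so two runs with the same seed agree
bit for bit. Scores <= 0.5 are called negative, > 0.5 positive. These
optimizer settings are package choices (recorded in `model_config()`),
selected once for stable convergence of the cross-entropy on the
synthetic study conditions; the architecture constants above are the
method's substance.

Cross-dataset co-training disables the embedding (its rows are tied to one
protein roster), pads all datasets to the common 200-fraction width,
down-samples every dataset's balanced pair list to the smallest one so each
contributes equally, and interleaves datasets round-robin within each
epoch.

## Complex detection

Scored pairs with score > 0.5 define a weighted adjacency; isolated nodes
are dropped. Two complementary smoothings are computed:

* **Markov clustering (MCL) flow**: self-loops added once, then exactly
  3 rounds of column normalization, squaring (expansion 2), elementwise
  squaring (inflation 2) and renormalization - a fixed-iteration transform
  rather than run-to-convergence, so the result is a smoothed flow matrix,
  not a hard partition.
* **Topological overlap (TOM)**: the adjacency is soft-thresholded by an
  elementwise 2.5th power (the elementwise reading keeps weights in [0,1];
  a matrix power would not), and each edge is augmented with shared
  neighbourhood: w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
  l the shared-neighbour sum and k the connectivity. The diagonal is set
  to 1, the conventional self-overlap, because rows subsequently feed
  cosine distances.

The two matrices are blended as 0.3*MCL + 0.7*TOM and 0.1*MCL + 0.9*TOM;
each blend's rows give pairwise cosine distances, Ward (ward.D2)
dendrograms, and an adaptive cut. The cut used here is the package's own:
among candidate partitions with 2..kmax clusters (kmax limited by the
`deep_split` level, 0-4, default 3; smaller levels cap resolution sooner
and suit small datasets), it keeps the partition maximizing the mean
silhouette width, then merges clusters below `min_cluster = 3` into their
nearest cluster by average distance. It is deterministic and needs no
tuning per dataset; it fills the role that dynamic dendrogram-cutting
algorithms play in weighted-network analysis, with the silhouette acting
as the branch-quality criterion.

The two clusterings are unioned (overlaps allowed). Clusters with 100 or
more members are recursively re-split on their importance submatrix (depth
capped at 10, then an error - an unsplittable 100-member blob indicates a
degenerate score matrix, which should be surfaced, not silently kept).
Finally, highly redundant clusters are merged iteratively: the pair with
the largest |X∩Y|^2 / (|X||Y|) strictly above 0.25 merges first (ties
broken lexicographically so the procedure is order-independent), until no
pair qualifies. A score of exactly 0.25 does not merge.

## Evaluation

* **Classification**: sensitivity, specificity, MCC (0 with a warning when
  a denominator factor vanishes) and AUC by the rank/Mann-Whitney
  formulation with midranks for ties.
* **Composite score** = overlap fraction + accuracy + MMR, in [0,3].
  Overlap fraction counts predicted clusters whose best overlap score
  exceeds 0.25 (strictly). Accuracy is sqrt(Sn x PPV) on member-overlap
  counts. MMR solves a maximum-weight one-to-one matching between
  reference complexes and clusters over overlap scores - an optimal
  assignment (Hungarian algorithm, written here because no assignment
  solver is among the package's dependencies), not a greedy one, divided
  by the number of reference complexes. An exhaustive-enumeration oracle
  guards the matching on all small instances in the test suite.
* **GOGO semantic similarity**: for a term t, its ancestor sub-DAG is
  collected over is_a/part_of edges; S-values decay upward by
  W_e = 1/(0.67 + nc(parent)) + d with d = 0.4 (is_a) or 0.3 (part_of),
  where nc counts the parent's children in the *full* ontology. Term
  similarity is the shared S-mass over the two semantic values; gene
  similarity is the best-match average over term sets; a cluster scores
  the mean over annotated gene pairs (unannotated genes are skipped
  pairwise and reported; fewer than two annotated genes gives NA). The
  published recursion line for S-values is self-referential as printed;
  this package implements the standard downward-max recursion that the
  rest of the equations require.
* **Colocalization**: the largest fraction of a cluster's annotated
  members sharing one compartment, over members with assignments only.
* **Representation separation**: cosine distances of protein feature
  representations within vs between complexes, compared by a
  Kruskal-Wallis rank test.
* **Size-matched bootstrap null**: given per-cluster scores and a pool of
  background scores per cluster size, each of n_boot (default 100,000)
  replicates draws one size-matched background score per observed cluster
  and records the replicate mean; a one-sample t-test compares the
  observed scores with the null mean. When observed scores are themselves
  drawn from the pool, the test rejects at about the nominal rate, which
  the test suite verifies over 500 seeded repeats.

## Saliency

The saliency of a pair is the absolute gradient of its predicted score
with respect to the two assembled input rows, averaged over the two
proteins (the per-pair reduction is unstated in the saliency literature
for pair models; the mean is the symmetric choice). Padded elution
positions are excluded from any intensity mean - they are constant zeros.
Each map is scaled by its maximum before the CF-MS-versus-sequence
comparison so the ±0.1 categorization margin acts on a common [0,1]
intensity scale; the margin is meaningless on raw gradient magnitudes,
whose scale depends on the trained weights. The difference of mean
intensities classifies each pair as CF-MS-dominant (> 0.1),
sequence-dominant (< -0.1) or balanced (boundaries included). Category
aggregates are elementwise sums min-max normalized to [0,1]; a constant
sum yields zeros with a warning.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure the pipeline
assumes: each planted complex draws a Gaussian elution apex and members
jitter around it (sd `apex_jitter`), so members co-elute; background
proteins get independent apexes. Peaks are Gaussian densities at integer
fractions with random amplitude - the simplest model that reproduces
coelution. Additive Gaussian noise is scaled to each profile's peak
height, negatives clip to zero, and cells go missing independently.
Sequences are uniform over the 20 canonical residues; members of a complex
share a fixed 8-mer motif with probability `motif_share`, giving the
sequence encoder a learnable signal. One GO leaf term per complex is
annotated to all members (plus random noise terms so annotations are not
perfectly clean), and one compartment per complex, so the GOGO and
colocalization scores can discriminate planted structure.

Defaults - 200 proteins, 40 fractions, 20 complexes of 3-8 members, peak
sd 2 fractions, jitter 0.5, 5% relative noise, 5% missingness, sequences
of 80-200 residues, motif share 0.8 - were fixed once as plausible
mid-range values for the experiment sizes above and are not revisited per
analysis. What the generator does *not* emulate: instrument noise
structure (spray instability, saturation), shared peptides and protein
inference ambiguity, correlated missingness, complexes with overlapping
membership, or realistic sequence composition. Tests passing on this
generator therefore demonstrate that the machinery recovers planted
coelution structure under its own assumptions; they do not certify
performance on real CF-MS data, where labels are incomplete and noise is
structured.

## Numerical and scale choices

The test suite and the acceptance script run the recovery experiment at
200 proteins / 20 complexes with 5-fold cross-validation and default
model settings, score all pairs in chunks of 1024, and compare the
composite score against 1,000 size-matched random clusterings; these
problem sizes keep a full run in the minutes range on one CPU while
leaving all planted structure intact. The fixture used by unit tests is
smaller (60 proteins, 8 complexes, 8 filters) for speed. Degenerate
inputs are errors, not silent repairs: empty graphs after score flooring,
all-zero representation rows, cosine of zero vectors, single-class AUC,
missing bootstrap pool sizes, and oversized unsplittable clusters all
raise with messages naming the offender.
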
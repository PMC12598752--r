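# cfnet

Protein–protein interaction and protein-complex inference from
co-fractionation mass spectrometry (CF-MS) combined with protein-sequence
representations.

CF-MS separates native protein assemblies across chromatographic
fractions; proteins in one complex co-elute, leaving correlated intensity
profiles. `cfnet` is for proteomics researchers who have such elution
matrices and want to go from raw profiles to a scored interactome and a
set of predicted complexes with quality metrics — including everything
needed to validate the machinery offline on seeded synthetic data.

## What it computes

**Inputs per protein.** The elution profile (missing values imputed to
zero, all-zero rows dropped, rows normalized to sum 1, zero-padded to 200
fractions) concatenated with a chaos-game encoding of the protein sequence
(FCGR, resolution 16, scale 0.863271, flattened to length 256 and scaled
to [0,1]) plus a trainable protein embedding added to the FCGR block.

**Classifier.** A convolutional network scores each protein pair:
a length-preserving 1-D convolution with F = 32 filters over each
protein's 456-long input row, ReLU, residual reinjection of the raw input
into every channel, then for a pair (i, j) the absolute differences
|H_i − H_j| and |X_i − X_j| are concatenated channel-wise, flattened, and
passed through three fully connected layers to a logistic score in (0,1).
Convolution cost is one pass per *protein*, not per pair — N·M rather than
2 N(N−1)·M operations for N proteins and M input positions. Labels come
from a reference complex catalog (pairs in a shared complex are positive,
pairs spanning complexes negative, positives without a coeluting fraction
— max per-fraction profile product ≤ 0.01 — demoted), balanced 1:1 and
evaluated by 5-fold cross-validation at a hard 0.5 threshold.

**Complex detection.** Scores > 0.5 define a weighted graph; Markov
clustering (expansion 2, inflation 2, 3 iterations) and a topological
overlap matrix on the elementwise 2.5th power,
w_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij), are blended (0.3/0.7 and
0.1/0.9), clustered by cosine distance + Ward + an adaptive
silhouette-guided dendrogram cut, capped below 100 members, and merged
when |X∩Y|²/(|X||Y|) > 0.25.

**Evaluation.** Composite score = overlap fraction + √(Sn·PPV) + maximum
matching ratio (optimal one-to-one matching) against a reference catalog;
GOGO semantic similarity over a typed GO DAG
(W_e = 1/(0.67 + nc) + d, d = 0.4 is_a / 0.3 part_of); colocalization
(largest same-compartment fraction); gradient saliency maps per pair with
CF-MS-versus-sequence categorization at a ±0.1 margin; and a size-matched
bootstrap null with a one-sample t-test.

## Worked example

Everything below runs offline on the seeded synthetic generator, which
plants complexes as shared Gaussian elution peaks plus shared sequence
motifs, GO terms and compartments:

```r
library(cfnet)

ds     <- simulate_dataset(sim_config(n_proteins = 200, n_complexes = 20,
                                      noise_sd = 0, missing_rate = 0,
                                      seed = 1))
E      <- pad_profiles(preprocess_elution(ds$elution))
S      <- fcgr_encode_all(ds$sequences[E$protein_ids])
labels <- make_folds(derive_pair_labels(ds$catalog, E), k = 5, seed = 1)
model  <- train_model(E, S, labels, model_config(seed = 1))
colMeans(model$cv_metrics[, c("sensitivity", "specificity", "mcc", "auc")])
#> sensitivity specificity         mcc         auc
#>   0.9407407   0.9000000   0.8442466   0.9744170

edges    <- score_edge_list(model, labels)
clusters <- cluster_complexes(edges)
unlist(composite_score(clusters, ds$catalog))
#> overlap_frac        sn          ppv     accuracy        mmr    composite
#>    0.7142857    0.8611111    0.6944444   0.7733006  0.3143856    1.8019719
```

The cross-validated metrics say the classifier separates held-out
positive from negative pairs almost perfectly on noiseless data; the
composite score (range 0–3) says the clustering stack recovers a large
share of the planted complexes — 71% of predicted clusters overlap a
planted complex beyond the 0.25 overlap-score cutoff — while background
proteins dilute cluster purity, which is the expected behaviour on data
where half the proteins belong to no complex. The same run on 1,000
size-matched random clusterings gives composite scores far below 1.8
(empirical p ≈ 0.001).

One-shot pipeline with all artifacts (edge list, cluster GMT, metric JSON,
reproducible YAML manifest):

```r
run_pipeline(run_config(seed = 1), outdir = "cfnet_out")
```

or from a shell: `Rscript inst/cli/cfnet-cli.R all --seed 1 --outdir cfnet_out`.

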
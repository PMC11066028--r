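# featscope

Self-supervised protein feature profiles from single-cell fluorescence
micrographs, in R.

## The problem

Proteome-scale imaging screens tag thousands of proteins and photograph
them in single cells. The hard part is turning micrograph crops into
quantitative descriptions of protein behavior without hand-annotating
millions of cells. `featscope` implements a self-supervised route: a
convolutional network is trained on the *pretext task* of predicting
**which protein** a 64×64 single-cell crop shows, with the cross-entropy
objective

L(ŷ, y) = −Σᵢ yᵢ log ŷᵢ

over the N protein identities. To succeed, the network must learn the
localization patterns that distinguish proteins — no human labels
required. The activations of the second fully-connected layer are the
**single-cell feature profiles (scFPs)**; their per-protein means are
**averaged feature profiles (aFPs)**.

On top of the profiles the package implements the downstream analytics:

* **Benchmarks** — ranked co-annotation pairs (average precision, max
  F-score) and clustering agreement (adjusted mutual information) against
  annotation standards.
* **Hierarchy** — whole-panel aFP dendrogram (correlation distance,
  average linkage) cut by an AMI-derivative diminishing-returns rule;
  silhouette-guided sub-compartment clustering; t-SNE embedding with
  per-label KDE annotation.
* **Localization mapping** — the linear evaluation protocol (a logistic
  probe on frozen scFPs), feature-importance tables,
  accuracy-vs-feature-count curves, and SmoothGrad gradient maps
  ∂fᵢ/∂x for feature interpretation.
* **Heterogeneity** — single / AND / OR localization calls per protein
  from per-crop probe probabilities (α_conf = 0.5, β = 0.5, OR threshold
  0.08), plus a cell-cycle CNN ensemble and Mann–Whitney association of
  localization changes with cell-cycle stage (p < 1e-3).
* **Complex discovery** — adaptive dendrogram thresholding over scFPs:
  composition-plateau root clusters scored by s = c·d/k (cell ratio ×
  descendant ratio / elbow distance), cutoff 0.6, benchmarked against
  k-means / DBSCAN / flat hierarchical grids by pairwise and per-cluster
  F1.
* **Simulation** — a synthetic micrograph generator with planted ground
  truth (archetypes, complexes, AND/OR heterogeneity, cell-cycle
  morphology) that makes the whole workflow testable end to end.

The CNN engine (convolution, batch-norm, pooling, Adam, backprop to the
input pixels) is implemented in the package on top of BLAS matrix
products and is verified against finite differences in the test suite.

## Worked example

The demonstration configuration simulates a 12-protein panel over four
localization archetypes (nucleus, cytoplasm, punctate, peripheral ring)
with two planted 3-member complexes and 2 AND + 2 OR proteins, ~100
cells per protein, and trains a reduced network (2 conv blocks, 16-d
feature layer) on one CPU:

```r
library(featscope)
res <- runPipeline(defaultPipelineConfig(seed = 1), verbose = TRUE)

res$train$test_accuracy      # 0.487  (chance = 1/12 = 0.083)
res$benchmark$AP             # 1.0    co-annotation average precision
res$benchmark$max_F1         # 1.0
res$hierarchy$threshold      # 0.21   AMI-derivative cutoff
res$hierarchy$archetype_AMI  # 1.0    planted archetypes recovered
res$complexes$pairwise_F1    # 0.81   planted complexes vs scFP clusters
res$heterogeneity$agreement  # 0.75   verdicts vs planted AND/OR types
```

Test accuracy 0.49 is ~5.8× chance: the network distinguishes most
proteins by their individual archetype parameterization, while members
of a planted complex (identical parameters, by construction) remain
confusable — exactly the behavior the feature profiles are meant to
have. Cutting the aFP dendrogram with the AMI-derivative rule lands at
distance 0.21, where the flat clusters reproduce the four planted
archetypes (AMI 1.0 on the singly-localizing subset), and adaptive
thresholding of the scFP dendrogram recovers both planted complexes
(pairwise F1 0.81 against the planted standard). Heterogeneity calling
is the most seed-sensitive stage at this scale: 9 of 12 verdicts match
here, with AND-localizing proteins the usual misses (the methods
vignette discusses why the probe's probability calibration makes the
AND rule fragile on small synthetic panels).

Artifacts (scFP/aFP matrices, cluster tables, heterogeneity calls) are
written as headered CSV/TSV when `outDir` is given; the objects
themselves (a `CropSet`, `FeatureProfileSet`s, the `FeatNet`, root
clusters) are returned in the result list.

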
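---
title: "Self-supervised protein feature profiles: models and methods"
author: "featscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised protein feature profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

High-throughput fluorescence microscopy can image a tagged protein in
thousands of single cells, but turning micrographs into quantitative,
comparable descriptions of protein behavior is hard: cells vary in shape
and position, intensities drift between images, and manual annotation
does not scale. `featscope` implements a self-supervised route around
annotation. A convolutional network is trained on a *pretext task* that
needs no labels beyond what the screen itself provides: **predict which
protein a single-cell crop shows**. With the cross-entropy objective

$$L(\hat y, y) = -\sum_{i=1}^{N} y_i \log \hat y_i$$

over the $N$ protein identities, the network can only succeed by
learning the localization patterns and morphological signatures that
distinguish proteins — exactly the information a biologist wants, and it
emerges without a single human label.

Two representations fall out of the trained network:

* **scFP** (single-cell feature profile): the activation vector of the
  second fully-connected layer for one crop (64-dimensional under the
  full architecture).
* **aFP** (averaged feature profile): the component-wise mean of a
  protein's scFPs — a per-protein summary of its spatial distribution.

Everything downstream — benchmark scoring, hierarchy cutting,
localization mapping, heterogeneity calling, complex discovery, gradient
interpretation — operates on these vectors.

## Architecture and training

The full architecture is eight convolutional blocks (3×3 convolution,
batch normalization, ReLU; 2×2 max-pooling after every second block,
channel width doubling every second block) followed by three
fully-connected layers; the second FC layer is the 64-dimensional
feature layer, with 5% dropout after it. Weights are initialized from a
truncated normal distribution (sd 0.1). Training uses Adam at learning
rate 1e-3 with a cosine-decay schedule, batches of 128, and dihedral
augmentation (random horizontal/vertical flips, rotations by 0/90/180/
270 degrees). Crops are instance-normalized: each channel of each crop
standardized to mean 0, variance 1, which removes absolute intensity
scale and forces the network onto spatial pattern.

Model selection uses an accuracy-saturation rule: training stops being
useful at the first epoch where the per-epoch increment of the test
accuracy stayed below 0.5 percentage points for 3 consecutive epochs
(`earlyStopEpoch()`). The point of stopping *there* rather than at
maximum accuracy is deliberate: trained further, the network starts
telling apart proteins that are genuinely morphologically
indistinguishable (e.g. members of one complex) by memorizing noise,
which corrupts every downstream analysis that relies on related proteins
staying close in feature space. We observed exactly this failure mode at
small scale: over-trained feature spaces collapse each protein into its
own tight island, and mixed-localization crops stop looking mixed.

The network engine itself is a compact, fully-tested CNN implementation
in R (im2col convolution over BLAS matrix products, batch-norm with
train/eval semantics, max-pool, dense layers, Adam, and backpropagation
all the way to the input pixels, which the gradient-map interpreter
needs). Gradient correctness is verified against finite differences in
the test suite.

## Working scale

The package's demonstration configuration (`defaultPipelineConfig()`)
is sized for a single CPU: 12 proteins over 4 archetypes with 2 planted
complexes of 3 and 2 AND + 2 OR proteins, ~100 cells per protein imaged
as 2 replicates × 4 fields, and a reduced network (2 conv blocks,
16-dimensional feature layer, 15-epoch cosine horizon). This trains in
a few minutes and reaches protein-identity accuracy several times above
chance; all package-level claims are made at this scale. Nothing in the
code is specific to it — `networkConfig()` exposes the full-size
architecture as defaults.

# The synthetic micrograph generator

Real proteome-scale image collections cannot ship with a package, so
every stage is exercised on synthetic micrographs with known ground
truth (`proteinPanel()`, `renderField()`, `generateDataset()`). The
generator emulates the *structure* of a screen, not its optics:

* **Cells** are circles with radius jitter (9–12 px) plus an optional
  bud whose relative size encodes cell-cycle stage (none in G1, 0.35 in
  S, 0.6 in MA, 0.85 in T), with the nucleus elongating toward the bud
  in MA/T. Stages are sampled at 40/25/20/15%.
* **Channels**: tagged protein (GFP), nuclear marker (one blob per
  cell), cytosolic marker (soft-edged cell body). Additive Gaussian
  noise (default sd 0.02 on a [0,1] intensity scale) on all channels.
* **Archetypes** are parametric templates in cell-local coordinates:
  nucleus, cytoplasm, nucleolus, punctate, peripheral ring, nuclear
  periphery ring, ER-like mesh, mitochondrial-like network. Each
  protein draws its own parameters (e.g. blob width, puncta count and
  radius, ring thickness); the ranges are deliberately wide so that two
  independent draws differ by more than replicate noise — distinct
  proteins must be individually recognizable or the pretext task is
  vacuous.
* **Complexes**: members share the entire parameterization including
  abundance, making their crops statistically exchangeable — the
  morphological signature of a stoichiometric complex, and the planted
  target for complex discovery.
* **Heterogeneity**: AND proteins render both archetypes in every cell.
  The mixing fraction is a *molecule* fraction — each compartment's
  template is normalized to unit integrated intensity before weighting,
  so a 50/50 split puts equal total signal into both compartments
  regardless of their areas — and the per-cell split is drawn from a
  Beta distribution around the protein's mixing fraction (default mean
  0.5), because dual-localizing proteins distribute continuously across
  cells; a fixed split would collapse an AND protein's crops into one
  featureless island. OR proteins render one archetype per cell
  (secondary with probability 0.3). Cell-cycle-dependent proteins
  switch archetype by stage (nuclear outside MA, secondary archetype in
  MA).

What the generator does **not** emulate: point-spread-function optics,
3-D structure, illumination gradients, cell crowding and debris,
photobleaching, or the long-tailed abundance distribution of a real
proteome. Passing tests on synthetic data therefore demonstrate that the
algorithms recover planted structure under controlled conditions; they
do not certify performance on any real screen.

The demonstration panel uses the four archetypes nucleus, cytoplasm,
punctate and peripheral ring. These are deliberately well separated;
nucleolus-versus-nucleus, for instance, is a genuinely hard
discrimination (one is a sub-compartment of the other) and belongs to
robustness experiments, not to a recovery demonstration whose
assumptions include separable compartments.

# Crop preparation

`prepareCrops()` implements the screen-preprocessing recipe: watershed
segmentation of the nuclear channel (Otsu threshold → distance transform
→ watershed, via EBImage) yields cell centers; centers closer than 10 px
to the border are discarded; 64×64 crops are cut around the rest using
0-based half-open windows $[c-32, c+32)$ so the center sits at the crop
midpoint. Two quality filters follow: crops whose total GFP intensity
falls below the dataset-wide 5th percentile are dropped (ties at the
boundary are kept), as are crops whose GFP variance falls below a
configurable floor (background-dominated, uniform signal; the floor
defaults to 1e-4 in normalized intensity units — the direction
"low variance = background" is an interpretation, exposed in config).
Proteins left with fewer than 10 crops are removed entirely. The
surviving crops are split 8:1:1 into train/validation/test per protein,
with a protein-id-salted seed so the split is independent of dataset
ordering.

# Benchmarks against annotation standards

`coannotationPairs()` ranks all pairs of annotated proteins by
correlation distance (1 − Pearson) between aFPs; pairs are positive if
their label sets agree under the standard's rule — exact equality for
pathway/complex-style standards, or at-least-half overlap for GO-style
standards with many labels (operationalized as
$|A \cap B| \ge 0.5\,\min(|A|,|B|)$, with a Jaccard variant in config).
`averagePrecision()` and `maxFScore()` score the ranking; since the
operating point of the F-score is not fixed by convention, the maximum
F1 over all ranking cuts is reported by default. `amiOverThresholds()`
scores clustering quality: hierarchical clustering (average linkage,
correlation distance) cut at thresholds 0.1–0.95 (step 0.05), clusters
of size < 2 dropped, adjusted mutual information against the labels of
singly-annotated proteins, maximum over thresholds reported.

AMI uses the permutation-model expectation (computed exactly from the
hypergeometric distribution) and max-entropy normalization:
$\mathrm{AMI} = (\mathrm{MI} - E[\mathrm{MI}]) / (\max(H_a, H_b) -
E[\mathrm{MI}])$. The test suite checks this implementation against an
exhaustive enumeration of all $n!$ permutations at small $n$.

# Cutting the hierarchy: the AMI-derivative rule

`selectCutoff()` picks a biologically meaningful flat clustering from
the aFP dendrogram. The AMI between flat clusters and standard labels is
evaluated on a fine grid of correlation-distance thresholds (step 0.01).
The scan starts at correlation 1 — i.e. at distance 0, the fine end —
and coarsens; the chosen cutoff is the first threshold at which the AMI
gain over the trailing 20-step window falls below 0.1. This is a
diminishing-returns elbow: at the cutoff, further coarsening no longer
improves agreement because the clusters already cover the standard's
groups. Two numerical details: thresholds below the first merge height
are skipped (the all-singleton clustering makes the curve trivially
flat there), and if the rule never fires the maximum-AMI threshold is
returned with a warning.

`subcompartmentClusters()` surveys per-localization trees over
thresholds 0.25–0.75 (step 0.05) and picks the threshold maximizing the
median silhouette $(b-a)/\max(a,b)$ across localizations.
`embedAnnotate()` provides the 2-D view: exact t-SNE (O(n²), adequate at
package scales; perplexity ~40 for per-protein profiles, ~200 for large
single-cell sets) with per-label Gaussian KDE annotation (Scott's rule
bandwidth) after removing points more than two standard deviations from
their label's mean along either axis.

# Localization mapping and feature interpretation

`trainLocalizationHead()` is the linear evaluation protocol: a
multinomial logistic regression trained with Adam (lr 1e-3,
cross-entropy) on *frozen* scFPs of singly-localizing proteins, with the
epoch of maximal validation accuracy selected (ties resolved toward the
later epoch). At proteome scale, five probe epochs correspond to tens of
thousands of optimizer steps at proteome scale; at package scale an
epoch is a few hundred samples, so the pipeline uses batch 32 and 20
epochs to give the probe a comparable optimization budget. This matters
beyond accuracy: the probe's *probabilities* drive the heterogeneity
rules below, and both an underfit probe (probabilities near class
priors) and an overconfident one (saturated probabilities on genuinely
mixed crops) corrupt the calls.

`featureImportance()` maps each feature to the localization of its
maximal coefficient (ties to the lowest class index) and flags
coefficients above 5 as strongly predictive;
`accuracyVsFeatureCount()` retrains the probe on top-N features (5
repeats, SD reported), with N = 0 the bias-only chance model.

`smoothGradMap()` interprets single features: the gradient of feature
$f_i$ with respect to the input image, averaged over $n = 100$ noisy
copies of the crop ($\sigma = 0.05$ in normalized-intensity units):
$$\hat M_i(x) = \frac{1}{n}\sum M_i(x + \mathcal N(0, \sigma^2)),\qquad
M_i(x) = \partial f_i(x) / \partial x.$$
With $\sigma = 0, n = 1$ this is the plain input gradient, checked
against finite differences in the tests.

# Localization heterogeneity (single / AND / OR)

For each protein, the two most frequent localizations (by mean probe
probability across its crops) define per-crop probability pairs
$[p_{i1}, p_{i2}]$. The rule cascade (`classifyHeterogeneity()`, with
the default constants $\alpha_{conf} = 0.5$, $\beta = 0.5$, OR
threshold 0.08):

1. crops with $p_{i1} + p_{i2} < \alpha_{conf}$ are low-confidence;
2. remaining crops are class 1 if $p_{i1} > p_{i2} + \beta$, class 2
   symmetrically, mixed otherwise;
3. with category fractions $c_1, c_2, m, k_{lc}$ (summing to 1): the
   protein is *undetermined* if $k_{lc}$ exceeds 0.5 (the "too many
   low-confidence cells" guard, set here to half), *AND*-localizing if $m > c_1 + c_2$, else
   *OR*-localizing if $\min(1, c_2) > 0.08$, else single. The literal
   $\min(1, c_2)$ equals $c_2$ for fractions; a $\min(c_1, c_2)$
   variant is config-exposed.

Cell-cycle association: an ensemble of three CNNs (four conv blocks,
two FC layers) on the nuclear + cytosolic channels predicts stages
G1/S/MA/T, with affine augmentation (arbitrary rotation, flips, zoom
within 0.02, shifts up to 9 px) and stratified 3-fold cross-validation;
ensemble probabilities are member means, and T and G1 are merged for
reporting. For a heterogeneous protein, each merged stage's per-crop
probability is compared between the crops assigned to the two
localizations with a two-sided Mann–Whitney U test; links at
p < 1e-3 are reported. The test uses the continuous stage
probabilities rather than hard labels, since the U statistic needs
ordinal data and the classifier supplies full probability vectors.

# Complex discovery by adaptive thresholding

`traceDendrogram()` cuts the scFP dendrogram top-to-bottom on a 0.05
grid of correlation-distance thresholds. `findRootClusters()` finds
*composition plateaus*: clusters at least 95% of whose scFP membership
persists into the largest child across consecutive thresholds
("morphologically inseparable" clusters). Composition is measured on
cells (cell-weighted protein composition) rather than protein sets: at
small panel sizes the protein set of a sizeable cluster almost never
changes between two thresholds, which would make the protein-set
reading vacuous. Plateau candidates are nested along branches;
`resolveRootClusters()` scores all of them and keeps a disjoint set
greedily by score, so the score itself — not the scan order — decides
the cut. (A coarsest-first scan fails at small scale: the sparse top of
a small tree contains "merge deserts" in which any supercluster is
trivially stable.)

Each root is scored (`scoreRootCluster()`) by
$$s = \frac{c \cdot d}{k}$$
with **c** the mean over member proteins of the fraction of their cells
captured by the cluster (cell ratio: higher = less dispersed), **k** the
correlation distance at the cut (elbow point: lower = tighter), and
**d** the descendant ratio. Descendants are the flat clusters at finer
thresholds that contain any cell of the root's proteins; a descendant
*agrees* when at least half of its cells lie inside the root **and**
its protein composition still matches the root's (protein-set Jaccard
above 0.5). `d` is the cell-weighted fraction of agreeing descendants,
surveyed over the whole remaining trace by default (depth is
config-exposed). This definition makes `d` a *separability* probe: a genuine complex
fragments into sub-clusters that keep mixing its members all the way
down (cells are exchangeable), whereas a cluster of merely similar
proteins resolves into pure per-protein fragments, and a supercluster
splits into large divergent halves — both of which lower `d`.

Clusters with $s \ge 0.6$ are reported as high-confidence.
`pairwiseComplexF1()` benchmarks a clustering against a complex
standard over all scFP pairs (positive = same complex, predicted = same
cluster); `foldEnrichment()` reports the best one-sided Fisher
enrichment against a same-localization background.
`baselineGrid()` compares against k-means (k = 5–500, step 5), DBSCAN
(ε = 0.1–5, step 0.1; implemented in-package, O(n²) at these scales)
and flat hierarchical clustering (threshold 0.05–0.5, step 0.025), each
reporting its best hyperparameter by the median per-cluster F1 (each
cluster scored by set-overlap F1 against its best-matching complex).

# Analysis inputs at small scale

A strict held-out protocol would extract scFPs from the test split only;
with ~100 cells per protein that is ~10 scFPs per protein, and
per-protein averages of 10 noisy vectors are too unstable for tree
geometry (complex members stray from their complex). The pipeline
therefore keeps the ranked-pair/AMI benchmarks on the test split
(held-out hygiene where the metric is the point) but feeds the
hierarchy, heterogeneity and complex-discovery stages with scFPs from
all crops — extraction is a deterministic evaluation-mode forward pass,
so no label leakage is involved.

# Known limitations

* Synthetic micrographs are structural caricatures; see the generator
  section for what they omit.
* The AMI-derivative cutoff assumes a reasonably smooth AMI curve; at
  very small panel sizes the curve is steppy and the 20-step window can
  straddle a merge gap. The max-AMI fallback (with warning) covers the
  degenerate case.
* AND-localizing proteins whose two compartments coincide with other
  proteins' archetypes genuinely bridge those groups in feature space;
  adaptive thresholding then reports the bridged group as a
  high-confidence morphology cluster. Against a complex-only standard
  this counts as a false positive, which bounds the achievable pairwise
  F1 on panels that plant heterogeneity and complexes together.
* The exact t-SNE is O(n²): fine for ~10⁴ profiles, not for full
  proteome-scale single-cell sets.
* Training the identity network too long collapses feature space onto
  protein identity (see the early-stopping discussion); all downstream
  results depend on stopping in the morphological regime.
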
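---
title: "Hybrid RBF network clustering: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid RBF network clustering: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfclust)
```

## The problem and the model

`rbfclust` groups nucleotide sequences by composition, without alignment.
A sequence of length $L$ is summarized by its vector of overlapping
$k$-mer counts ($k = 5$ by default, so at most $4^5 = 1024$ features);
windows containing any non-ACGT letter are skipped. Counts are Z-scored
per feature,

$$Z_{ij} = \frac{M_{ij} - \mu_j}{\sigma_j},$$

with the population (divide-by-$n$) standard deviation, and zero-variance
features are dropped. Standardization matters: without it a handful of
very abundant k-mers (common repeats) dominate the Euclidean metric that
the kernel is built on.

Clustering operates on the Gaussian RBF affinity matrix

$$W_{ij} = \exp\!\left(-\frac{d(x_i, x_j)^2}{2\sigma^2}\right),
\qquad
\rho_i = \frac{1}{n-1}\sum_{j \ne i} W_{ij},$$

in two phases:

1. **Subcluster detection.** Points with normalized density
   $\rho_i < P_1 - P_3$ are provisionally *isolated* (set $S$). Remaining
   points are visited in decreasing density order (ties to the lower
   index); each still-unvisited point seeds a subcluster containing every
   unvisited, non-isolated point with affinity $\ge \tau_{\text{link}}$
   to it. A seed with no qualifying neighbor is a singleton subcluster.
2. **Merging and final assignment.** The connectivity of two subclusters
   is the mean affinity over all cross pairs; pairs at or above
   $\tau_{\text{merge}}$ are linked, and final clusters are the connected
   components of the link graph — a single pass that is order-independent
   and transitively closed. Each isolated point is then assigned to the
   cluster with the largest mean affinity to it (equivalently, the
   shortest kernel-influenced distance), ties to the lowest label.

The whole pipeline is a pure function of the feature matrix and the
parameters; there is no randomness and repeated runs are byte-identical.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `k` | 5 | bases | k-mer length; fixed, no auto-selection |
| `p1` | 0.15 | normalized density, (0,1] | density threshold |
| `p2` | 1.0 | unitless multiplier | kernel spread; `sigma = p2 x` mean 5-NN distance |
| `p3` | 0.05 | normalized density, >= 0 | resolution modifier; isolation cutoff is `p1 - p3` |
| `n_sigma_neighbors` | 5 | count | neighbors in the sigma initialization |
| `tau_link` | `exp(-1/2)` = 0.6065 | affinity, (0,1) | subcluster membership: points within one sigma of the seed |
| `tau_merge` | 0.2 | affinity, (0,1) | minimum mean cross-affinity to merge |
| `min_length` | 1000 | bases | QC floor on sequence length |

Three of these are stated operating values of the method
(`p1 = 0.15`, `p2 = 1.0`, `p3 = 0.05`); the rest are this package's
operationalization of quantities the method description leaves open, fixed
once and documented below.

## Design choices where the design was open

* **Density normalization.** A raw density $\sum_j W_{ij}$ grows linearly
  with $n$, which would make a fixed isolation cutoff of $0.10$
  meaningless across dataset sizes. We therefore exclude the structural
  self-weight ($W_{ii}=1$) and divide by $n-1$, giving
  $\rho_i \in [0,1]$; the cutoff `p1 - p3` applies to this normalized
  density and is size-invariant.
* **Sigma–P2 coupling.** The spread is initialized from the data as the
  grand mean of each point's mean distance to its 5 nearest neighbors;
  `p2` multiplies it, so `p2 = 1` reproduces the
  average-5-nearest-neighbor initialization and `p2` is unitless.
* **"Important neighbors".** Membership in a seed's subcluster requires
  $W_{ij} \ge \exp(-1/2)$, i.e. lying within one sigma of the seed — a
  natural kernel-scale definition of the influence range. It is
  configurable (`tau_link`).
* **Seed order.** Seeds are taken in decreasing density (ties to the
  lower index): deterministic, and dense cores claim their neighborhoods
  first.
* **Merge statistic.** Mean cross-pair affinity (robust to subcluster
  size imbalance) with threshold `tau_merge = 0.2`; a maximum
  (single-linkage) variant is available via `merge_stat = "max"`.
  "Single-phase" merging is realized as connected components, which is
  order-independent.
* **Number of clusters.** $K$ is emergent — there is no $K$ input. With
  the defaults on well-separated planted families, $K$ equals the planted
  number.
* **"Bi-subcluster".** Treated as a synonym of subcluster; subclusters
  may have any size (a pairs-only reading is not supported).
* **t-test flavor.** The printed unpooled statistic is implemented as
  Welch's t with Satterthwaite degrees of freedom.
* **NMI normalization.** Arithmetic mean of the entropies (natural logs);
  the geometric variant is a flag. Two constant labelings are identical
  partitions (NMI 1); if exactly one entropy is zero, NMI is 0.
* **Silhouette singletons** score 0, the common convention; when
  $\max(a,b) = 0$ (coincident clusters) the score is 0 as well.
* **DB dispersion** uses the *mean* (not RMS) distance to the centroid,
  matching the printed definition.
* **Chi-square.** The package exposes a generic Pearson independence
  test; what contingency table to test is the caller's modeling decision.
* **Quality control.** "Incomplete" sequences are operationalized as
  more than 50% `N` content; deduplication keys on (gene symbol,
  accession) and keeps the first occurrence.

## Cross-validating an unsupervised method

The stability protocol shuffles indices with a seed, splits them into
`n_folds` (default 5) folds, clusters each complementary 80% subset, and
reports per-fold internal metrics (mean and sd across folds) plus the
mean pairwise NMI between fold partitions restricted to the points two
training subsets share. On cleanly separated data the pairwise NMI is
1.0. Note that the Calinski–Harabasz index scales with the sample count,
so its across-fold sd is small but not zero even for perfectly stable
partitions; silhouette and DB are size-free. A fold whose training subset
yields fewer than 2 clusters records missing metrics with a warning.

`compare_algorithms()` runs several algorithms on identical folds, Welch
tests the reference against each baseline per metric, runs a one-way
ANOVA per metric, and jointly Holm-adjusts all pairwise t p-values.
Baselines are thin adapters (`baseline_kmeans()`, `baseline_hclust()`,
`baseline_random()`); their internals are not part of the method.

## What the synthetic generator does and does not emulate

`generate_planted_sequences()` draws one uniform-random ACGT ancestor per
cluster (ancestor pairs closer than `between_divergence` normalized
Hamming distance are redrawn; random pairs sit at 0.75 expected, so
values above 0.75 error), copies it `per_cluster` times with i.i.d.
per-base substitution at `within_mut_rate` (to a uniformly random other
base), and appends uniform-random outliers labeled 0. Defaults (3
clusters x 20 sequences of 2000 bp, 1% within-family substitution, 3
outliers) emulate the target regime: a few hundred genes of at least
1000 bp with family structure, at a size that keeps the test suite fast.

The model is substitution-only — no indels, no codon structure, no GC
heterogeneity, no shared domains between families. Real gene families are
far messier: a green recovery test establishes that the algorithm and its
plumbing are correct on separable compositional structure, not that any
particular biological dataset will separate this cleanly. Outliers carry
truth label 0 so isolation detection has a ground truth; because the
final partition must absorb them, recovery NMI is scored on the planted
members, and outlier handling is scored on the isolated set $S$ before
final assignment.

## Numerical notes

* Affinities are symmetrized as `(W + t(W))/2` to erase floating-point
  asymmetry from the distance computation; the diagonal is set to exactly 1.
* Standardization requires $n \ge 2$ and drops exact-zero-variance
  columns; `kept_columns` records the surviving feature indices.
* Degenerate inputs fail loudly: all-coincident points (sigma would be
  0), non-finite features, a merge phase with zero subclusters followed
  by isolated-point assignment ("no clusters to absorb isolated points"),
  silhouette with one cluster, DB with coincident centroids, Welch t with
  two zero-variance samples.
* `p1 - p3 <= 0` is allowed and simply disables isolation (with a
  warning); `tau_merge > tau_link` is allowed but warned about.

## Known limitations

* Dense $n \times n$ affinity and $O(n^2 m)$ distance computation: fine
  for hundreds to a few thousand sequences, not for genome-scale corpora.
* No reverse-complement canonicalization of k-mers; strand-flipped
  duplicates of the same gene would look dissimilar.
* $K$ cannot be forced; if a target cluster count is needed it must be
  reached through the thresholds.
* The chi-square entry point tests whatever table the caller constructs;
  the package does not prescribe one.
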
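# rbfclust

Alignment-free clustering of nucleotide sequences with a hybrid radial
basis function (RBF) network, for researchers who want to group genes by
sequence composition — e.g. disease gene panels where families of
functionally related genes (tumor suppressors, mismatch-repair genes,
inflammasome components) share compositional signatures — without building
alignments or trees.

## The method

Each sequence is encoded as its profile of overlapping k-mer counts
(default k = 5), Z-scored per feature with population standard deviation:

    Z[i,j] = (M[i,j] - mu_j) / sigma_j

Clustering then runs on a Gaussian RBF affinity matrix

    W[i,j] = exp( -d(x_i, x_j)^2 / (2 sigma^2) ),

with kernel width `sigma = P2 x` (mean over points of the mean Euclidean
distance to their 5 nearest neighbors). The normalized density
`rho_i = sum_{j != i} W[i,j] / (n - 1)` drives a two-phase procedure:

* **Phase 1 — subcluster detection.** Points with `rho_i < P1 - P3` are
  set aside in the isolated set S. The rest are processed in decreasing
  density order; each unprocessed point seeds a subcluster containing every
  unprocessed point with affinity at least `tau_link` to it
  (default `exp(-1/2)`, i.e. within one sigma).
* **Phase 2 — merging.** Subcluster pairs whose mean cross-affinity
  reaches `tau_merge` are linked; final clusters are the connected
  components of the link graph. Isolated points are then assigned to the
  cluster with the largest mean affinity to them.

The pipeline is fully deterministic. Defaults are `P1 = 0.15`,
`P2 = 1.0`, `P3 = 0.05`. The package also ships the internal validity
indices (silhouette, Calinski–Harabasz, Davies–Bouldin), normalized mutual
information, a statistics workflow (Welch t, one-way ANOVA, chi-square,
Holm–Bonferroni correction, k-fold stability protocol), and a
planted-cluster sequence simulator so everything is testable offline.

## Worked example

Three planted gene families (20 sequences each, 2000 bp, 1% within-family
substitution) plus 3 random outlier sequences:

```r
library(rbfclust)
design <- planted_design(n_clusters = 3, per_cluster = 20, seq_length = 2000,
                         within_mut_rate = 0.01, between_divergence = 0.20,
                         n_outliers = 3, seed = 1)
gen <- generate_planted_sequences(design)
z   <- standardize(count_kmers(gen$sequences, k = 5))
fit <- rbf_fit(z, rbf_params(p1 = 0.15, p2 = 1.0, p3 = 0.05))
fit
#> <clustering_result> K = 3 cluster(s), 63 point(s), 3 isolated, sigma = 22.01
#> cluster
#>  1  2  3
#> 21 22 20
fit$isolated
#> [1] 61 62 63        # exactly the three planted outliers went through S
silhouette_score(z, fit$final_labels)$mean   # 0.513
calinski_harabasz(z, fit$final_labels)       # 52.7
davies_bouldin(z, fit$final_labels)          # 0.828
m <- gen$labels > 0
nmi(fit$final_labels[m], gen$labels[m])      # 1: perfect member recovery
```

The three families are recovered exactly (NMI = 1 on the planted members);
the three outliers are flagged as isolated before being absorbed into their
nearest cluster. The validity indices describe the standardized k-mer
space: a silhouette of 0.51 with DB of 0.83 reflects tight, well-separated
but high-dimensional clusters.

Holm–Bonferroni on three raw p-values (0.012, 0.025, 0.015):

```r
holm_bonferroni(c(0.012, 0.025, 0.015))$adjusted
#> [1] 0.036 0.036 0.036   # all remain significant at alpha = 0.05
```

## Command line

```sh
Rscript inst/cli/rbfclust.R simulate --mode sequences --config design.json --out sim/
Rscript inst/cli/rbfclust.R cluster  --fasta sim/sequences.fasta --k 5 \
        --p1 0.15 --p2 1.0 --p3 0.05 --tau-merge 0.2 --out out/
Rscript inst/cli/rbfclust.R evaluate --features f.csv --labels out/labels.csv \
        --truth sim/truth.csv --out report.json
```

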
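Package: rbfclust
Title: Hybrid Radial Basis Function Network Clustering of Gene Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free clustering of nucleotide sequences via k-mer
    frequency profiles and a two-phase density clustering algorithm built on
    a Gaussian radial basis function (RBF) affinity matrix. Phase 1 detects
    dense subclusters and sets aside low-density (isolated) points; Phase 2
    merges subclusters by mean cross-affinity and re-assigns isolated points
    to their nearest cluster under the kernel. Includes FASTA/tabular
    sequence ingestion with deduplication and quality filtering, k-mer
    counting and Z-score standardization, internal cluster validity indices
    (silhouette, Calinski-Harabasz, Davies-Bouldin) and normalized mutual
    information, a statistical comparison workflow (Welch t, one-way ANOVA,
    chi-square, Holm-Bonferroni correction, k-fold stability protocol), and
    a planted-cluster sequence simulator for end-to-end testing without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
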
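#' Planted-cluster sequence design
#'
#' Describes a synthetic dataset emulating the regime the method targets:
#' hundreds of genes of >= 1000 bases with a handful of well-diverged
#' families. One uniform-random ACGT ancestor is drawn per cluster (pairs
#' closer than `between_divergence` normalized Hamming distance are
#' redrawn); members are ancestor copies with i.i.d. per-base substitution
#' at `within_mut_rate`; outliers are fresh uniform sequences labeled 0.
#'
#' @param n_clusters number of planted clusters (>= 1).
#' @param per_cluster sequences per cluster (>= 1).
#' @param seq_length sequence length in bases.
#' @param within_mut_rate per-base substitution probability from the
#'   cluster ancestor, in `[0, 1]`.
#' @param between_divergence minimum normalized Hamming distance between
#'   ancestors, in `[0, 1]`; random ancestors differ at 0.75 of sites in
#'   expectation, so values above 0.75 are rejected as unattainable.
#' @param n_outliers number of uniform-random outlier sequences (label 0).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `planted_design`.
#' @export
planted_design <- function(n_clusters = 3L, per_cluster = 20L,
                           seq_length = 2000L, within_mut_rate = 0.01,
                           between_divergence = 0.20, n_outliers = 3L,
                           seed = 1L) {
  stopifnot(n_clusters >= 1, per_cluster >= 1, seq_length >= 1,
            within_mut_rate >= 0, within_mut_rate <= 1,
            between_divergence >= 0, between_divergence <= 1,
            n_outliers >= 0)
  if (within_mut_rate >= between_divergence && n_clusters > 1) {
    warning("within_mut_rate >= between_divergence: design may not be separable")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 per_cluster = as.integer(per_cluster),
                 seq_length = as.integer(seq_length),
                 within_mut_rate = within_mut_rate,
                 between_divergence = between_divergence,
                 n_outliers = as.integer(n_outliers),
                 seed = as.integer(seed)),
            class = "planted_design")
}

BASES <- c("A", "C", "G", "T")

random_seq_chars <- function(L) sample(BASES, L, replace = TRUE)

mutate_chars <- function(chars, rate) {
  hit <- which(rbinom(length(chars), 1L, rate) == 1L)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  chars
}

#' Generate a planted-cluster sequence set
#'
#' @param design a [planted_design()].
#' @return list with `sequences` (a [sequence_set()], cluster members first
#'   in cluster order, outliers last) and `labels` (integer truth labels,
#'   0 for outliers).
#' @export
generate_planted_sequences <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  if (design$between_divergence > 0.75) {
    stop("between_divergence > 0.75 is unattainable for uniform ancestors")
  }
  set.seed(design$seed)
  L <- design$seq_length
  ## draw ancestors until every pair is at least between_divergence apart
  ancestors <- NULL
  for (attempt in seq_len(100L)) {
    ancestors <- lapply(seq_len(design$n_clusters), function(i) random_seq_chars(L))
    ok <- TRUE
    if (design$n_clusters > 1) {
      for (a in seq_len(design$n_clusters - 1L)) {
        for (b in seq(a + 1L, design$n_clusters)) {
          if (mean(ancestors[[a]] != ancestors[[b]]) < design$between_divergence) {
            ok <- FALSE
          }
        }
      }
    }
    if (ok) break
    ancestors <- NULL
  }
  if (is.null(ancestors)) {
    stop("could not draw sufficiently diverged ancestors in 100 attempts")
  }
  n_members <- design$n_clusters * design$per_cluster
  n_total <- n_members + design$n_outliers
  seqs <- character(n_total)
  labels <- integer(n_total)
  idx <- 0L
  for (cl in seq_len(design$n_clusters)) {
    for (m in seq_len(design$per_cluster)) {
      idx <- idx + 1L
      seqs[idx] <- paste(mutate_chars(ancestors[[cl]], design$within_mut_rate),
                         collapse = "")
      labels[idx] <- cl
    }
  }
  for (o in seq_len(design$n_outliers)) {
    idx <- idx + 1L
    seqs[idx] <- paste(random_seq_chars(L), collapse = "")
    labels[idx] <- 0L
  }
  ss <- sequence_set(
    gene_symbol = sprintf("gene%03d", seq_len(n_total)),
    accession = sprintf("SYN%06d", seq_len(n_total)),
    sequence = seqs,
    provenance = sprintf("planted_design(seed=%d)", design$seed))
  list(sequences = ss, labels = labels)
}

#' Generate Gaussian feature-space blobs with known labels
#'
#' Cluster centers are drawn i.i.d. uniform in the cube `[0,
#' center_spread]^dims`; members are center plus isotropic Gaussian noise
#' with standard deviation `within_sd`; outliers are uniform in the cube
#' and labeled 0. Deterministic given `seed`.
#'
#' @param n_clusters,per_cluster,n_outliers design counts.
#' @param dims feature dimension.
#' @param center_spread side of the sampling cube (> 0).
#' @param within_sd isotropic within-cluster standard deviation (> 0 or 0
#'   for coincident members).
#' @param seed integer seed.
#' @return list with `x` (numeric matrix) and `labels` (0 for outliers).
#' @export
generate_feature_blobs <- function(n_clusters, per_cluster, dims = 2L,
                                   center_spread = 10, within_sd = 0.5,
                                   n_outliers = 0L, seed = 1L) {
  stopifnot(center_spread > 0, within_sd >= 0,
            n_clusters >= 1, per_cluster >= 1, n_outliers >= 0)
  set.seed(seed)
  centers <- matrix(runif(n_clusters * dims, 0, center_spread),
                    nrow = n_clusters)
  n <- n_clusters * per_cluster + n_outliers
  x <- matrix(0, nrow = n, ncol = dims)
  labels <- integer(n)
  row <- 0L
  for (cl in seq_len(n_clusters)) {
    for (m in seq_len(per_cluster)) {
      row <- row + 1L
      x[row, ] <- centers[cl, ] + rnorm(dims, sd = within_sd)
      labels[row] <- cl
    }
  }
  for (o in seq_len(n_outliers)) {
    row <- row + 1L
    x[row, ] <- runif(dims, 0, center_spread)
    labels[row] <- 0L
  }
  list(x = x, labels = labels)
}
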
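#' Silhouette coefficient
#'
#' For point i, `a(i)` is the mean distance to the other points of its own
#' cluster and `b(i)` the minimum over other clusters of the mean distance
#' to that cluster's points; `s(i) = (b - a) / max(a, b)`. Points in
#' singleton clusters score 0 by convention, as do points where
#' `max(a, b) = 0`.
#'
#' @param x feature matrix (or `std_matrix`/`kmer_counts`).
#' @param labels integer cluster labels, one per row; at least 2 distinct
#'   clusters required.
#' @return list with `mean` and `per_point` silhouette values.
#' @export
silhouette_score <- function(x, labels) {
  x <- as_feature_matrix(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouette undefined for k=1")
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(cl, own),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean = mean(s), per_point = s)
}

#' Calinski-Harabasz index
#'
#' `CH = (Tr(B_k) / Tr(W_k)) * ((N - k) / (k - 1))` where `B_k` and `W_k`
#' are the between- and within-cluster scatter matrices about the cluster
#' centroids and the grand centroid.
#'
#' @inheritParams silhouette_score
#' @return the CH index; `Inf` with a warning when `Tr(W_k) = 0`.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as_feature_matrix(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  N <- nrow(x)
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2L || k > N - 1L) stop("calinski_harabasz requires 2 <= k <= N-1")
  grand <- colMeans(x)
  tr_w <- 0
  tr_b <- 0
  for (g in cl) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    tr_w <- tr_w + sum(sweep(xg, 2L, cg)^2)
    tr_b <- tr_b + nrow(xg) * sum((cg - grand)^2)
  }
  if (tr_w == 0) {
    warning("Tr(W_k) = 0: all points lie on their centroids; CH is infinite")
    return(Inf)
  }
  (tr_b / tr_w) * ((N - k) / (k - 1))
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) * sum_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`
#' where `sigma_i` is the mean Euclidean distance of cluster i's points to
#' their centroid `c_i` (mean, not RMS).
#'
#' @inheritParams silhouette_score
#' @return the DB index (lower is better).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as_feature_matrix(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2L) stop("davies_bouldin requires k >= 2")
  centroids <- do.call(rbind, lapply(cl, function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  sig <- vapply(seq_along(cl), function(ii) {
    xg <- x[labels == cl[ii], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2L, centroids[ii, ])^2)))
  }, numeric(1))
  dc <- as.matrix(dist(centroids))
  ratios <- numeric(k)
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      if (dc[i, j] == 0) {
        stop(sprintf("coincident centroids for clusters %d and %d",
                     cl[i], cl[j]))
      }
      r <- max(r, (sig[i] + sig[j]) / dc[i, j])
    }
    ratios[i] <- r
  }
  mean(ratios)
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(A; B) / mean(H(A), H(B))` with natural logarithms and, by
#' default, the arithmetic mean of the entropies (a geometric-mean variant
#' is available). When both labelings are constant the partitions are
#' identical and NMI is 1; when only one entropy is zero NMI is 0.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param normalization `"arithmetic"` (default) or `"geometric"` mean of
#'   the two entropies.
#' @return NMI in `[0, 1]`; symmetric and invariant to relabeling.
#' @export
nmi <- function(labels_a, labels_b,
                normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b)) {
    stop("labels_a and labels_b must have the same length")
  }
  if (length(labels_a) == 0L) stop("empty labelings")
  joint <- table(labels_a, labels_b)
  n <- sum(joint)
  pij <- joint / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 && hb == 0) return(1)   # both single-cluster partitions
  if (ha == 0 || hb == 0) return(0)
  outer_p <- outer(pa, pb)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer_p), 0))
  denom <- if (normalization == "arithmetic") (ha + hb) / 2 else sqrt(ha * hb)
  val <- mi / denom
  min(max(val, 0), 1)
}

#' All validity metrics in one report
#'
#' @param x feature matrix.
#' @param labels cluster labels.
#' @param truth optional reference labels for NMI.
#' @return list with `silhouette_mean`, `silhouette_per_point`,
#'   `calinski_harabasz`, `davies_bouldin` and (if `truth` given) `nmi`.
#' @export
validity_report <- function(x, labels, truth = NULL) {
  sil <- silhouette_score(x, labels)
  out <- list(silhouette_mean = sil$mean,
              silhouette_per_point = sil$per_point,
              calinski_harabasz = calinski_harabasz(x, labels),
              davies_bouldin = davies_bouldin(x, labels))
  if (!is.null(truth)) out$nmi <- nmi(labels, truth)
  out
}
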
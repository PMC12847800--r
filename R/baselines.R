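#' Baseline clustering adapters
#'
#' Thin wrappers turning standard R clustering routines into the
#' `function(x) -> labels` shape that [compare_algorithms()] expects. The
#' baselines' internals are not part of this package's method; they exist
#' only as comparison points.
#'
#' @param k number of clusters.
#' @param nstart restarts for `stats::kmeans`.
#' @return a function mapping a feature matrix to integer labels.
#' @name baselines
NULL

#' @rdname baselines
#' @export
baseline_kmeans <- function(k, nstart = 10L) {
  force(k); force(nstart)
  function(x) kmeans(x, centers = k, nstart = nstart)$cluster
}

#' @rdname baselines
#' @param method agglomeration method for `stats::hclust`.
#' @export
baseline_hclust <- function(k, method = "average") {
  force(k); force(method)
  function(x) cutree(hclust(dist(x), method = method), k = k)
}

#' @rdname baselines
#' @param params an [rbf_params()] object.
#' @export
baseline_hybrid_rbf <- function(params = rbf_params()) {
  force(params)
  function(x) rbf_fit(x, params)$final_labels
}

#' @rdname baselines
#' @export
baseline_random <- function(k) {
  force(k)
  function(x) sample.int(k, nrow(x), replace = TRUE)
}
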
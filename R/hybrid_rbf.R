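#' Parameters of the hybrid RBF network clustering
#'
#' The two-phase algorithm is governed by the density threshold `p1`, the
#' kernel spread multiplier `p2`, and the resolution modifier `p3`: a point
#' whose normalized density falls below `p1 - p3` is provisionally isolated.
#' The kernel width is `sigma = p2 *` (grand mean over points of the mean
#' Euclidean distance to their `n_sigma_neighbors` nearest neighbors), so
#' `p2 = 1` reproduces the average-5-nearest-neighbor initialization.
#' `tau_link` is the minimum affinity for a point to join a seed's
#' subcluster (default `exp(-1/2)`, i.e. points within one sigma);
#' `tau_merge` is the minimum mean cross-affinity for two subclusters to be
#' merged.
#'
#' @param p1 density threshold in (0, 1].
#' @param p2 spread multiplier, > 0.
#' @param p3 resolution modifier, >= 0. `p1 - p3 <= 0` disables isolation.
#' @param n_sigma_neighbors number of nearest neighbors for the sigma
#'   initialization (default 5).
#' @param tau_link subcluster membership weight threshold in (0, 1).
#' @param tau_merge merge connectivity threshold in (0, 1).
#' @param merge_stat cross-subcluster connectivity statistic: mean
#'   cross-pair affinity (default) or maximum (single linkage).
#' @return an object of class `rbf_params`.
#' @export
rbf_params <- function(p1 = 0.15, p2 = 1.0, p3 = 0.05,
                       n_sigma_neighbors = 5L,
                       tau_link = exp(-0.5), tau_merge = 0.2,
                       merge_stat = c("mean", "max")) {
  merge_stat <- match.arg(merge_stat)
  if (!(p1 > 0 && p1 <= 1)) stop("p1 must be in (0, 1]")
  if (p2 <= 0) stop("p2 must be > 0")
  if (p3 < 0) stop("p3 must be >= 0")
  n_sigma_neighbors <- as.integer(n_sigma_neighbors)
  if (n_sigma_neighbors < 1L) stop("n_sigma_neighbors must be >= 1")
  if (!(tau_link > 0 && tau_link < 1)) stop("tau_link must be in (0, 1)")
  if (!(tau_merge > 0 && tau_merge < 1)) stop("tau_merge must be in (0, 1)")
  if (tau_merge > tau_link) {
    warning("tau_merge > tau_link: merging is stricter than subcluster linking")
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3,
                 n_sigma_neighbors = n_sigma_neighbors,
                 tau_link = tau_link, tau_merge = tau_merge,
                 merge_stat = merge_stat),
            class = "rbf_params")
}

#' Kernel width from the mean nearest-neighbor distance
#'
#' `sigma = p2 x` mean over all points of the mean Euclidean distance to
#' their `n_sigma_neighbors` nearest other points.
#'
#' @param z a `std_matrix`, `kmer_counts` or numeric matrix.
#' @param params an [rbf_params()] object.
#' @return positive scalar sigma.
#' @export
compute_sigma <- function(z, params = rbf_params()) {
  x <- as_feature_matrix(z)
  n <- nrow(x)
  k <- params$n_sigma_neighbors
  if (n < k + 1L) stop("need at least n_sigma_neighbors + 1 points")
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  knn_mean <- apply(d, 1L, function(row) mean(sort(row, partial = k)[seq_len(k)]))
  sigma <- params$p2 * mean(knn_mean)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate data: all pairwise distances are zero")
  }
  sigma
}

#' Build the Gaussian RBF affinity state
#'
#' Computes the symmetric kernel weight matrix
#' `W[i,j] = exp(-d(x_i, x_j)^2 / (2 sigma^2))` (unit diagonal) and the
#' densities `rho_raw[i] = sum_{j != i} W[i,j]`, normalized to
#' `rho_norm = rho_raw / (n - 1)` in `[0, 1]` so that the isolation
#' threshold `p1 - p3` is independent of the dataset size.
#'
#' @param z features (`std_matrix`, `kmer_counts` or matrix).
#' @param sigma kernel width, > 0.
#' @return an object of class `affinity_state` with fields `w`, `sigma`,
#'   `rho_raw`, `rho_norm`.
#' @export
build_affinity <- function(z, sigma) {
  x <- as_feature_matrix(z)
  if (!all(is.finite(x))) stop("features must be finite")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  d2 <- as.matrix(dist(x))^2
  w <- exp(-d2 / (2 * sigma^2))
  dimnames(w) <- NULL
  diag(w) <- 1
  w <- (w + t(w)) / 2          # exact symmetry against fp noise
  n <- nrow(w)
  rho_raw <- rowSums(w) - 1
  structure(list(w = w, sigma = sigma, rho_raw = rho_raw,
                 rho_norm = if (n > 1) rho_raw / (n - 1) else rho_raw * 0),
            class = "affinity_state")
}

#' Phase 1: density-ordered subcluster detection
#'
#' Points with `rho_norm < p1 - p3` go to the isolated set S. Remaining
#' points are processed in decreasing density order (ties broken by lower
#' index): each still-unprocessed point seeds a subcluster containing
#' itself and every unprocessed, non-isolated point whose affinity to the
#' seed is at least `tau_link`. A seed with no qualifying neighbor forms a
#' singleton subcluster.
#'
#' @param aff an [build_affinity()] result.
#' @param params an [rbf_params()] object.
#' @return an object of class `subcluster_state`: `labels` (0 for isolated,
#'   1..t subcluster ids), `isolated` (indices of S in index order),
#'   `subclusters` (list of index vectors) and `t`.
#' @export
detect_subclusters <- function(aff, params = rbf_params()) {
  stopifnot(inherits(aff, "affinity_state"))
  n <- nrow(aff$w)
  thr <- params$p1 - params$p3
  if (thr <= 0) {
    warning("p1 - p3 <= 0: no point can be isolated")
  }
  iso <- aff$rho_norm < thr
  labels <- integer(n)
  processed <- iso
  subclusters <- list()
  t <- 0L
  for (i in order(-aff$rho_norm, seq_len(n))) {
    if (processed[i]) next
    t <- t + 1L
    members <- which(!processed & aff$w[i, ] >= params$tau_link)
    members <- sort(unique(c(i, members)))
    labels[members] <- t
    processed[members] <- TRUE
    subclusters[[t]] <- members
  }
  structure(list(labels = labels, isolated = which(iso),
                 subclusters = subclusters, t = t),
            class = "subcluster_state")
}

## connected components of a symmetric logical adjacency matrix; returns an
## integer component id per node
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Phase 2: single-pass merging of subclusters
#'
#' The connectivity between two subclusters is the mean (or maximum, per
#' `merge_stat`) affinity over all cross pairs of their members. Pairs at or
#' above `tau_merge` are linked, and final clusters are the connected
#' components of the link graph (transitive closure in one pass). Final
#' cluster labels are numbered 1..K in order of their smallest member
#' index; isolated points keep label 0 until [assign_isolated()].
#'
#' @param state a [detect_subclusters()] result.
#' @param aff the [build_affinity()] result it was computed from.
#' @param params an [rbf_params()] object.
#' @return an object of class `clustering_result` with fields
#'   `final_labels`, `n_clusters`, `merge_log` (list of subcluster-id sets
#'   per final cluster), `isolated_assignments`, `connectivity` (t x t
#'   matrix), `params_used`, `sigma`, `subcluster_labels`, `isolated`.
#' @export
merge_subclusters <- function(state, aff, params = rbf_params()) {
  stopifnot(inherits(state, "subcluster_state"), inherits(aff, "affinity_state"))
  t <- state$t
  if (t == 0L) {
    return(structure(list(final_labels = integer(length(state$labels)),
                          n_clusters = 0L, merge_log = list(),
                          isolated_assignments = integer(0),
                          connectivity = matrix(numeric(0), 0, 0),
                          params_used = params, sigma = aff$sigma,
                          subcluster_labels = state$labels,
                          isolated = state$isolated),
                     class = "clustering_result"))
  }
  conn <- matrix(1, t, t)
  if (t > 1L) {
    for (a in seq_len(t - 1L)) {
      for (b in seq(a + 1L, t)) {
        wab <- aff$w[state$subclusters[[a]], state$subclusters[[b]], drop = FALSE]
        conn[a, b] <- conn[b, a] <-
          if (params$merge_stat == "mean") mean(wab) else max(wab)
      }
    }
  }
  adj <- conn >= params$tau_merge
  diag(adj) <- TRUE
  comp <- graph_components(adj)
  ## renumber components 1..K by smallest member point index
  first_point <- vapply(split(seq_len(t), comp),
                        function(scs) min(unlist(state$subclusters[scs])),
                        numeric(1))
  new_id <- integer(max(comp))
  new_id[as.integer(names(sort(first_point)))] <- seq_along(first_point)
  comp <- new_id[comp]
  K <- max(comp)
  final_labels <- integer(length(state$labels))
  for (sc in seq_len(t)) {
    final_labels[state$subclusters[[sc]]] <- comp[sc]
  }
  merge_log <- lapply(seq_len(K), function(cl) which(comp == cl))
  structure(list(final_labels = final_labels, n_clusters = K,
                 merge_log = merge_log,
                 isolated_assignments = integer(0),
                 connectivity = conn, params_used = params,
                 sigma = aff$sigma, subcluster_labels = state$labels,
                 isolated = state$isolated),
            class = "clustering_result")
}

#' Assign isolated points to final clusters
#'
#' Each point in the isolated set S is assigned to the cluster with the
#' largest mean affinity over that cluster's non-isolated members (the
#' shortest kernel-influenced distance); ties go to the lowest cluster
#' label.
#'
#' @param result a [merge_subclusters()] result.
#' @param state the matching [detect_subclusters()] state.
#' @param aff the matching [build_affinity()] state.
#' @return the completed `clustering_result` covering all points.
#' @export
assign_isolated <- function(result, state, aff) {
  stopifnot(inherits(result, "clustering_result"))
  if (length(state$isolated) == 0L) return(result)
  if (result$n_clusters < 1L) stop("no clusters to absorb isolated points")
  members <- lapply(seq_len(result$n_clusters), function(cl) {
    which(result$final_labels == cl & state$labels > 0L)
  })
  assignments <- integer(length(state$isolated))
  for (idx in seq_along(state$isolated)) {
    i <- state$isolated[idx]
    mw <- vapply(members, function(m) mean(aff$w[i, m]), numeric(1))
    assignments[idx] <- which.max(mw)   # ties -> lowest label
    result$final_labels[i] <- assignments[idx]
  }
  result$isolated_assignments <- setNames(assignments,
                                          as.character(state$isolated))
  result
}

#' Fit the hybrid RBF network clustering
#'
#' Full deterministic pipeline: kernel width from the mean
#' nearest-neighbor distance, Gaussian affinity matrix and densities,
#' phase-1 subcluster detection with isolation, phase-2 merging, and final
#' assignment of isolated points. No randomness is involved anywhere.
#'
#' @param z features: a `std_matrix`, `kmer_counts` or numeric matrix with
#'   at least 2 rows.
#' @param params an [rbf_params()] object.
#' @return a `clustering_result`; `final_labels` is a total partition of
#'   the rows into `n_clusters` clusters.
#' @examples
#' blobs <- generate_feature_blobs(n_clusters = 2, per_cluster = 10,
#'                                 dims = 2, center_spread = 50,
#'                                 within_sd = 0.5, seed = 1)
#' fit <- rbf_fit(blobs$x)
#' table(fit$final_labels, blobs$labels)
#' @export
rbf_fit <- function(z, params = rbf_params()) {
  x <- as_feature_matrix(z)
  if (nrow(x) < 2L) stop("need at least 2 points")
  sigma <- compute_sigma(x, params)
  aff <- build_affinity(x, sigma)
  state <- detect_subclusters(aff, params)
  result <- merge_subclusters(state, aff, params)
  assign_isolated(result, state, aff)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> K = %d cluster(s), %d point(s), %d isolated, sigma = %.4g\n",
              x$n_clusters, length(x$final_labels), length(x$isolated),
              x$sigma))
  if (x$n_clusters > 0) {
    print(table(cluster = x$final_labels))
  }
  invisible(x)
}

#' Write clustering outputs to a directory
#'
#' Emits `labels.csv` (row id, subcluster id, final cluster id, isolated
#' flag), `merge_log.json` and `params.json`.
#'
#' @param result a `clustering_result`.
#' @param dir output directory (created if needed).
#' @param ids optional record identifiers (defaults to row numbers).
#' @return `dir`, invisibly.
#' @export
save_clustering <- function(result, dir, ids = NULL) {
  stopifnot(inherits(result, "clustering_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(result$final_labels)
  if (is.null(ids)) ids <- seq_len(n)
  df <- data.frame(id = ids,
                   subcluster = result$subcluster_labels,
                   cluster = result$final_labels,
                   isolated = seq_len(n) %in% result$isolated)
  write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(result$merge_log, file.path(dir, "merge_log.json"))
  jsonlite::write_json(c(unclass(result$params_used), sigma = result$sigma),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}
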
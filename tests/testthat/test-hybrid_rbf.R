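test_that("rbf_params validates ranges and warns on odd thresholds", {
  p <- rbf_params()
  expect_equal(p$p1, 0.15)
  expect_equal(p$p2, 1.0)
  expect_equal(p$p3, 0.05)
  expect_equal(p$tau_link, exp(-0.5))
  expect_error(rbf_params(p1 = 0), "p1")
  expect_error(rbf_params(p2 = -1), "p2")
  expect_error(rbf_params(tau_link = 1.5), "tau_link")
  expect_warning(rbf_params(tau_link = 0.1, tau_merge = 0.5), "stricter")
})

test_that("compute_sigma equals the mean-of-mean-kNN distance (1-D 0..9)", {
  x <- matrix(0:9, ncol = 1)
  # brute force: endpoints 3.0, points 1 and 8 give 2.2, interior 1.8;
  # grand mean (2*3.0 + 2*2.2 + 6*1.8)/10 = 2.12
  knn <- sapply(1:10, function(i) {
    d <- sort(abs(x[i, 1] - x[-i, 1]))
    mean(d[1:5])
  })
  expect_equal(mean(knn), 2.12)
  expect_equal(compute_sigma(x, rbf_params(p2 = 1)), 2.12)
  expect_equal(compute_sigma(x, rbf_params(p2 = 2)), 4.24)  # linear in p2
  expect_error(compute_sigma(x[1:3, , drop = FALSE], rbf_params()),
               "n_sigma_neighbors")
})

test_that("compute_sigma tolerates coincident points but not degenerate data", {
  x <- matrix(c(0, 0, 1, 2, 3, 4, 5), ncol = 1)
  expect_gt(compute_sigma(x, rbf_params()), 0)
  xz <- matrix(0, nrow = 6, ncol = 2)
  expect_error(compute_sigma(xz, rbf_params()), "degenerate")
})

test_that("build_affinity matches the analytic kernel", {
  sigma <- 1.7
  x <- matrix(c(0, 0,
                sigma, 0,
                sigma * sqrt(2 * log(2)), 0,
                0, 0), ncol = 2, byrow = TRUE)
  aff <- build_affinity(x, sigma)
  expect_equal(diag(aff$w), rep(1, 4))
  expect_equal(aff$w[1, 4], 1)                      # d = 0
  expect_equal(aff$w[1, 2], exp(-1 / 2))            # d = sigma
  expect_equal(aff$w[1, 3], 0.5)                    # half-weight distance
  expect_true(isSymmetric(aff$w))
  expect_equal(aff$rho_raw, rowSums(aff$w) - 1)
  expect_equal(aff$rho_norm, aff$rho_raw / 3)
  expect_error(build_affinity(matrix(c(0, NA), 2), 1), "finite")
  expect_error(build_affinity(x, 0), "sigma")
})

test_that("densities match a naive double-loop recomputation", {
  set.seed(21)
  for (trial in 1:5) {
    n <- sample(8:30, 1)
    x <- matrix(rnorm(n * 3), nrow = n)
    sigma <- runif(1, 0.5, 2)
    aff <- build_affinity(x, sigma)
    expect_equal(aff$rho_raw, oracle_densities(x, sigma), tolerance = 1e-10)
  }
})

test_that("detect_subclusters isolates low-density outliers between two blobs", {
  x <- rbind(c(0, 0), c(0, 0.1), c(0.1, 0),
             c(10, 10), c(10, 10.1), c(10.1, 10),
             c(5, 5))
  aff <- build_affinity(x, sigma = 0.5)
  st <- detect_subclusters(aff, rbf_params(tau_link = 0.5))
  expect_equal(st$isolated, 7L)                 # rho_norm ~ 0 < 0.15 - 0.05
  expect_equal(st$t, 2L)
  expect_setequal(st$subclusters[[which(st$labels[1] == seq_len(st$t))]],
                  1:3)
  expect_equal(sort(unlist(st$subclusters)), 1:6)
  expect_equal(st$labels[7], 0L)
  expect_equal(sort(c(unlist(st$subclusters), st$isolated)), 1:7)
})

test_that("p1 - p3 <= 0 disables isolation with a warning", {
  set.seed(2)
  x <- matrix(rnorm(20), ncol = 2)
  aff <- build_affinity(x, sigma = 1)
  expect_warning(st <- detect_subclusters(aff, rbf_params(p1 = 0.05, p3 = 0.05)),
                 "no point")
  expect_length(st$isolated, 0)
})

test_that("all points close with tiny tau_link yields a single subcluster", {
  x <- matrix(rnorm(16, sd = 0.01), ncol = 2)
  aff <- build_affinity(x, sigma = 5)
  st <- suppressWarnings(
    detect_subclusters(aff, rbf_params(p1 = 0.01, p3 = 0.05,
                                       tau_link = 0.01)))
  expect_equal(st$t, 1L)
  expect_length(st$isolated, 0)
})

## constructs an affinity_state and subcluster_state directly so merge can be
## tested against hand-computed connectivities
fake_state <- function(w, subclusters, isolated = integer(0)) {
  n <- nrow(w)
  labels <- integer(n)
  for (i in seq_along(subclusters)) labels[subclusters[[i]]] <- i
  aff <- structure(list(w = w, sigma = 1, rho_raw = rowSums(w) - 1,
                        rho_norm = (rowSums(w) - 1) / (n - 1)),
                   class = "affinity_state")
  st <- structure(list(labels = labels, isolated = isolated,
                       subclusters = subclusters,
                       t = length(subclusters)),
                  class = "subcluster_state")
  list(aff = aff, st = st)
}

test_that("merge_subclusters links by mean cross affinity and closes transitively", {
  # 3 singleton-pair subclusters with prescribed cross means
  w <- diag(6)
  cross <- function(w, a, b, val) {
    w[a, b] <- val; w[b, a] <- val
    w
  }
  # SC1 = {1,2}, SC2 = {3,4}, SC3 = {5,6}
  for (i in 1:2) for (j in 3:4) w <- cross(w, i, j, 0.8)
  for (i in 3:4) for (j in 5:6) w <- cross(w, i, j, 0.1)
  for (i in 1:2) for (j in 5:6) w <- cross(w, i, j, 0.05)
  w[1, 2] <- w[2, 1] <- 0.9; w[3, 4] <- w[4, 3] <- 0.9
  w[5, 6] <- w[6, 5] <- 0.9
  fs <- fake_state(w, list(1:2, 3:4, 5:6))
  res <- merge_subclusters(fs$st, fs$aff, rbf_params(tau_merge = 0.5))
  expect_equal(res$n_clusters, 2L)
  expect_equal(res$final_labels, c(1, 1, 1, 1, 2, 2))
  expect_equal(res$connectivity[1, 2], 0.8)
  expect_equal(res$connectivity[2, 3],
               oracle_connectivity(w, 3:4, 5:6))

  # transitive closure: C(1,2) = C(2,3) = 0.6, C(1,3) = 0 -> one cluster
  w2 <- diag(6)
  for (i in 1:2) for (j in 3:4) w2 <- cross(w2, i, j, 0.6)
  for (i in 3:4) for (j in 5:6) w2 <- cross(w2, i, j, 0.6)
  fs2 <- fake_state(w2, list(1:2, 3:4, 5:6))
  res2 <- merge_subclusters(fs2$st, fs2$aff, rbf_params(tau_merge = 0.5))
  expect_equal(res2$n_clusters, 1L)
  expect_equal(res2$final_labels, rep(1, 6))
})

test_that("merge of a single subcluster is the identity; t = 0 gives K = 0", {
  w <- matrix(0.9, 3, 3); diag(w) <- 1
  fs <- fake_state(w, list(1:3))
  res <- merge_subclusters(fs$st, fs$aff, rbf_params())
  expect_equal(res$n_clusters, 1L)
  expect_equal(res$final_labels, rep(1, 3))

  fs0 <- fake_state(diag(3), list(), isolated = 1:3)
  res0 <- merge_subclusters(fs0$st, fs0$aff, rbf_params())
  expect_equal(res0$n_clusters, 0L)
  expect_error(assign_isolated(res0, fs0$st, fs0$aff), "no clusters")
})

test_that("assign_isolated maximizes mean affinity with lowest-label ties", {
  w <- diag(5)
  w[1, 2] <- w[2, 1] <- 0.9
  w[3, 4] <- w[4, 3] <- 0.9
  w[5, 1] <- w[1, 5] <- 0.9; w[5, 2] <- w[2, 5] <- 0.9
  w[5, 3] <- w[3, 5] <- 0.1; w[5, 4] <- w[4, 5] <- 0.1
  fs <- fake_state(w, list(1:2, 3:4), isolated = 5L)
  res <- merge_subclusters(fs$st, fs$aff, rbf_params(tau_merge = 0.5))
  res <- assign_isolated(res, fs$st, fs$aff)
  expect_equal(res$final_labels[5], 1L)
  expect_equal(unname(res$isolated_assignments), 1L)

  # exact tie -> lowest cluster label
  w[5, 3] <- w[3, 5] <- 0.9; w[5, 4] <- w[4, 5] <- 0.9
  fs <- fake_state(w, list(1:2, 3:4), isolated = 5L)
  res <- merge_subclusters(fs$st, fs$aff, rbf_params(tau_merge = 0.5))
  res <- assign_isolated(res, fs$st, fs$aff)
  expect_equal(res$final_labels[5], 1L)

  # empty S -> unchanged
  fs2 <- fake_state(w, list(1:2, 3:5))
  res2 <- merge_subclusters(fs2$st, fs2$aff, rbf_params(tau_merge = 0.05))
  expect_identical(assign_isolated(res2, fs2$st, fs2$aff), res2)
})

test_that("fit recovers well-separated planted blobs exactly", {
  blobs <- generate_feature_blobs(n_clusters = 2, per_cluster = 12, dims = 3,
                                  center_spread = 100, within_sd = 0.5,
                                  seed = 4)
  fit <- rbf_fit(blobs$x, rbf_params())
  expect_equal(fit$n_clusters, 2L)
  expect_equal(nmi(fit$final_labels, blobs$labels), 1.0)
  expect_true(all(fit$final_labels %in% 1:2))
})

test_that("kernel limits: huge p2 gives one cluster, tiny p2 isolates all", {
  blobs <- generate_feature_blobs(n_clusters = 2, per_cluster = 8, dims = 2,
                                  center_spread = 10, within_sd = 0.3,
                                  seed = 9)
  big <- rbf_fit(blobs$x, rbf_params(p2 = 1e3))
  expect_equal(big$n_clusters, 1L)
  expect_length(big$isolated, 0)
  expect_error(rbf_fit(blobs$x, rbf_params(p2 = 1e-6)), "no clusters")
})

test_that("fit is deterministic and permutation-equivariant", {
  blobs <- generate_feature_blobs(n_clusters = 3, per_cluster = 10, dims = 4,
                                  center_spread = 30, within_sd = 1,
                                  n_outliers = 2, seed = 13)
  f1 <- rbf_fit(blobs$x, rbf_params())
  f2 <- rbf_fit(blobs$x, rbf_params())
  expect_identical(f1, f2)
  set.seed(99)
  perm <- sample(nrow(blobs$x))
  fp <- rbf_fit(blobs$x[perm, ], rbf_params())
  expect_equal(nmi(fp$final_labels, f1$final_labels[perm]), 1.0)
})

test_that("lowering tau_merge never increases K; raising p1 never shrinks S", {
  blobs <- generate_feature_blobs(n_clusters = 3, per_cluster = 8, dims = 2,
                                  center_spread = 20, within_sd = 1.5,
                                  n_outliers = 3, seed = 17)
  sigma <- compute_sigma(blobs$x, rbf_params())
  aff <- build_affinity(blobs$x, sigma)
  prev_k <- Inf
  for (tm in c(0.8, 0.5, 0.3, 0.1, 0.02)) {
    p <- suppressWarnings(rbf_params(tau_merge = tm))
    st <- detect_subclusters(aff, p)
    res <- merge_subclusters(st, aff, p)
    expect_lte(res$n_clusters, prev_k)
    prev_k <- res$n_clusters
  }
  prev_s <- integer(0)
  for (p1 in c(0.06, 0.10, 0.15, 0.25, 0.5)) {
    st <- detect_subclusters(aff, rbf_params(p1 = p1, p3 = 0.05))
    expect_true(all(prev_s %in% st$isolated))
    prev_s <- st$isolated
  }
})

test_that("scale coupling: scaling features and sigma together preserves W and labels", {
  blobs <- generate_feature_blobs(n_clusters = 2, per_cluster = 9, dims = 3,
                                  center_spread = 15, within_sd = 1,
                                  seed = 23)
  sigma <- compute_sigma(blobs$x, rbf_params())
  c_scale <- 7.3
  aff1 <- build_affinity(blobs$x, sigma)
  aff2 <- build_affinity(blobs$x * c_scale, sigma * c_scale)
  expect_equal(aff2$w, aff1$w, tolerance = 1e-12)
  p <- rbf_params()
  st1 <- detect_subclusters(aff1, p)
  st2 <- detect_subclusters(aff2, p)
  expect_equal(st2$labels, st1$labels)
})

test_that("fit yields a total partition with provenance structures consistent", {
  blobs <- generate_feature_blobs(n_clusters = 3, per_cluster = 7, dims = 3,
                                  center_spread = 25, within_sd = 1,
                                  n_outliers = 2, seed = 31)
  fit <- rbf_fit(blobs$x, rbf_params())
  n <- nrow(blobs$x)
  expect_length(fit$final_labels, n)
  expect_true(all(fit$final_labels >= 1 & fit$final_labels <= fit$n_clusters))
  expect_lte(fit$n_clusters, max(fit$subcluster_labels))
  expect_equal(sort(unique(fit$final_labels)), seq_len(fit$n_clusters))
})

test_that("save_clustering writes labels, merge log and params", {
  blobs <- generate_feature_blobs(2, 6, dims = 2, center_spread = 40,
                                  within_sd = 0.5, seed = 8)
  fit <- rbf_fit(blobs$x)
  dir <- withr::local_tempdir()
  save_clustering(fit, dir)
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(lab$cluster, fit$final_labels)
  pj <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(pj$p1, 0.15)
  expect_true(file.exists(file.path(dir, "merge_log.json")))
})
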
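#' Welch two-sample t-test
#'
#' Unpooled statistic `t = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution.
#'
#' @param x1,x2 numeric samples, each of size >= 2; at least one must have
#'   positive variance.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  v1 <- var(x1); v2 <- var(x2)
  if (v1 == 0 && v2 == 0) stop("degenerate samples: both variances are zero")
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-way ANOVA F-test
#'
#' Classical decomposition `F = MS_between / MS_within` with
#' `df1 = k - 1`, `df2 = N - k`.
#'
#' @param groups list of >= 2 numeric samples, each of size >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_f <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("each group needs n >= 2")
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(g) sum((groups[[g]] - means[g])^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all_x) - length(groups)
  if (ssw == 0) stop("within-group variance is zero")
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` on an r x c contingency table with expected
#' counts from the product of the marginals; `df = (r - 1)(c - 1)`. No
#' continuity correction is applied.
#'
#' @param table nonnegative numeric matrix with strictly positive row and
#'   column sums.
#' @return list with `stat`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("table entries must be nonnegative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column marginal")
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(stat = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending, sets the i-th smallest adjusted value to
#' `max_{j <= i} (m - j + 1) * p_(j)` capped at 1, and maps back to the
#' input order. Controls the family-wise error rate.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @param alpha rejection level for the `reject` flags.
#' @return list with `adjusted` (same order as input) and `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1L) * pvals[o]), 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

## seed-deterministic shuffled fold assignment: returns a list of index
## vectors, one per fold, of near-equal size
make_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  split(perm, rep_len(seq_len(n_folds), n))
}

## internal metrics of one clustering on one feature subset; NA when the
## partition is degenerate (K < 2)
fold_internal_metrics <- function(x, labels) {
  if (length(unique(labels)) < 2L) {
    warning("fold produced K < 2 clusters: metrics recorded as missing")
    return(c(silhouette = NA_real_, ch = NA_real_, db = NA_real_))
  }
  c(silhouette = silhouette_score(x, labels)$mean,
    ch = calinski_harabasz(x, labels),
    db = davies_bouldin(x, labels))
}

#' k-fold stability protocol for the hybrid clustering
#'
#' Shuffles the indices with `seed`, splits them into `n_folds` folds, and
#' for each fold clusters the complementary (1 - 1/n_folds) training subset
#' and records its internal validity metrics. Stability is summarized by
#' the per-metric mean and standard deviation across folds and by the mean
#' pairwise NMI between fold partitions restricted to the points the two
#' training subsets share.
#'
#' @param z features (`std_matrix`, `kmer_counts` or matrix), n >= 2 *
#'   n_folds rows.
#' @param params an [rbf_params()] object.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return list with `fold_metrics` (data frame: algorithm, fold,
#'   silhouette, ch, db), `summary` (per-metric mean/sd over non-missing
#'   folds), `mean_pairwise_nmi`, and `fold_labels` (per-fold label
#'   vectors indexed by original row, NA for held-out points).
#' @export
crossval_stability <- function(z, params = rbf_params(), n_folds = 5L,
                               seed = 1L) {
  x <- as_feature_matrix(z)
  n <- nrow(x)
  n_folds <- as.integer(n_folds)
  if (n < 2L * n_folds) stop("need n >= 2 * n_folds")
  folds <- make_folds(n, n_folds, seed)
  fold_labels <- vector("list", n_folds)
  rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- sort(setdiff(seq_len(n), folds[[f]]))
    fit <- rbf_fit(x[train, , drop = FALSE], params)
    lab <- rep(NA_integer_, n)
    lab[train] <- fit$final_labels
    fold_labels[[f]] <- lab
    rows[[f]] <- data.frame(algorithm = "hybrid_rbf", fold = f,
                            t(fold_internal_metrics(x[train, , drop = FALSE],
                                                    fit$final_labels)))
  }
  fm <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("silhouette", "ch", "db"),
    mean = vapply(c("silhouette", "ch", "db"),
                  function(m) mean(fm[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("silhouette", "ch", "db"),
                function(m) sd(fm[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  pairs_nmi <- c()
  for (a in seq_len(n_folds - 1L)) {
    for (b in seq(a + 1L, n_folds)) {
      shared <- which(!is.na(fold_labels[[a]]) & !is.na(fold_labels[[b]]))
      pairs_nmi <- c(pairs_nmi, nmi(fold_labels[[a]][shared],
                                    fold_labels[[b]][shared]))
    }
  }
  list(fold_metrics = fm, summary = summ,
       mean_pairwise_nmi = mean(pairs_nmi), fold_labels = fold_labels)
}

#' Compare clustering algorithms across folds with statistical tests
#'
#' Runs every algorithm on the same training subsets (identical folds),
#' collects per-fold internal metrics, tests the reference algorithm
#' against every other one per metric with [welch_t()], tests overall
#' differences per metric with [anova_f()], and jointly Holm-adjusts all
#' pairwise t p-values.
#'
#' @param z features.
#' @param algorithms named list of functions `function(x) -> labels`; see
#'   [baseline_kmeans()] for adapters. The hybrid method itself can be
#'   included as `function(x) rbf_fit(x, params)$final_labels`.
#' @param reference name of the reference algorithm (default: first).
#' @param n_folds,seed fold protocol as in [crossval_stability()].
#' @param alpha rejection level after correction.
#' @return list with `fold_metrics`, `t_tests` (data frame with raw and
#'   Holm-adjusted p), `anova` (per metric), `alpha`.
#' @export
compare_algorithms <- function(z, algorithms, reference = names(algorithms)[1],
                               n_folds = 5L, seed = 1L, alpha = 0.05) {
  if (length(algorithms) < 2L) stop("need at least 2 algorithms")
  if (is.null(names(algorithms)) || any(!nzchar(names(algorithms)))) {
    stop("algorithms must be a named list")
  }
  x <- as_feature_matrix(z)
  n <- nrow(x)
  folds <- make_folds(n, n_folds, seed)
  rows <- list()
  for (alg in names(algorithms)) {
    for (f in seq_len(n_folds)) {
      train <- sort(setdiff(seq_len(n), folds[[f]]))
      ## per-(algorithm, fold) seed so stochastic baselines are reproducible
      set.seed(seed + 7919L * f + match(alg, names(algorithms)))
      labels <- algorithms[[alg]](x[train, , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = alg, fold = f,
                   t(fold_internal_metrics(x[train, , drop = FALSE], labels)))
    }
  }
  fm <- do.call(rbind, rows)
  metrics <- c("silhouette", "ch", "db")
  tt <- list()
  for (m in metrics) {
    ref_vals <- fm[[m]][fm$algorithm == reference]
    for (alg in setdiff(names(algorithms), reference)) {
      other <- fm[[m]][fm$algorithm == alg]
      res <- tryCatch(welch_t(ref_vals[!is.na(ref_vals)],
                              other[!is.na(other)]),
                      error = function(e) list(t = NA_real_, df = NA_real_,
                                               p = NA_real_))
      tt[[length(tt) + 1L]] <- data.frame(metric = m, reference = reference,
                                          algorithm = alg, t = res$t,
                                          df = res$df, p_raw = res$p)
    }
  }
  t_tests <- do.call(rbind, tt)
  ok <- !is.na(t_tests$p_raw)
  t_tests$p_adjusted <- NA_real_
  t_tests$reject <- NA
  if (any(ok)) {
    hb <- holm_bonferroni(t_tests$p_raw[ok], alpha)
    t_tests$p_adjusted[ok] <- hb$adjusted
    t_tests$reject[ok] <- hb$reject
  }
  anova_rows <- lapply(metrics, function(m) {
    gr <- lapply(names(algorithms), function(alg) {
      v <- fm[[m]][fm$algorithm == alg]
      v[!is.na(v)]
    })
    res <- tryCatch(anova_f(gr),
                    error = function(e) list(F = NA_real_, df1 = NA_real_,
                                             df2 = NA_real_, p = NA_real_))
    data.frame(metric = m, F = res$F, df1 = res$df1, df2 = res$df2, p = res$p)
  })
  list(fold_metrics = fm, t_tests = t_tests,
       anova = do.call(rbind, anova_rows), alpha = alpha)
}
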
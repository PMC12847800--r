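# Independent brute-force oracles: naive double-loop implementations of the
# printed formulas, deliberately sharing no code with the package internals.

oracle_dist <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))

oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(sapply(mates, function(j) oracle_dist(x, i, j)))
    b <- Inf
    for (g in setdiff(unique(labels), own)) {
      pts <- which(labels == g)
      b <- min(b, mean(sapply(pts, function(j) oracle_dist(x, i, j))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean = mean(s), per_point = s)
}

oracle_ch <- function(x, labels) {
  N <- nrow(x)
  cl <- unique(labels)
  k <- length(cl)
  grand <- colMeans(x)
  trb <- 0
  trw <- 0
  for (g in cl) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    trb <- trb + nrow(xg) * sum((cg - grand)^2)
    for (i in seq_len(nrow(xg))) trw <- trw + sum((xg[i, ] - cg)^2)
  }
  (trb / trw) * ((N - k) / (k - 1))
}

oracle_db <- function(x, labels) {
  cl <- sort(unique(labels))
  k <- length(cl)
  cent <- lapply(cl, function(g) colMeans(x[labels == g, , drop = FALSE]))
  sig <- sapply(seq_len(k), function(ii) {
    xg <- x[labels == cl[ii], , drop = FALSE]
    mean(sapply(seq_len(nrow(xg)),
                function(i) sqrt(sum((xg[i, ] - cent[[ii]])^2))))
  })
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (sig[i] + sig[j]) / dij)
    }
    total <- total + worst
  }
  total / k
}

# densities and mean cross-subcluster affinities by naive loops
oracle_densities <- function(x, sigma) {
  n <- nrow(x)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rho[i] <- rho[i] + exp(-oracle_dist(x, i, j)^2 / (2 * sigma^2))
    }
  }
  rho
}

oracle_connectivity <- function(w, sc_a, sc_b) {
  tot <- 0
  for (i in sc_a) for (j in sc_b) tot <- tot + w[i, j]
  tot / (length(sc_a) * length(sc_b))
}

# per-sequence valid k-mer window count by explicit scan
oracle_valid_windows <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  count <- 0
  if (length(chars) < k) return(0)
  for (start in seq_len(length(chars) - k + 1)) {
    win <- chars[start:(start + k - 1)]
    if (all(win %in% c("A", "C", "G", "T"))) count <- count + 1
  }
  count
}

random_labeled_data <- function(n, k, dims = 3) {
  x <- matrix(rnorm(n * dims), nrow = n)
  labels <- sample.int(k, n, replace = TRUE)
  # guarantee every cluster non-empty
  labels[seq_len(k)] <- seq_len(k)
  list(x = x, labels = labels)
}

toy_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
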
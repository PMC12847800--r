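#' Count overlapping k-mers in a sequence set
#'
#' Slides a window of width `k` with step 1 over each sequence and counts
#' every window made up purely of A/C/G/T; windows containing any other
#' letter (N or IUPAC ambiguity codes) are skipped. The vocabulary is the
#' lexicographically sorted union of observed k-mers, or the full 4^k grid
#' when `full_vocab = TRUE` (column order is then the full sorted grid).
#'
#' @param s a [sequence_set()].
#' @param k k-mer length (default 5).
#' @param full_vocab use all 4^k k-mers as columns instead of observed ones.
#' @return an object of class `kmer_counts`: list with `counts` (n x m
#'   integer matrix, rows in input order), `vocabulary` (column k-mers) and
#'   `k`. Sequences shorter than `k` give an all-zero row with a warning.
#' @export
count_kmers <- function(s, k = 5L, full_vocab = FALSE) {
  stopifnot(inherits(s, "sequence_set"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  n <- nrow(s)
  if (any(s$length < k)) {
    warning(sprintf("%d sequence(s) shorter than k = %d: all-zero rows",
                    sum(s$length < k), k))
  }
  per_seq <- vector("list", n)
  for (i in seq_len(n)) {
    L <- s$length[i]
    if (L < k) {
      per_seq[[i]] <- integer(0)
      next
    }
    starts <- seq_len(L - k + 1L)
    windows <- substring(s$sequence[i], starts, starts + k - 1L)
    windows <- windows[!grepl("[^ACGT]", windows)]
    per_seq[[i]] <- table(windows)
  }
  vocabulary <- if (full_vocab) {
    sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                           stringsAsFactors = FALSE),
               1L, paste, collapse = ""))
  } else {
    sort(unique(unlist(lapply(per_seq, names), use.names = FALSE)))
  }
  counts <- matrix(0L, nrow = n, ncol = length(vocabulary),
                   dimnames = list(s$gene_symbol, vocabulary))
  for (i in seq_len(n)) {
    tb <- per_seq[[i]]
    if (length(tb)) {
      hit <- names(tb) %in% vocabulary
      counts[i, names(tb)[hit]] <- as.integer(tb[hit])
    }
  }
  structure(list(counts = counts, vocabulary = vocabulary, k = k),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> %d sequences x %d %d-mers (total count %s)\n",
              nrow(x$counts), ncol(x$counts), x$k,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Z-score standardize a k-mer count matrix
#'
#' Per-column standardization Z = (M - mu) / sigma with population
#' (divide-by-n) standard deviation, the convention of the usual
#' feature-scaling step. Zero-variance columns are dropped; their indices
#' are the complement of `kept_columns`.
#'
#' @param mc a `kmer_counts` object or a plain numeric matrix (n >= 2 rows).
#' @return an object of class `std_matrix`: list with `z` (n x m' matrix),
#'   `column_means`, `column_sds` (of the kept columns) and `kept_columns`
#'   (indices into the source columns).
#' @export
standardize <- function(mc) {
  x <- if (inherits(mc, "kmer_counts")) mc$counts else as.matrix(mc)
  if (nrow(x) < 2L) stop("standardize requires at least 2 rows")
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  kept <- which(sds > 0)
  if (length(kept) == 0L) stop("all columns have zero variance")
  z <- sweep(sweep(x[, kept, drop = FALSE], 2L, mu[kept]), 2L, sds[kept], "/")
  structure(list(z = z, column_means = unname(mu[kept]),
                 column_sds = unname(sds[kept]), kept_columns = unname(kept)),
            class = "std_matrix")
}

#' @export
print.std_matrix <- function(x, ...) {
  cat(sprintf("<std_matrix> %d x %d (z-scored)\n", nrow(x$z), ncol(x$z)))
  invisible(x)
}

## Coerce the containers accepted by the clustering/validity functions to a
## plain numeric feature matrix.
as_feature_matrix <- function(x) {
  if (inherits(x, "std_matrix")) return(x$z)
  if (inherits(x, "kmer_counts")) return(x$counts)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Export a count or standardized matrix
#'
#' Writes either a dense CSV (`format = "csv"`) or a MatrixMarket sparse
#' file plus a sidecar `<path>.vocab.txt` with the column k-mers
#' (`format = "mtx"`).
#'
#' @param x a `kmer_counts` or `std_matrix` object.
#' @param path output file path.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
export_features <- function(x, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  m <- as_feature_matrix(x)
  if (format == "csv") {
    write.csv(as.data.frame(m), path, row.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    vocab <- if (inherits(x, "kmer_counts")) x$vocabulary else colnames(m)
    if (!is.null(vocab)) {
      writeLines(vocab, paste0(path, ".vocab.txt"))
    }
  }
  invisible(path)
}
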
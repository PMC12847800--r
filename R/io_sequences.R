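#' Construct a sequence set
#'
#' A `sequence_set` is an ordered collection of quality-controlled
#' nucleotide records: one gene symbol, an optional accession, and an
#' uppercase sequence over the DNA alphabet (IUPAC ambiguity letters
#' permitted). It is represented as a data frame with columns
#' `gene_symbol`, `accession`, `sequence`, `length` plus a `provenance`
#' attribute.
#'
#' @param gene_symbol character vector of non-empty gene symbols.
#' @param accession character vector of accessions (may be empty strings).
#' @param sequence character vector of nucleotide sequences (uppercased).
#' @param provenance free-text source label.
#' @return an object of class `sequence_set`.
#' @export
sequence_set <- function(gene_symbol, accession = rep("", length(gene_symbol)),
                         sequence, provenance = "") {
  gene_symbol <- as.character(gene_symbol)
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(gene_symbol))) {
    stop("gene_symbol must be non-empty for every record")
  }
  if (any(grepl("\\s", sequence))) {
    stop("sequences must not contain whitespace")
  }
  df <- data.frame(
    gene_symbol = gene_symbol,
    accession = accession,
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("sequence_set", "data.frame"),
            provenance = provenance)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %d records (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  if (nrow(x) > 0) {
    cat(sprintf("  lengths: %d..%d bases\n", min(x$length), max(x$length)))
  }
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Headers are parsed as `>symbol|accession description`: text after the
#' first whitespace is dropped, then the remaining token is split on the
#' first `'|'` into gene symbol and accession; without a `'|'` the whole
#' token is the gene symbol and the accession is empty. Multi-line bodies
#' are concatenated and uppercased.
#'
#' @param path path to a FASTA file.
#' @param provenance source label stored on the result; defaults to `path`.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, provenance = path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA: sequence data before any '>' header in ", path)
  }
  is_hdr <- startsWith(lines, ">")
  rec_id <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  bodies <- vapply(split(lines[!is_hdr], factor(rec_id[!is_hdr],
                                                levels = seq_along(headers))),
                   function(b) paste(b, collapse = ""), character(1))
  empty <- !nzchar(bodies)
  if (any(empty)) {
    stop("malformed FASTA: empty sequence body for header '",
         headers[which(empty)[1]], "'")
  }
  token <- sub("\\s.*$", "", headers)
  has_bar <- grepl("|", token, fixed = TRUE)
  symbol <- ifelse(has_bar, sub("\\|.*$", "", token), token)
  acc <- ifelse(has_bar, sub("^[^|]*\\|", "", token), "")
  sequence_set(symbol, acc, bodies, provenance = provenance)
}

#' Write a sequence set to FASTA
#'
#' Inverse of [read_fasta()]: headers are `>symbol|accession` (or
#' `>symbol` when the accession is empty), bodies wrapped at `width`.
#'
#' @param s a [sequence_set()].
#' @param path output file path.
#' @param width line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(s, path, width = 70L) {
  stopifnot(inherits(s, "sequence_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(s))) {
    hdr <- if (nzchar(s$accession[i])) {
      paste0(">", s$gene_symbol[i], "|", s$accession[i])
    } else {
      paste0(">", s$gene_symbol[i])
    }
    writeLines(hdr, con)
    seq_i <- s$sequence[i]
    starts <- seq(1L, nchar(seq_i), by = width)
    writeLines(substring(seq_i, starts, pmin(starts + width - 1L, nchar(seq_i))),
               con)
  }
  invisible(path)
}

#' Read sequences from a CSV/TSV table
#'
#' Expects columns `gene_symbol`, `accession`, `sequence`. The delimiter is
#' inferred from the file extension (`.tsv`/`.tab` use tab, anything else
#' comma) unless `sep` is given.
#'
#' @param path input table path.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return a [sequence_set()].
#' @export
read_sequence_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "sequence")
  if (!all(need %in% names(df))) {
    stop("table must have columns gene_symbol and sequence (accession optional)")
  }
  acc <- if ("accession" %in% names(df)) df$accession else rep("", nrow(df))
  acc[is.na(acc)] <- ""
  sequence_set(df$gene_symbol, acc, df$sequence, provenance = path)
}

#' Deduplicate a sequence set
#'
#' Keeps the first occurrence of each (gene_symbol, accession) key and drops
#' later ones; relative order of survivors is preserved. The number of
#' dropped records is reported via `message()`.
#'
#' @param s a [sequence_set()].
#' @return the deduplicated [sequence_set()].
#' @export
deduplicate <- function(s) {
  stopifnot(inherits(s, "sequence_set"))
  key <- paste(s$gene_symbol, s$accession, sep = "\r")
  keep <- !duplicated(key)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("deduplicate: dropped %d duplicate record(s)", n_drop))
  }
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(s), provenance = attr(s, "provenance"))
}

#' Quality-filter a sequence set
#'
#' Removes records shorter than `min_length` bases and records whose
#' sequence is more than `max_n_frac` ambiguous `'N'` content (treated as
#' incomplete). Order is preserved.
#'
#' @param s a [sequence_set()].
#' @param min_length minimum sequence length in bases (default 1000).
#' @param max_n_frac maximum tolerated fraction of `'N'` characters.
#' @return the filtered [sequence_set()]; a warning is raised if no record
#'   survives.
#' @export
filter_quality <- function(s, min_length = 1000L, max_n_frac = 0.5) {
  stopifnot(inherits(s, "sequence_set"))
  if (min_length < 1) stop("min_length must be >= 1")
  n_count <- nchar(gsub("[^N]", "", s$sequence))
  frac_n <- ifelse(s$length > 0, n_count / s$length, 1)
  keep <- s$length >= min_length & frac_n <= max_n_frac
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0 && nrow(s) > 0) {
    warning("filter_quality: all records removed")
  }
  structure(out, class = class(s), provenance = attr(s, "provenance"))
}
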
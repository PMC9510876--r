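# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# per-base flattening oracle: label every base of a gene with the set of
# transcripts covering it, then merge maximal runs of identical non-empty
# support
oracle_flatten <- function(exons) {
  hi <- max(exons$end)
  labels <- character(hi)
  for (b in seq_len(hi)) {
    cov <- exons$transcript_id[exons$start <= (b - 1) & exons$end >= b]
    labels[b] <- paste(sort(unique(cov)), collapse = "+")
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values != ""
  tibble::tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    transcripts = runs$values[keep]
  )
}

# random single-gene annotation: <= 5 transcripts drawn as subsets of <= 8
# elementary exons separated by gaps of >= 1
random_gene <- function(gene = "gX", max_tx = 5, max_exons = 8) {
  n_ex <- sample(2:max_exons, 1)
  widths <- sample(5:40, n_ex, replace = TRUE)
  gaps <- sample(1:30, n_ex, replace = TRUE)
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_ex)]
  ends <- starts + widths
  n_tx <- sample(1:max_tx, 1)
  rows <- list()
  for (t in seq_len(n_tx)) {
    pick <- sort(sample(seq_len(n_ex), sample(seq_len(n_ex), 1)))
    rows[[t]] <- tibble::tibble(
      gene_id = gene, transcript_id = sprintf("%s_t%d", gene, t),
      contig = "chr1", strand = "+",
      start = starts[pick], end = ends[pick]
    )
  }
  dplyr::bind_rows(rows)
}

# pooled-variance two-sample t from its textbook definition
oracle_pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

# exhaustive 4-mer scan for the UWAA motif on the U alphabet
oracle_scan <- function(sequence) {
  s <- chartr("tT", "uU", toupper(sequence))
  s <- gsub("T", "U", s, fixed = TRUE)
  n <- nchar(s)
  hits <- integer(0)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      if (substr(s, i, i + 3) %in% c("UAAA", "UUAA")) {
        hits <- c(hits, i - 1L)
      }
    }
  }
  hits
}

# random RNA sequence (uniform base composition)
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
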
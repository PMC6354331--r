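# Independent brute-force oracles used across the suite.

# Hypergeometric tail/pmf by exhaustive enumeration of all C(N, n) draws:
# items 1..K are "marked"; count marked items in every possible draw.
enum_hyper <- function(k, K, n, N, tail = c("upper", "pmf")) {
  tail <- match.arg(tail)
  if (n == 0) {
    hits <- 0L
  } else {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)
  }
  if (tail == "pmf") mean(hits == k) else mean(hits >= k)
}

# Spearman distance by explicit average-rank-via-sorting + textbook Pearson.
oracle_spearman_distance <- function(mat) {
  avg_rank <- function(x) {
    o <- order(x)
    r <- numeric(length(x))
    r[o] <- seq_along(x)
    # average ranks over tied values
    for (v in unique(x)) {
      idx <- which(x == v)
      r[idx] <- mean(r[idx])
    }
    r
  }
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  ranks <- t(apply(mat, 1L, avg_rank))
  m <- nrow(mat)
  d <- matrix(0, m, m, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) d[i, j] <- 1 - pearson(ranks[i, ], ranks[j, ])
  }
  d
}

# Small hand-built annotation corpus used by several suites:
# 2 diseases, 6 PMIDs (5 in the universe), gene 11 disease-A-specific,
# gene 22 shared, gene 33 only on the out-of-universe article.
tiny_corpus <- function() {
  gene_records <- data.frame(
    tax_id = 9606L,
    gene_id = c(11L, 11L, 22L, 22L, 22L, 33L),
    pmid = c(1L, 2L, 2L, 4L, 5L, 6L))
  disease_records <- data.frame(
    pmid = c(1L, 2L, 3L, 4L, 5L),
    disease_id = c("D000001", "D000001", "D000001", "D000002", "D000002"))
  build_corpus(gene_records, disease_records, c("D000001", "D000002"))
}

# write a throwaway TSV fixture file
write_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
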
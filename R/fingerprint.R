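#' Hypergeometric probability mass for a 2x2 literature contingency table
#'
#' For a gene appearing in `K` of `N` articles and a disease annotated on `n`
#' of them, the probability that exactly `k` articles mention both, under
#' sampling without replacement:
#' \deqn{P = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}}
#' Computed on the log-choose scale for numerical stability.
#'
#' @param k Articles mentioning both gene and disease (vectorised).
#' @param K Articles mentioning the gene.
#' @param n Articles annotated with the disease.
#' @param N Total articles in the universe.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

check_counts <- function(k, K, n, N) {
  if (any(!is.finite(k)) || any(!is.finite(K)) ||
      any(!is.finite(n)) || any(!is.finite(N))) {
    stop("counts must be finite")
  }
  if (any(k != floor(k) | K != floor(K) | n != floor(n) | N != floor(N))) {
    stop("counts must be integers")
  }
  if (any(K > N) || any(n > N) || any(k < 0) || any(K < 0) || any(n < 0)) {
    stop("counts violate K <= N, n <= N, nonnegativity")
  }
  bad <- k > pmin(K, n) | k < pmax(0, n + K - N)
  if (any(bad)) {
    stop("k outside hypergeometric support [max(0, n+K-N), min(K, n)]: k=",
         paste(k[bad], collapse = ","))
  }
  invisible(TRUE)
}

#' Enrichment p-value for gene/disease literature co-occurrence
#'
#' Over-representation is assessed with the upper tail of the hypergeometric
#' distribution, `P(X >= k)` (default). `tail = "pmf"` returns the point mass
#' `P(X = k)` instead, for literal reproduction of the tabulated formula.
#'
#' @inheritParams hypergeom_pmf
#' @param tail `"upper"` (default) or `"pmf"`.
#' @return p-value in (0, 1\].
#' @export
enrichment_pvalue <- function(k, K, n, N, tail = c("upper", "pmf")) {
  tail <- match.arg(tail)
  check_counts(k, K, n, N)
  if (tail == "pmf") return(hypergeom_pmf(k, K, n, N))
  mapply(function(k1, K1, n1, N1) {
    hi <- min(K1, n1)
    if (k1 <= max(0, n1 + K1 - N1)) return(1)
    sum(hypergeom_pmf(k1:hi, K1, n1, N1))
  }, k, K, n, N)
}

#' Build the gene fingerprint of one disease
#'
#' Scores every gene co-occurring at least once with the disease's articles
#' (k >= 1; genes never directly co-mentioned are excluded so indirect
#' relations cannot propagate noise into the profile) and weights it by the
#' negative log enrichment p-value.
#'
#' @param corpus An `annotation_corpus` from [build_corpus()].
#' @param disease_id Disease in the corpus universe.
#' @param p_cutoff Optional p-value cutoff applied to entries (strict `<=`
#'   is not used; entries with `p_value > p_cutoff` are dropped). `NULL`
#'   (default) keeps all co-occurring genes.
#' @param tail Tail convention passed to [enrichment_pvalue()].
#' @param log_base Base of the log transform for weights (default 10).
#' @return A data.frame of class `gene_fingerprint` with columns `gene_id`,
#'   `k`, `K`, `n`, `N`, `p_value`, `weight` and attribute `disease_id`.
#' @export
build_fingerprint <- function(corpus, disease_id, p_cutoff = NULL,
                              tail = "upper", log_base = 10) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!disease_id %in% corpus$disease_universe) {
    stop("disease not in corpus universe: ", disease_id)
  }
  d_pmids <- corpus$disease_to_pmids[[disease_id]]
  N <- corpus$n_universe
  n <- length(d_pmids)
  empty <- data.frame(gene_id = integer(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      weight = numeric())
  if (n == 0L) {
    message("disease ", disease_id, " has no annotated articles; ",
            "empty fingerprint")
    return(new_fingerprint(empty, disease_id))
  }
  genes_on <- corpus$pmid_to_genes[as.character(d_pmids)]
  genes_on <- genes_on[!vapply(genes_on, is.null, logical(1))]
  if (length(genes_on) == 0L) return(new_fingerprint(empty, disease_id))
  tab <- table(unlist(genes_on, use.names = FALSE))
  gene_id <- as.integer(names(tab))
  k <- as.integer(tab)
  K <- vapply(as.character(gene_id),
              function(g) length(corpus$gene_to_pmids[[g]]), integer(1))
  p <- enrichment_pvalue(k, K, n, N, tail = tail)
  floored <- p < .Machine$double.xmin
  if (any(floored)) {
    message(sum(floored), " p-value(s) underflowed; floored at ",
            .Machine$double.xmin)
    p[floored] <- .Machine$double.xmin
  }
  fp <- data.frame(gene_id = gene_id, k = k, K = K, n = n, N = N,
                   p_value = p, weight = -log(p, base = log_base))
  if (!is.null(p_cutoff)) fp <- fp[fp$p_value <= p_cutoff, , drop = FALSE]
  fp <- fp[order(fp$gene_id), , drop = FALSE]
  rownames(fp) <- NULL
  new_fingerprint(fp, disease_id)
}

new_fingerprint <- function(df, disease_id) {
  attr(df, "disease_id") <- disease_id
  class(df) <- c("gene_fingerprint", "data.frame")
  df
}

#' @export
print.gene_fingerprint <- function(x, ...) {
  cat("gene_fingerprint for", attr(x, "disease_id"), "-", nrow(x),
      "genes\n")
  NextMethod()
}

#' Fingerprints for every disease in the universe
#'
#' @inheritParams build_fingerprint
#' @return Named list of `gene_fingerprint` objects keyed by disease id.
#' @export
build_all_fingerprints <- function(corpus, p_cutoff = NULL, tail = "upper",
                                   log_base = 10) {
  fps <- lapply(corpus$disease_universe, function(d) {
    suppressMessages(build_fingerprint(corpus, d, p_cutoff = p_cutoff,
                                       tail = tail, log_base = log_base))
  })
  names(fps) <- corpus$disease_universe
  fps
}

#' Select highly relevant genes from a fingerprint
#'
#' @param fp A `gene_fingerprint`.
#' @param cutoff p-value cutoff in (0, 1).
#' @param strict Use strict inequality `p < cutoff` (default); `FALSE` uses
#'   `p <= cutoff`.
#' @return Sorted integer vector of gene ids.
#' @export
select_highly_relevant_genes <- function(fp, cutoff, strict = TRUE) {
  stopifnot(inherits(fp, "gene_fingerprint"),
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  keep <- if (strict) fp$p_value < cutoff else fp$p_value <= cutoff
  sort(fp$gene_id[keep])
}

#' Serialise fingerprints to TSV
#'
#' One row per (disease, gene) with the full contingency counts.
#'
#' @param fps Named list of `gene_fingerprint` objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_fingerprints <- function(fps, path) {
  rows <- lapply(names(fps), function(d) {
    fp <- fps[[d]]
    if (nrow(fp) == 0L) return(NULL)
    cbind(disease_id = d, as.data.frame(fp))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(disease_id = character(), gene_id = integer(),
                     k = integer(), K = integer(), n = integer(),
                     N = integer(), p_value = numeric(), weight = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints serialised by [write_fingerprints()]
#'
#' @param path TSV path.
#' @return Named list of `gene_fingerprint` objects.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, sep = "\t",
                          colClasses = c(disease_id = "character"))
  fps <- lapply(split(df[, -1L], df$disease_id), function(x) {
    rownames(x) <- NULL
    x
  })
  mapply(new_fingerprint, fps, names(fps), SIMPLIFY = FALSE)
}
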
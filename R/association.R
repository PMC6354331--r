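#' Spearman correlation distance between disease rows
#'
#' `d(a, b) = 1 - rho(a, b)` where `rho` is the Spearman rank correlation
#' (Pearson correlation of average ranks); distances lie in \[0, 2\].
#'
#' @param mat Numeric matrix with >= 3 rows (diseases) and non-constant rows.
#' @return Square symmetric matrix with zero diagonal, dimnames taken from
#'   the rownames of `mat`.
#' @export
spearman_distance <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3L)
  const <- apply(mat, 1L, function(r) diff(range(r)) == 0)
  if (any(const)) {
    stop("constant row(s) have undefined rank correlation: ",
         paste(rownames(mat)[const], collapse = ", "))
  }
  rho <- stats::cor(t(mat), method = "spearman")
  d <- 1 - rho
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Spectral clustering of a disease-disease distance matrix
#'
#' Builds a Gaussian affinity `A = exp(-d^2 / (2 sigma^2))` with `sigma` set
#' to the median off-diagonal distance, embeds the diseases into the top `k`
#' eigenvectors of the symmetric normalised affinity
#' `D^{-1/2} A D^{-1/2}`, row-normalises the embedding and partitions it with
#' seeded k-means (multiple restarts, best within-cluster sum of squares
#' wins). Labels are canonicalised by first appearance, so the result is
#' deterministic given (`dist`, `k`, `seed`) and equivariant under permuting
#' the disease order.
#'
#' @param dist Square symmetric distance matrix with dimnames.
#' @param k Number of clusters, `1 <= k <= nrow(dist)`.
#' @param seed Integer seed driving the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return Object of class `cluster_assignment`: list with `ids`, `labels`
#'   (integers in `[0, k)`), `k`, `seed`.
#' @export
spectral_cluster <- function(dist, k, seed = 1L, nstart = 50L) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dist)))
  m <- nrow(dist)
  if (k < 1L || k > m) stop("k = ", k, " out of range [1, ", m, "]")
  if (k == 1L) {
    return(new_cluster_assignment(ids, rep.int(0L, m), k, seed))
  }
  off <- dist[upper.tri(dist)]
  sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma <= 0) {
    warning("degenerate distance matrix (median off-diagonal distance 0); ",
            "using sigma = 1")
    sigma <- 1
  }
  A <- exp(-dist^2 / (2 * sigma^2))
  diag(A) <- 0
  deg <- rowSums(A)
  if (any(deg <= .Machine$double.eps)) {
    warning("isolated node(s) in affinity graph; regularising degrees")
    deg <- deg + .Machine$double.eps
  }
  Dhalf <- 1 / sqrt(deg)
  L <- Dhalf * t(Dhalf * A)        # D^{-1/2} A D^{-1/2}, symmetric
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  emb <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  norms[norms == 0] <- 1
  emb <- emb / norms
  # fix eigenvector signs for run-to-run reproducibility
  for (j in seq_len(k)) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  km <- with_seed(seed,
    stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100L))
  new_cluster_assignment(ids, canonical_labels(km$cluster), k, seed)
}

canonical_labels <- function(labels) {
  first <- unique(labels)
  match(labels, first) - 1L
}

new_cluster_assignment <- function(ids, labels, k, seed) {
  structure(list(ids = ids, labels = labels, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$ids), "diseases in", x$k,
      "clusters (seed", paste0(x$seed, ")"), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Call diseases related to a query from a cluster assignment
#'
#' Relatedness is same-cluster membership: every disease sharing the query's
#' cluster label, excluding the query itself.
#'
#' @param assign A `cluster_assignment`.
#' @param query_id Disease id present in the assignment.
#' @param parameters Optional named list echoed into the result.
#' @return Object of class `association_result`: list with `query_id`,
#'   `related` (sorted character vector), `assignment`, `parameters`.
#' @export
call_related <- function(assign, query_id, parameters = list()) {
  stopifnot(inherits(assign, "cluster_assignment"))
  i <- match(query_id, assign$ids)
  if (is.na(i)) stop("query disease not in clustering: ", query_id)
  same <- assign$ids[assign$labels == assign$labels[i]]
  structure(list(query_id = query_id,
                 related = sort(setdiff(same, query_id)),
                 assignment = assign,
                 parameters = parameters),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result: query", x$query_id, "-", length(x$related),
      "related disease(s)\n")
  if (length(x$related)) cat(" ", paste(x$related, collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the fingerprint-to-clustering pipeline with its
#' default. `r` overrides the energy rule with an explicit rank when set.
#'
#' @param min_genes Minimum fingerprint size for a disease row.
#' @param p_cutoff Optional fingerprint p-value cutoff (`NULL` = keep all
#'   co-occurring genes).
#' @param p_tail Tail convention for enrichment p-values.
#' @param log_base Base of the weight log transform.
#' @param energy_target Energy fraction for rank selection.
#' @param energy_mode `"sum"` or `"sum_of_squares"`.
#' @param r Explicit rank (`NULL` = use the energy rule).
#' @param k Number of spectral clusters.
#' @param seed Seed for the clustering restarts.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_genes = 1L, p_cutoff = NULL,
                            p_tail = "upper", log_base = 10,
                            energy_target = 0.95, energy_mode = "sum",
                            r = NULL, k = 2L, seed = 1L) {
  stopifnot(min_genes >= 1L, k >= 1L,
            energy_target > 0, energy_target <= 1,
            energy_mode %in% c("sum", "sum_of_squares"),
            p_tail %in% c("upper", "pmf"))
  structure(list(min_genes = as.integer(min_genes), p_cutoff = p_cutoff,
                 p_tail = p_tail, log_base = log_base,
                 energy_target = energy_target, energy_mode = energy_mode,
                 r = r, k = as.integer(k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full fingerprint-to-association pipeline
#'
#' Composes fingerprint construction, matrix assembly and filtering, low-rank
#' approximation, Spearman distance, spectral clustering and the relatedness
#' call for a query disease. All parameters and checksums of the key
#' intermediates are recorded on the result for provenance.
#'
#' @param corpus An `annotation_corpus` (carries the disease universe).
#' @param query_id Query disease id.
#' @param config A [pipeline_config()].
#' @return `association_result` with extra fields `distance`, `model`,
#'   `matrix`, `checksums`.
#' @export
run_pipeline <- function(corpus, query_id, config = pipeline_config()) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(config, "pipeline_config"))
  fps <- build_all_fingerprints(corpus, p_cutoff = config$p_cutoff,
                                tail = config$p_tail,
                                log_base = config$log_base)
  mat <- build_matrix(fps, min_genes = config$min_genes)
  if (!query_id %in% rownames(mat)) {
    stop("query disease ", query_id, " was filtered out of the matrix ",
         "(min_genes = ", config$min_genes, ")")
  }
  model <- lowrank_fit(mat, config$energy_target, config$energy_mode)
  r <- if (!is.null(config$r)) as.integer(config$r) else model$rank_selected
  # full-rank reconstruction is the identity; skip it so floating-point
  # fuzz cannot perturb the exact-zero ties that Spearman ranks depend on
  approx <- if (r >= length(model$d)) mat else reconstruct(model, r)
  d <- spearman_distance(approx)
  assign <- spectral_cluster(d, k = config$k, seed = config$seed)
  params <- c(unclass(config), list(rank_used = r))
  res <- call_related(assign, query_id, parameters = params)
  res$distance <- d
  res$model <- model
  res$matrix <- mat
  res$checksums <- list(matrix = digest_num(mat), distance = digest_num(d))
  res
}

# order-stable checksum of a numeric matrix, for run metadata
digest_num <- function(x) {
  v <- c(dim(x), round(as.numeric(x), 10))
  sum(v * seq_along(v)) %% 1e9
}
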
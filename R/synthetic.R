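#' Specification of a synthetic literature corpus
#'
#' Describes a corpus of article annotations with planted disease clusters:
#' each cluster owns a pool of signature genes, each disease's articles draw
#' genes from its cluster pool with probability `pool_gene_prob` and from a
#' common background otherwise, and adjacent cluster pools share a fraction
#' `cross_pool_overlap` of genes (real disease families share genes across
#' groups).
#'
#' Defaults describe a small but realistic literature: 3 disease families of
#' 6 diseases, 40 signature genes per family with 20% shared between
#' neighbouring families, 200 background genes, 30-60 annotated articles per
#' disease, 2-5 gene mentions per article and an 80% chance that a mention
#' comes from the family pool.
#'
#' @param n_clusters Number of planted disease clusters.
#' @param diseases_per_cluster Diseases in each cluster.
#' @param pool_genes_per_cluster Signature-pool size per cluster.
#' @param background_genes Genes shared by all diseases.
#' @param pmids_per_disease Integer range (length 2) of articles per disease.
#' @param genes_per_pmid Integer range (length 2) of gene mentions per
#'   article.
#' @param pool_gene_prob Probability a mention comes from the cluster pool.
#' @param cross_pool_overlap Fraction of pool genes shared with the previous
#'   cluster, in \[0, 1).
#' @param seed Seed making generation fully deterministic.
#' @return Named list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 3L, diseases_per_cluster = 6L,
                           pool_genes_per_cluster = 40L,
                           background_genes = 200L,
                           pmids_per_disease = c(30L, 60L),
                           genes_per_pmid = c(2L, 5L),
                           pool_gene_prob = 0.8,
                           cross_pool_overlap = 0.2,
                           seed = 7L) {
  stopifnot(n_clusters >= 1L, diseases_per_cluster >= 1L,
            pool_genes_per_cluster >= 1L, background_genes >= 1L,
            length(pmids_per_disease) == 2L,
            pmids_per_disease[1] >= 1L,
            pmids_per_disease[1] <= pmids_per_disease[2],
            length(genes_per_pmid) == 2L, genes_per_pmid[1] >= 1L,
            genes_per_pmid[1] <= genes_per_pmid[2],
            pool_gene_prob > 0, pool_gene_prob <= 1,
            cross_pool_overlap >= 0, cross_pool_overlap < 1)
  if (pool_genes_per_cluster < genes_per_pmid[2] ||
      background_genes < genes_per_pmid[2]) {
    stop("infeasible spec: gene pools smaller than the maximum number of ",
         "gene mentions per article")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 diseases_per_cluster = as.integer(diseases_per_cluster),
                 pool_genes_per_cluster = as.integer(pool_genes_per_cluster),
                 background_genes = as.integer(background_genes),
                 pmids_per_disease = as.integer(pmids_per_disease),
                 genes_per_pmid = as.integer(genes_per_pmid),
                 pool_gene_prob = pool_gene_prob,
                 cross_pool_overlap = cross_pool_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic annotation corpus with planted clusters
#'
#' Disease ids use the reserved synthetic range `D9xxxxx` (never colliding
#' with real MeSH descriptor UIs) and are placed under the fictional tree
#' branch `C99`. Output is fully determined by `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_corpus` with elements `corpus` (an
#'   `annotation_corpus`), `truth` (list with `cluster_of`, `planted_genes`,
#'   `query_id`), `gene_records`, `disease_records`, `mesh_entries`, `spec`.
#' @export
generate <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_dis <- spec$n_clusters * spec$diseases_per_cluster
    disease_ids <- sprintf("D9%05d", seq_len(n_dis))
    cluster_of <- rep(seq_len(spec$n_clusters) - 1L,
                      each = spec$diseases_per_cluster)
    names(cluster_of) <- disease_ids

    # chained pools: each cluster inherits `shared` genes from the previous
    P <- spec$pool_genes_per_cluster
    shared <- as.integer(round(spec$cross_pool_overlap * P))
    pools <- vector("list", spec$n_clusters)
    next_gene <- 1L
    for (c in seq_len(spec$n_clusters)) {
      if (c == 1L || shared == 0L) {
        pool <- seq.int(next_gene, length.out = P)
        next_gene <- next_gene + P
      } else {
        inherited <- utils::tail(pools[[c - 1L]], shared)
        fresh <- seq.int(next_gene, length.out = P - shared)
        next_gene <- next_gene + P - shared
        pool <- c(inherited, fresh)
      }
      pools[[c]] <- pool
    }
    background <- seq.int(next_gene, length.out = spec$background_genes)

    pmid <- 100001L
    g_pmid <- integer(0); g_gene <- integer(0)
    d_pmid <- integer(0); d_dis <- character(0)
    for (i in seq_len(n_dis)) {
      pool <- pools[[cluster_of[i] + 1L]]
      n_articles <- sample(spec$pmids_per_disease[1]:spec$pmids_per_disease[2],
                           1L)
      for (a in seq_len(n_articles)) {
        g <- sample(spec$genes_per_pmid[1]:spec$genes_per_pmid[2], 1L)
        n_pool <- stats::rbinom(1L, g, spec$pool_gene_prob)
        genes <- c(if (n_pool > 0L) sample(pool, n_pool),
                   if (g - n_pool > 0L) sample(background, g - n_pool))
        g_pmid <- c(g_pmid, rep.int(pmid, length(genes)))
        g_gene <- c(g_gene, genes)
        d_pmid <- c(d_pmid, pmid)
        d_dis <- c(d_dis, disease_ids[i])
        pmid <- pmid + 1L
      }
    }

    gene_records <- unique(data.frame(tax_id = 9606L, gene_id = g_gene,
                                      pmid = g_pmid))
    gene_records <- gene_records[order(gene_records$gene_id,
                                       gene_records$pmid), ]
    rownames(gene_records) <- NULL
    disease_records <- data.frame(pmid = d_pmid, disease_id = d_dis)

    mesh_entries <- data.frame(
      disease_id = disease_ids,
      name = sprintf("Synthetic disease %d", seq_len(n_dis)),
      tree_numbers = sprintf("C99.%03d.%03d", cluster_of + 1L,
                             seq_len(n_dis)))

    corpus <- build_corpus(gene_records, disease_records, disease_ids)
    truth <- list(cluster_of = cluster_of,
                  planted_genes = stats::setNames(
                    lapply(seq_len(n_dis),
                           function(i) pools[[cluster_of[i] + 1L]]),
                    disease_ids),
                  query_id = disease_ids[1L])
    structure(list(corpus = corpus, truth = truth,
                   gene_records = gene_records,
                   disease_records = disease_records,
                   mesh_entries = mesh_entries, spec = spec),
              class = "synthetic_corpus")
  })
}

#' Derive expert labels from the planted truth
#'
#' Non-query diseases sharing the query's planted cluster are `related`, the
#' rest `non_related`; a seeded random subset of size
#' `round(undefined_fraction * (n - 1))` is then relabelled `undefined`.
#'
#' @param truth The `truth` element of a [generate()] result.
#' @param query_id Query disease (default: the truth's designated query).
#' @param undefined_fraction Fraction of non-query diseases hidden as
#'   undefined (default 0.2).
#' @param seed Seed for the undefined subset.
#' @return An `expert_labels` object.
#' @export
make_labels <- function(truth, query_id = truth$query_id,
                        undefined_fraction = 0.2, seed = 1L) {
  stopifnot(query_id %in% names(truth$cluster_of),
            undefined_fraction >= 0, undefined_fraction <= 1)
  others <- setdiff(names(truth$cluster_of), query_id)
  lab <- ifelse(truth$cluster_of[others] == truth$cluster_of[[query_id]],
                "related", "non_related")
  n_undef <- round(undefined_fraction * length(others))
  if (n_undef > 0L) {
    undef <- with_seed(seed, sample(others, n_undef))
    lab[match(undef, others)] <- "undefined"
  }
  expert_labels(query_id,
                data.frame(disease_id = others, label = unname(lab)))
}

#' Write a synthetic corpus to its on-disk exchange formats
#'
#' Emits `gene2pubmed.tsv`, `disease2pubmed.tsv`, `mesh_tree.tsv`,
#' `labels.tsv` and `truth.json` into `dir`; the files round-trip through
#' the corpus readers unchanged.
#'
#' @param gen A `synthetic_corpus` from [generate()].
#' @param dir Output directory (created if absent).
#' @param labels Optional `expert_labels` to write (default: derived with
#'   [make_labels()] at its defaults, seeded by the spec seed).
#' @return Invisibly, named vector of file paths.
#' @export
write_synthetic <- function(gen, dir, labels = NULL) {
  stopifnot(inherits(gen, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_corpus(gen$corpus, dir)
  mesh_path <- file.path(dir, "mesh_tree.tsv")
  utils::write.table(gen$mesh_entries, mesh_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(labels)) {
    labels <- make_labels(gen$truth, seed = gen$spec$seed)
  }
  labels_path <- file.path(dir, "labels.tsv")
  write_labels(labels, labels_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(cluster_of = as.list(gen$truth$cluster_of),
         planted_genes = gen$truth$planted_genes,
         query_id = gen$truth$query_id),
    truth_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mesh_tree = mesh_path, labels = labels_path,
              truth = truth_path))
}
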
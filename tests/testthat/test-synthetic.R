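test_that("synthetic_spec validates its fields", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(pool_gene_prob = 0), "pool_gene_prob")
  expect_error(synthetic_spec(cross_pool_overlap = 1))
  expect_error(synthetic_spec(pool_genes_per_cluster = 3,
                              genes_per_pmid = c(2, 5)), "infeasible")
})

test_that("pure pool sampling keeps fingerprints inside the cluster pool", {
  gen <- generate(synthetic_spec(n_clusters = 2L, diseases_per_cluster = 3L,
                                 pool_genes_per_cluster = 10L,
                                 background_genes = 20L,
                                 pmids_per_disease = c(5L, 10L),
                                 pool_gene_prob = 1, cross_pool_overlap = 0,
                                 seed = 2L))
  for (d in names(gen$truth$cluster_of)) {
    fp <- build_fingerprint(gen$corpus, d)
    expect_true(all(fp$gene_id %in% gen$truth$planted_genes[[d]]))
  }
})

test_that("generation is deterministic and leaves the global RNG alone", {
  spec <- synthetic_spec(n_clusters = 2L, diseases_per_cluster = 3L,
                         pool_genes_per_cluster = 10L, background_genes = 20L,
                         pmids_per_disease = c(5L, 8L), seed = 42L)
  set.seed(1); before <- runif(1)
  set.seed(1)
  g1 <- generate(spec)
  after <- runif(1)
  expect_identical(before, after)  # global stream untouched
  g2 <- generate(spec)
  expect_identical(g1$gene_records, g2$gene_records)
  expect_identical(g1$disease_records, g2$disease_records)

  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic(g1, d1)
  write_synthetic(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("adjacent cluster pools share the requested overlap", {
  spec <- synthetic_spec(cross_pool_overlap = 0.2,
                         pool_genes_per_cluster = 40L)
  gen <- generate(spec)
  pools <- unique(gen$truth$planted_genes)  # one pool per cluster
  expect_length(pools, spec$n_clusters)
  expect_length(intersect(pools[[1]], pools[[2]]), 8L)
  expect_length(intersect(pools[[2]], pools[[3]]), 8L)
  expect_length(intersect(pools[[1]], pools[[3]]), 0L)
})

test_that("synthetic ids avoid real vocabularies and map to a mesh branch", {
  gen <- generate(synthetic_spec(n_clusters = 2L, diseases_per_cluster = 3L,
                                 pool_genes_per_cluster = 10L,
                                 background_genes = 20L,
                                 pmids_per_disease = c(5L, 8L), seed = 3L))
  expect_true(all(grepl("^D9\\d{5}$", gen$corpus$disease_universe)))
  expect_setequal(select_branch(gen$mesh_entries, "C99"),
                  gen$corpus$disease_universe)
})

test_that("make_labels partitions by planted cluster and hides a fraction", {
  gen <- generate(synthetic_spec(seed = 5L))
  q <- gen$truth$query_id

  full <- make_labels(gen$truth, undefined_fraction = 0, seed = 1)
  expect_equal(nrow(full$labels), length(gen$truth$cluster_of) - 1L)
  mates <- names(gen$truth$cluster_of)[
    gen$truth$cluster_of == gen$truth$cluster_of[[q]]]
  expect_setequal(label_related <- with(full$labels,
                                        disease_id[label == "related"]),
                  setdiff(mates, q))

  all_undef <- make_labels(gen$truth, undefined_fraction = 1, seed = 1)
  expect_true(all(all_undef$labels$label == "undefined"))

  part <- make_labels(gen$truth, undefined_fraction = 0.3, seed = 1)
  expect_equal(sum(part$labels$label == "undefined"),
               round(0.3 * (length(gen$truth$cluster_of) - 1L)))
})

test_that("planted genes are enriched over background across seeds", {
  # weight convention of the primary matrix: a gene absent from the
  # fingerprint carries weight 0
  for (s in 1:10) {
    gen <- generate(synthetic_spec(pool_gene_prob = 0.5, seed = s))
    all_planted <- unique(unlist(gen$truth$planted_genes))
    for (d in names(gen$truth$cluster_of)) {
      fp <- build_fingerprint(gen$corpus, d)
      w <- setNames(fp$weight, fp$gene_id)
      weight_of <- function(g) {
        out <- w[as.character(g)]
        out[is.na(out)] <- 0
        out
      }
      background <- setdiff(as.integer(names(gen$corpus$gene_to_pmids)),
                            all_planted)
      expect_gt(median(weight_of(gen$truth$planted_genes[[d]])),
                median(weight_of(background)))
    }
  }
})

test_that("written synthetic corpora round-trip through corpus_io", {
  gen <- generate(synthetic_spec(n_clusters = 2L, diseases_per_cluster = 3L,
                                 pool_genes_per_cluster = 10L,
                                 background_genes = 20L,
                                 pmids_per_disease = c(5L, 8L), seed = 9L))
  dir <- tempfile()
  write_synthetic(gen, dir)
  gr <- read_gene2pubmed(file.path(dir, "gene2pubmed.tsv"))
  dr <- read_disease2pubmed(file.path(dir, "disease2pubmed.tsv"))
  universe <- select_branch(read_mesh_tree(file.path(dir, "mesh_tree.tsv")),
                            "C99")
  again <- build_corpus(gr, dr, universe)
  expect_identical(again$pmid_to_genes, gen$corpus$pmid_to_genes)
  expect_identical(again$disease_to_pmids, gen$corpus$disease_to_pmids)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$query_id, gen$truth$query_id)
})
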
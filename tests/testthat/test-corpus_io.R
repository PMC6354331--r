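test_that("read_gene2pubmed filters by taxon, de-duplicates, skips headers", {
  f <- write_fixture(c("#Format: tax_id GeneID PubMed_ID",
                       "9606\t10\t100",
                       "10090\t20\t101",
                       "9606\t30\t102",
                       "9606\t10\t100"))
  recs <- read_gene2pubmed(f, tax_id = 9606)
  expect_equal(recs$gene_id, c(10L, 30L))
  expect_equal(recs$pmid, c(100L, 102L))

  hdr_only <- write_fixture("#Format: tax_id GeneID PubMed_ID")
  expect_equal(nrow(read_gene2pubmed(hdr_only)), 0L)

  expect_warning(read_gene2pubmed(f, tax_id = 7227), "no gene2pubmed records")
})

test_that("read_gene2pubmed reports malformed lines by number", {
  f <- write_fixture(c("9606\t10\t100", "9606\tnot_a_gene\t101"))
  expect_error(read_gene2pubmed(f), "line 2")
  f2 <- write_fixture(c("9606\t10\t100", "9606\t11"))
  expect_error(read_gene2pubmed(f2), "line 2")
})

test_that("read_disease2pubmed de-duplicates and validates PMIDs", {
  f <- write_fixture(c("1\tD029424", "2\tD008171", "2\tD008171", "3\tD029424"))
  recs <- read_disease2pubmed(f)
  expect_equal(nrow(recs), 3L)
  expect_true("D029424" %in% recs$disease_id)

  empty <- write_fixture(character(0))
  expect_equal(nrow(read_disease2pubmed(empty)), 0L)

  bad <- write_fixture(c("1\tD029424", "x\tD008171"))
  expect_error(read_disease2pubmed(bad), "line 2")
})

test_that("extract_mesh_from_pubmed_xml pulls (PMID, UI) pairs", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<PubmedArticleSet>",
    " <PubmedArticle><MedlineCitation>",
    "  <PMID>101</PMID>",
    "  <MeshHeadingList>",
    '   <MeshHeading><DescriptorName UI="D029424">COPD</DescriptorName></MeshHeading>',
    '   <MeshHeading><DescriptorName UI="D008171">Lung Diseases</DescriptorName></MeshHeading>',
    '   <MeshHeading><DescriptorName UI="D029424">COPD</DescriptorName></MeshHeading>',
    "  </MeshHeadingList>",
    " </MedlineCitation></PubmedArticle>",
    " <PubmedArticle><MedlineCitation>",
    "  <PMID>102</PMID>",
    " </MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), xml)
  recs <- extract_mesh_from_pubmed_xml(xml)
  expect_equal(nrow(recs), 2L)  # duplicate descriptor collapsed, cite 2 empty
  expect_setequal(recs$disease_id, c("D029424", "D008171"))
  expect_true(all(recs$pmid == 101L))
})

test_that("extract_mesh_from_pubmed_xml warns on missing UI, errors on bad XML", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<Set><MedlineCitation><PMID>7</PMID><MeshHeadingList>",
    "<MeshHeading><DescriptorName>no ui</DescriptorName></MeshHeading>",
    '<MeshHeading><DescriptorName UI="D000001">ok</DescriptorName></MeshHeading>',
    "</MeshHeadingList></MedlineCitation></Set>"), xml)
  expect_warning(recs <- extract_mesh_from_pubmed_xml(xml), "without UI")
  expect_equal(recs$disease_id, "D000001")

  broken <- tempfile(fileext = ".xml")
  writeLines("<unclosed>", broken)
  expect_error(extract_mesh_from_pubmed_xml(broken))
})

test_that("select_branch uses prefix semantics with segment boundaries", {
  entries <- data.frame(
    disease_id = c("A", "B", "C", "E"),
    name = letters[1:4],
    tree_numbers = c("C08.381", "C08.381.495", "C01.100", "C08.3811"))
  expect_equal(select_branch(entries, "C08.381"), c("A", "B"))
  expect_equal(select_branch(entries, "C08.381.495"), "B")
  # "C08.3811" must not match branch "C08.381"
  expect_false("E" %in% select_branch(entries, "C08.381"))
  expect_warning(out <- select_branch(entries, "C99"), "no descriptors")
  expect_length(out, 0L)
  # order independence
  shuf <- entries[c(3, 1, 4, 2), ]
  expect_equal(select_branch(shuf, "C08.381"),
               select_branch(entries, "C08.381"))
  # multi-tree descriptors match on any code
  multi <- data.frame(disease_id = "M", name = "m",
                      tree_numbers = "C01.100;C08.381.200")
  expect_equal(select_branch(multi, "C08.381"), "M")
})

test_that("build_corpus restricts to the universe and counts N correctly", {
  corpus <- tiny_corpus()
  expect_equal(corpus$n_universe, 5L)           # PMIDs 1..5, not 6
  expect_false("33" %in% names(corpus$gene_to_pmids))  # only on PMID 6
  expect_equal(corpus$gene_to_pmids[["22"]], c(2L, 4L, 5L))
  expect_equal(corpus$disease_to_pmids[["D000002"]], c(4L, 5L))

  # disjoint PMID sets add up
  dr <- data.frame(pmid = 1:5,
                   disease_id = c("Da", "Da", "Db", "Db", "Db"))
  gr <- data.frame(tax_id = 9606L, gene_id = 1L, pmid = 1L)
  expect_equal(build_corpus(gr, dr, c("Da", "Db"))$n_universe, 5L)

  # unrestricted mode counts every seen PMID
  expect_equal(build_corpus(gr, dr, "Da", restrict_universe = FALSE)$n_universe,
               5L)
  expect_equal(build_corpus(gr, dr, "Da")$n_universe, 2L)

  expect_message(build_corpus(gr, dr, c("Da", "Dmissing")), "zero annotated")
  expect_error(build_corpus(gr, dr, character(0)), "non-empty")
})

test_that("N_universe is invariant under input record permutation", {
  gr <- data.frame(tax_id = 9606L, gene_id = c(1L, 2L, 1L),
                   pmid = c(1L, 2L, 3L))
  dr <- data.frame(pmid = c(1L, 2L, 3L, 4L),
                   disease_id = c("Da", "Db", "Da", "Db"))
  c1 <- build_corpus(gr, dr, c("Da", "Db"))
  c2 <- build_corpus(gr[3:1, ], dr[sample(4), ], c("Db", "Da"))
  expect_identical(c1, c2)
})

test_that("a corpus round-trips through the TSV exchange formats", {
  gen <- generate(synthetic_spec(n_clusters = 2L, diseases_per_cluster = 3L,
                                 pool_genes_per_cluster = 10L,
                                 background_genes = 20L,
                                 pmids_per_disease = c(5L, 8L),
                                 seed = 11L))
  dir <- tempfile()
  write_corpus(gen$corpus, dir)
  gr <- read_gene2pubmed(file.path(dir, "gene2pubmed.tsv"))
  dr <- read_disease2pubmed(file.path(dir, "disease2pubmed.tsv"))
  again <- build_corpus(gr, dr, gen$corpus$disease_universe)
  expect_identical(again$pmid_to_genes, gen$corpus$pmid_to_genes)
  expect_identical(again$pmid_to_diseases, gen$corpus$pmid_to_diseases)
  expect_identical(again$n_universe, gen$corpus$n_universe)
})
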
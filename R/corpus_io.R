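#' Read an NCBI gene2pubmed-format file
#'
#' Parses the standard 3-column tab-separated mapping of genes to the PubMed
#' articles that discuss them (columns `tax_id`, `GeneID`, `PubMed_ID`), keeps
#' the records of a single taxon and collapses duplicated (gene, article)
#' pairs.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   treated as header/comment lines and skipped.
#' @param tax_id Taxonomy identifier to retain (default `9606`, human).
#' @return A data.frame with integer columns `tax_id`, `gene_id`, `pmid`,
#'   de-duplicated on (`gene_id`, `pmid`).
#' @examples
#' f <- tempfile()
#' writeLines(c("#Format: tax_id GeneID PubMed_ID",
#'              "9606\t1017\t100", "10090\t22059\t101"), f)
#' read_gene2pubmed(f)
#' @export
read_gene2pubmed <- function(path, tax_id = 9606L) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("gene2pubmed file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(tax_id = integer(), gene_id = integer(),
                      pmid = integer()))
  }
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- idx[which(nf != 3L)[1L]]
    stop("malformed gene2pubmed line ", bad, ": expected 3 tab-separated ",
         "columns, found ", nf[which(nf != 3L)[1L]])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  vals <- suppressWarnings(array(as.integer(m), dim = dim(m)))
  if (anyNA(vals)) {
    bad <- idx[which(rowSums(is.na(vals)) > 0L)[1L]]
    stop("malformed gene2pubmed line ", bad, ": non-integer field")
  }
  if (any(vals <= 0L)) {
    bad <- idx[which(rowSums(vals <= 0L) > 0L)[1L]]
    stop("malformed gene2pubmed line ", bad, ": fields must be positive")
  }
  df <- data.frame(tax_id = vals[, 1L], gene_id = vals[, 2L],
                   pmid = vals[, 3L])
  df <- df[df$tax_id == as.integer(tax_id), , drop = FALSE]
  df <- unique(df[, c("tax_id", "gene_id", "pmid")])
  df <- df[order(df$gene_id, df$pmid), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) {
    warning("no gene2pubmed records left after filtering tax_id ", tax_id)
  }
  df
}

#' Read a disease-to-PubMed annotation table
#'
#' Simple 2-column tab-separated exchange format (`pmid`, MeSH descriptor UI)
#' standing in for parsed PubMed XML.
#'
#' @param path Path to a headerless 2-column TSV.
#' @return A data.frame with columns `pmid` (integer) and `disease_id`
#'   (character), de-duplicated.
#' @export
read_disease2pubmed <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("disease2pubmed file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  if (!any(keep)) {
    return(data.frame(pmid = integer(), disease_id = character()))
  }
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    stop("malformed disease2pubmed line ", bad, ": expected 2 columns")
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  pmid <- suppressWarnings(as.integer(m[, 1L]))
  if (anyNA(pmid) || any(pmid <= 0L)) {
    bad <- idx[which(is.na(pmid) | pmid <= 0L)[1L]]
    stop("malformed disease2pubmed line ", bad, ": bad PMID")
  }
  df <- unique(data.frame(pmid = pmid, disease_id = m[, 2L]))
  df <- df[order(df$pmid, df$disease_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract MeSH disease annotations from MedlineCitation-style PubMed XML
#'
#' Consumes only the `PMID` element and the `DescriptorName/@UI` attributes of
#' each citation's `MeshHeadingList`; citations without headings contribute
#' nothing.
#'
#' @param path Path to an XML file containing `MedlineCitation` elements.
#' @return A data.frame with columns `pmid`, `disease_id` (one row per
#'   distinct (PMID, descriptor) pair).
#' @export
extract_mesh_from_pubmed_xml <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("PubMed XML file not found: ", path)
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, "//MedlineCitation")
  out_pmid <- integer(0)
  out_ui <- character(0)
  for (cite in cites) {
    pmid_node <- xml2::xml_find_first(cite, "./PMID")
    if (is.na(pmid_node)) next
    pmid <- suppressWarnings(as.integer(xml2::xml_text(pmid_node)))
    if (is.na(pmid)) next
    desc <- xml2::xml_find_all(cite, ".//MeshHeadingList/MeshHeading/DescriptorName")
    if (length(desc) == 0L) next
    uis <- xml2::xml_attr(desc, "UI")
    if (anyNA(uis)) {
      warning("PMID ", pmid, ": ", sum(is.na(uis)),
              " MeSH heading(s) without UI attribute skipped")
      uis <- uis[!is.na(uis)]
    }
    uis <- unique(uis)
    out_pmid <- c(out_pmid, rep.int(pmid, length(uis)))
    out_ui <- c(out_ui, uis)
  }
  df <- unique(data.frame(pmid = out_pmid, disease_id = out_ui))
  df <- df[order(df$pmid, df$disease_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a MeSH tree table
#'
#' 3-column TSV: descriptor UI, preferred name, semicolon-joined tree numbers.
#'
#' @param path Path to the table (no header).
#' @return A data.frame with columns `disease_id`, `name`, `tree_numbers`
#'   (the latter a semicolon-joined string; see [select_branch()]).
#' @export
read_mesh_tree <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("MeSH tree file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          quote = "", comment.char = "#",
                          colClasses = "character")
  if (ncol(df) != 3L) stop("MeSH tree table must have 3 columns")
  names(df) <- c("disease_id", "name", "tree_numbers")
  df
}

#' Select descriptors under a MeSH tree branch
#'
#' Returns descriptors carrying at least one tree number equal to the branch
#' code or strictly under it (`branch_code` followed by a dot). Segment
#' boundaries are respected: `C08.3811` is not under `C08.381`.
#'
#' @param entries data.frame as returned by [read_mesh_tree()], or with a
#'   list-column `tree_numbers` of character vectors.
#' @param branch_code Dotted tree prefix, e.g. `"C08.381"`.
#' @return Sorted character vector of descriptor UIs.
#' @export
select_branch <- function(entries, branch_code) {
  stopifnot(is.data.frame(entries), is.character(branch_code),
            length(branch_code) == 1L, nzchar(branch_code))
  if (!grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", branch_code)) {
    stop("branch_code is not a dotted MeSH tree code: ", branch_code)
  }
  trees <- entries$tree_numbers
  if (!is.list(trees)) trees <- strsplit(as.character(trees), ";", fixed = TRUE)
  hit <- vapply(trees, function(tn) {
    tn <- trimws(tn)
    any(tn == branch_code | startsWith(tn, paste0(branch_code, ".")))
  }, logical(1))
  out <- sort(unique(entries$disease_id[hit]))
  if (length(out) == 0L) {
    warning("no descriptors found under branch ", branch_code)
  }
  out
}

#' Assemble an annotation corpus over a disease universe
#'
#' Restricts article annotations to a chosen disease universe (typically one
#' MeSH branch). `N`, the total article count entering every enrichment
#' contingency table, is the number of distinct PMIDs annotated with at least
#' one universe disease; gene annotations are retained only for those PMIDs.
#' With `restrict_universe = FALSE` all PMIDs seen in either input are kept
#' and count toward `N`.
#'
#' @param gene_records data.frame from [read_gene2pubmed()].
#' @param disease_records data.frame from [read_disease2pubmed()] or
#'   [extract_mesh_from_pubmed_xml()].
#' @param disease_universe Character vector of disease ids defining the
#'   universe (order is preserved after sorting).
#' @param restrict_universe Logical; see Details above. Default `TRUE`.
#' @return An object of class `annotation_corpus`: a list with
#'   `pmid_to_genes`, `pmid_to_diseases` (named lists keyed by PMID),
#'   `gene_to_pmids`, `disease_to_pmids` (inverted maps), `disease_universe`
#'   and `n_universe`.
#' @export
build_corpus <- function(gene_records, disease_records, disease_universe,
                         restrict_universe = TRUE) {
  stopifnot(is.data.frame(gene_records), is.data.frame(disease_records))
  if (length(disease_universe) == 0L) stop("disease_universe must be non-empty")
  disease_universe <- sort(unique(as.character(disease_universe)))

  dr <- disease_records[disease_records$disease_id %in% disease_universe, ,
                        drop = FALSE]
  universe_pmids <- sort(unique(dr$pmid))
  if (restrict_universe) {
    pmid_pool <- universe_pmids
  } else {
    pmid_pool <- sort(unique(c(disease_records$pmid, gene_records$pmid)))
  }
  n_universe <- length(pmid_pool)

  gr <- gene_records[gene_records$pmid %in% pmid_pool, , drop = FALSE]

  split_map <- function(keys, values) {
    if (length(keys) == 0L) return(structure(list(), names = character(0)))
    lapply(split(values, factor(keys, levels = sort(unique(keys)))),
           function(v) sort(unique(v)))
  }
  pmid_to_genes <- split_map(gr$pmid, gr$gene_id)
  pmid_to_diseases <- split_map(dr$pmid, dr$disease_id)
  gene_to_pmids <- split_map(gr$gene_id, gr$pmid)
  disease_to_pmids <- split_map(dr$disease_id, dr$pmid)

  empty <- setdiff(disease_universe, names(disease_to_pmids))
  if (length(empty) > 0L) {
    message("universe disease(s) with zero annotated PMIDs retained: ",
            paste(empty, collapse = ", "))
    for (d in empty) disease_to_pmids[[d]] <- integer(0)
    disease_to_pmids <- disease_to_pmids[order(names(disease_to_pmids))]
  }

  structure(list(pmid_to_genes = pmid_to_genes,
                 pmid_to_diseases = pmid_to_diseases,
                 gene_to_pmids = gene_to_pmids,
                 disease_to_pmids = disease_to_pmids,
                 disease_universe = disease_universe,
                 n_universe = n_universe),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation_corpus:", length(x$disease_universe), "diseases,",
      length(x$gene_to_pmids), "genes,", x$n_universe,
      "articles in universe\n")
  invisible(x)
}

#' Write an annotation corpus back to its exchange formats
#'
#' Emits `gene2pubmed.tsv` (3 columns with `#` header, tax_id fixed to the
#' `tax_id` argument) and `disease2pubmed.tsv` (2 columns) into `dir`.
#' Re-reading and rebuilding reproduces the corpus maps.
#'
#' @param corpus An `annotation_corpus`.
#' @param dir Output directory (created if absent).
#' @param tax_id Taxon id written to the gene2pubmed column (default 9606).
#' @return Invisibly, the two file paths.
#' @export
write_corpus <- function(corpus, dir, tax_id = 9606L) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g_path <- file.path(dir, "gene2pubmed.tsv")
  d_path <- file.path(dir, "disease2pubmed.tsv")

  g_pmid <- rep.int(as.integer(names(corpus$pmid_to_genes)),
                    lengths(corpus$pmid_to_genes))
  g_gene <- unlist(corpus$pmid_to_genes, use.names = FALSE)
  con <- file(g_path, "w")
  writeLines("#Format: tax_id GeneID PubMed_ID (tab is used as a separator)",
             con)
  if (length(g_gene) > 0L) {
    o <- order(g_gene, g_pmid)
    writeLines(paste(tax_id, g_gene[o], g_pmid[o], sep = "\t"), con)
  }
  close(con)

  d_pmid <- rep.int(as.integer(names(corpus$pmid_to_diseases)),
                    lengths(corpus$pmid_to_diseases))
  d_dis <- unlist(corpus$pmid_to_diseases, use.names = FALSE)
  con <- file(d_path, "w")
  if (length(d_dis) > 0L) {
    o <- order(d_pmid, d_dis)
    writeLines(paste(d_pmid[o], d_dis[o], sep = "\t"), con)
  }
  close(con)
  invisible(c(gene2pubmed = g_path, disease2pubmed = d_path))
}
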
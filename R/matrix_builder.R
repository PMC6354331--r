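#' Assemble the primary disease-by-gene weight matrix
#'
#' Rows are diseases, columns are genes, entries are fingerprint weights
#' (0 where a gene is absent from a disease's fingerprint). Two filters are
#' applied until a fixed point so both hold on the final matrix:
#' genes associated with only one retained disease are removed, and diseases
#' whose fingerprints carry fewer than `min_genes` genes are removed.
#'
#' @param fingerprints Named list of `gene_fingerprint` objects.
#' @param min_genes Minimum fingerprint size for a disease row (default 1).
#' @param count_post_filter If `TRUE`, measure a disease's gene count on the
#'   current (gene-filtered) matrix rather than on its raw fingerprint.
#' @return Dense numeric matrix with disease ids as rownames and gene ids
#'   as colnames, rows/columns sorted.
#' @export
build_matrix <- function(fingerprints, min_genes = 1L,
                         count_post_filter = FALSE) {
  stopifnot(is.list(fingerprints), length(fingerprints) > 0L,
            min_genes >= 1L)
  if (is.null(names(fingerprints))) {
    names(fingerprints) <- vapply(fingerprints, attr, "", "disease_id")
  }
  diseases <- sort(names(fingerprints))
  genes <- sort(unique(unlist(lapply(fingerprints, `[[`, "gene_id"))))
  mat <- matrix(0, nrow = length(diseases), ncol = length(genes),
                dimnames = list(diseases, as.character(genes)))
  for (d in diseases) {
    fp <- fingerprints[[d]]
    if (nrow(fp) > 0L) mat[d, as.character(fp$gene_id)] <- fp$weight
  }
  fp_size <- vapply(fingerprints[diseases], nrow, integer(1))

  repeat {
    changed <- FALSE
    gene_support <- colSums(mat > 0)
    drop_g <- gene_support < 2L
    if (any(drop_g)) {
      mat <- mat[, !drop_g, drop = FALSE]
      changed <- TRUE
    }
    row_count <- if (count_post_filter) rowSums(mat > 0) else
      fp_size[rownames(mat)]
    drop_d <- row_count < min_genes
    if (any(drop_d)) {
      mat <- mat[!drop_d, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  if (nrow(mat) < 3L) {
    stop("fewer than 3 diseases remain after filtering (",
         nrow(mat), "); clustering is undefined")
  }
  mat
}

#' Export a disease-by-gene matrix as TSV
#'
#' Header row of gene ids, first column of disease ids.
#'
#' @param mat Matrix from [build_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(disease_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = c(disease_id = "character"))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$disease_id
  mat
}
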
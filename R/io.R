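#' Read a gene-by-cell count matrix
#'
#' Supports the Matrix Market layout (`matrix.mtx` with one-column
#' `genes.tsv` / `barcodes.tsv` sidecars, genes as rows) and dense CSV
#' (first column = gene ids, remaining columns = cells).
#'
#' @param path Path to the `.mtx` or `.csv` file.
#' @param genes,cells Sidecar paths for the MTX layout; default
#'   `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @return A genes x cells `dgCMatrix` with dimnames.
#' @export
read_count_matrix <- function(path, genes = NULL, cells = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    genes <- genes %||% file.path(dir, "genes.tsv")
    cells <- cells %||% file.path(dir, "barcodes.tsv")
    gn <- utils::read.table(genes, sep = "\t",
                            stringsAsFactors = FALSE)[[1L]]
    cn <- utils::read.table(cells, sep = "\t",
                            stringsAsFactors = FALSE)[[1L]]
    if (length(gn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar lengths do not match the matrix dimensions")
    dimnames(m) <- list(gn, cn)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
  if (any(m < 0)) stop("count matrix has negative entries")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("gene or cell identifiers are not unique")
  m
}

#' Write a count matrix in Matrix Market layout
#'
#' @param m Genes x cells matrix.
#' @param dir Output directory (created if missing); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m) %||% as.character(seq_len(nrow(m))),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(m) %||% as.character(seq_len(ncol(m))),
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a marker gene list (one symbol per line)
#'
#' @param path Text file path; blank lines and `#` comments are skipped.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Bundled S-phase and G2/M marker gene sets
#'
#' The standard S-phase and G2/M marker lists widely used for single-cell
#' phase scoring, shipped as plain-text fixtures.
#'
#' @return Named list with character vectors `S` and `G2M`.
#' @export
cell_cycle_gene_sets <- function() {
  list(S = read_gene_list(system.file("extdata", "genes_s_phase.txt",
                                      package = "cctraj", mustWork = TRUE)),
       G2M = read_gene_list(system.file("extdata", "genes_g2m_phase.txt",
                                        package = "cctraj", mustWork = TRUE)))
}
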
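# Readers/writers for the plain-text interchange formats: AIRR rearrangement
# TSV, Matrix-Market expression triplets with gene/barcode sidecars,
# per-cell metadata TSV, newline-delimited gene lists.

#' Read an AIRR-style rearrangement table
#'
#' Tab-separated, one row per assembled contig, with the AIRR column names
#' (`cell_id`, `locus`, `productive`, `v_call`, `d_call`, `j_call`,
#' `junction`, `junction_aa`, `c_call`, `duplicate_count`, `sequence`) plus
#' the mutation columns `v_mut_count`, `j_mut_count`, `vj_aligned_length`.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_rearrangements <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      productive = readr::col_logical(),
      duplicate_count = readr::col_integer(),
      v_mut_count = readr::col_integer(),
      j_mut_count = readr::col_integer(),
      vj_aligned_length = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Write an AIRR-style rearrangement table
#'
#' @param records tibble of contig records.
#' @param path output file path (TSV). List columns are dropped.
#' @return `records`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  flat <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(records)
}

#' Read / write per-cell metadata
#'
#' @param path file path (TSV).
#' @return A tibble.
#' @export
read_cell_meta <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      total_umi = readr::col_integer(),
      n_genes = readr::col_integer(),
      mito_fraction = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' @rdname read_cell_meta
#' @param meta tibble of per-cell metadata.
#' @export
write_cell_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(meta)
}

#' Write an expression matrix as Matrix-Market with sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return A dgCMatrix with gene and barcode dimnames.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(
    readLines(file.path(dir, "genes.tsv")),
    readLines(file.path(dir, "barcodes.tsv"))
  )
  m
}

#' Read a newline-delimited gene list
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
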
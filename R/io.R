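#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path TSV file path.
#' @return integer matrix with gene row names and sample column names.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name of the first (row-name) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a count matrix in MatrixMarket coordinate format
#'
#' Emits `<stem>.mtx` plus sidecar `<stem>.rownames.txt` and
#' `<stem>.colnames.txt` files.
#'
#' @param m integer matrix.
#' @param stem output path stem (without extension).
#' @export
write_counts_mtx <- function(m, stem) {
  nz <- which(m != 0, arr.ind = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(m), ncol(m), nrow(nz)),
             paste(nz[, 1], nz[, 2], m[nz]))
  writeLines(lines, paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".rownames.txt"))
  writeLines(colnames(m), paste0(stem, ".colnames.txt"))
}

#' Read a two/three-column term-to-gene annotation TSV
#'
#' Columns: term_id, gene_id, optional term name; no header required (a
#' header line starting with "term_id" is skipped).
#'
#' @param path TSV file path.
#' @return data.frame with columns `term_id`, `gene_id` (and `term_name`).
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && identical(df[1, 1], "term_id")) df <- df[-1, , drop = FALSE]
  names(df)[1:2] <- c("term_id", "gene_id")
  if (ncol(df) >= 3) names(df)[3] <- "term_name"
  rownames(df) <- NULL
  df
}

#' Read sample metadata TSV
#'
#' Expects columns `sample_id`, `sample_type`, optional `replicate`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sample_type") %in% names(df))) {
    stop("metadata must have columns sample_id and sample_type")
  }
  df
}

#' Read gene features TSV (gene_id, length, gc)
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `length`, `gc`.
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length", "gc") %in% names(df))) {
    stop("features must have columns gene_id, length, gc")
  }
  df
}

#' Write a simulated dataset to a directory
#'
#' Emits counts (TSV and MatrixMarket), gene features, sample metadata,
#' ground truth and true offsets as plain-text files.
#'
#' @param sim a [simulate_counts()] result.
#' @param outdir output directory (created if missing).
#' @param mtx also write MatrixMarket output.
#' @return `outdir`, invisibly.
#' @export
write_simdata <- function(sim, outdir, mtx = FALSE) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(sim$counts, file.path(outdir, "counts.tsv"))
  if (mtx) write_counts_mtx(sim$counts, file.path(outdir, "counts"))
  utils::write.table(sim$features, file.path(outdir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$meta, file.path(outdir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$offsets, file.path(outdir, "true_offsets.tsv"))
  invisible(outdir)
}
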
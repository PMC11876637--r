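# readers/writers for the plain-text exchange formats used by the package:
# MatrixMarket counts + genes/cells TSVs, FASTA proteins, signal-region and
# marker/ortholog/evidence TSVs. All tabular files are tab-separated with a
# header and no quoting.

#' Write a labeled count matrix as MatrixMarket + TSVs
#'
#' Writes `matrix.mtx` (cells x genes, MatrixMarket coordinate format),
#' `genes.tsv` (column `gene`) and `cells.tsv` (columns `cell_id`,
#' `cluster`, `part`, `library`) into `dir`.
#'
#' @param x a `labeled_counts` object (see [simulate_atlas()]).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_counts_dir <- function(x, dir) {
  stopifnot(inherits(x, "labeled_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write_tsv(data.frame(gene = x$genes), file.path(dir, "genes.tsv"))
  write_tsv(x$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a labeled count matrix written by [write_counts_dir()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a `labeled_counts` object (without simulation truth).
#' @export
read_counts_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- read_tsv(file.path(dir, "genes.tsv"))$gene
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  if (nrow(counts) != nrow(cells))
    stopf("matrix has %d rows but cells.tsv has %d", nrow(counts),
          nrow(cells))
  if (ncol(counts) != length(genes))
    stopf("matrix has %d columns but genes.tsv has %d", ncol(counts),
          length(genes))
  dimnames(counts) <- list(cells$cell_id, genes)
  structure(list(counts = counts, cells = cells, genes = genes,
                 truth = NULL, config = NULL),
            class = "labeled_counts")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' Write signal-peptide regions as a 1-based inclusive TSV
#'
#' The on-disk convention follows predictor-style output: columns
#' `protein`, `region` (N/H/C), `start`, `end`, 1-based inclusive.
#' Internally the package uses 0-based half-open coordinates; this writer
#' converts.
#'
#' @param signals data frame with `protein`, `region`, `start`, `end`
#'   in 0-based half-open coordinates (as produced by
#'   [simulate_proteins()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(signals, path) {
  out <- data.frame(protein = signals$protein, region = signals$region,
                    start = signals$start + 1L, end = signals$end)
  write_tsv(out, path)
}
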
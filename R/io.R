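# Plain-text interchange: BED-dialect intervals (0-based half-open
# throughout), bedGraph tracks, pair TSVs, and sparse upper-triangle COO
# matrices with a side-car bin table.

#' Read a BED3+/BED4/BED6 file
#' @param path tab-separated file without header.
#' @return data.frame with chrom, start, end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write intervals as BED
#' @param df data.frame whose first columns are chrom, start, end (further
#'   columns written as extra BED fields).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  old <- options(scipen = 15)   # BED coordinates must not be scientific
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a compartment track as bedGraph (pc1) plus BED4 labels
#' @param track `CompartmentTrack`.
#' @param bedgraph,bed4 output paths (either may be NULL to skip).
#' @export
write_compartment_track <- function(track, bedgraph = NULL, bed4 = NULL) {
  if (!is.null(bedgraph)) {
    ok <- !is.na(track$pc1)
    write_bed(track[ok, c("chrom", "start", "end", "pc1")], bedgraph)
  }
  if (!is.null(bed4)) {
    ok <- !is.na(track$label)
    write_bed(track[ok, c("chrom", "start", "end", "label")], bed4)
  }
  invisible(track)
}

#' Read chromosome sizes from a 2-column TSV
#' @param path file with chrom and size columns, no header.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  as_chrom_sizes(df[, 1:2])
}

#' Read a 4-column pairs TSV (chrom1, pos1, chrom2, pos2)
#'
#' Malformed rows (non-numeric or missing positions) are dropped with a
#' logged count, never silently.
#'
#' @param path tab-separated file without header.
#' @return data.frame with chrom1, pos1, chrom2, pos2.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric",
                                         "character", "numeric"))
  names(df) <- c("chrom1", "pos1", "chrom2", "pos2")
  bad <- !is.finite(df$pos1) | !is.finite(df$pos2)
  if (any(bad))
    log_msg("read_pairs: dropped %d malformed record(s)", sum(bad))
  df[!bad, , drop = FALSE]
}

#' Write a contact matrix as COO TSV plus a bin-table BED
#'
#' The matrix file holds the upper triangle (diagonal included) as
#' `bin_i<TAB>bin_j<TAB>value` with 0-based bin indices; the bin table is
#' BED3 plus the bin index (and the mask flag as a fifth column).
#'
#' @param m ContactMatrix.
#' @param matrix_path,bins_path output files.
#' @export
write_matrix_coo <- function(m, matrix_path, bins_path) {
  tm <- methods::as(m$mat, "TsparseMatrix")
  coo <- data.frame(i = pmin(tm@i, tm@j), j = pmax(tm@i, tm@j), x = tm@x)
  coo <- coo[order(coo$i, coo$j), ]
  utils::write.table(coo, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bins <- cbind(m$bins[c("chrom", "start", "end", "bin")],
                mask = as.integer(m$mask))
  write_bed(bins, bins_path)
  invisible(m)
}

#' Read a COO TSV + bin table pair back into a ContactMatrix
#' @param matrix_path,bins_path files written by [write_matrix_coo()].
#' @return ContactMatrix.
#' @export
read_matrix_coo <- function(matrix_path, bins_path) {
  bins_df <- utils::read.table(bins_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
  names(bins_df) <- c("chrom", "start", "end", "bin", "mask")[seq_len(ncol(bins_df))]
  bins <- bin_table(bins_df$chrom, bins_df$start, bins_df$end)
  coo <- utils::read.table(matrix_path, sep = "\t", header = FALSE)
  mat <- Matrix::sparseMatrix(i = coo[[1L]] + 1L, j = coo[[2L]] + 1L,
                              x = coo[[3L]], dims = rep(nrow(bins), 2L),
                              symmetric = TRUE)
  mask <- if ("mask" %in% names(bins_df)) bins_df$mask > 0 else NULL
  contact_matrix(bins, mat, mask = mask)
}

#' Write an expression table (gene_id, TPM) as TSV
#' @param expr data.frame with gene_id and TPM.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV (gene_id, TPM header expected)
#' @param path input file.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write all planted truth of a synthetic genome to a directory
#'
#' Emits compartments.bed (BED4 A/B), tads.bed (BED3), bias.tsv (bin index,
#' factor), all 0-based half-open.
#'
#' @param genome `SyntheticGenome`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cbind(genome$bins[c("chrom", "start", "end")],
                  label = genome$compartment_truth),
            file.path(dir, "compartments.bed"))
  tads <- do.call(rbind, lapply(names(genome$tad_truth), function(ch)
    cbind(chrom = ch, genome$tad_truth[[ch]])))
  write_bed(tads, file.path(dir, "tads.bed"))
  utils::write.table(data.frame(bin = genome$bins$bin,
                                factor = genome$bias_truth),
                     file.path(dir, "bias.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(genome)
}
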
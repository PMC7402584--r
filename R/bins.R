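# Bin tables: the genomic index every matrix is defined over.
#
# A bin table is a data.frame with columns chrom, start, end (0-based
# half-open) and a dense genome-wide 0-based index column `bin`.  Bins within
# a chromosome are sorted, non-overlapping and contiguous.

#' Construct and validate a bin table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open coordinates.
#' @return data.frame with columns chrom, start, end, bin (dense 0-based
#'   genome-wide index).
#' @export
bin_table <- function(chrom, start, end) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start))
    stop("bin table contains empty or reversed bins", call. = FALSE)
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop(sprintf("bins on %s are not sorted", ch), call. = FALSE)
    if (nrow(b) > 1L && any(b$start[-1L] != b$end[-nrow(b)]))
      stop(sprintf("bins on %s are not contiguous", ch), call. = FALSE)
  }
  df$bin <- seq_len(nrow(df)) - 1L
  df
}

#' Fixed-width bin table from chromosome sizes
#'
#' The last bin of each chromosome is truncated at the chromosome end.
#'
#' @param chrom_sizes named numeric vector (chromosome -> length in bp) or a
#'   two-column data.frame (chrom, size).
#' @param bin_size bin width in bp.
#' @return bin table (see [bin_table()]).
#' @export
fixed_bins <- function(chrom_sizes, bin_size) {
  check_scalar(bin_size, "bin_size", lower = 0, strict_lower = TRUE,
               integer = TRUE)
  sizes <- as_chrom_sizes(chrom_sizes)
  pieces <- lapply(names(sizes), function(ch) {
    starts <- seq(0, sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, sizes[[ch]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  bin_table(df$chrom, df$start, df$end)
}

# normalize chromosome-size input to a named numeric vector
as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    sizes <- as.numeric(x[[2L]])
    names(sizes) <- as.character(x[[1L]])
  } else if (is.numeric(x) && !is.null(names(x))) {
    sizes <- x
  } else stop("chrom_sizes must be a named numeric vector or a 2-column data.frame",
              call. = FALSE)
  if (any(sizes <= 0)) stop("chromosome sizes must be positive", call. = FALSE)
  sizes
}

# normalize genome sequence input: named character vector, DNAStringSet, or
# path to a FASTA file -> named character vector of uppercase sequences
as_genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
             file.exists(genome)) {
    seqs <- as.character(Biostrings::readDNAStringSet(genome))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome) && !is.null(names(genome))) {
    seqs <- genome
  } else stop("genome must be a named character vector, a DNAStringSet, or a FASTA path",
              call. = FALSE)
  toupper(seqs)
}

#' Restriction-site bin table
#'
#' Cuts each chromosome at every exact occurrence of the restriction site on
#' the forward strand (the classical Hi-C enzymes HindIII `AAGCTT` and MboI
#' `GATC` are reverse-complement palindromes, so one strand suffices) and
#' returns the intervals between consecutive cut starts, plus the leading and
#' trailing intervals.  Zero-length intervals (site at position 0) are
#' dropped.
#'
#' @param genome genome sequences (named character vector, `DNAStringSet`, or
#'   FASTA file path).
#' @param site recognition sequence over A/C/G/T, e.g. `"GATC"`.
#' @return bin table covering each chromosome exactly.
#' @export
restriction_bins <- function(genome, site) {
  if (!is.character(site) || length(site) != 1L || nchar(site) == 0L ||
      grepl("[^ACGT]", toupper(site)))
    stop("'site' must be a non-empty string over A/C/G/T", call. = FALSE)
  site <- toupper(site)
  seqs <- as_genome_seqs(genome)
  pieces <- lapply(names(seqs), function(ch) {
    hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seqs[[ch]]))
    cuts <- BiocGenerics::start(hits) - 1L   # 0-based cut starts
    len <- nchar(seqs[[ch]])
    edges <- unique(c(0, cuts, len))
    edges <- sort(edges[edges <= len])
    data.frame(chrom = ch, start = edges[-length(edges)], end = edges[-1L],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  df <- df[df$end > df$start, , drop = FALSE]
  bin_table(df$chrom, df$start, df$end)
}

# bin index (1-based row) for positions on one chromosome; NA outside bounds
locate_bins <- function(bins, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    b <- which(bins$chrom == ch)
    if (!length(b)) next
    p <- pos[sel]
    ok <- !is.na(p) & p >= bins$start[b[1L]] & p < bins$end[b[length(b)]]
    loc <- findInterval(p[ok], bins$start[b])
    idx[sel[ok]] <- b[loc]
  }
  idx
}
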
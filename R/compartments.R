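# A/B compartment calling: observed/expected -> correlation -> PC1 ->
# sign orientation by activating-mark peaks.  All per chromosome.

# mean of unmasked entries at each separation distance (0..n-1) of a dense
# per-chromosome matrix with NA at masked bins
diagonal_means <- function(d) {
  n <- nrow(d)
  vapply(0:(n - 1L), function(k) {
    i <- seq_len(n - k)
    v <- d[cbind(i, i + k)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Observed/expected transformation of a corrected matrix
#'
#' Divides each intra-chromosomal entry by the mean of unmasked entries at
#' the same bin separation, removing the distance-decay so the plaid
#' (compartment) signal dominates.  Distances whose mean is zero (or all
#' masked) yield NA.  Chromosomes with fewer than 4 unmasked bins yield an
#' all-NA matrix with a warning.
#'
#' @param m corrected `ContactMatrix` at fixed resolution.
#' @return named list of dense per-chromosome O/E matrices (NA at masked
#'   bins).
#' @export
observed_expected <- function(m) {
  out <- list()
  for (ch in unique(m$bins$chrom)) {
    dc <- cm_dense_chrom(m, ch)
    d <- dc$mat
    if (sum(!dc$masked) < 4L) {
      warning(sprintf("observed_expected: chromosome %s has < 4 unmasked bins; all NA", ch))
      d[] <- NA_real_
      out[[ch]] <- d
      next
    }
    ev <- diagonal_means(d)
    ev[!is.na(ev) & ev == 0] <- NA_real_
    n <- nrow(d)
    dist <- abs(outer(seq_len(n), seq_len(n), `-`))
    oe <- d / matrix(ev[dist + 1L], n, n)
    out[[ch]] <- oe
  }
  out
}

#' First principal component of the O/E correlation matrix
#'
#' Computes the pairwise-complete Pearson correlation matrix of the O/E rows,
#' then the eigenvector of its largest eigenvalue (unit norm).  Bin pairs
#' with fewer than 3 complete observations get NA correlation; bins whose
#' correlation row is entirely NA (masked or constant rows) get NA in the
#' returned vector; any residual isolated NA correlations are treated as 0
#' for the eigendecomposition.  The sign of the eigenvector is arbitrary at
#' this stage — see [orient_and_label()].
#'
#' @param oe dense O/E matrix for one chromosome (NAs allowed).
#' @return numeric vector, one pc1 value per bin (NA for undefined bins).
#' @export
correlation_pc1 <- function(oe) {
  n <- nrow(oe)
  pc1 <- rep(NA_real_, n)
  C <- suppressWarnings(stats::cor(oe, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(oe))
  C[npairs < 3L] <- NA_real_
  valid <- which(rowSums(!is.na(C)) > 1L)
  if (length(valid) < 2L) return(pc1)
  Cs <- C[valid, valid, drop = FALSE]
  diag(Cs) <- 1
  Cs[is.na(Cs)] <- 0
  eg <- eigen(Cs, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  pc1[valid] <- v / sqrt(sum(v^2))
  pc1
}

# fraction of each bin's length covered by (reduced) peaks
bin_peak_cover <- function(bins, peaks) {
  gb <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start + 1L, bins$end))
  if (nrow(peaks) == 0L) return(rep(0, nrow(bins)))
  gp <- GenomicRanges::reduce(GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)))
  hits <- GenomicRanges::findOverlaps(gb, gp)
  ov <- IRanges::width(IRanges::pintersect(
    gb[S4Vectors::queryHits(hits)], gp[S4Vectors::subjectHits(hits)]))
  cov <- rep(0, nrow(bins))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  cov[as.integer(names(agg))] <- as.numeric(agg)
  cov / (bins$end - bins$start)
}

#' Orient PC1 sign with activating-mark peaks and label compartments
#'
#' Per chromosome, compares the mean peak-covered fraction of bins with
#' pc1 > 0 against bins with pc1 < 0; if the negative side is denser the
#' chromosome's pc1 sign is flipped, so that positive values mark the
#' transcriptionally active A compartment.  Chromosomes without peaks keep
#' their sign and are flagged as unoriented.
#'
#' @param pc1 per-bin pc1 vector aligned with `bins` (NA allowed).
#' @param peaks BED3-style data.frame of activating-mark peaks (e.g.
#'   H3K36me3).
#' @param bins bin table the pc1 vector is defined over.
#' @return `CompartmentTrack`: data.frame(chrom, start, end, pc1, label) with
#'   label A (pc1 > 0), B (pc1 < 0) or NA; attribute `unoriented` lists
#'   chromosomes lacking orientation evidence.
#' @export
orient_and_label <- function(pc1, peaks, bins) {
  stopifnot(length(pc1) == nrow(bins))
  cov <- bin_peak_cover(bins, peaks)
  unoriented <- character(0)
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    has_peaks <- nrow(peaks) > 0L && any(peaks$chrom == ch)
    if (!has_peaks) {
      unoriented <- c(unoriented, ch)
      next
    }
    pos <- rows[!is.na(pc1[rows]) & pc1[rows] > 0]
    neg <- rows[!is.na(pc1[rows]) & pc1[rows] < 0]
    if (!length(pos) || !length(neg)) next
    if (mean(cov[neg]) > mean(cov[pos])) pc1[rows] <- -pc1[rows]
  }
  if (length(unoriented))
    warning(sprintf("orient_and_label: no peaks on %s; sign left as computed",
                    paste(unoriented, collapse = ", ")))
  label <- ifelse(is.na(pc1) | pc1 == 0, NA_character_,
                  ifelse(pc1 > 0, "A", "B"))
  track <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                      pc1 = pc1, label = label, stringsAsFactors = FALSE)
  attr(track, "unoriented") <- unoriented
  class(track) <- c("CompartmentTrack", "data.frame")
  track
}

#' Call compartments from a corrected matrix in one step
#'
#' Convenience chain: [observed_expected()] -> [correlation_pc1()] per
#' chromosome -> [orient_and_label()].  Warns when a chromosome yields fewer
#' than 3 segments, a symptom of PC1 tracking chromosome arms instead of
#' compartments.
#'
#' @param m corrected `ContactMatrix` at compartment resolution
#'   (conventionally 100 kb).
#' @param peaks activating-mark peaks (BED3-style data.frame).
#' @return `CompartmentTrack`.
#' @export
call_compartments <- function(m, peaks) {
  oe <- observed_expected(m)
  pc1 <- rep(NA_real_, nrow(m$bins))
  for (ch in names(oe)) {
    rows <- which(m$bins$chrom == ch)
    pc1[rows] <- correlation_pc1(oe[[ch]])
  }
  track <- orient_and_label(pc1, peaks, m$bins)
  segs <- segment_compartments(track)
  tab <- table(segs$chrom)
  few <- names(tab)[tab < 3L]
  if (length(few))
    warning(sprintf("call_compartments: < 3 segments on %s; PC1 may reflect chromosome arms rather than compartments",
                    paste(few, collapse = ", ")))
  track
}

#' Collapse a compartment track into maximal same-label segments
#'
#' NA bins break runs.  Per-label total bp is attached as attribute
#' `label_bp` for downstream genome-fraction summaries.
#'
#' @param track `CompartmentTrack`.
#' @return data.frame(chrom, start, end, label, n_bins) of class
#'   `CompartmentSegments`.
#' @export
segment_compartments <- function(track) {
  pieces <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    r <- rle(ifelse(is.na(t$label), "NA", t$label))
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values != "NA"
    if (!any(keep)) next
    pieces[[ch]] <- data.frame(chrom = ch,
                               start = t$start[starts_i[keep]],
                               end = t$end[ends_i[keep]],
                               label = r$values[keep],
                               n_bins = r$lengths[keep],
                               stringsAsFactors = FALSE)
  }
  segs <- if (length(pieces)) do.call(rbind, pieces)
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), label = character(),
                          n_bins = integer(), stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  attr(segs, "label_bp") <- tapply(segs$end - segs$start, segs$label, sum)
  class(segs) <- c("CompartmentSegments", "data.frame")
  segs
}
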
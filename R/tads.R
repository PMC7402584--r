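# TAD boundary detection: per-diagonal z-scoring, diamond separation
# (insulation) scores over several windows, local-minimum candidates, and a
# one-sided Wilcoxon rank-sum test against the flanking maxima with
# Bonferroni correction.

#' Wilcoxon rank-sum p-value
#'
#' Thin wrapper around the exact Mann-Whitney distribution: for tie-free
#' samples with both sizes below 50 the p-value is exact (equal to
#' enumeration of the rank-sum null); otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param alternative "less" (x tends lower), "greater", or "two.sided".
#' @return p-value.
#' @export
ranksum_p <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative)$p.value)
}

#' Per-diagonal z-score transformation
#'
#' Standardizes each intra-chromosomal entry against the mean and sd of all
#' unmasked entries at the same bin separation, so that locally depleted
#' contacts (boundaries) become comparable across distances.  Diagonals with
#' sd 0 (or a single entry) yield NA.
#'
#' @param m corrected `ContactMatrix` at TAD resolution (conventionally
#'   40 kb).
#' @return named list of dense per-chromosome z matrices (NA at masked
#'   bins).
#' @export
zscore_transform <- function(m) {
  out <- list()
  for (ch in unique(m$bins$chrom)) {
    d <- cm_dense_chrom(m, ch)$mat
    n <- nrow(d)
    z <- matrix(NA_real_, n, n)
    for (k in 0:(n - 1L)) {
      i <- seq_len(n - k)
      idx <- cbind(i, i + k)
      v <- d[idx]
      mu <- mean(v, na.rm = TRUE)
      sdv <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(mu) || !is.finite(sdv) || sdv == 0) next
      zz <- (v - mu) / sdv
      z[idx] <- zz
      z[idx[, c(2L, 1L), drop = FALSE]] <- zz
    }
    out[[ch]] <- z
  }
  out
}

# z-values in the diamond straddling the edge before bin i (1-based), width w:
# rows (i-w)..(i-1) x cols i..(i+w-1); NULL when context is incomplete
diamond_values <- function(z, i, w) {
  n <- nrow(z)
  if (i - w < 1L || i + w - 1L > n) return(NULL)
  as.vector(z[(i - w):(i - 1L), i:(i + w - 1L)])
}

# pooled diamond z-values over all windows with full context at edge i;
# NULL if no window fits (nested windows weight short-range pairs up, which
# is shared by candidate and flank samples alike)
diamond_pooled <- function(z, i, windows) {
  v <- unlist(lapply(windows, function(w) diamond_values(z, i, w)))
  if (length(v)) v else NULL
}

#' Multi-window separation (insulation) score track
#'
#' For every interior bin edge and window size w, the score is the mean z
#' over the diamond of bin pairs straddling the edge; low scores indicate
#' insulation, i.e. candidate TAD boundaries.  The aggregate is the mean over
#' the windows that have full context at that edge, and NA when none has
#' (the outermost edges).  Windows larger than a chromosome are skipped with
#' a warning.
#'
#' @param z list of per-chromosome z matrices (from [zscore_transform()]).
#' @param bins bin table of the matrix the z-scores came from.
#' @param windows integer window sizes in bins, each >= 2.
#' @return `SeparationTrack` data.frame: chrom, pos (bp of the bin edge),
#'   edge (1-based index of the bin right of the edge), one `w<k>` column per
#'   window, and `score` (aggregate).
#' @export
separation_score <- function(z, bins, windows = c(3L, 5L, 7L, 10L)) {
  stopifnot(all(windows >= 2L))
  windows <- sort(unique(as.integer(windows)))
  pieces <- list()
  for (ch in names(z)) {
    zm <- z[[ch]]
    n <- nrow(zm)
    use <- windows[2L * windows <= n]
    if (length(use) < length(windows))
      warning(sprintf("separation_score: window(s) %s exceed chromosome %s; skipped",
                      paste(setdiff(windows, use), collapse = ","), ch))
    if (!length(use) || n < 2L) next
    starts <- bins$start[bins$chrom == ch]
    edges <- 2:n
    sc <- matrix(NA_real_, length(edges), length(use),
                 dimnames = list(NULL, paste0("w", use)))
    for (e in seq_along(edges)) {
      for (wi in seq_along(use)) {
        v <- diamond_values(zm, edges[e], use[wi])
        if (!is.null(v) && any(is.finite(v)))
          sc[e, wi] <- mean(v, na.rm = TRUE)
      }
    }
    agg <- rowMeans(sc, na.rm = TRUE)
    agg[rowSums(!is.na(sc)) == 0L] <- NA_real_
    pieces[[ch]] <- data.frame(chrom = ch, pos = starts[edges],
                               edge = edges, sc, score = agg,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(pieces)) do.call(rbind, pieces)
         else data.frame(chrom = character(), pos = numeric(),
                         edge = integer(), score = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "windows") <- windows
  class(out) <- c("SeparationTrack", "data.frame")
  out
}

# indices (into s) of local minima / maxima of a numeric vector with NAs;
# NAs and vector ends act as -Inf padding for maxima and +Inf for minima
local_extrema <- function(s) {
  n <- length(s)
  left <- c(NA, s[-n]); right <- c(s[-1L], NA)
  fin <- is.finite(s)
  lmax <- fin &
    (ifelse(is.na(left), -Inf, left) < s) &
    (ifelse(is.na(right), -Inf, right) < s)
  list(minima = which(fin & !is.na(left) & !is.na(right) &
                        s < left & s < right),
       maxima = which(lmax))
}

#' Detect significant TAD boundaries
#'
#' Candidates are local minima of the aggregate separation score lying at
#' least `delta` below both nearest flanking local maxima.  Each candidate's
#' pooled diamond z-values (all windows with full context at that edge) are
#' compared against the pooled diamond z-values at the two flanking maxima
#' edges by a one-sided rank-sum test
#' (candidate lower); p-values are Bonferroni-corrected over all candidates
#' and boundaries with adjusted p below `p_threshold` are reported.
#'
#' @param track `SeparationTrack` from [separation_score()].
#' @param z per-chromosome z matrices the track was computed from.
#' @param delta minimum score drop from the flanking maxima.
#' @param p_threshold adjusted-p cutoff (default 0.01).
#' @return `TADBoundaries` data.frame: chrom, pos, score, p, p_adj, sorted by
#'   position within chromosome; attribute `n_candidates` records the
#'   Bonferroni denominator.
#' @export
find_boundaries <- function(track, z, delta = 0.01, p_threshold = 0.01) {
  check_scalar(delta, "delta", lower = 0)
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1)
  windows <- attr(track, "windows")
  cand <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    s <- t$score
    ex <- local_extrema(s)
    if (!length(ex$minima) || !length(ex$maxima)) next
    for (e in ex$minima) {
      lmx <- ex$maxima[ex$maxima < e]
      rmx <- ex$maxima[ex$maxima > e]
      if (!length(lmx) || !length(rmx)) next
      lmx <- max(lmx); rmx <- min(rmx)
      if (min(s[lmx], s[rmx]) - s[e] < delta) next
      zm <- z[[ch]]
      dv <- diamond_pooled(zm, t$edge[e], windows)
      fl <- c(diamond_pooled(zm, t$edge[lmx], windows),
              diamond_pooled(zm, t$edge[rmx], windows))
      if (is.null(dv) || is.null(fl)) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, pos = t$pos[e], score = s[e],
        p = ranksum_p(dv, fl, alternative = "less"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    out <- data.frame(chrom = character(), pos = numeric(), score = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_candidates") <- 0L
    class(out) <- c("TADBoundaries", "data.frame")
    return(out)
  }
  cc <- do.call(rbind, cand)
  m <- nrow(cc)
  cc$p_adj <- pmin(1, m * cc$p)
  out <- cc[!is.na(cc$p_adj) & cc$p_adj < p_threshold, , drop = FALSE]
  out <- out[order(match(out$chrom, unique(cc$chrom)), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- m
  attr(out, "candidates") <- cc
  class(out) <- c("TADBoundaries", "data.frame")
  out
}

#' Intervals between consecutive boundaries
#'
#' Each chromosome with at least one significant boundary is tiled into TADs
#' by its boundaries plus the chromosome ends (the flanks count as TADs since
#' they are bounded by a significant boundary); chromosomes with no boundary
#' contribute no TADs.
#'
#' @param bs `TADBoundaries` (or data.frame with chrom, pos).
#' @param chrom_sizes named numeric vector or 2-column data.frame.
#' @return `TADSet` data.frame: chrom, start, end.
#' @export
boundaries_to_tads <- function(bs, chrom_sizes) {
  sizes <- as_chrom_sizes(chrom_sizes)
  pieces <- list()
  for (ch in unique(bs$chrom)) {
    if (!ch %in% names(sizes))
      stop(sprintf("boundaries_to_tads: unknown chromosome %s", ch),
           call. = FALSE)
    pos <- sort(unique(bs$pos[bs$chrom == ch]))
    pos <- pos[pos > 0 & pos < sizes[[ch]]]
    if (!length(pos)) next
    edges <- c(0, pos, sizes[[ch]])
    pieces[[ch]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                               end = edges[-1L], stringsAsFactors = FALSE)
  }
  out <- if (length(pieces)) do.call(rbind, pieces)
         else data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("TADSet", "data.frame")
  out
}

#' Call TADs from a corrected matrix in one step
#'
#' Convenience chain: [zscore_transform()] -> [separation_score()] ->
#' [find_boundaries()] -> [boundaries_to_tads()].
#'
#' @param m corrected `ContactMatrix` at TAD resolution.
#' @param windows window sizes in bins.
#' @param delta minimum score drop (see [find_boundaries()]).
#' @param p_threshold adjusted-p cutoff.
#' @return list with `boundaries` (`TADBoundaries`), `tads` (`TADSet`) and
#'   `track` (`SeparationTrack`).
#' @export
call_tads <- function(m, windows = c(3L, 5L, 7L, 10L), delta = 0.01,
                      p_threshold = 0.01) {
  z <- zscore_transform(m)
  track <- separation_score(z, m$bins, windows)
  bounds <- find_boundaries(track, z, delta, p_threshold)
  sizes <- tapply(m$bins$end, m$bins$chrom, max)[unique(m$bins$chrom)]
  list(boundaries = bounds, tads = boundaries_to_tads(bounds, sizes),
       track = track)
}
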
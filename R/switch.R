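# Integration of two samples: compartment-switch classification, gene
# assignment, expression-by-group contrasts, normalized per-chromosome
# scores, TAD conservation, and boundary-proximity expression.

#' Classify per-bin compartment switches between two samples
#'
#' Joins two compartment tracks on identical bins and assigns each bin one of
#' stableA, AtoB, BtoA, stableB; bins NA in either sample are NA.  The stable
#' fraction (stableA + stableB over classified bins, as a percentage) is
#' attached as attribute `stable_pct`.
#'
#' @param t1,t2 `CompartmentTrack`s over identical bin tables.
#' @return `SwitchTable` data.frame: chrom, start, end, label1, label2,
#'   class.
#' @export
classify_switches <- function(t1, t2) {
  if (!identical(t1[c("chrom", "start", "end")], t2[c("chrom", "start", "end")]))
    stop("classify_switches: bin tables differ", call. = FALSE)
  cls <- rep(NA_character_, nrow(t1))
  ok <- !is.na(t1$label) & !is.na(t2$label)
  cls[ok] <- ifelse(t1$label[ok] == t2$label[ok],
                    paste0("stable", t1$label[ok]),
                    paste0(t1$label[ok], "to", t2$label[ok]))
  out <- data.frame(chrom = t1$chrom, start = t1$start, end = t1$end,
                    label1 = t1$label, label2 = t2$label, class = cls,
                    stringsAsFactors = FALSE)
  n_cls <- sum(ok)
  attr(out, "stable_pct") <-
    if (n_cls) 100 * sum(cls[ok] %in% c("stableA", "stableB")) / n_cls
    else NA_real_
  class(out) <- c("SwitchTable", "data.frame")
  out
}

# TSS coordinate per gene: start on +, end-1 on -
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

#' Assign genes to compartment segments by TSS
#'
#' A gene belongs to the segment whose half-open interval contains its 1-bp
#' TSS (start for + strand, end-1 for -); a TSS exactly at a segment end
#' falls in the following segment.  Genes in NA gaps stay unassigned (label
#' NA).
#'
#' @param genes BED6-style data.frame (chrom, start, end, gene_id, score,
#'   strand).
#' @param segments `CompartmentSegments` from [segment_compartments()].
#' @return data.frame: gene_id, chrom, tss, label.
#' @export
assign_genes <- function(genes, segments) {
  tss <- gene_tss(genes)
  lab <- rep(NA_character_, nrow(genes))
  if (nrow(segments)) {
    gg <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1L, tss + 1L))
    gs <- GenomicRanges::GRanges(segments$chrom,
                                 IRanges::IRanges(segments$start + 1L,
                                                  segments$end))
    hits <- GenomicRanges::findOverlaps(gg, gs, type = "within", select = "first")
    lab[!is.na(hits)] <- segments$label[hits[!is.na(hits)]]
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, tss = tss,
             label = lab, stringsAsFactors = FALSE)
}

#' Per-gene switch classes from two samples' assignments
#'
#' @param a1,a2 gene assignments (from [assign_genes()]) for the two samples,
#'   same genes in the same order.
#' @return data.frame: gene_id, chrom, tss, label1, label2, class (as in
#'   [classify_switches()]).
#' @export
gene_switch_classes <- function(a1, a2) {
  stopifnot(identical(a1$gene_id, a2$gene_id))
  cls <- rep(NA_character_, nrow(a1))
  ok <- !is.na(a1$label) & !is.na(a2$label)
  cls[ok] <- ifelse(a1$label[ok] == a2$label[ok],
                    paste0("stable", a1$label[ok]),
                    paste0(a1$label[ok], "to", a2$label[ok]))
  data.frame(gene_id = a1$gene_id, chrom = a1$chrom, tss = a1$tss,
             label1 = a1$label, label2 = a2$label, class = cls,
             stringsAsFactors = FALSE)
}

#' Expression summaries and tests per switch class
#'
#' Transforms TPM to log10(TPM+1), summarizes each class (n, median,
#' quartiles) and runs the canonical rank-sum contrasts: BtoA vs stableB
#' and AtoB vs stableA (two-sided).  Empty classes get n = 0 and their test
#' is skipped.
#'
#' @param assign data.frame with gene_id and class columns (see
#'   [gene_switch_classes()]).
#' @param expr data.frame: gene_id, TPM.
#' @return list with `summary` (data.frame per class) , `values` (named list
#'   of per-gene log10(TPM+1) vectors) and `tests` (data.frame: contrast, p).
#' @export
expression_by_group <- function(assign, expr) {
  stopifnot(all(c("gene_id", "class") %in% names(assign)),
            all(c("gene_id", "TPM") %in% names(expr)))
  merged <- merge(assign, expr, by = "gene_id")
  merged$log_expr <- log10(merged$TPM + 1)
  classes <- c("stableA", "AtoB", "BtoA", "stableB")
  values <- lapply(stats::setNames(classes, classes), function(cl)
    merged$log_expr[!is.na(merged$class) & merged$class == cl])
  summ <- do.call(rbind, lapply(classes, function(cl) {
    v <- values[[cl]]
    data.frame(class = cl, n = length(v),
               q1 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q3 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  contrasts <- list(c("BtoA", "stableB"), c("AtoB", "stableA"))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    x <- values[[ct[1L]]]; y <- values[[ct[2L]]]
    p <- if (length(x) && length(y))
      ranksum_p(x, y, alternative = "two.sided") else NA_real_
    data.frame(contrast = paste(ct, collapse = " vs "), n1 = length(x),
               n2 = length(y), p = p, stringsAsFactors = FALSE)
  }))
  list(summary = summ, values = values, tests = tests)
}

#' Random background sample of stable-region genes
#'
#' @param assign data.frame with gene_id and class.
#' @param n sample size (capped at the stable pool with a warning).
#' @param seed integer seed.
#' @return data.frame subset of `assign` rows (stable genes only).
#' @export
random_stable_background <- function(assign, n, seed = 1L) {
  pool <- which(!is.na(assign$class) &
                  assign$class %in% c("stableA", "stableB"))
  if (!length(pool))
    stop("random_stable_background: no stable-region genes", call. = FALSE)
  if (n > length(pool)) {
    warning(sprintf("random_stable_background: n = %d exceeds pool (%d); returning the whole pool",
                    n, length(pool)))
    n <- length(pool)
  }
  idx <- with_seed(seed, sample(pool, n))
  out <- assign[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized per-chromosome scores for compartments or TADs
#'
#' For compartment segments: score(label, chrom) = count(label, chrom) /
#' total segment count(chrom) / chromosome size.  For a `TADSet` the label
#' dimension collapses and the per-chromosome count is divided by the
#' genome-wide TAD total and the chromosome size.  The double division is the
#' source procedure taken literally; the unusual 1/bp units are intentional.
#'
#' @param items `CompartmentSegments` or `TADSet`.
#' @param chrom_sizes named numeric vector or 2-column data.frame.
#' @return data.frame: chrom, label, score (label "TAD" for TAD sets; NA
#'   score when a chromosome has zero total).
#' @export
normalized_scores <- function(items, chrom_sizes) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (inherits(items, "TADSet")) {
    total <- nrow(items)
    out <- do.call(rbind, lapply(names(sizes), function(ch) {
      cnt <- sum(items$chrom == ch)
      data.frame(chrom = ch, label = "TAD",
                 score = if (total) cnt / total / sizes[[ch]] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }
  stopifnot(all(c("chrom", "label") %in% names(items)))
  out <- do.call(rbind, lapply(names(sizes), function(ch) {
    tot <- sum(items$chrom == ch)
    do.call(rbind, lapply(c("A", "B"), function(lb) {
      cnt <- sum(items$chrom == ch & items$label == lb)
      data.frame(chrom = ch, label = lb,
                 score = if (tot) cnt / tot / sizes[[ch]] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Reciprocal-overlap TAD conservation between two samples
#'
#' A TAD is conserved when some partner TAD overlaps it by more than `frac`
#' of *both* lengths (reciprocal; set `reciprocal = FALSE` for the
#' single-sided variant, > frac of the query TAD only).  Each TAD is matched
#' to at most one partner: greatest overlap, ties broken by leftmost
#' partner.
#'
#' @param s1,s2 `TADSet`s on the same genome.
#' @param frac overlap fraction threshold (default 0.7).
#' @param reciprocal require the fraction on both intervals (default TRUE).
#' @return list: `conserved` (data.frame of matched pairs with coordinates
#'   and overlap bp), `unique1`, `unique2` (unmatched TADs of each set),
#'   `n_conserved1`, `n_conserved2`.
#' @export
tad_overlap <- function(s1, s2, frac = 0.7, reciprocal = TRUE) {
  check_scalar(frac, "frac", lower = 0, upper = 1)
  g1 <- GenomicRanges::GRanges(s1$chrom, IRanges::IRanges(s1$start + 1L, s1$end))
  g2 <- GenomicRanges::GRanges(s2$chrom, IRanges::IRanges(s2$start + 1L, s2$end))
  hits <- GenomicRanges::findOverlaps(g1, g2)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(g1[q], g2[s]))
  len1 <- s1$end - s1$start; len2 <- s2$end - s2$start
  pass <- ov > frac * len1[q] & (if (reciprocal) ov > frac * len2[s] else TRUE)
  q <- q[pass]; s <- s[pass]; ov <- ov[pass]
  # greatest-overlap partner per query, ties -> leftmost partner
  ord <- order(q, -ov, s2$start[s])
  q <- q[ord]; s <- s[ord]; ov <- ov[ord]
  first <- !duplicated(q)
  conserved <- data.frame(chrom = s1$chrom[q[first]],
                          start1 = s1$start[q[first]], end1 = s1$end[q[first]],
                          start2 = s2$start[s[first]], end2 = s2$end[s[first]],
                          overlap = ov[first], stringsAsFactors = FALSE)
  cons1 <- unique(q); cons2 <- unique(s)
  list(conserved = conserved,
       unique1 = s1[setdiff(seq_len(nrow(s1)), cons1), , drop = FALSE],
       unique2 = s2[setdiff(seq_len(nrow(s2)), cons2), , drop = FALSE],
       n_conserved1 = length(cons1), n_conserved2 = length(cons2))
}

#' Count TADs lying in compartment-switching regions
#'
#' A TAD counts when at least half of its length (configurable) falls in
#' bins classed AtoB or BtoA.
#'
#' @param tads `TADSet` (conventionally 40 kb calls).
#' @param switches `SwitchTable` (conventionally 100 kb bins).
#' @param min_frac minimum fraction of TAD length in switching bins.
#' @return list: count, fraction (of all TADs), and per-TAD switching bp.
#' @export
tads_in_switch_regions <- function(tads, switches, min_frac = 0.5) {
  sw <- switches[!is.na(switches$class) &
                   switches$class %in% c("AtoB", "BtoA"), , drop = FALSE]
  bp <- rep(0, nrow(tads))
  if (nrow(sw) && nrow(tads)) {
    gt <- GenomicRanges::GRanges(tads$chrom,
                                 IRanges::IRanges(tads$start + 1L, tads$end))
    gs <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sw$chrom, IRanges::IRanges(sw$start + 1L, sw$end)))
    hits <- GenomicRanges::findOverlaps(gt, gs)
    ov <- IRanges::width(IRanges::pintersect(
      gt[S4Vectors::queryHits(hits)], gs[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  inside <- bp >= min_frac * (tads$end - tads$start)
  list(count = sum(inside),
       fraction = if (nrow(tads)) sum(inside) / nrow(tads) else NA_real_,
       switch_bp = bp)
}

#' Expression of genes near vs far from TAD boundaries
#'
#' NEAR = genes whose TSS is strictly closer than `dist` to the nearest
#' boundary on its chromosome; FAR = the remaining genes on chromosomes that
#' have boundaries (i.e. genes within the TAD-tiled span).  One-sided
#' rank-sum test of NEAR > FAR on log10(TPM+1).
#'
#' @param genes BED6-style gene table.
#' @param expr data.frame: gene_id, TPM.
#' @param boundaries `TADBoundaries` (chrom, pos).
#' @param dist proximity cutoff in bp (default 40000; strict `<`).
#' @return list: n_near, n_far, median_near, median_far, p (NA with a
#'   message when either group is empty).
#' @export
boundary_proximity_expression <- function(genes, expr, boundaries,
                                          dist = 40000) {
  check_scalar(dist, "dist", lower = 0, strict_lower = TRUE)
  tss <- gene_tss(genes)
  dmin <- rep(NA_real_, nrow(genes))
  for (ch in unique(boundaries$chrom)) {
    pos <- sort(boundaries$pos[boundaries$chrom == ch])
    sel <- which(genes$chrom == ch)
    if (!length(sel)) next
    dmin[sel] <- vapply(tss[sel], function(p) min(abs(p - pos)), numeric(1))
  }
  merged <- merge(data.frame(gene_id = genes$gene_id, dmin = dmin,
                             stringsAsFactors = FALSE),
                  expr, by = "gene_id")
  merged <- merged[!is.na(merged$dmin), , drop = FALSE]
  lx <- log10(merged$TPM + 1)
  near <- lx[merged$dmin < dist]
  far <- lx[merged$dmin >= dist]
  p <- NA_real_
  if (!length(near) || !length(far))
    log_msg("boundary_proximity_expression: empty group (near n=%d, far n=%d); test skipped",
            length(near), length(far))
  else p <- ranksum_p(near, far, alternative = "greater")
  list(n_near = length(near), n_far = length(far),
       median_near = if (length(near)) stats::median(near) else NA_real_,
       median_far = if (length(far)) stats::median(far) else NA_real_,
       p = p)
}
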
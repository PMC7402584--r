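# Independent oracles and small fixture builders.  Every oracle here is a
# deliberately naive re-derivation (brute force, enumeration, closed form)
# kept separate from the package's own code paths.

# ---- fixtures ---------------------------------------------------------------

# uniform-compartment genome with k equal TADs of tad_bins bins each
planted_tad_genome <- function(n_tads = 10L, tad_bins = 10L, bin_size = 4e4,
                               labels = NULL) {
  nb <- n_tads * tad_bins
  tads <- data.frame(start = (seq_len(n_tads) - 1L) * tad_bins * bin_size,
                     end = seq_len(n_tads) * tad_bins * bin_size)
  synthetic_genome(c(chr1 = nb * bin_size), bin_size,
                   compartment = labels %||% rep("A", nb),
                   tads = list(chr1 = tads),
                   bias = rep(1, nb))
}

# CompartmentTrack straight from a label vector over a genome's bins
track_from_labels <- function(bins, labels) {
  tr <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   pc1 = ifelse(is.na(labels), NA_real_,
                                ifelse(labels == "A", 1, -1)),
                   label = labels, stringsAsFactors = FALSE)
  class(tr) <- c("CompartmentTrack", "data.frame")
  tr
}

# small random symmetric nonnegative dense matrix
random_symm <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.5, 4), n, n)
  (a + t(a)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- oracles ----------------------------------------------------------------

# dense O/E by explicit per-diagonal loops
oe_oracle <- function(d) {
  n <- nrow(d)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- abs(i - j)
    vals <- c()
    for (a in seq_len(n)) for (b in seq_len(n))
      if (abs(a - b) == k) vals <- c(vals, d[a, b])
    mu <- mean(vals, na.rm = TRUE)
    if (is.finite(mu) && mu != 0) out[i, j] <- d[i, j] / mu
  }
  out
}

# dense per-diagonal standardization
zscore_oracle <- function(d) {
  n <- nrow(d)
  out <- matrix(NA_real_, n, n)
  for (k in 0:(n - 1)) {
    vals <- sapply(seq_len(n - k), function(i) d[i, i + k])
    mu <- mean(vals, na.rm = TRUE); sdv <- sd(vals, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    for (i in seq_len(n - k)) {
      out[i, i + k] <- (d[i, i + k] - mu) / sdv
      out[i + k, i] <- out[i, i + k]
    }
  }
  out
}

# diamond mean for the edge before 1-based bin i, window w
diamond_oracle <- function(z, i, w) {
  vals <- c()
  for (a in (i - w):(i - 1)) for (b in i:(i + w - 1))
    vals <- c(vals, z[a, b])
  mean(vals, na.rm = TRUE)
}

# exact rank-sum null by enumeration of all group assignments
ranksum_enum_oracle <- function(x, y, alternative = "less") {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  if (alternative == "less") mean(ws <= w_obs) else mean(ws >= w_obs)
}

# all-pairs reciprocal-overlap conservation count
tad_overlap_oracle <- function(s1, s2, frac = 0.7) {
  cons1 <- rep(FALSE, nrow(s1)); cons2 <- rep(FALSE, nrow(s2))
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
    if (s1$chrom[i] != s2$chrom[j]) next
    ov <- max(0, min(s1$end[i], s2$end[j]) - max(s1$start[i], s2$start[j]))
    if (ov > frac * (s1$end[i] - s1$start[i]) &&
        ov > frac * (s2$end[j] - s2$start[j])) {
      cons1[i] <- TRUE; cons2[j] <- TRUE
    }
  }
  list(n1 = sum(cons1), n2 = sum(cons2))
}

# closed-form upper binomial tail P(X >= k)
binom_tail_oracle <- function(k, n, p) {
  sum(sapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x)))
}

# symmetric Sinkhorn balancing (independent of the package's ICE): returns a
# doubly-balanced kernel proportional to the input
sinkhorn_balance <- function(K, iters = 3000) {
  r <- rep(1, nrow(K))
  for (it in seq_len(iters)) {
    s <- rowSums(K * outer(r, r))
    r <- r / sqrt(s / mean(s))
  }
  K * outer(r, r)
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  table(paste0(ch[-length(ch)], ch[-1L]))
}

# naive per-position PWM log2-odds scorer, one strand
scan_oracle <- function(seq, mat, bg = rep(0.25, 4)) {
  ch <- strsplit(seq, "")[[1L]]
  L <- ncol(mat)
  idx <- match(ch, c("A", "C", "G", "T"))
  n <- length(ch)
  if (n < L) return(numeric(0))
  sapply(seq_len(n - L + 1L), function(p) {
    sc <- 0
    for (k in seq_len(L)) {
      b <- idx[p + k - 1L]
      sc <- sc + if (is.na(b)) -Inf else as.numeric(log2(mat[b, k] / bg[b]))
    }
    unname(sc)
  })
}
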
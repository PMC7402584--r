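# Two-sample integration: switch classes, gene assignment, expression
# contrasts, normalized scores, TAD conservation.

test_that("classify_switches partitions bins and counts match brute force", {
  bins <- fixed_bins(c(chr1 = 1e9), 1e5)
  set.seed(50)
  l1 <- sample(c("A", "B", NA), 1e4, replace = TRUE, prob = c(.45, .45, .1))
  l2 <- sample(c("A", "B", NA), 1e4, replace = TRUE, prob = c(.45, .45, .1))
  t1 <- track_from_labels(bins, l1); t2 <- track_from_labels(bins, l2)
  sw <- classify_switches(t1, t2)
  # brute-force tabulation
  for (pair in list(c("A", "A", "stableA"), c("A", "B", "AtoB"),
                    c("B", "A", "BtoA"), c("B", "B", "stableB"))) {
    expect_equal(sum(sw$class == pair[3], na.rm = TRUE),
                 sum(l1 == pair[1] & l2 == pair[2], na.rm = TRUE))
  }
  expect_equal(sum(is.na(sw$class)), sum(is.na(l1) | is.na(l2)))
  expect_equal(sum(!is.na(sw$class)) + sum(is.na(sw$class)), 1e4)
  # identity -> 100% stable
  expect_equal(attr(classify_switches(t1, t1), "stable_pct"), 100)
  # definitional pairs
  bins2 <- fixed_bins(c(chr1 = 2e5), 1e5)
  ta <- track_from_labels(bins2, c("A", "B"))
  tb <- track_from_labels(bins2, c("B", "A"))
  expect_equal(classify_switches(ta, tb)$class, c("AtoB", "BtoA"))
  # mismatched bins rejected
  expect_error(classify_switches(t1, ta), "bin tables differ")
})

test_that("assign_genes follows the half-open TSS containment rule", {
  segs <- data.frame(chrom = "chr1", start = c(1e5, 2e5), end = c(2e5, 5e5),
                     label = c("A", "B"), n_bins = c(1L, 3L))
  class(segs) <- c("CompartmentSegments", "data.frame")
  genes <- data.frame(chrom = "chr1", start = c(150000, 200000, 50000),
                      end = c(151000, 201000, 51000),
                      gene_id = c("g1", "g2", "g3"), score = 0, strand = "+")
  a <- assign_genes(genes, segs)
  expect_equal(a$label, c("A", "B", NA))  # g2: TSS at segment end -> next
  # minus strand: TSS = end - 1
  gm <- data.frame(chrom = "chr1", start = 190000, end = 200000,
                   gene_id = "gm", score = 0, strand = "-")
  expect_equal(assign_genes(gm, segs)$label, "A")
  # random TSSs vs quadratic containment oracle
  set.seed(51)
  starts <- sort(sample(seq(0, 9.8e6, by = 2e5), 20))
  rsegs <- data.frame(chrom = "chr1", start = starts, end = starts + 1e5,
                      label = sample(c("A", "B"), 20, TRUE), n_bins = 1L)
  class(rsegs) <- c("CompartmentSegments", "data.frame")
  rg <- data.frame(chrom = "chr1", start = sample(0:1e7, 1000),
                   end = 0, gene_id = sprintf("g%d", 1:1000), score = 0,
                   strand = "+")
  rg$end <- rg$start + 500
  got <- assign_genes(rg, rsegs)
  for (i in seq_len(1000)) {
    hit <- which(rsegs$start <= rg$start[i] & rg$start[i] < rsegs$end)
    expect_identical(got$label[i],
                     if (length(hit)) rsegs$label[hit[1]] else NA_character_)
  }
})

test_that("expression_by_group transforms and tests as stated", {
  assign <- data.frame(gene_id = c("a", "b", "c", "d"),
                       class = c("stableA", "stableB", "BtoA", "AtoB"))
  expr <- data.frame(gene_id = c("a", "b", "c", "d"), TPM = c(0, 9, 99, 9))
  r <- expression_by_group(assign, expr)
  expect_equal(unname(r$values$stableA), 0)    # log10(0 + 1)
  expect_equal(unname(r$values$stableB), 1)    # log10(9 + 1)
  expect_equal(unname(r$values$BtoA), 2)
  expect_equal(r$summary$n, c(1L, 1L, 1L, 1L))
  # empty class: n = 0, test NA
  r2 <- expression_by_group(assign[1:2, ], expr)
  expect_equal(r2$summary$n[r2$summary$class == "BtoA"], 0L)
  expect_true(is.na(r2$tests$p[1]))
})

test_that("random_stable_background samples uniformly without replacement", {
  assign <- data.frame(gene_id = sprintf("g%d", 1:30),
                       class = rep(c("stableA", "stableB", "AtoB"), each = 10))
  pool <- assign$gene_id[assign$class != "AtoB"]
  # n = pool -> whole pool
  expect_warning(all20 <- random_stable_background(assign, 25, seed = 1),
                 "exceeds pool")
  expect_setequal(all20$gene_id, pool)
  # determinism
  expect_identical(random_stable_background(assign, 5, seed = 9),
                   random_stable_background(assign, 5, seed = 9))
  # inclusion frequencies uniform within binomial 99% bounds
  counts <- table(factor(unlist(
    lapply(1:2000, function(s)
      random_stable_background(assign, 5, seed = s)$gene_id)), levels = pool))
  p_inc <- 5 / 20
  expect_true(all(counts >= qbinom(0.005, 2000, p_inc)))
  expect_true(all(counts <= qbinom(0.995, 2000, p_inc)))
})

test_that("normalized_scores applies the double division literally", {
  segs <- data.frame(chrom = rep("chr1", 50),
                     start = seq(0, 49) * 2e6, end = seq(1, 50) * 2e6,
                     label = c(rep("A", 40), rep("B", 10)), n_bins = 20L)
  class(segs) <- c("CompartmentSegments", "data.frame")
  sc <- normalized_scores(segs, c(chr1 = 1e8))
  expect_equal(sc$score[sc$label == "A"], 40 / 50 / 1e8)
  expect_equal(sc$score[sc$label == "B"], 10 / 50 / 1e8)
  # single-label chromosome: ratio term 1
  segs1 <- segs; segs1$label <- "A"
  sc1 <- normalized_scores(segs1, c(chr1 = 1e8))
  expect_equal(sc1$score[sc1$label == "A"], 1 / 1e8)
  # random sets vs spreadsheet-style oracle, multiple chromosomes
  set.seed(52)
  rs <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   start = 0, end = 1e5,
                   label = sample(c("A", "B"), 100, TRUE), n_bins = 1L)
  class(rs) <- c("CompartmentSegments", "data.frame")
  sizes <- c(chr1 = 5e7, chr2 = 3e7)
  out <- normalized_scores(rs, sizes)
  for (ch in names(sizes)) for (lb in c("A", "B")) {
    expect_equal(out$score[out$chrom == ch & out$label == lb],
                 sum(rs$chrom == ch & rs$label == lb) /
                   sum(rs$chrom == ch) / sizes[[ch]])
  }
  # TAD variant: per-chromosome count / genome total / size
  tads <- structure(data.frame(chrom = rep(c("chr1", "chr2"), c(30, 20)),
                               start = 0, end = 1e6),
                    class = c("TADSet", "data.frame"))
  ts <- normalized_scores(tads, sizes)
  expect_equal(ts$score, c(30 / 50 / 5e7, 20 / 50 / 3e7))
})

test_that("tad_overlap reciprocal criterion matches brute force", {
  mk <- function(df) structure(df, class = c("TADSet", "data.frame"))
  s <- mk(data.frame(chrom = "chr1", start = c(0, 100, 250),
                     end = c(100, 250, 400)))
  r <- tad_overlap(s, s)
  expect_equal(r$n_conserved1, 3L)
  expect_equal(nrow(r$unique1), 0L)
  expect_equal(nrow(r$unique2), 0L)
  # worked arithmetic: [0,100) vs [10,110), overlap 90 > 70 both ways
  a <- mk(data.frame(chrom = "chr1", start = 0, end = 100))
  b <- mk(data.frame(chrom = "chr1", start = 10, end = 110))
  expect_equal(tad_overlap(a, b)$n_conserved1, 1L)
  # at exactly the threshold the strict > fails
  c70 <- mk(data.frame(chrom = "chr1", start = 30, end = 100))
  expect_equal(tad_overlap(mk(data.frame(chrom = "chr1", start = 0, end = 100)),
                           c70)$n_conserved1, 0L)
  # random interval sets vs all-pairs oracle; symmetry of conserved counts
  set.seed(53)
  for (r in 1:5) {
    mkrand <- function() {
      cuts <- sort(sample(seq(1e5, 1.99e7, by = 1e5), 150))
      edges <- c(0, cuts, 2e7)
      mk(data.frame(chrom = "chr1", start = edges[-length(edges)],
                    end = edges[-1]))
    }
    s1 <- mkrand(); s2 <- mkrand()
    got <- tad_overlap(s1, s2)
    want <- tad_overlap_oracle(s1, s2)
    expect_equal(got$n_conserved1, want$n1)
    expect_equal(got$n_conserved2, want$n2)
    expect_equal(nrow(got$unique1), nrow(s1) - want$n1)
    # symmetry under the reciprocal criterion
    rev <- tad_overlap(s2, s1)
    expect_equal(rev$n_conserved1, got$n_conserved2)
    expect_equal(rev$n_conserved2, got$n_conserved1)
  }
})

test_that("tads_in_switch_regions applies the half-length rule", {
  mk <- function(df) structure(df, class = c("TADSet", "data.frame"))
  bins <- fixed_bins(c(chr1 = 1e6), 1e5)
  sw <- classify_switches(track_from_labels(bins, rep("A", 10)),
                          track_from_labels(bins, c(rep("B", 5), rep("A", 5))))
  # no switching bins
  sw0 <- classify_switches(track_from_labels(bins, rep("A", 10)),
                           track_from_labels(bins, rep("A", 10)))
  expect_equal(tads_in_switch_regions(mk(data.frame(chrom = "chr1", start = 0,
                                                    end = 4e5)), sw0)$count, 0)
  # TAD fully inside one switching bin
  t1 <- mk(data.frame(chrom = "chr1", start = 110000, end = 150000))
  expect_equal(tads_in_switch_regions(t1, sw)$count, 1)
  # random configurations vs brute-force bp intersection
  set.seed(54)
  for (r in 1:5) {
    st <- sort(sample(0:96, 8)) * 1e4
    tt <- mk(data.frame(chrom = "chr1", start = st,
                        end = pmin(st + sample(2:4, 8, TRUE) * 1e4, 1e6)))
    res <- tads_in_switch_regions(tt, sw)
    swbins <- sw[!is.na(sw$class) & sw$class %in% c("AtoB", "BtoA"), ]
    want <- 0
    for (i in seq_len(nrow(tt))) {
      bp <- 0
      for (j in seq_len(nrow(swbins)))
        bp <- bp + max(0, min(tt$end[i], swbins$end[j]) -
                         max(tt$start[i], swbins$start[j]))
      if (bp >= 0.5 * (tt$end[i] - tt$start[i])) want <- want + 1
    }
    expect_equal(res$count, want)
  }
})

test_that("boundary_proximity_expression groups by strict distance", {
  bset <- structure(data.frame(chrom = "chr1", pos = c(1e6, 2e6)),
                    class = c("TADBoundaries", "data.frame"))
  genes <- data.frame(chrom = "chr1",
                      start = c(1e6, 1e6 + 4e4, 1.5e6),
                      end = c(1e6 + 1e3, 1e6 + 4.1e4, 1.5e6 + 1e3),
                      gene_id = c("at", "exact", "far"), score = 0,
                      strand = "+")
  expr <- data.frame(gene_id = c("at", "exact", "far"), TPM = c(5, 5, 5))
  r <- boundary_proximity_expression(genes, expr, bset, dist = 4e4)
  expect_equal(r$n_near, 1L)   # only the TSS at the boundary (distance 0)
  expect_equal(r$n_far, 2L)    # distance exactly dist is FAR (strict <)
  # planted NEAR excess of 0.5 log10 units: p < 1e-6 (median over 10 seeds)
  ps <- sapply(1:10, function(s) {
    set.seed(s)
    nearg <- data.frame(chrom = "chr1",
                        start = rep(c(1e6, 2e6), each = 150) +
                          sample(-39999:39999, 300, TRUE),
                        end = 0, gene_id = sprintf("n%d", 1:300), score = 0,
                        strand = "+")
    farg <- data.frame(chrom = "chr1",
                       start = sample(seq(1.1e6, 1.9e6, by = 1e3), 300),
                       end = 0, gene_id = sprintf("f%d", 1:300), score = 0,
                       strand = "+")
    gg <- rbind(nearg, farg); gg$end <- gg$start + 100
    ee <- data.frame(gene_id = gg$gene_id,
                     TPM = 10^(c(rnorm(300, 1.5, 0.5), rnorm(300, 1.0, 0.5))) - 1)
    ee$TPM <- pmax(ee$TPM, 0)
    boundary_proximity_expression(gg, ee, bset, dist = 4e4)$p
  })
  expect_lt(median(ps), 1e-6)
})

test_that("two samples from one truth are stable; planted flips recovered", {
  g <- generate_genome(1, 1e7, 1e5, 1e6, 10, seed = 55)
  pk <- simulate_peaks(g, sim_params(), seed = 55)
  stab <- sapply(1:5, function(s) {
    m1 <- simulate_contacts(g, sim_params(), seed = 100 + s)
    m2 <- simulate_contacts(g, sim_params(), seed = 200 + s)
    t1 <- suppressWarnings(call_compartments(ice_normalize(filter_bins(m1)), pk))
    t2 <- suppressWarnings(call_compartments(ice_normalize(filter_bins(m2)), pk))
    attr(classify_switches(t1, t2), "stable_pct")
  })
  expect_gte(median(stab), 95)
})
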
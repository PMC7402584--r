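# Matrix construction, filtering, balancing, rebinning.

test_that("restriction_bins matches brute-force string scans", {
  # worked MboI example
  b <- restriction_bins(c(chr1 = "TTGATCTTGATCTT"), "GATC")
  expect_equal(b$start, c(0, 2, 8))
  expect_equal(b$end, c(2, 8, 14))
  # site absent -> single bin
  b2 <- restriction_bins(c(chr1 = "AAAAAA"), "GATC")
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$end, 6)
  # site at position 0: zero-length leading bin dropped
  b3 <- restriction_bins(c(chr1 = "AAGCTT"), "AAGCTT")
  expect_equal(b3$start, 0)
  expect_equal(b3$end, 6)
  # random sequences vs gregexpr oracle
  set.seed(42)
  for (r in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    got <- restriction_bins(c(chrX = s), "GATC")
    cuts <- as.integer(gregexpr("(?=GATC)", s, perl = TRUE)[[1L]])
    cuts <- cuts[cuts > 0] - 1L
    edges <- unique(c(0, cuts, nchar(s)))
    expect_equal(got$start, edges[-length(edges)])
    expect_equal(got$end, edges[-1L])
  }
  expect_error(restriction_bins(c(chr1 = "ACGT"), "GANC"), "A/C/G/T")
})

test_that("pairs_to_matrix counts every accepted pair once", {
  bins <- fixed_bins(c(chr1 = 1e6), 1e5)
  p1 <- data.frame(chrom1 = "chr1", pos1 = 350000, chrom2 = "chr1",
                   pos2 = 399999)
  m1 <- pairs_to_matrix(p1, bins)
  expect_equal(as.matrix(m1$mat)[4, 4], 1)
  expect_equal(matrix_total(m1), 1)
  # symmetry of entry accumulation
  p2 <- data.frame(chrom1 = c("chr1", "chr1"), pos1 = c(0, 150000),
                   chrom2 = c("chr1", "chr1"), pos2 = c(150000, 0))
  m2 <- pairs_to_matrix(p2, bins)
  expect_equal(as.matrix(m2$mat)[1, 2], 2)
  # 1e4 random pairs: conservation + skipped pairs logged
  set.seed(1)
  n <- 1e4
  pr <- data.frame(chrom1 = sample(c("chr1", "chrZ"), n, TRUE, c(0.95, 0.05)),
                   pos1 = floor(runif(n, 0, 1e6)),
                   chrom2 = "chr1", pos2 = floor(runif(n, 0, 1e6)))
  expect_message(m3 <- pairs_to_matrix(pr, bins), "skipped")
  expect_equal(matrix_total(m3), sum(pr$chrom1 == "chr1"))
})

test_that("merge_matrices sums counts and rejects mismatched bins", {
  bins <- fixed_bins(c(chr1 = 1e6), 1e5)
  set.seed(2)
  ms <- lapply(1:3, function(k) {
    d <- matrix(rpois(100, 4), 10)
    contact_matrix(bins, d + t(d))
  })
  zero <- contact_matrix(bins, matrix(0, 10, 10))
  expect_equal(as.matrix(merge_matrices(list(ms[[1]], zero))$mat),
               as.matrix(ms[[1]]$mat))
  expect_equal(as.matrix(merge_matrices(list(ms[[1]], ms[[1]]))$mat),
               2 * as.matrix(ms[[1]]$mat))
  expect_equal(as.matrix(merge_matrices(ms)$mat),
               as.matrix(ms[[1]]$mat) + as.matrix(ms[[2]]$mat) +
                 as.matrix(ms[[3]]$mat))
  other <- contact_matrix(fixed_bins(c(chr2 = 1e6), 1e5), matrix(0, 10, 10))
  expect_error(merge_matrices(list(ms[[1]], other)), "bin tables differ")
})

test_that("remove_chromosomes extracts the remaining block", {
  bins <- fixed_bins(c(chr1 = 5e5, chr2 = 5e5), 1e5)
  set.seed(3)
  d <- matrix(rpois(100, 3), 10); d <- d + t(d)
  m <- contact_matrix(bins, d)
  expect_identical(remove_chromosomes(m, "chrY"), m)
  m2 <- remove_chromosomes(m, "chr2")
  expect_equal(as.matrix(m2$mat), d[1:5, 1:5])
  expect_equal(m2$bins$bin, 0:4)
  expect_warning(remove_chromosomes(m, c("chr1", "chr2")), "empty")
})

test_that("filter_bins masks by quantile and MAD as computed directly", {
  bins <- fixed_bins(c(chr1 = 1e7), 1e5)
  # uniform coverage, permissive knobs: nothing masked
  u <- matrix(1, 100, 100)
  mu <- filter_bins(contact_matrix(bins, u), low_quantile = 0,
                    mad_factor = Inf)
  expect_false(any(mu$mask))
  # one extreme bin: exactly that bin masked by the MAD cut
  set.seed(4)
  d <- matrix(rpois(1e4, 20), 100); d <- d + t(d)
  d[7, ] <- d[7, ] * 100; d[, 7] <- t(d[7, , drop = FALSE])
  d[7, 7] <- d[7, 7]
  d <- (d + t(d)) / 2
  mf <- filter_bins(contact_matrix(bins, d), low_quantile = 0, mad_factor = 3)
  cov <- rowSums(d)
  lc <- log(cov)
  expected <- lc > median(lc) + 3 * mad(lc)
  expect_identical(which(mf$mask), which(expected))
  expect_identical(which(mf$mask), 7L)
  expect_true(all(as.matrix(mf$mat)[7, ] == 0))
  # low quantile on distinct coverages: exactly the 5 lowest masked
  set.seed(5)
  v <- sample(seq(100, 1090, by = 10))
  dl <- diag(v / 2)  # diagonal-only: coverage = v
  ml <- filter_bins(contact_matrix(bins, dl), low_quantile = 0.05,
                    mad_factor = Inf)
  expect_identical(sort(which(ml$mask)), sort(order(v)[1:5]))
  # idempotence
  expect_identical(filter_bins(ml, 0.05, Inf)$mask, ml$mask)
})

test_that("ice_normalize equalizes marginals and recovers planted bias", {
  bins4 <- fixed_bins(c(chr1 = 3e5), 1e5)
  # hand 3x3 matrix vs independent scalar iteration
  h <- matrix(c(0, 2, 4, 2, 0, 8, 4, 8, 0), 3)
  bins3 <- bin_table("chr1", c(0, 1e5, 2e5), c(1e5, 2e5, 3e5))
  mi <- ice_normalize(contact_matrix(bins3, h), tol = 1e-10, max_iter = 1000)
  marg <- marginals(mi)
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-8)
  # oracle: same fixed point reached by naive elementwise loop
  W <- h; b <- rep(1, 3)
  for (it in 1:1000) {
    s <- rowSums(W); f <- s / mean(s)
    b <- b * f
    W <- h / outer(b, b)
  }
  expect_equal(as.matrix(mi$mat), W, tolerance = 1e-6)
  # fixed point: balanced matrix unchanged, bias uniform
  bal <- matrix(1, 3, 3)
  mb <- ice_normalize(contact_matrix(bins3, bal))
  expect_equal(as.matrix(mb$mat), bal)
  expect_equal(mb$bias, rep(1, 3))
  # planted-bias recovery on a Sinkhorn-balanced kernel
  n <- 60
  K <- sinkhorn_balance((1 + abs(outer(1:n, 1:n, "-")))^-1)
  set.seed(6); bias <- rlnorm(n, 0, 0.3)
  binsN <- fixed_bins(c(chr1 = n * 1e5), 1e5)
  mr <- ice_normalize(contact_matrix(binsN, K * outer(bias, bias)),
                      tol = 1e-10, max_iter = 1000)
  expect_gt(cor(mr$bias, bias), 0.999)
  # scale invariance: counts * c -> matrix * c, bias shape unchanged
  m1 <- ice_normalize(contact_matrix(bins3, h), tol = 1e-10, max_iter = 1000)
  m5 <- ice_normalize(contact_matrix(bins3, 5 * h), tol = 1e-10,
                      max_iter = 1000)
  expect_equal(as.matrix(m5$mat), 5 * as.matrix(m1$mat), tolerance = 1e-6)
  expect_equal(m5$bias / m5$bias[1], m1$bias / m1$bias[1], tolerance = 1e-6)
  # unmasked zero row rejected; non-convergence warns
  z <- h; z[1, ] <- 0; z[, 1] <- 0
  expect_error(ice_normalize(contact_matrix(bins3, z)), "all-zero")
  expect_warning(ice_normalize(contact_matrix(bins3, h), tol = 1e-12,
                               max_iter = 2), "not converged")
})

test_that("rebin conserves totals and matches dense aggregation", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE), collapse = "")
  frag <- restriction_bins(c(chr1 = s), "GATC")
  nf <- nrow(frag)
  d <- matrix(rpois(nf * nf, 2), nf); d <- d + t(d)
  m <- contact_matrix(frag, d)
  r <- rebin(m, 1e4)
  expect_equal(matrix_total(r), matrix_total(m))
  # dense brute-force aggregation by fragment midpoint (each unordered
  # fragment pair counted once, as in the pair-count convention)
  mid <- floor((frag$start + frag$end) / 2)
  grp <- pmin(mid %/% 1e4, ceiling(nchar(s) / 1e4) - 1) + 1
  ng <- nrow(r$bins)
  dense <- matrix(0, ng, ng)
  dm <- as.matrix(m$mat)
  for (i in seq_len(nf)) for (j in i:nf) {
    a <- min(grp[i], grp[j]); b <- max(grp[i], grp[j])
    dense[a, b] <- dense[a, b] + dm[i, j]
  }
  got <- as.matrix(r$mat)
  got[lower.tri(got)] <- 0
  expect_equal(unname(got), unname(dense))
  # identity rebin at the existing uniform size
  bins <- fixed_bins(c(chr1 = 1e6), 1e5)
  du <- matrix(rpois(100, 3), 10); du <- du + t(du)
  mu <- contact_matrix(bins, du)
  ru <- rebin(mu, 1e5)
  expect_equal(as.matrix(ru$mat), as.matrix(mu$mat))
  expect_error(rebin(mu, 0), "resolution")
})

test_that("COO round trip preserves matrix, bins and mask", {
  g <- generate_genome(1, 2e6, 1e5, 4e5, 5, seed = 1)
  m <- simulate_contacts(g, sim_params(depth = 5e4), seed = 2)
  m <- filter_bins(m, 0.1, 3)
  mp <- tempfile(); bp <- tempfile()
  write_matrix_coo(m, mp, bp)
  m2 <- read_matrix_coo(mp, bp)
  expect_equal(as.matrix(m2$mat), as.matrix(m$mat))
  expect_identical(m2$mask, m$mask)
  expect_identical(m2$bins, m$bins)
})
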
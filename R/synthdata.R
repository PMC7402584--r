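# Synthetic Hi-C world with planted structure: distance-decaying contacts
# with a two-state plaid (compartment) overlay, block-diagonal TAD
# enrichment, multiplicative per-bin biases, Poisson counting noise,
# A-compartment-elevated expression, and activating-mark peaks concentrated
# in A bins.  Every generator is deterministic under its seed.

#' Simulation parameter set
#'
#' Bundles the knobs of the synthetic contact model.  Defaults are the
#' package's stated world: decay exponent 1 (the qualitative Hi-C decay),
#' plaid factor 1.6 and depth 2e6 pairs (compartment-recovery regime), TAD
#' factor 2, log-normal bias sigma 0.3, one log10 unit of A-compartment
#' expression excess, and H3K36me3-like peak probabilities 0.6 (A) vs 0.1 (B).
#'
#' @param decay_exponent alpha in expected contact ~ (1+d)^-alpha, d in bins.
#' @param plaid_factor multiplier (>= 1) for same-compartment bin pairs.
#' @param tad_factor multiplier (>= 1) for within-TAD bin pairs.
#' @param depth total expected read pairs over the genome.
#' @param bias_sd log-normal sigma of per-bin biases (see
#'   [generate_genome()]).
#' @param expr_logfc mean log10(TPM+1) excess of A-compartment genes.
#' @param peak_prob_A,peak_prob_B per-bin peak probabilities by compartment.
#' @return list of class `SimulationParams`.
#' @export
sim_params <- function(decay_exponent = 1, plaid_factor = 1.6, tad_factor = 2,
                       depth = 2e6, bias_sd = 0.3, expr_logfc = 1,
                       peak_prob_A = 0.6, peak_prob_B = 0.1) {
  check_scalar(decay_exponent, "decay_exponent", lower = 0)
  check_scalar(plaid_factor, "plaid_factor", lower = 1)
  check_scalar(tad_factor, "tad_factor", lower = 1)
  check_scalar(depth, "depth", lower = 0, strict_lower = TRUE)
  check_scalar(bias_sd, "bias_sd", lower = 0)
  check_scalar(expr_logfc, "expr_logfc")
  check_scalar(peak_prob_A, "peak_prob_A", lower = 0, upper = 1)
  check_scalar(peak_prob_B, "peak_prob_B", lower = 0, upper = 1)
  if (peak_prob_B > peak_prob_A)
    stop("peak_prob_B must not exceed peak_prob_A", call. = FALSE)
  structure(list(decay_exponent = decay_exponent, plaid_factor = plaid_factor,
                 tad_factor = tad_factor, depth = depth, bias_sd = bias_sd,
                 expr_logfc = expr_logfc, peak_prob_A = peak_prob_A,
                 peak_prob_B = peak_prob_B),
            class = "SimulationParams")
}

#' Construct a synthetic genome with explicit planted truth
#'
#' Low-level constructor used both by [generate_genome()] and directly by
#' tests that need exact planted structure (e.g. ten 10-bin TADs).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp; must divide every chromosome length.
#' @param compartment per-bin labels, "A"/"B", length = total bins.
#' @param tads list (per chromosome, same order/names as `chrom_sizes`) of
#'   data.frames with columns start, end (bp, half-open) tiling the
#'   chromosome.
#' @param bias per-bin positive factors.
#' @param seed integer recorded for provenance.
#' @return object of class `SyntheticGenome`.
#' @export
synthetic_genome <- function(chrom_sizes, bin_size, compartment, tads, bias,
                             seed = NA_integer_) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (any(sizes %% bin_size != 0))
    stop("bin_size must divide every chromosome length", call. = FALSE)
  bins <- fixed_bins(sizes, bin_size)
  n <- nrow(bins)
  compartment <- as.character(compartment)
  stopifnot(length(compartment) == n, all(compartment %in% c("A", "B")),
            length(bias) == n, all(bias > 0),
            identical(sort(names(tads)), sort(names(sizes))))
  for (ch in names(sizes)) {
    tt <- tads[[ch]]
    o <- order(tt$start)
    tt <- tt[o, , drop = FALSE]
    if (tt$start[1L] != 0 || tt$end[nrow(tt)] != sizes[[ch]] ||
        (nrow(tt) > 1L && any(tt$start[-1L] != tt$end[-nrow(tt)])))
      stop(sprintf("TAD intervals must tile chromosome %s exactly", ch),
           call. = FALSE)
    tads[[ch]] <- tt
  }
  structure(list(chrom_sizes = sizes, bin_size = bin_size, bins = bins,
                 compartment_truth = compartment, tad_truth = tads,
                 bias_truth = as.numeric(bias), seed = seed),
            class = "SyntheticGenome")
}

#' Generate a random synthetic genome
#'
#' Compartment labels alternate in blocks of geometric length (mean
#' `compartment_block_bins` bins; if the mean is at least the chromosome's
#' bin count the whole chromosome becomes a single block — the only faithful
#' realization of the requested mean).  TADs are drawn with geometric sizes
#' around `mean_tad_size`, each a whole number of bins and at least 2 bins,
#' tiling each chromosome exactly.  Biases are LogNormal(0, `bias_sd`).
#'
#' @param n_chrom number of chromosomes (named chr1, chr2, ...).
#' @param chrom_length chromosome length in bp; `bin_size` must divide it.
#' @param bin_size bin width in bp.
#' @param mean_tad_size mean TAD size in bp (>= 2 * bin_size).
#' @param compartment_block_bins mean compartment block length in bins.
#' @param bias_sd log-normal sigma of per-bin biases (0 = no bias).
#' @param seed integer; fixes every random draw.
#' @return `SyntheticGenome` (see [synthetic_genome()]).
#' @export
generate_genome <- function(n_chrom = 1L, chrom_length = 1e7, bin_size = 1e5,
                            mean_tad_size = 1e6,
                            compartment_block_bins = 10L, bias_sd = 0.3,
                            seed = 1L) {
  check_scalar(n_chrom, "n_chrom", lower = 1, integer = TRUE)
  check_scalar(chrom_length, "chrom_length", lower = 1)
  check_scalar(bin_size, "bin_size", lower = 1)
  if (chrom_length %% bin_size != 0)
    stop("bin_size must divide chrom_length exactly", call. = FALSE)
  if (mean_tad_size < 2 * bin_size)
    stop("mean_tad_size must be at least 2 * bin_size", call. = FALSE)
  check_scalar(compartment_block_bins, "compartment_block_bins", lower = 1)
  check_scalar(bias_sd, "bias_sd", lower = 0)
  nb <- as.integer(chrom_length / bin_size)
  sizes <- stats::setNames(rep(chrom_length, n_chrom),
                           paste0("chr", seq_len(n_chrom)))
  with_seed(seed, {
    comp <- character(0)
    tads <- list()
    for (ch in names(sizes)) {
      # alternating geometric compartment blocks
      lab <- sample(c("A", "B"), 1L)
      cc <- character(0)
      while (length(cc) < nb) {
        len <- if (compartment_block_bins >= nb) nb
               else 1L + stats::rgeom(1L, 1 / compartment_block_bins)
        cc <- c(cc, rep(lab, min(len, nb - length(cc))))
        lab <- if (lab == "A") "B" else "A"
      }
      comp <- c(comp, cc)
      # geometric TAD sizes in bins, minimum 2 bins, tiling exactly
      mean_bins <- mean_tad_size / bin_size
      sizes_b <- integer(0)
      while (sum(sizes_b) < nb) {
        s <- 2L + stats::rgeom(1L, 1 / (mean_bins - 1))
        sizes_b <- c(sizes_b, s)
      }
      excess <- sum(sizes_b) - nb
      k <- length(sizes_b)
      sizes_b[k] <- sizes_b[k] - excess
      if (sizes_b[k] < 2L && k > 1L) {         # merge a too-small remainder
        sizes_b[k - 1L] <- sizes_b[k - 1L] + sizes_b[k]
        sizes_b <- sizes_b[-k]
      }
      ends <- cumsum(sizes_b) * bin_size
      tads[[ch]] <- data.frame(start = c(0, ends[-length(ends)]), end = ends)
    }
    bias <- if (bias_sd > 0) stats::rlnorm(nb * n_chrom, 0, bias_sd)
            else rep(1, nb * n_chrom)
    synthetic_genome(sizes, bin_size, comp, tads, bias, seed = seed)
  })
}

# TAD id per bin on one chromosome (bins of width bin_size tiling it)
tad_id_per_bin <- function(genome, chrom) {
  tt <- genome$tad_truth[[chrom]]
  starts <- genome$bins$start[genome$bins$chrom == chrom]
  findInterval(starts, tt$start)
}

#' Simulate a Poisson contact matrix from planted truth
#'
#' Expected count for intra-chromosomal bins i, j is proportional to
#' (1+|i-j|)^-alpha * plaid(i,j) * tad(i,j) * bias_i * bias_j, scaled so the
#' genome-wide expected pair total equals `depth`, then Poisson-sampled on
#' the upper triangle (diagonal included, d = 0) and mirrored.
#' Inter-chromosomal cells are zero: all downstream structure calling here is
#' intra-chromosomal.
#'
#' @param genome `SyntheticGenome`.
#' @param params `SimulationParams`.
#' @param seed integer seed.
#' @return raw-count `ContactMatrix` over the genome's bins.
#' @export
simulate_contacts <- function(genome, params = sim_params(), seed = 1L) {
  stopifnot(inherits(genome, "SyntheticGenome"),
            inherits(params, "SimulationParams"))
  check_scalar(params$depth, "depth", lower = 0, strict_lower = TRUE)
  bins <- genome$bins
  lam <- vector("list", length(genome$chrom_sizes))
  names(lam) <- names(genome$chrom_sizes)
  for (ch in names(genome$chrom_sizes)) {
    rows <- which(bins$chrom == ch)
    n <- length(rows)
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    L <- (1 + d)^(-params$decay_exponent)
    cc <- genome$compartment_truth[rows]
    same_comp <- outer(cc, cc, `==`)
    L[same_comp] <- L[same_comp] * params$plaid_factor
    tid <- tad_id_per_bin(genome, ch)
    same_tad <- outer(tid, tid, `==`)
    L[same_tad] <- L[same_tad] * params$tad_factor
    b <- genome$bias_truth[rows]
    lam[[ch]] <- L * outer(b, b)
  }
  tot <- sum(vapply(lam, function(L) {
    sum(L[upper.tri(L, diag = TRUE)])
  }, numeric(1)))
  scale <- params$depth / tot
  n_all <- nrow(bins)
  with_seed(seed, {
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    for (ch in names(lam)) {
      rows <- which(bins$chrom == ch)
      L <- lam[[ch]] * scale
      ut <- which(upper.tri(L, diag = TRUE), arr.ind = TRUE)
      x <- stats::rpois(nrow(ut), L[ut])
      nz <- x > 0
      ti <- c(ti, rows[ut[nz, 1L]])
      tj <- c(tj, rows[ut[nz, 2L]])
      tx <- c(tx, x[nz])
    }
    mat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                dims = c(n_all, n_all), symmetric = TRUE)
    contact_matrix(bins, mat)
  })
}

#' Simulate gene annotations and expression coupled to compartments
#'
#' TSS positions are uniform over the genome; log10(TPM+1) is
#' Normal(`mu_b`, `sd`) for genes whose TSS bin is planted B and
#' Normal(`mu_b` + `expr_logfc`, `sd`) for A, truncated at 0 so TPM >= 0.
#' All genes are emitted on the + strand (TSS = start).
#'
#' @param genome `SyntheticGenome`.
#' @param n_genes number of genes (>= 1).
#' @param expr_logfc mean log10(TPM+1) excess of A-compartment genes.
#' @param sd Gaussian sd on the log10(TPM+1) scale.
#' @param mu_b baseline mean log10(TPM+1) of B-compartment genes.
#' @param seed integer seed.
#' @return list with `genes` (BED6-style data.frame: chrom, start, end,
#'   gene_id, score, strand) and `expression` (data.frame: gene_id, TPM).
#' @export
simulate_genes_expression <- function(genome, n_genes = 500L, expr_logfc = 1,
                                      sd = 0.5, mu_b = 0.5, seed = 1L) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(sd, "sd", lower = 0)
  with_seed(seed, {
    sizes <- genome$chrom_sizes
    chrom <- sample(names(sizes), n_genes, replace = TRUE,
                    prob = sizes / sum(sizes))
    tss <- floor(stats::runif(n_genes) * sizes[chrom])
    ids <- sprintf("gene%04d", seq_len(n_genes))
    binrow <- locate_bins(genome$bins, chrom, tss)
    lab <- genome$compartment_truth[binrow]
    x <- stats::rnorm(n_genes, mu_b + expr_logfc * (lab == "A"), sd)
    x <- pmax(x, 0)
    genes <- data.frame(chrom = chrom,
                        start = tss,
                        end = pmin(tss + 1000, sizes[chrom]),
                        gene_id = ids, score = 0, strand = "+",
                        stringsAsFactors = FALSE, row.names = NULL)
    expr <- data.frame(gene_id = ids, TPM = 10^x - 1,
                       stringsAsFactors = FALSE)
    list(genes = genes, expression = expr)
  })
}

#' Simulate activating-mark peaks concentrated in A bins
#'
#' Emits one bin-wide peak interval per selected bin; bins are selected
#' independently with probability `peak_prob_A` (planted A) or `peak_prob_B`
#' (planted B).
#'
#' @param genome `SyntheticGenome`.
#' @param params `SimulationParams` (fields peak_prob_A / peak_prob_B).
#' @param seed integer seed.
#' @return BED3-style data.frame (chrom, start, end), possibly empty.
#' @export
simulate_peaks <- function(genome, params = sim_params(), seed = 1L) {
  stopifnot(inherits(genome, "SyntheticGenome"),
            inherits(params, "SimulationParams"))
  with_seed(seed, {
    p <- ifelse(genome$compartment_truth == "A",
                params$peak_prob_A, params$peak_prob_B)
    sel <- stats::runif(length(p)) < p
    genome$bins[sel, c("chrom", "start", "end"), drop = FALSE] |>
      (\(d) { rownames(d) <- NULL; d })()
  })
}
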
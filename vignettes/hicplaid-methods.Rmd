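---
title: "hicplaid: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicplaid: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicplaid)
```

# What the package computes

`hicplaid` is a desk-scale re-implementation of the standard integrative
Hi-C analysis chain used to compare chromatin organization between two cell
states:

1. **Matrix building and balancing** — read pairs are binned (either at
   restriction-fragment boundaries or fixed width), replicates merged, sex
   chromosomes optionally removed, low-coverage and outlier bins masked, and
   multiplicative per-bin biases removed by iterative correction (ICE).
2. **A/B compartments** — per chromosome, the corrected matrix is divided
   by its distance-decay expectation (O/E), the Pearson correlation matrix
   of the O/E rows is computed, and the first principal component (PC1)
   splits bins into two interaction families. The sign is oriented with
   activating histone-mark peaks (H3K36me3-like) so that positive PC1 means
   the active A compartment.
3. **TADs** — the corrected matrix at finer resolution is z-scored per
   diagonal; multi-window "diamond" separation scores are minimized at
   insulating edges; candidate minima are tested by a one-sided Wilcoxon
   rank-sum against their flanking maxima and Bonferroni-corrected.
4. **Switch integration** — two samples' compartment tracks are joined into
   stable A / A-to-B / B-to-A / stable B bins, genes are assigned by their
   1-bp TSS, expression (log10(TPM+1)) is contrasted across switch classes,
   TAD sets are compared by reciprocal overlap, and normalized
   per-chromosome scores are produced.
5. **Boundary motifs** — ±20 kb sequences around boundaries are scanned
   with log-odds PWMs on both strands and compared against a
   dinucleotide-shuffled background by a binomial rate test. This is a
   transparent, testable stand-in for de novo discovery tools and is not
   intended to reproduce their null models.

Every stage can be driven by the synthetic generator, which plants ground
truth so that recovery is measurable exactly.

# The synthetic world

`simulate_contacts()` draws Poisson counts around the expectation

$$\lambda_{ij} \propto (1+|i-j|)^{-\alpha}\; p^{[c_i=c_j]}\;
t^{[\mathrm{tad}_i=\mathrm{tad}_j]}\; b_i b_j ,$$

with $\alpha$ the decay exponent (default 1 — the qualitative shape of
empirical Hi-C decay), $p \ge 1$ the plaid factor for same-compartment
pairs, $t \ge 1$ the within-TAD factor, and $b_i$ log-normal biases. The
matrix is scaled so its upper-triangle total equals the requested depth,
then sampled on the upper triangle and mirrored; inter-chromosomal cells
are zero because every downstream statistic here is intra-chromosomal.

Stated-world defaults (used verbatim by the acceptance tests):

| parameter | default | role |
|---|---|---|
| `decay_exponent` | 1 | contact fall-off with bin distance |
| `plaid_factor` | 1.6 | compartment contrast (recovery regime) |
| `tad_factor` | 2 | within-TAD enrichment |
| `depth` | 2e6 pairs | sequencing depth per matrix |
| `bias_sd` | 0.3 | LogNormal sigma of per-bin biases |
| `expr_logfc` | 1.0 | A-compartment excess on log10(TPM+1) |
| `peak_prob_A` / `peak_prob_B` | 0.6 / 0.1 | peak rate by compartment |

Compartment blocks alternate with geometric lengths (mean 10 bins by
default, i.e. ~1 Mb at 100 kb — the megabase scale at which compartments
are described); when the requested mean reaches the chromosome's bin count
the whole chromosome becomes one block, the only faithful realization of
that mean. TAD sizes are geometric with a 2-bin minimum and tile each
chromosome exactly. Expression is Gaussian on the log10(TPM+1) scale
(baseline mean 0.5, sd 0.5, truncated at 0 so TPM ≥ 0) because that is the
transform on which the expression contrasts are defined. All generators
take one integer seed and restore global RNG state, so outputs are
bit-identical under a fixed seed.

What the generator does **not** emulate: mappability and GC structure in
the bias field (biases are iid), loops/stripes, nested TAD hierarchies,
translocations, replicate-level variability beyond Poisson counting, and
read-level artifacts (the pairs format is assumed pre-filtered, as those
filters live in the upstream alignment stack). A green recovery test
therefore establishes correctness of the inference chain under the stated
generative model, not performance on real libraries.

# Numerical and procedural choices

**Bin filtering.** The described "threshold on a bimodal distribution" is
realized as two explicit knobs on the log-coverage of nonzero bins: a low
quantile cut (default 0.05) and a high cut at median + 3·MAD. The raw
coverage vector is cached on the filtered object so re-filtering reproduces
the same thresholds — filtering is idempotent.

**ICE.** Plain marginal rescaling: $b \leftarrow b \cdot s/\bar s$ with
$s$ the unmasked marginals of the corrected matrix, until the maximum
relative deviation of marginals is below `tol` (default 1e-5, cap 200
iterations with a convergence warning). Scaling counts by a constant scales
the output by the same constant and leaves the bias shape unchanged. Bias
recovery against a planted vector is exact (r > 0.999) when the biased
matrix is built on a doubly balanced kernel; on structured Poisson data the
bias additionally absorbs genuine marginal structure, so no such identity
holds or is claimed.

**PC1.** Correlation is pairwise-complete with bins under 3 complete pairs
set to NA; bins whose correlation row is entirely NA (masked or constant)
get NA PC1, and any isolated remaining NA correlation is treated as 0 for
the eigendecomposition. PC1 is computed per chromosome; exact zeros are
labeled NA rather than tie-broken. Orientation compares mean peak-covered
*fraction* of positive- versus negative-PC1 bins (robust to peak
fragmentation); chromosomes without peaks keep their sign and are flagged.
A chromosome yielding fewer than 3 segments triggers a warning, since PC1
occasionally tracks chromosome arms instead of compartments.

**Separation scores.** For the edge left of bin $i$ and window $w$, the
score is the mean z over $\{(a,b): i-w \le a < i \le b < i+w\}$. Each
window's score is NA without full context; the aggregate averages the
windows that do have context and is NA only at the outermost edges where
none does. The strict alternative (aggregate NA unless *every* window
fits) silently makes the first and last real junctions of a chromosome
undetectable — they sit at the ends of the finite run and can never be
interior local minima — which is why the in-context mean was chosen.

**Boundary testing.** Candidates are local minima at least `delta` (0.01,
z-units) below both nearest flanking maxima. The rank-sum contrast pools
diamond values over all in-context windows at the candidate and at both
flank edges; pooling keeps the flank samples adequately sized near
chromosome ends, where the largest window alone provides only a handful of
values. The test is one-sided (candidate lower), exact when tie-free and
both sizes < 50, and Bonferroni-corrected over the number of candidates
actually tested, with adjusted p < 0.01 reported. TADs are the intervals
between consecutive boundaries, with chromosome-end flanks included once at
least one significant boundary exists on the chromosome.

**Switch statistics.** Conservation percentages are computed over bins
classified in both samples (NA excluded from numerator and denominator).
TAD conservation uses reciprocal >70% overlap (single-sided available via
`reciprocal = FALSE`); a TAD lies "in" switching regions when ≥50% of its
length does. The normalized per-chromosome score implements the double
division (label count ÷ chromosome total ÷ chromosome size) literally; its
1/bp units are unusual but intentional. Multiple-testing correction is not
applied across the expression contrasts, which are reported as single
tests.

**Motif enrichment.** Hits require a log2-odds score ≥ 0.8 of the maximum
attainable. Background is 10 dinucleotide-shuffled copies per foreground
sequence (Altschul–Erickson Eulerian shuffle, exact dinucleotide counts
preserved, seed-controlled). The one-sided binomial tail is evaluated via
the regularized incomplete beta, which coincides with the exact sum for
integer counts and extends smoothly to the 0.5 pseudo-hit floor used when
the background has zero hits.

# Degenerate inputs

Empty peak sets leave chromosomes unoriented (flagged, not guessed);
chromosomes under 4 unmasked bins produce all-NA compartment tracks with a
warning; windows larger than a chromosome are skipped; empty candidate
lists yield empty boundary sets; empty switch classes skip their tests;
all-masked matrices and unmasked all-zero bins are hard errors with
explicit messages.

# Known limitations

Sub-compartment calling, nested TADs, loop/stripe detection, cross-
chromosome PCA, GO enrichment and figure rendering are out of scope. The
motif stage reports rate enrichment only and does not emulate
hypergeometric ZOOPS models, so its p-values are not comparable to those of
discovery tools. Analyses here are intra-chromosomal; the simulator's
inter-chromosomal cells are structural zeros.
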
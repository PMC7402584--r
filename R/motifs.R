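# Known-motif enrichment at TAD boundaries: +/-20 kb sequence extraction,
# log-odds PWM scanning on both strands, and a binomial rate test against a
# dinucleotide-shuffled background.  A transparent, fully testable stand-in
# for de novo motif discovery tools.

#' Construct a position-weight matrix
#'
#' @param name motif name.
#' @param mat 4 x L numeric matrix of per-position base probabilities, rows
#'   A, C, G, T; every column must sum to 1 within 1e-6 and L >= 4.
#' @param bg background base frequencies (A, C, G, T), default uniform.
#' @return object of class `PWM`.
#' @export
pwm <- function(name, mat, bg = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 4L, all(mat >= 0),
            length(bg) == 4L, all(bg > 0))
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("PWM columns must sum to 1 (within 1e-6)", call. = FALSE)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, mat = mat, bg = bg / sum(bg)), class = "PWM")
}

#' Read JASPAR-style plain-text PWMs
#'
#' Accepts the common JASPAR flavors: a `>name` header followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional).  Counts are converted to
#' probabilities with a per-cell pseudocount.
#'
#' @param path text file with one or more matrices.
#' @param pseudocount added to every count before normalization.
#' @return list of `PWM` objects, named by motif.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in PWM file", call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    block <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    name <- trimws(sub("^>\\s*", "", lines[heads[h]]))
    name <- strsplit(name, "\\s+")[[1L]][1L]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(sprintf("^\\s*%s\\b", b), block)][1L]
      if (is.na(ln)) stop(sprintf("PWM %s: missing %s row", name, b),
                          call. = FALSE)
      nums <- regmatches(ln, gregexpr("[0-9.eE+-]+", ln))[[1L]]
      as.numeric(nums)
    })
    counts <- do.call(rbind, rows) + pseudocount
    out[[name]] <- pwm(name, sweep(counts, 2L, colSums(counts), "/"))
  }
  out
}

#' Extract sequences flanking TAD boundaries
#'
#' One sequence per boundary spanning `[pos - flank, pos + flank)`, clipped
#' at chromosome ends, uppercase (N allowed).  Boundaries on chromosomes
#' absent from the genome are skipped with a warning.
#'
#' @param boundaries `TADBoundaries` (chrom, pos).
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @param flank bp on each side (default 20000).
#' @return named character vector (`chrom:start-end` names).
#' @export
extract_boundary_sequences <- function(boundaries, genome, flank = 20000) {
  check_scalar(flank, "flank", lower = 1, integer = TRUE)
  seqs <- as_genome_seqs(genome)
  unknown <- setdiff(unique(boundaries$chrom), names(seqs))
  if (length(unknown))
    warning(sprintf("extract_boundary_sequences: skipping boundaries on unknown chromosome(s) %s",
                    paste(unknown, collapse = ", ")))
  bs <- boundaries[boundaries$chrom %in% names(seqs), , drop = FALSE]
  inb <- bs$pos >= 0 & bs$pos <= nchar(seqs[bs$chrom])
  if (any(!inb))
    warning(sprintf("extract_boundary_sequences: %d boundary(ies) outside chromosome bounds skipped",
                    sum(!inb)))
  bs <- bs[inb, , drop = FALSE]
  out <- character(nrow(bs))
  nm <- character(nrow(bs))
  for (r in seq_len(nrow(bs))) {
    len <- nchar(seqs[[bs$chrom[r]]])
    a <- max(0, bs$pos[r] - flank)
    b <- min(len, bs$pos[r] + flank)
    out[r] <- substr(seqs[[bs$chrom[r]]], a + 1L, b)
    nm[r] <- sprintf("%s:%d-%d", bs$chrom[r], a, b)
  }
  stats::setNames(out, nm)
}

# integer codes 1..4 for ACGT, NA otherwise
seq_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1L]], c("A", "C", "G", "T"))
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# log2-odds score at every start position; positions covering non-ACGT get -Inf
scan_scores <- function(code, lo) {
  L <- ncol(lo); n <- length(code)
  if (n < L) return(numeric(0))
  np <- n - L + 1L
  sc <- rep(0, np)
  for (k in seq_len(L)) {
    v <- lo[, k][code[k:(k + np - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every position with log2(p/background); a hit requires score >=
#' `score_fraction` times the maximum attainable score.  Overlapping hits are
#' allowed; minus-strand hits are reported at their forward-strand offset.
#'
#' @param seqs named character vector of sequences.
#' @param pwm `PWM` object.
#' @param score_fraction fraction of the maximum score (default 0.8).
#' @return data.frame of class `MotifHits`: seq_id, offset (0-based), strand,
#'   score.
#' @export
scan_pwm <- function(seqs, pwm, score_fraction = 0.8) {
  stopifnot(inherits(pwm, "PWM"))
  check_scalar(score_fraction, "score_fraction", lower = 0, upper = 1)
  lo <- log2(pwm$mat / pwm$bg)
  # minus strand = scanning with the reverse-complemented matrix
  lo_rc <- lo[c("T", "G", "C", "A"), rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  thr <- score_fraction * sum(apply(lo, 2L, max))
  res <- list()
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  for (s in seq_along(seqs)) {
    code <- seq_codes(seqs[[s]])
    for (str in c("+", "-")) {
      sc <- scan_scores(code, if (str == "+") lo else lo_rc)
      hit <- which(is.finite(sc) & sc >= thr)
      if (length(hit))
        res[[length(res) + 1L]] <- data.frame(
          seq_id = ids[s], offset = hit - 1L, strand = str,
          score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(seq_id = character(), offset = integer(),
                         strand = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: the returned sequence has exactly
#' the same dinucleotide (and hence mononucleotide) counts as the input, with
#' the first and last characters fixed.
#'
#' @param s a single sequence (character scalar).
#' @param seed integer seed.
#' @return shuffled sequence.
#' @export
dinuc_shuffle <- function(s, seed = 1L) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  if (n <= 2L) return(s)
  with_seed(seed, {
    verts <- unique(chars)
    from <- chars[-n]; to <- chars[-1L]
    last <- chars[n]
    edges <- split(to, factor(from, levels = verts))
    repeat {
      # pick a candidate final edge for every vertex except the walk's end
      last_edge <- vapply(verts, function(v) {
        if (v == last || !length(edges[[v]])) NA_character_
        else sample(edges[[v]], 1L)
      }, character(1))
      # the chosen edges must form a tree pointing into `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || !length(edges[[v]])) next
        cur <- v; seen <- character(0)
        while (cur != last) {
          if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    shuffled <- lapply(stats::setNames(verts, verts), function(v) {
      ee <- edges[[v]]
      if (!length(ee)) return(ee)
      if (v == last || is.na(last_edge[[v]])) return(sample(ee))
      pick <- which(ee == last_edge[[v]])[1L]
      c(sample(ee[-pick]), ee[pick])
    })
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- chars[1L]
    cur <- chars[1L]
    for (k in 2:n) {
      nxt <- shuffled[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[k] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Binomial motif-enrichment test
#'
#' Rate ratio (fg_hits/fg_bp) / (bg_hits/bg_bp) with a one-sided binomial
#' test of fg_hits successes out of fg_hits + bg_hits trials at null
#' probability fg_bp / (fg_bp + bg_bp).  Zero background hits are floored at
#' 0.5 pseudo-hits; the tail is then evaluated through the regularized
#' incomplete beta function, which coincides with the exact binomial sum for
#' integer counts.
#'
#' @param fg_hits,bg_hits hit counts in foreground/background.
#' @param fg_bp,bg_bp scanned lengths in bp (bg_bp >= fg_bp expected).
#' @param p_threshold significance cutoff (default 0.01).
#' @return list: ratio, p, significant.
#' @export
motif_enrichment <- function(fg_hits, fg_bp, bg_hits, bg_bp,
                             p_threshold = 0.01) {
  check_scalar(fg_hits, "fg_hits", lower = 0)
  check_scalar(bg_hits, "bg_hits", lower = 0)
  check_scalar(fg_bp, "fg_bp", lower = 0, strict_lower = TRUE)
  check_scalar(bg_bp, "bg_bp", lower = 0, strict_lower = TRUE)
  bg_eff <- max(bg_hits, 0.5)
  ratio <- (fg_hits / fg_bp) / (bg_eff / bg_bp)
  p0 <- fg_bp / (fg_bp + bg_bp)
  # P(X >= k), X ~ Binom(n, p0) == pbeta(p0, k, n - k + 1)
  p <- if (fg_hits == 0) 1 else stats::pbeta(p0, fg_hits, bg_eff + 1)
  list(ratio = ratio, p = p, significant = p < p_threshold)
}

#' Scan-and-test convenience for one motif over boundary sequences
#'
#' Builds the background as `n_shuffles` dinucleotide-shuffled copies of each
#' foreground sequence (seeded), scans both with [scan_pwm()], and runs
#' [motif_enrichment()].
#'
#' @param seqs named character vector of boundary sequences.
#' @param pwm `PWM`.
#' @param n_shuffles shuffled copies per sequence (default 10).
#' @param score_fraction scanning threshold fraction.
#' @param p_threshold significance cutoff.
#' @param seed integer seed for the shuffles.
#' @return list: motif, fg_hits, bg_hits, fg_bp, bg_bp, ratio, p,
#'   significant.
#' @export
motif_enrichment_test <- function(seqs, pwm, n_shuffles = 10,
                                  score_fraction = 0.8, p_threshold = 0.01,
                                  seed = 1L) {
  check_scalar(n_shuffles, "n_shuffles", lower = 1, integer = TRUE)
  fg <- scan_pwm(seqs, pwm, score_fraction)
  bg_seqs <- character(0)
  k <- 0L
  for (s in seq_along(seqs)) {
    for (r in seq_len(n_shuffles)) {
      k <- k + 1L
      bg_seqs <- c(bg_seqs, dinuc_shuffle(seqs[[s]], seed = seed + k))
    }
  }
  bg <- scan_pwm(bg_seqs, pwm, score_fraction)
  fg_bp <- sum(nchar(seqs)); bg_bp <- sum(nchar(bg_seqs))
  enr <- motif_enrichment(nrow(fg), fg_bp, nrow(bg), bg_bp, p_threshold)
  c(list(motif = pwm$name, fg_hits = nrow(fg), bg_hits = nrow(bg),
         fg_bp = fg_bp, bg_bp = bg_bp), enr)
}
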
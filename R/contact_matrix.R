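# ContactMatrix: a symmetric sparse matrix over a bin table, plus a per-bin
# exclusion mask and (after correction) a per-bin bias vector.

#' Construct a ContactMatrix
#'
#' @param bins bin table (see [bin_table()]).
#' @param mat symmetric numeric matrix (dense or `Matrix` sparse), one
#'   row/column per bin.
#' @param mask logical per-bin vector; `TRUE` marks bins excluded from
#'   balancing and structure calling.  Masked rows/columns must be zero.
#' @param bias per-bin positive multiplicative factor; only present on
#'   corrected matrices (`NA` at masked bins).
#' @param corrected logical; `TRUE` once [ice_normalize()] has run.
#' @return object of class `ContactMatrix`.
#' @export
contact_matrix <- function(bins, mat, mask = NULL, bias = NULL,
                           corrected = FALSE) {
  n <- nrow(bins)
  mat <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  if (nrow(mat) != n || ncol(mat) != n)
    stop("matrix dimensions do not match the bin table", call. = FALSE)
  if (!Matrix::isSymmetric(mat, tol = 0))
    stop("contact matrix must be exactly symmetric", call. = FALSE)
  mat <- methods::as(Matrix::forceSymmetric(mat, uplo = "U"), "CsparseMatrix")
  mask <- mask %||% rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  if (!is.null(bias)) stopifnot(length(bias) == n)
  structure(list(bins = bins, mat = mat, mask = mask, bias = bias,
                 corrected = corrected),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins on %d chromosome(s); %s; %d masked bin(s)\n",
              nrow(x$bins), length(unique(x$bins$chrom)),
              if (x$corrected) "corrected" else "raw counts", sum(x$mask)))
  cat(sprintf("  total (upper triangle + diagonal): %.6g\n", matrix_total(x)))
  invisible(x)
}

#' Total of a contact matrix over the upper triangle plus diagonal
#'
#' For raw matrices this equals the number of pairs counted.
#' @param m ContactMatrix.
#' @return numeric scalar.
#' @export
matrix_total <- function(m) {
  tm <- methods::as(m$mat, "TsparseMatrix")  # symmetric: stores one triangle
  sum(tm@x)
}

#' Per-bin marginal sums (full symmetric row sums)
#' @param m ContactMatrix.
#' @return numeric vector, one value per bin.
#' @export
marginals <- function(m) as.numeric(Matrix::rowSums(m$mat))

# dense per-chromosome submatrix with NA at masked bins; returns list(mat, rows)
cm_dense_chrom <- function(m, chrom) {
  rows <- which(m$bins$chrom == chrom)
  d <- as.matrix(m$mat[rows, rows, drop = FALSE])
  bad <- m$mask[rows]
  d[bad, ] <- NA_real_
  d[, bad] <- NA_real_
  list(mat = d, rows = rows, masked = bad)
}

#' Bin read pairs into a contact matrix
#'
#' Each pair contributes one count to the (i, j) cell holding its two ends.
#' Pairs on chromosomes absent from the bin table, or with missing/out-of-
#' range positions, are skipped and their count logged — never silently.
#'
#' @param pairs data.frame with columns chrom1, pos1, chrom2, pos2 (bp).
#' @param bins bin table.
#' @return raw-count `ContactMatrix`; total equals the number of accepted
#'   pairs.
#' @export
pairs_to_matrix <- function(pairs, bins) {
  stopifnot(all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(pairs)))
  n <- nrow(bins)
  i <- locate_bins(bins, as.character(pairs$chrom1), as.numeric(pairs$pos1))
  j <- locate_bins(bins, as.character(pairs$chrom2), as.numeric(pairs$pos2))
  ok <- !is.na(i) & !is.na(j)
  if (any(!ok))
    log_msg("pairs_to_matrix: skipped %d of %d pairs (unknown chromosome or position out of range)",
            sum(!ok), length(ok))
  i <- i[ok]; j <- j[ok]
  lo <- pmin(i, j); hi <- pmax(i, j)
  mat <- Matrix::sparseMatrix(i = lo, j = hi, x = 1, dims = c(n, n),
                              symmetric = TRUE)
  contact_matrix(bins, mat)
}

#' Merge replicate contact matrices by element-wise sum
#'
#' @param ms list of raw-count `ContactMatrix` objects over identical bin
#'   tables.
#' @return merged `ContactMatrix`.
#' @export
merge_matrices <- function(ms) {
  stopifnot(is.list(ms), length(ms) >= 1L)
  ref <- ms[[1L]]
  for (m in ms[-1L]) {
    if (!identical(m$bins[c("chrom", "start", "end")],
                   ref$bins[c("chrom", "start", "end")]))
      stop("merge_matrices: bin tables differ", call. = FALSE)
  }
  tot <- Reduce(`+`, lapply(ms, function(m) m$mat))
  contact_matrix(ref$bins, tot)
}

#' Drop chromosomes from a contact matrix
#'
#' Bins of the listed chromosomes are deleted and bin indices re-densified.
#' Chromosome Y removal before correction is the canonical use.
#'
#' @param m ContactMatrix.
#' @param names character vector of chromosome names (absent names are a
#'   no-op).
#' @return ContactMatrix without the listed chromosomes.
#' @export
remove_chromosomes <- function(m, names) {
  keep <- !(m$bins$chrom %in% names)
  if (all(keep)) return(m)
  if (!any(keep)) {
    warning("remove_chromosomes: all chromosomes removed; matrix is empty")
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), bin = integer())
    return(structure(list(bins = empty,
                          mat = Matrix::sparseMatrix(i = integer(), j = integer(),
                                                     x = numeric(), dims = c(0L, 0L),
                                                     symmetric = TRUE),
                          mask = logical(0), bias = NULL, corrected = m$corrected),
                     class = "ContactMatrix"))
  }
  bins <- bin_table(m$bins$chrom[keep], m$bins$start[keep], m$bins$end[keep])
  contact_matrix(bins, m$mat[keep, keep, drop = FALSE],
                 mask = m$mask[keep],
                 bias = if (!is.null(m$bias)) m$bias[keep] else NULL,
                 corrected = m$corrected)
}

#' Aggregate a fragment-resolution matrix to fixed-width bins
#'
#' Each source bin (fragment) is assigned to the fixed-width bin containing
#' its midpoint; values are aggregated by sum, so the pair total is conserved.
#' The mask and bias are dropped: rebinning is intended for raw matrices
#' upstream of filtering and correction.
#'
#' @param m ContactMatrix.
#' @param resolution target bin width in bp.
#' @return ContactMatrix on a fixed-width bin table (last bin of each
#'   chromosome truncated at the chromosome end).
#' @export
rebin <- function(m, resolution) {
  check_scalar(resolution, "resolution", lower = 0, strict_lower = TRUE,
               integer = TRUE)
  sizes <- tapply(m$bins$end, m$bins$chrom, max)
  sizes <- sizes[unique(m$bins$chrom)]   # keep original chromosome order
  bins <- fixed_bins(sizes, resolution)
  mid <- floor((m$bins$start + m$bins$end) / 2)
  map <- locate_bins(bins, m$bins$chrom, mid)
  stopifnot(!anyNA(map))
  tm <- methods::as(m$mat, "TsparseMatrix")
  ni <- map[tm@i + 1L]; nj <- map[tm@j + 1L]
  lo <- pmin(ni, nj); hi <- pmax(ni, nj)
  mat <- Matrix::sparseMatrix(i = lo, j = hi, x = tm@x,
                              dims = c(nrow(bins), nrow(bins)),
                              symmetric = TRUE)
  contact_matrix(bins, mat)
}
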
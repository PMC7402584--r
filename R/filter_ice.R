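# Bin filtering and ICE (iterative correction) matrix balancing.

#' Mask low-count and outlier bins
#'
#' Amplification and mappability artifacts show up as a low mode and extreme
#' outliers in the per-bin coverage distribution.  Thresholds are computed on
#' the log-coverage of nonzero bins of the *raw* matrix: bins below the
#' `low_quantile` quantile, or above median + `mad_factor` * MAD, are masked
#' (rows/columns zeroed, recorded in the mask).  The raw coverage vector is
#' stored with the result so that re-filtering with the same parameters
#' reproduces the same thresholds — the operation is idempotent.
#'
#' @param m raw-count ContactMatrix.
#' @param low_quantile fraction; quantile of log-coverage below which bins are
#'   masked (0 disables the low cut for nonzero bins; zero-coverage bins are
#'   always masked).
#' @param mad_factor unitless; high cut at median + mad_factor * MAD of
#'   log-coverage (`Inf` disables).
#' @return ContactMatrix with updated mask and zeroed masked rows/columns.
#' @export
filter_bins <- function(m, low_quantile = 0.05, mad_factor = 3) {
  check_scalar(low_quantile, "low_quantile", lower = 0, upper = 1)
  if (!(is.numeric(mad_factor) && length(mad_factor) == 1L &&
        (is.finite(mad_factor) || is.infinite(mad_factor)) && mad_factor >= 0))
    stop("'mad_factor' must be a non-negative number (Inf allowed)", call. = FALSE)
  cov_raw <- attr(m, "coverage_raw") %||% marginals(m)
  nz <- cov_raw > 0
  if (!any(nz)) stop("filter_bins: all bins have zero coverage", call. = FALSE)
  lc <- log(cov_raw[nz])
  low <- if (low_quantile > 0) stats::quantile(lc, low_quantile, names = FALSE)
         else -Inf
  high <- if (is.finite(mad_factor))
    stats::median(lc) + mad_factor * stats::mad(lc) else Inf
  bad <- !nz
  bad[nz] <- lc < low | lc > high
  if (all(bad))
    stop("filter_bins: thresholds mask every bin; relax low_quantile/mad_factor",
         call. = FALSE)
  mat <- m$mat
  if (any(bad)) {
    keep <- Matrix::Diagonal(length(bad), x = as.numeric(!bad))
    mat <- methods::as(Matrix::forceSymmetric(keep %*% mat %*% keep, uplo = "U"),
                       "CsparseMatrix")
  }
  out <- contact_matrix(m$bins, mat, mask = bad, corrected = FALSE)
  attr(out, "coverage_raw") <- cov_raw
  out
}

#' Iterative correction (ICE) of a filtered contact matrix
#'
#' Removes multiplicative per-bin biases by the marginal-rescaling iteration:
#' maintain a bias vector b with corrected matrix W_ij = M_ij / (b_i b_j);
#' repeat b <- b * (marginal(W) / mean marginal(W)) over unmasked bins until
#' the maximum relative deviation of unmasked marginals from their mean drops
#' below `tol`, or `max_iter` is reached (which logs a convergence warning).
#' After convergence the unmasked marginals of W are equal within `tol`.
#'
#' @param m filtered ContactMatrix (unmasked all-zero bins are an error: mask
#'   them first).
#' @param tol relative marginal deviation at convergence.
#' @param max_iter iteration cap.
#' @return corrected ContactMatrix with `bias` set (NA at masked bins) and
#'   `corrected = TRUE`.
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 200L) {
  check_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  check_scalar(max_iter, "max_iter", lower = 1, integer = TRUE)
  un <- which(!m$mask)
  if (!length(un)) stop("ice_normalize: no unmasked bins", call. = FALSE)
  marg0 <- marginals(m)
  if (any(marg0[un] == 0))
    stop("ice_normalize: unmasked all-zero bin(s) present; run filter_bins first",
         call. = FALSE)
  W <- m$mat
  b <- rep(1, nrow(m$bins))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric(Matrix::rowSums(W))[un]
    dev <- max(abs(s / mean(s) - 1))
    if (dev < tol) { converged <- TRUE; break }
    f <- s / mean(s)
    b[un] <- b[un] * f
    scale <- rep(1, nrow(m$bins)); scale[un] <- 1 / f
    D <- Matrix::Diagonal(length(scale), x = scale)
    W <- methods::as(Matrix::forceSymmetric(D %*% W %*% D, uplo = "U"),
                     "CsparseMatrix")
  }
  if (!converged)
    warning(sprintf("ice_normalize: not converged after %d iterations (deviation %.3g)",
                    max_iter, dev))
  bias <- rep(NA_real_, nrow(m$bins))
  bias[un] <- b[un]
  contact_matrix(m$bins, W, mask = m$mask, bias = bias, corrected = TRUE)
}
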
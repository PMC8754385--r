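#' Remove confounds by linear regression
#'
#' Projects each node's time series onto the orthogonal complement of
#' `[intercept | confounds]` by ordinary least squares, returning the
#' residuals. Collinear confound columns are dropped with a warning (QR
#' pivoting decides which). A one-hot "scrub" regressor therefore zeroes the
#' flagged volume's residual exactly.
#'
#' @param ts Volumes-by-nodes numeric matrix.
#' @param confounds Volumes-by-k numeric matrix or data frame (no intercept
#'   column needed; one is always added). `NULL` mean-centers only.
#' @return Residual matrix, same shape and dimnames as `ts`.
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  y <- as.matrix(ts)
  n <- nrow(y)
  x <- cbind(`(intercept)` = rep(1, n))
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    if (nrow(cf) != n) abort("Confounds must have one row per volume.")
    if (ncol(cf) >= n) abort("More confounds than volumes.")
    x <- cbind(x, cf)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    warn(paste0("Dropping collinear confound column(s): ",
                paste(dropped, collapse = ", ")))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  res <- qr.resid(qx, y)
  dimnames(res) <- dimnames(y)
  res
}

#' Quadratic motion confound expansion
#'
#' The 6 rigid-body parameters and their squares, the standard 12-column
#' motion design.
#'
#' @param motion Volumes-by-6 motion matrix.
#' @return Volumes-by-12 matrix.
#' @export
motion_confounds <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) abort("Motion table must have 6 columns.")
  out <- cbind(m, m^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"))
  out
}

#' One-hot scrub regressors for flagged volumes
#'
#' @param flagged Integer vector of volume indices to scrub.
#' @param n_vols Number of volumes.
#' @return Volumes-by-length(flagged) 0/1 matrix (or NULL if none).
#' @export
scrub_regressors <- function(flagged, n_vols) {
  flagged <- unique(as.integer(flagged))
  if (!length(flagged)) return(NULL)
  if (any(flagged < 1L | flagged > n_vols)) abort("Scrub index out of range.")
  out <- matrix(0, n_vols, length(flagged))
  out[cbind(flagged, seq_along(flagged))] <- 1
  colnames(out) <- paste0("scrub", flagged)
  out
}

#' Zero-phase ideal band-pass filter
#'
#' Filters each column of a time-series matrix with an ideal frequency-
#' domain mask: Fourier coefficients with frequency magnitude outside
#' `[low, high]` Hz are zeroed and the series inverted back. The mask is
#' symmetric, so the filter is zero-phase and idempotent; the DC component
#' is removed whenever `low > 0`.
#'
#' @param ts Volumes-by-nodes numeric matrix.
#' @param tr Repetition time, seconds.
#' @param low,high Pass-band edges in Hz; `0 <= low < high < 1/(2 tr)`.
#' @return Filtered matrix, same shape.
#' @export
bandpass_filter <- function(ts, tr, low = 0.008, high = 0.09) {
  y <- as.matrix(ts)
  n <- nrow(y)
  nyq <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) abort("Need 0 <= low < high.")
  if (high >= nyq) abort("`high` must be below the Nyquist frequency.")
  freqs <- (seq_len(n) - 1L) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)          # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  out <- apply(y, 2, function(col) Re(fft(fft(col) * keep, inverse = TRUE)) / n)
  dimnames(out) <- dimnames(y)
  out
}
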
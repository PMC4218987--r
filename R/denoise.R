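#' Low-rank SVD denoising
#'
#' Decomposes the normalized matrix as `U D V'` and reconstructs it
#' from the leading `k` singular triplets (default 50, the rank used
#' for the full experiment collection), discarding the trailing
#' directions that are dominated by uncorrelated noise. `k` is capped
#' at the matrix rank; by Eckart-Young the Frobenius reconstruction
#' error is the root of the sum of squared discarded singular values.
#'
#' @param matrix a `CountMatrix` (no missing values).
#' @param k number of leading singular vectors to keep.
#' @return reconstructed `CountMatrix`.
#' @export
svd_denoise <- function(matrix, k = 50) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (k <= 0) stop("k must be >= 1")
  vals <- matrix$values
  if (anyNA(vals)) stop("svd_denoise: matrix contains missing values")
  r <- min(dim(vals))
  if (k < r) {
    s <- svd(vals, nu = k, nv = k)
    rec <- s$u %*% (s$d[seq_len(k)] * t(s$v))
  } else {
    if (k > r)
      message(sprintf("svd_denoise: k = %d capped at matrix rank bound %d", k, r))
    rec <- vals
  }
  dimnames(rec) <- dimnames(vals)
  count_matrix(rec, matrix$fragments, matrix$experiments)
}

# Savitzky-Golay coefficients: row `center` of the hat matrix
# X (X'X)^-1 X' for a degree-p polynomial over window offsets
savgol_coeffs <- function(window, polyorder, at = (window + 1) / 2) {
  stopifnot(window %% 2 == 1, window > polyorder)
  z <- seq_len(window) - (window + 1) / 2
  X <- outer(z, 0:polyorder, `^`)
  H <- X %*% solve(crossprod(X), t(X))
  H[at, ]
}

# smooth one numeric series; edges handled by evaluating the
# least-squares polynomial of the terminal window at the edge points
# (polynomial extrapolation within the window)
savgol_series <- function(x, window, polyorder) {
  n <- length(x)
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1
    warning("savgol: window shrunk to ", window, " for a series of length ", n)
    if (window <= polyorder) polyorder <- window - 1
  }
  h <- (window - 1) / 2
  out <- x
  cc <- savgol_coeffs(window, polyorder)
  if (n >= window && h >= 1) {
    interior <- (h + 1):(n - h)
    out[interior] <- vapply(interior, function(i)
      sum(cc * x[(i - h):(i + h)]), numeric(1))
    # terminal windows: fit the polynomial once, evaluate at the edge offsets
    z <- seq_len(window) - 1
    X <- outer(z, 0:polyorder, `^`)
    beta_l <- solve(crossprod(X), crossprod(X, x[seq_len(window)]))
    out[seq_len(h)] <- (X %*% beta_l)[seq_len(h)]
    beta_r <- solve(crossprod(X), crossprod(X, x[(n - window + 1):n]))
    out[(n - h + 1):n] <- (X %*% beta_r)[(window - h + 1):window]
  } else if (window > polyorder) {
    z <- seq_len(n) - 1
    X <- outer(z, 0:min(polyorder, n - 1), `^`)
    out <- as.numeric(X %*% solve(crossprod(X), crossprod(X, x)))
  }
  out
}

#' Savitzky-Golay smoothing of a replication profile
#'
#' Local least-squares polynomial smoothing in fragment-index space
#' (uniform filter taps; fragment lengths vary but the inter-origin
#' structure spans many fragments, so index-space smoothing is a
#' documented simplification). Applied independently per chromosome —
#' never across a chromosome boundary. Interior points use the closed
#' -form convolution weights; each terminal half-window is replaced by
#' the least-squares polynomial fitted to the terminal window
#' (polynomial extrapolation). The filter reproduces polynomials up to
#' `polyorder` exactly and is linear, so it commutes with shifts and
#' scalings of the signal.
#'
#' @param profile a `ReplicationProfile` (or any data.frame with
#'   `chrom` and `value`).
#' @param window odd window width in fragments (default 9).
#' @param polyorder polynomial degree (default 3, < window).
#' @return the smoothed profile, same shape.
#' @export
savgol_smooth <- function(profile, window = 9, polyorder = 3) {
  stopifnot(window %% 2 == 1, window > polyorder)
  out <- profile
  for (ch in unique(profile$chrom)) {
    sel <- profile$chrom == ch
    out$value[sel] <- savgol_series(profile$value[sel], window, polyorder)
  }
  out
}
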
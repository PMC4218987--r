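#' Copy-number (CNV) correction
#'
#' Chromosomal duplications or deletions shift a whole chromosome's
#' signal irrespective of replication timing. Per experiment, each
#' chromosome's values are rescaled so every chromosome has the same
#' median per-fragment signal, with the genome-wide median as the
#' reference: `factor(chrom) = median(genome) / median(chrom)`. The
#' median is robust to the origin-driven within-chromosome skew that a
#' mean would chase. A chromosome whose median is zero gets factor 1
#' with a warning. Scale factors are attached as the
#' `"cnv_factors"` attribute (chromosomes x experiments).
#'
#' @param matrix a `CountMatrix`.
#' @return corrected `CountMatrix`.
#' @export
correct_cnv <- function(matrix) {
  stopifnot(inherits(matrix, "CountMatrix"))
  vals <- matrix$values
  chroms <- unique(matrix$fragments$chrom)
  factors <- matrix(1, length(chroms), ncol(vals),
                    dimnames = list(chroms, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    target <- stats::median(vals[, j])
    for (ch in chroms) {
      sel <- matrix$fragments$chrom == ch
      m <- stats::median(vals[sel, j])
      if (m == 0) {
        warning("correct_cnv: zero median on ", ch, " in ",
                colnames(vals)[j], "; factor left at 1")
        next
      }
      factors[ch, j] <- target / m
      vals[sel, j] <- vals[sel, j] * factors[ch, j]
    }
  }
  out <- count_matrix(vals, matrix$fragments, matrix$experiments)
  attr(out, "cnv_factors") <- factors
  out
}

#' Per-experiment z-scoring
#'
#' Normalizes each experiment column to mean 0 and standard deviation 1
#' using the population convention (divisor `n`), making experiments of
#' different depth and dynamic range directly comparable. Missing
#' values are ignored in the moments and propagated.
#'
#' @param matrix a `CountMatrix`.
#' @return z-scored `CountMatrix`.
#' @export
zscore_experiments <- function(matrix) {
  stopifnot(inherits(matrix, "CountMatrix"))
  vals <- matrix$values
  if (nrow(vals) < 2) stop("z-scoring needs at least 2 fragments")
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    ok <- !is.na(x)
    mu <- mean(x[ok])
    sdv <- sqrt(mean((x[ok] - mu)^2))  # divisor n
    if (sdv == 0)
      stop("constant column cannot be z-scored: ", colnames(vals)[j])
    vals[, j] <- (x - mu) / sdv
  }
  count_matrix(vals, matrix$fragments, matrix$experiments)
}

#' Remove the fragment-length bias
#'
#' Sequencing yield depends on fragment length (size selection, PCR).
#' Per experiment, the signal is ordered by fragment length, a running
#' mean over the length-ranked values estimates the smoothed
#' length-trend, and the trend is subtracted. The bandwidth defaults to
#' 5% of the rows (an odd window, at least 3); with fewer rows than the
#' bandwidth the window shrinks with a warning. With
#' `recenter = "mean"` the column mean is added back after subtraction
#' so the signal stays on its original (positive) scale — used by the
#' pipeline ahead of the control ratio, which needs a positive-scale
#' control.
#'
#' @param matrix a `CountMatrix`.
#' @param bandwidth running-mean window (fragments); NULL = 5% of rows.
#' @param recenter `"none"` (pure subtraction, residual scale) or
#'   `"mean"` (column mean restored).
#' @return corrected `CountMatrix`.
#' @export
remove_length_bias <- function(matrix, bandwidth = NULL,
                               recenter = c("none", "mean")) {
  stopifnot(inherits(matrix, "CountMatrix"))
  recenter <- match.arg(recenter)
  n <- nrow(matrix$values)
  if (is.null(bandwidth)) bandwidth <- max(3, ceiling(0.05 * n))
  if (bandwidth > n) {
    warning("remove_length_bias: bandwidth ", bandwidth,
            " larger than row count ", n, "; shrunk")
    bandwidth <- n
  }
  if (bandwidth %% 2 == 0) bandwidth <- bandwidth - 1
  ord <- order(matrix$fragments$length)
  vals <- matrix$values
  for (j in seq_len(ncol(vals))) {
    trend_ranked <- running_mean(vals[ord, j], bandwidth)
    trend <- numeric(n)
    trend[ord] <- trend_ranked
    vals[, j] <- vals[, j] - trend
    if (recenter == "mean") vals[, j] <- vals[, j] + mean(matrix$values[, j])
  }
  count_matrix(vals, matrix$fragments, matrix$experiments)
}

# centered running mean; windows shrink symmetrically at the ends so a
# linear trend is reproduced exactly everywhere
running_mean <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  hi_ <- pmin(h, seq_len(n) - 1, n - seq_len(n))
  cs <- cumsum(c(0, x))
  lo <- seq_len(n) - hi_
  hi <- seq_len(n) + hi_
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Divide by the mean G1/G2 control signal
#'
#' The G1/G2-sorted control measures every fragment at uniform copy
#' number, so its mean across control experiments captures the
#' fragment-specific capture efficiency (mappability, residual length
#' and GC effects). Dividing every column by this per-fragment control
#' mean cancels those biases. The division is performed on
#' positive-scale (pre-z-score) signal; control means below a floor
#' (the `floor_quantile` quantile of the positive control means) flag
#' the fragment's values as missing rather than exploding. With
#' `rescore = TRUE` the ratio matrix is re-z-scored per experiment.
#'
#' @param matrix a `CountMatrix` on positive scale.
#' @param control_ids experiment ids of the control columns; default
#'   all columns with gate `"G1G2"`.
#' @param floor_quantile quantile of positive control means used as the
#'   division floor.
#' @param rescore z-score the result per experiment.
#' @param drop_controls drop the control columns from the output
#'   (they are ratios of themselves once divided).
#' @return a `CountMatrix` of ratios (possibly with NA rows flagged).
#' @export
ratio_to_control <- function(matrix, control_ids = NULL,
                             floor_quantile = 0.05, rescore = TRUE,
                             drop_controls = FALSE) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (is.null(control_ids))
    control_ids <- matrix$experiments$id[matrix$experiments$gate == "G1G2"]
  ctrl <- match(control_ids, matrix$experiments$id)
  if (length(ctrl) == 0 || anyNA(ctrl))
    stop("ratio_to_control: control columns not found (",
         paste(control_ids, collapse = ", "), ")")
  cmean <- rowMeans(matrix$values[, ctrl, drop = FALSE])
  pos <- cmean[cmean > 0]
  if (length(pos) == 0) stop("ratio_to_control: control mean is nowhere positive")
  floor_val <- stats::quantile(pos, floor_quantile, names = FALSE)
  low <- cmean < floor_val
  if (any(low))
    message(sprintf(
      "ratio_to_control: %d fragments below control floor %.4g flagged missing",
      sum(low), floor_val))
  vals <- sweep(matrix$values, 1, cmean, "/")
  vals[low, ] <- NA_real_
  out <- count_matrix(vals, matrix$fragments, matrix$experiments)
  if (drop_controls) out <- subset_cols(out, matrix$experiments$gate != "G1G2")
  if (rescore) out <- zscore_experiments(out)
  out
}
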
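#' Fraction of the genome covered by origin windows
#'
#' Places a window of `half_width` bp on each side of every reference
#' origin, clips to chromosome bounds, merges overlaps, and returns
#' union length / genome length. This is the success probability `p`
#' of the null model: a uniformly random genomic location counts as a
#' "real" origin exactly when it lands in one of these windows.
#'
#' @param origins data.frame with `chrom`, `pos`.
#' @param genome a `GenomeSpec`.
#' @param half_width window half-width in bp (default 5000).
#' @return coverage fraction in `[0, 1]`.
#' @export
window_coverage_fraction <- function(origins, genome, half_width = 5000) {
  stopifnot(inherits(genome, "GenomeSpec"))
  if (nrow(origins) == 0) return(0)
  covered <- 0
  for (ch in unique(origins$chrom)) {
    L <- chrom_length(genome, ch)
    pos <- origins$pos[origins$chrom == ch]
    # windows [x - hw, x + hw) in 0-based half-open coordinates,
    # clipped to [0, L); IRanges is 1-based closed, hence the shift
    s <- pmax(pos - half_width, 0)
    e <- pmin(pos + half_width, L)
    ir <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / genome_length(genome)
}

#' Match predicted peaks to reference origins
#'
#' A predicted origin (profile peak) is "real" if at least one
#' reference origin lies within `max_dist` bp on the same chromosome
#' (inclusive: distance exactly `max_dist` matches). Each peak is
#' evaluated independently, so several peaks may match one origin.
#'
#' @param peaks data.frame with `chrom`, `pos` (predicted origins).
#' @param origins data.frame with `chrom`, `pos` (reference).
#' @param max_dist matching distance in bp (default 5000).
#' @return list with `N` (peaks), `K` (matched peaks), and `pairs`
#'   (data.frame of each matched peak with its nearest origin and
#'   distance).
#' @export
match_peaks <- function(peaks, origins, max_dist = 5000) {
  N <- nrow(peaks)
  if (N == 0 || nrow(origins) == 0)
    return(list(N = N, K = 0L,
                pairs = data.frame(chrom = character(), peak = numeric(),
                                   origin = numeric(), dist = numeric())))
  pairs <- list()
  K <- 0L
  for (ch in unique(peaks$chrom)) {
    pp <- peaks$pos[peaks$chrom == ch]
    oo <- sort(origins$pos[origins$chrom == ch])
    if (length(oo) == 0) next
    # nearest origin via the sorted neighbourhood of each peak
    i <- findInterval(pp, oo)
    d_lo <- ifelse(i >= 1, abs(pp - oo[pmax(i, 1)]), Inf)
    d_hi <- ifelse(i < length(oo), abs(oo[pmin(i + 1, length(oo))] - pp), Inf)
    near <- ifelse(d_hi < d_lo, oo[pmin(i + 1, length(oo))], oo[pmax(i, 1)])
    d <- pmin(d_lo, d_hi)
    hit <- d <= max_dist
    K <- K + sum(hit)
    if (any(hit))
      pairs[[length(pairs) + 1]] <-
        data.frame(chrom = ch, peak = pp[hit], origin = near[hit],
                   dist = d[hit])
  }
  list(N = N, K = as.integer(K),
       pairs = if (length(pairs)) do.call(rbind, pairs)
       else data.frame(chrom = character(), peak = numeric(),
                       origin = numeric(), dist = numeric()))
}

#' Binomial tail probability of the match count (log10)
#'
#' Under the null that the N predicted origins are uniformly random
#' locations, each matches independently with probability `p` (the
#' window coverage fraction), so the number of matches is
#' Binomial(N, p) and the enrichment P-value is the upper tail
#' `P(X >= K) = sum_{i=K}^{N} C(N,i) p^i (1-p)^(N-i)`. Computed in log
#' space so tails of order 1e-100 keep full relative precision; the
#' return value is log10 of the tail.
#'
#' @param N number of predicted origins.
#' @param K number matched (`0 <= K <= N`).
#' @param p null success probability in (0, 1).
#' @return log10 of the tail probability (0 when K = 0).
#' @export
binom_tail_pvalue <- function(N, K, p) {
  stopifnot(length(N) == 1, length(K) == 1, length(p) == 1)
  if (K < 0 || K > N) stop("K must satisfy 0 <= K <= N")
  if (p <= 0 || p >= 1) stop("p must lie strictly inside (0, 1)")
  if (K == 0) return(0)
  stats::pbinom(K - 1, size = N, prob = p,
                lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Brute-force binomial tail oracle
#'
#' Independent check for [binom_tail_pvalue()]: explicit term-by-term
#' summation of `C(N,i) p^i (1-p)^(N-i)` with binomial coefficients
#' from Pascal-style log recursion, summed from the smallest term up.
#' Positive-term summation is well conditioned, so doubles give ~1e-13
#' relative accuracy — it shares no code path with the incomplete-beta
#' routine behind `pbinom`.
#'
#' @param N,K,p as in [binom_tail_pvalue()].
#' @return the tail probability itself (not log10).
#' @export
binom_tail_bruteforce <- function(N, K, p) {
  if (K == 0) return(1)
  i <- N:K  # smallest terms first when K is in the upper tail
  lc <- cumsum(c(0, log(seq_len(N)))) # log factorials 0..N
  lt <- lc[N + 1] - lc[i + 1] - lc[N - i + 1] + i * log(p) + (N - i) * log1p(-p)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

#' Evaluate peak-based origin prediction
#'
#' Composes peak calling, the 5-kb matching rule, the genome coverage
#' fraction and the binomial tail statistic into one report: how much
#' better than chance do the profile's peaks land near known origins.
#'
#' @param profile a smoothed `ReplicationProfile`.
#' @param origins reference origins (data.frame `chrom`, `pos`).
#' @param genome a `GenomeSpec`.
#' @param half_width matching distance / window half-width (bp).
#' @param min_prominence passed to [find_extrema()].
#' @return object of class `PredictionResult`: list with `N`, `K`,
#'   `d`, `p`, `log10_p_value`, `peaks`, `pairs`.
#' @export
evaluate_prediction <- function(profile, origins, genome,
                                half_width = 5000, min_prominence = 0.2) {
  ext <- find_extrema(profile, min_prominence = min_prominence)
  peaks <- data.frame(chrom = ext$maxima$chrom, pos = ext$maxima$midpoint)
  m <- match_peaks(peaks, origins, max_dist = half_width)
  p <- window_coverage_fraction(origins, genome, half_width = half_width)
  lp <- if (m$N == 0) 0 else binom_tail_pvalue(m$N, m$K, p)
  structure(list(N = m$N, K = m$K, d = half_width, p = p,
                 log10_p_value = lp, peaks = peaks, pairs = m$pairs),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf(
    "PredictionResult: %d/%d peaks within %d bp of an origin (coverage p = %.3f), log10 P = %.2f\n",
    x$K, x$N, x$d, x$p, x$log10_p_value))
  invisible(x)
}

#' Serialize a prediction result as JSON
#' @param result a `PredictionResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(result, path) {
  jsonlite::write_json(
    list(N = result$N, K = result$K, d = result$d, p = result$p,
         log10_p_value = result$log10_p_value),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
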
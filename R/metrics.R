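#' Call local extrema of a replication profile
#'
#' Local maxima of a smoothed profile mark active origins; minima mark
#' termination zones between them. A point is a candidate maximum when
#' it is higher than both neighbours (a plateau of equal values yields
#' its centre point); candidates are kept when their topographic
#' prominence — the drop to the highest saddle separating the point
#' from higher terrain, measured on each side up to the nearest higher
#' point or the chromosome end — reaches `min_prominence` times the
#' profile standard deviation. Minima are called symmetrically on the
#' negated signal. Chromosome-terminal points are never extrema, and
#' retained maxima and minima are forced to alternate (within a run of
#' same-type extrema only the most extreme survives).
#'
#' @param profile a `ReplicationProfile` (smoothed).
#' @param min_prominence prominence threshold as a fraction of the
#'   profile standard deviation (default 0.2).
#' @return object of class `ExtremaSet`: list with data.frames
#'   `maxima` and `minima` (`chrom`, `row` — row index into the
#'   profile, `midpoint`, `value`) and the absolute `threshold` used.
#' @export
find_extrema <- function(profile, min_prominence = 0.2) {
  threshold <- min_prominence * stats::sd(profile$value)
  maxima <- list(); minima <- list()
  for (ch in unique(profile$chrom)) {
    rows <- which(profile$chrom == ch)
    x <- profile$value[rows]
    if (length(x) < 3) {
      warning("find_extrema: chromosome ", ch, " has fewer than 3 fragments")
      next
    }
    mx <- series_peaks(x, threshold)
    mn <- series_peaks(-x, threshold)
    ev <- rbind(
      if (length(mx)) data.frame(i = mx, type = "max", v = x[mx]),
      if (length(mn)) data.frame(i = mn, type = "min", v = x[mn]))
    if (is.null(ev) || nrow(ev) == 0) next
    ev <- ev[order(ev$i), , drop = FALSE]
    ev <- enforce_alternation(ev)
    for (tp in c("max", "min")) {
      sub <- ev[ev$type == tp, , drop = FALSE]
      if (nrow(sub) == 0) next
      d <- data.frame(chrom = ch, row = rows[sub$i],
                      midpoint = profile$midpoint[rows[sub$i]],
                      value = sub$v)
      if (tp == "max") maxima[[ch]] <- d else minima[[ch]] <- d
    }
  }
  empty <- data.frame(chrom = character(), row = integer(),
                      midpoint = numeric(), value = numeric())
  structure(list(maxima = if (length(maxima)) do.call(rbind, c(maxima, list(make.row.names = FALSE))) else empty,
                 minima = if (length(minima)) do.call(rbind, c(minima, list(make.row.names = FALSE))) else empty,
                 threshold = threshold),
            class = "ExtremaSet")
}

#' @export
print.ExtremaSet <- function(x, ...) {
  cat(sprintf("ExtremaSet: %d maxima, %d minima (prominence threshold %.4g)\n",
              nrow(x$maxima), nrow(x$minima), x$threshold))
  invisible(x)
}

# indices of prominent local maxima of a series (plateau centres),
# terminal points excluded
series_peaks <- function(x, threshold) {
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 3) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  v <- r$values
  cand <- which(v[-c(1, nr)] > v[-c(nr - 1, nr)] &
                v[-c(1, nr)] > v[-c(1, 2)]) + 1
  keep <- cand[vapply(cand, function(k)
    run_prominence(v, k) >= threshold, logical(1))]
  floor((starts[keep] + ends[keep]) / 2)
}

# prominence of compressed-run peak k: on each side take the minimum
# until the first run higher than the peak (or the end); prominence is
# the drop to the higher of the two side minima
run_prominence <- function(v, k) {
  h <- v[k]
  left <- Inf
  j <- k - 1
  while (j >= 1 && v[j] <= h) { left <- min(left, v[j]); j <- j - 1 }
  right <- Inf
  j <- k + 1
  while (j <= length(v) && v[j] <= h) { right <- min(right, v[j]); j <- j + 1 }
  h - max(left, right)
}

# within runs of same-type events keep the most extreme one
enforce_alternation <- function(ev) {
  keep <- logical(nrow(ev))
  i <- 1
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1] == ev$type[i]) j <- j + 1
    block <- i:j
    best <- if (ev$type[i] == "max") block[which.max(ev$v[block])]
    else block[which.min(ev$v[block])]
    keep[best] <- TRUE
    i <- j + 1
  }
  ev[keep, , drop = FALSE]
}

#' Profile heights at reference origin positions
#'
#' Reads `f_strain(x_i)` — the profile value at each reference origin —
#' for every strain: the relative activation time/efficiency of the
#' origin in that strain. The value comes from the fragment containing
#' `x_i`; if the position falls in a filtered-out gap, the nearest
#' fragment midpoint within `max_gap` bp is used, else the row is
#' flagged missing.
#'
#' @param profiles named list of `ReplicationProfile` on a shared
#'   fragment index (as produced by [strain_profiles()]).
#' @param origins data.frame with `chrom`, `pos`.
#' @param max_gap maximum distance (bp) to the nearest fragment
#'   midpoint before a row is flagged missing.
#' @return an `OriginActivationTable`: data.frame with `chrom`, `pos`,
#'   `row` (profile row or NA), `missing`, and one `f_<strain>` column
#'   per profile.
#' @export
activation_heights <- function(profiles, origins, max_gap = 5000) {
  if (inherits(profiles, "ReplicationProfile")) profiles <- list(profiles)
  ref <- profiles[[1]]
  out <- data.frame(chrom = origins$chrom, pos = origins$pos,
                    row = NA_integer_, missing = FALSE)
  for (k in seq_len(nrow(origins))) {
    rows <- which(ref$chrom == origins$chrom[k])
    if (length(rows) == 0) { out$missing[k] <- TRUE; next }
    inside <- rows[ref$start[rows] <= origins$pos[k] &
                   origins$pos[k] < ref$end[rows]]
    if (length(inside) >= 1) { out$row[k] <- inside[1]; next }
    d <- abs(ref$midpoint[rows] - origins$pos[k])
    if (min(d) <= max_gap) out$row[k] <- rows[which.min(d)]
    else out$missing[k] <- TRUE
  }
  nm <- names(profiles) %||% paste0("strain", seq_along(profiles))
  for (s in seq_along(profiles))
    out[[paste0("f_", nm[s])]] <-
      ifelse(is.na(out$row), NA_real_, profiles[[s]]$value[out$row])
  class(out) <- c("OriginActivationTable", "data.frame")
  out
}

#' Sharpness of a strain profile relative to wild-type
#'
#' Evaluates `f_strain(x_i) - f_wt(x_i)` separately at the wild-type
#' profile's local maxima and local minima. A sharpened profile (more
#' origin firing, e.g. under slow forks) has positive differences at
#' maxima and negative at minima of the z-scored signal; a smoothed
#' profile shows the opposite; a pure S-phase rescaling leaves the
#' differences at zero. Reported per side: the differences, their
#' 25/50/75th percentiles (the boxplot summary) and a histogram.
#'
#' @param strain_profile,wt_profile `ReplicationProfile`s on the same
#'   fragment index.
#' @param wt_extrema `ExtremaSet` of the wild-type profile; computed
#'   with defaults when NULL.
#' @param breaks histogram breaks (passed to [graphics::hist()] logic
#'   via [base::cut()]-free binning), default 30 equal-width bins.
#' @return object of class `SharpnessSummary`: list with `maxima` and
#'   `minima`, each holding `diffs`, `percentiles` (25/50/75) and
#'   `hist` (`mids`, `counts`).
#' @export
sharpness_summary <- function(strain_profile, wt_profile,
                              wt_extrema = NULL, breaks = 30) {
  stopifnot(nrow(strain_profile) == nrow(wt_profile))
  if (is.null(wt_extrema)) wt_extrema <- find_extrema(wt_profile)
  if (nrow(wt_extrema$maxima) == 0 && nrow(wt_extrema$minima) == 0)
    stop("sharpness_summary: wild-type profile has no extrema")
  side <- function(rows) {
    d <- strain_profile$value[rows] - wt_profile$value[rows]
    h <- if (length(d)) graphics::hist(d, breaks = breaks, plot = FALSE)
    else list(mids = numeric(), counts = integer())
    list(diffs = d,
         percentiles = stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE),
         hist = list(mids = h$mids, counts = h$counts))
  }
  structure(list(maxima = side(wt_extrema$maxima$row),
                 minima = side(wt_extrema$minima$row),
                 strain = attr(strain_profile, "strain"),
                 wt = attr(wt_profile, "strain")),
            class = "SharpnessSummary")
}

#' @export
print.SharpnessSummary <- function(x, ...) {
  cat(sprintf("SharpnessSummary (%s vs %s)\n", x$strain %||% "strain",
              x$wt %||% "wt"))
  cat(sprintf("  maxima: n = %d, quartiles = %s\n", length(x$maxima$diffs),
              paste(signif(x$maxima$percentiles, 3), collapse = " / ")))
  cat(sprintf("  minima: n = %d, quartiles = %s\n", length(x$minima$diffs),
              paste(signif(x$minima$percentiles, 3), collapse = " / ")))
  invisible(x)
}

#' Autocorrelation decay of a profile
#'
#' Normalized autocorrelation (mean removed, lag 0 = 1) computed per
#' chromosome and averaged across chromosomes weighted by series
#' length — never concatenated, which would manufacture spurious
#' boundary correlation. A sharp, peak-rich profile decorrelates over
#' a short genomic distance; the decay is summarized by the first lag
#' (in fragments) at which the averaged ACF falls below 0.5.
#'
#' @param profile a `ReplicationProfile`.
#' @param max_lag maximum lag in fragments; reduced with a warning if
#'   it reaches the shortest chromosome series.
#' @return list with `lag` (0..max_lag), `acf`, and `half_decay_lag`
#'   (NA when the ACF never crosses 0.5 within `max_lag`).
#' @export
autocorrelation <- function(profile, max_lag = 100) {
  lens <- table(profile$chrom)
  shortest <- min(lens)
  if (max_lag >= shortest) {
    warning("autocorrelation: max_lag reduced to ", shortest - 1)
    max_lag <- shortest - 1
  }
  num <- rep(0, max_lag + 1); wsum <- 0
  for (ch in names(lens)) {
    x <- profile$value[profile$chrom == ch]
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    w <- length(x)
    num <- num + w * a
    wsum <- wsum + w
  }
  a <- num / wsum
  below <- which(a < 0.5)
  list(lag = 0:max_lag, acf = a,
       half_decay_lag = if (length(below)) below[1] - 1 else NA_integer_)
}

#' Pearson correlation matrix across strain profiles
#'
#' Profiles are intersected on their shared fragment ids (chromosome +
#' start) first; the correlation is computed over shared fragments
#' only. The result is symmetric with unit diagonal.
#'
#' @param profiles named list of `ReplicationProfile`.
#' @return correlation matrix (strains x strains).
#' @export
correlation_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  ids <- lapply(profiles, function(p) paste(p$chrom, p$start))
  shared <- Reduce(intersect, ids)
  if (length(shared) < 2)
    stop("correlation_matrix: fewer than 2 shared fragments")
  m <- vapply(seq_along(profiles), function(k)
    profiles[[k]]$value[match(shared, ids[[k]])],
    numeric(length(shared)))
  colnames(m) <- names(profiles) %||% paste0("strain", seq_along(profiles))
  stats::cor(m)
}
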
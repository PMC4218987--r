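#' Replication profile container
#'
#' Per-fragment normalized, denoised (and typically smoothed) DNA
#' abundance for one strain; higher value = earlier / more efficient
#' replication; local maxima mark active origins.
#'
#' @param fragments a `FragmentTable`.
#' @param value numeric signal, one value per fragment.
#' @param strain strain label.
#' @return object of class `ReplicationProfile` (a data.frame with
#'   `chrom`, `start`, `end`, `midpoint`, `value`).
#' @export
replication_profile <- function(fragments, value, strain = "strain") {
  stopifnot(nrow(fragments) == length(value), all(is.finite(value)))
  out <- data.frame(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end,
                    midpoint = fragment_midpoints(fragments),
                    value = value)
  attr(out, "strain") <- strain
  class(out) <- c("ReplicationProfile", "data.frame")
  out
}

#' Per-strain profiles from a processed matrix
#'
#' Averages each strain's S-phase replicate columns (mean by default,
#' median by option) of an already normalized/denoised matrix, then
#' applies Savitzky-Golay smoothing per chromosome.
#'
#' @param matrix processed `CountMatrix`.
#' @param smooth apply [savgol_smooth()].
#' @param window,polyorder smoothing parameters.
#' @param stat `"mean"` or `"median"` across replicate columns.
#' @return named list of `ReplicationProfile`, one per strain.
#' @export
strain_profiles <- function(matrix, smooth = TRUE, window = 9,
                            polyorder = 3, stat = c("mean", "median")) {
  stopifnot(inherits(matrix, "CountMatrix"))
  stat <- match.arg(stat)
  ex <- matrix$experiments
  s_cols <- which(ex$gate == "S")
  if (length(s_cols) == 0) stop("no S-phase experiments in matrix")
  out <- list()
  for (st in unique(ex$strain[s_cols])) {
    cols <- s_cols[ex$strain[s_cols] == st]
    v <- if (stat == "mean") rowMeans(matrix$values[, cols, drop = FALSE])
    else apply(matrix$values[, cols, drop = FALSE], 1, stats::median)
    p <- replication_profile(matrix$fragments, v, strain = st)
    if (smooth) p <- savgol_smooth(p, window = window, polyorder = polyorder)
    out[[st]] <- p
  }
  out
}

#' Export a profile as bedGraph
#' @param profile a `ReplicationProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path) {
  lines <- sprintf("track type=bedGraph name=\"%s\"",
                   attr(profile, "strain") %||% "profile")
  lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", profile$chrom,
                            as.integer(profile$start),
                            as.integer(profile$end), profile$value))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
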
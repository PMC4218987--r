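#' Fragment-by-experiment count matrix
#'
#' The central data container: a numeric matrix of fragments (rows) by
#' experiments (columns), carrying its `FragmentTable` row index and
#' per-experiment metadata (strain label and sorted gate, `S` for the
#' S-phase library and `G1G2` for the control). Raw counts are
#' non-negative integers; after normalization the values are real.
#'
#' @param values numeric matrix, fragments x experiments.
#' @param fragments `FragmentTable` with one row per matrix row.
#' @param experiments data.frame with columns `id`, `strain`, `gate`
#'   (one row per matrix column); a `total_reads` column is added from
#'   the raw column sums when absent.
#' @return object of class `CountMatrix`.
#' @export
count_matrix <- function(values, fragments, experiments) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(fragments),
            ncol(values) == nrow(experiments),
            all(c("id", "strain", "gate") %in% names(experiments)))
  if (anyDuplicated(experiments$id)) stop("experiment ids must be unique")
  if (!all(experiments$gate %in% c("S", "G1G2")))
    stop("gate must be 'S' or 'G1G2'")
  if (is.null(experiments$total_reads))
    experiments$total_reads <- colSums(values)
  colnames(values) <- experiments$id
  rownames(values) <- fragments$id
  structure(list(values = values, fragments = fragments,
                 experiments = experiments),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d fragments x %d experiments (%d S, %d G1G2)\n",
              nrow(x$values), ncol(x$values),
              sum(x$experiments$gate == "S"),
              sum(x$experiments$gate == "G1G2")))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

# rebuild with a row subset, keeping metadata in step
subset_rows <- function(matrix, keep) {
  fr <- matrix$fragments[keep, , drop = FALSE]
  rownames(fr) <- NULL
  class(fr) <- class(matrix$fragments)
  count_matrix(matrix$values[keep, , drop = FALSE], fr, matrix$experiments)
}

subset_cols <- function(matrix, keep) {
  ex <- matrix$experiments[keep, , drop = FALSE]
  rownames(ex) <- NULL
  count_matrix(matrix$values[, keep, drop = FALSE], matrix$fragments, ex)
}

#' Write a count matrix as TSV
#'
#' One fragment-identifier column (`fragment`) followed by one column
#' per experiment; experiment metadata goes in a sibling
#' `<path>.experiments.tsv` file so the pair round-trips.
#'
#' @param matrix a `CountMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  df <- data.frame(fragment = matrix$fragments$id,
                   chrom = matrix$fragments$chrom,
                   start = matrix$fragments$start,
                   end = matrix$fragments$end,
                   matrix$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$experiments, paste0(path, ".experiments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV path.
#' @return a `CountMatrix`.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ex <- utils::read.table(paste0(path, ".experiments.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  fr <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                   length = df$end - df$start, id = df$fragment)
  class(fr) <- c("FragmentTable", "data.frame")
  vals <- as.matrix(df[, ex$id, drop = FALSE])
  count_matrix(vals, fr, ex)
}

#' Simulate sequencing counts from an abundance track
#'
#' Emulates one FACS-sorted S-phase library and one G1/G2 control
#' library over a fragment table. The expected count of fragment `f`
#' is proportional to `A(midpoint of f) * length_bias(length(f))`,
#' rescaled so each column's expected total equals `depth`; observed
#' counts are then drawn from the chosen noise law. The G1/G2 column
#' is generated identically with flat abundance (all loci fully
#' replicated), so it carries only the fragment-specific biases --
#' exactly what dividing by the control mean is meant to remove.
#'
#' @param abundance an `AbundanceTrack` (evaluated at, or interpolated
#'   to, fragment midpoints).
#' @param fragments a `FragmentTable`.
#' @param depth expected total reads per experiment.
#' @param length_bias function of fragment length giving the relative
#'   capture efficiency; default a saturating monotone bias
#'   `l / (l + 500)` typical of size selection against short fragments.
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param seed integer seed; the two columns use split streams.
#' @param s_id,g_id experiment ids for the two columns.
#' @param strain strain label recorded in the metadata.
#' @return a `CountMatrix` with one `S` and one `G1G2` column.
#' @export
synth_counts <- function(abundance, fragments, depth = 2e6,
                         length_bias = function(l) l / (l + 500),
                         noise = c("poisson", "negative_binomial"),
                         nb_size = 20, seed = 1L,
                         s_id = "S1", g_id = "G1", strain = "wt") {
  noise <- match.arg(noise)
  stopifnot(depth > 0)
  if (nrow(fragments) == 0) stop("empty fragment table")
  mids <- fragment_midpoints(fragments)
  a <- track_at(abundance, fragments$chrom, mids)
  bias <- length_bias(fragments$length)
  if (any(bias < 0)) stop("length bias must be non-negative")
  draw <- function(A, key) {
    w <- A * bias
    mu <- w / sum(w) * depth
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, key))
    if (noise == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = nb_size)
  }
  vals <- cbind(draw(a, paste0("counts-S-", s_id)),
                draw(rep(1, length(a)), paste0("counts-G-", g_id)))
  ex <- data.frame(id = c(s_id, g_id), strain = strain,
                   gate = c("S", "G1G2"))
  count_matrix(vals, fragments, ex)
}

# value of a (chrom, pos, value) track at query loci: exact position
# match when available, else nearest position on the same chromosome
track_at <- function(track, chrom, pos, value_col = "abundance") {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) stop("track has no positions on chromosome ", ch)
    ord <- order(d$pos)
    tp <- d$pos[ord]; tv <- d[[value_col]][ord]
    i <- findInterval(pos[sel], tp, all.inside = TRUE)
    left <- pmax(i, 1)
    right <- pmin(i + 1, length(tp))
    use_right <- abs(tp[right] - pos[sel]) < abs(tp[left] - pos[sel])
    out[sel] <- ifelse(use_right, tv[right], tv[left])
  }
  out
}
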
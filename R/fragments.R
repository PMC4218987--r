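#' In-silico restriction digestion
#'
#' Cuts each chromosome at every occurrence of the recognition site
#' (default `GATC`, the DpnII site, the quantification unit for
#' fragment-level read counting). Cut positions are the 0-based start
#' coordinates of the site matches on the forward strand (sufficient
#' for palindromic sites); fragments are the half-open intervals
#' between consecutive cuts, plus the leading `[0, first cut)` and
#' trailing `[last cut, length)` intervals. Zero-length fragments
#' (site at position 0, or adjacent identical cuts) are dropped. A
#' chromosome without the site yields a single spanning fragment.
#' Matching is case-insensitive and exact, so site occurrences
#' containing ambiguity codes (e.g. `N`) are skipped, never fatal.
#'
#' @param genome a `GenomeSpec` with sequences.
#' @param site recognition sequence, default `"GATC"`.
#' @return a `FragmentTable`: data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `length` and a stable `id` column.
#' @examples
#' gs <- genome_spec(data.frame(name = "c1", length = 14),
#'                   c(c1 = "AAGATCCCGATCTT"))
#' digest_genome(gs)  # fragments [0,2), [2,8), [8,14)
#' @export
digest_genome <- function(genome, site = "GATC") {
  stopifnot(inherits(genome, "GenomeSpec"), nzchar(site))
  if (is.null(genome$sequences)) stop("genome has no sequences to digest")
  rows <- lapply(seq_len(nrow(genome$chromosomes)), function(k) {
    ch <- genome$chromosomes$name[k]
    L <- genome$chromosomes$length[k]
    m <- Biostrings::matchPattern(toupper(site),
                                  genome$sequences[[ch]], fixed = TRUE)
    cuts <- BiocGenerics::start(m) - 1  # 0-based cut coordinates
    bounds <- unique(c(0, cuts, L))
    data.frame(chrom = ch,
               start = utils::head(bounds, -1),
               end = utils::tail(bounds, -1))
  })
  fr <- do.call(rbind, rows)
  fr$length <- fr$end - fr$start
  fr <- fr[fr$length > 0, , drop = FALSE]
  rownames(fr) <- NULL
  fr$id <- sprintf("%s:%d-%d", fr$chrom, fr$start, fr$end)
  class(fr) <- c("FragmentTable", "data.frame")
  fr
}

#' Fragment midpoints
#' @param fragments a `FragmentTable`.
#' @return numeric vector of interval midpoints (bp).
#' @export
fragment_midpoints <- function(fragments) {
  (fragments$start + fragments$end) / 2
}

#' Count reads per restriction fragment
#'
#' Each read increments the unique fragment whose half-open interval
#' `[start, end)` contains its 5'-most mapped position; a read whose
#' position equals a fragment start belongs to that fragment. Reads on
#' chromosomes absent from the fragment table are tallied as
#' unassigned (logged, never fatal). Assigned + unassigned always
#' equals the number of input reads.
#'
#' @param alignments data.frame with `chrom` and `pos` (0-based 5'-most
#'   mapped position).
#' @param fragments a `FragmentTable`.
#' @return list with `counts` (integer, one per fragment), `assigned`,
#'   `unassigned`.
#' @export
count_reads_per_fragment <- function(alignments, fragments) {
  stopifnot(all(c("chrom", "pos") %in% names(alignments)))
  counts <- integer(nrow(fragments))
  unassigned <- 0L
  for (ch in unique(alignments$chrom)) {
    pos <- alignments$pos[alignments$chrom == ch]
    sel <- which(fragments$chrom == ch)
    if (length(sel) == 0) {
      unassigned <- unassigned + length(pos)
      message(sprintf("count_reads_per_fragment: %d reads on unknown chromosome %s",
                      length(pos), ch))
      next
    }
    starts <- fragments$start[sel]
    ends <- fragments$end[sel]
    # fragments tile [min(start), max(end)); findInterval on the sorted
    # starts locates the candidate fragment, then bounds are checked
    idx <- findInterval(pos, starts)
    ok <- idx >= 1 & pos < ends[pmax(idx, 1)] & pos >= 0
    unassigned <- unassigned + sum(!ok)
    tab <- tabulate(idx[ok], nbins = length(sel))
    counts[sel] <- counts[sel] + tab
  }
  list(counts = counts, assigned = nrow(alignments) - unassigned,
       unassigned = unassigned)
}

#' Read alignment positions from a BED or SAM file
#'
#' Only the chromosome and the 5'-most mapped coordinate are used. BED
#' input is taken as-is (0-based starts); SAM positions are 1-based and
#' converted. SAM lines with flag bit 4 (unmapped) are skipped.
#'
#' @param path file path; format inferred from extension
#'   (`.sam` vs anything else = BED-like TSV).
#' @return data.frame with `chrom`, `pos` (0-based).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "@")]
    f <- strsplit(ln, "\t")
    flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
    keep <- bitwAnd(flag, 4L) == 0L
    data.frame(chrom = vapply(f, `[`, character(1), 3)[keep],
               pos = vapply(f, function(x) as.numeric(x[4]), numeric(1))[keep] - 1)
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    data.frame(chrom = as.character(bed[[1]]), pos = as.numeric(bed[[2]]))
  }
}
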
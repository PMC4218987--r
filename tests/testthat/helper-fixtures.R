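# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# genome without sequence, one or more chromosomes
bare_genome <- function(lengths, names = NULL) {
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  genome_spec(data.frame(name = names, length = lengths))
}

# single-origin / explicit-origin program helper
prog <- function(chrom, pos, firing_time, v, T_S, efficiency = 1) {
  origin_program(
    data.frame(chrom = chrom, pos = pos, firing_time = firing_time,
               efficiency = efficiency),
    fork_velocity = v, s_phase_duration = T_S)
}

# FragmentTable with given lengths laid head-to-tail on one chromosome
toy_fragments <- function(lengths, chrom = "chr1") {
  ends <- cumsum(as.numeric(lengths))
  fr <- data.frame(chrom = rep(chrom, length(ends)),
                   start = ends - lengths, end = ends,
                   length = as.numeric(lengths))
  fr$id <- sprintf("%s:%d-%d", fr$chrom, fr$start, fr$end)
  class(fr) <- c("FragmentTable", "data.frame")
  fr
}

# CountMatrix from a plain matrix, fragments derived from lengths
toy_matrix <- function(values, lengths = NULL, chrom = NULL,
                       gate = NULL, strain = "wt") {
  values <- as.matrix(values)
  if (is.null(lengths)) lengths <- rep(200L, nrow(values))
  if (is.null(chrom)) {
    fr <- toy_fragments(lengths)
  } else {
    fr <- do.call(rbind, lapply(split(seq_along(lengths), chrom), function(i)
      toy_fragments(lengths[i], chrom = chrom[i[1]])))
    fr <- fr[order(match(fr$chrom, unique(chrom))), ]
    rownames(fr) <- NULL
    class(fr) <- c("FragmentTable", "data.frame")
  }
  if (is.null(gate)) gate <- rep("S", ncol(values))
  ex <- data.frame(id = paste0("e", seq_len(ncol(values))),
                   strain = strain, gate = gate)
  count_matrix(values, fr, ex)
}

# profile over equally spaced fragments on one chromosome
toy_profile <- function(values, chrom = "chr1", width = 100, strain = "s") {
  n <- length(values)
  fr <- toy_fragments(rep(width, n), chrom = chrom)
  replication_profile(fr, values, strain = strain)
}

# multi-chromosome profile
toy_profile_multi <- function(value_list, width = 100, strain = "s") {
  frs <- lapply(seq_along(value_list), function(k)
    toy_fragments(rep(width, length(value_list[[k]])),
                  chrom = paste0("chr", k)))
  fr <- do.call(rbind, frs)
  rownames(fr) <- NULL
  class(fr) <- c("FragmentTable", "data.frame")
  replication_profile(fr, unlist(value_list), strain = strain)
}

# per-base boolean-marking oracle for window coverage (independent of
# the IRanges route)
coverage_oracle <- function(origins, genome, half_width = 5000) {
  total <- 0
  covered <- 0
  for (k in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[k]
    L <- genome$chromosomes$length[k]
    total <- total + L
    mark <- logical(L)
    for (x in origins$pos[origins$chrom == ch]) {
      lo <- max(x - half_width, 0)
      hi <- min(x + half_width, L)
      if (hi > lo) mark[(lo + 1):hi] <- TRUE
    }
    covered <- covered + sum(mark)
  }
  covered / total
}

# fraction of `origins` rows having a peak within max_dist
origin_recall <- function(origins, peaks, max_dist = 5000) {
  hit <- vapply(seq_len(nrow(origins)), function(i) {
    pp <- peaks$pos[peaks$chrom == origins$chrom[i]]
    length(pp) > 0 && min(abs(pp - origins$pos[i])) <= max_dist
  }, logical(1))
  mean(hit)
}
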
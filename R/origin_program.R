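#' Origin firing program
#'
#' Ground truth for the replication simulator: origin positions, firing
#' times `T_i` (minutes into S phase), firing efficiencies `q_i`
#' (per-cell firing probability), a common fork velocity `v` (bp/min)
#' and the S-phase duration `T_S` (minutes). In the deterministic model
#' a locus replicates at `t(x) = min_i (T_i + |x - x_i| / v)`, so `T_S`
#' must be at least the largest attainable `t(x)` for replication to
#' complete within S phase.
#'
#' @param origins data.frame with columns `chrom`, `pos` (bp),
#'   `firing_time` (minutes, >= 0) and `efficiency` (in \[0, 1\]).
#' @param fork_velocity fork speed, bp per minute, > 0.
#' @param s_phase_duration S-phase length in minutes; checked against
#'   the genome in [validate_program()].
#' @return object of class `OriginProgram`.
#' @export
origin_program <- function(origins, fork_velocity, s_phase_duration) {
  stopifnot(is.data.frame(origins),
            all(c("chrom", "pos", "firing_time", "efficiency") %in% names(origins)))
  origins$chrom <- as.character(origins$chrom)
  if (any(origins$firing_time < 0)) stop("firing times must be >= 0")
  if (any(origins$efficiency < 0 | origins$efficiency > 1))
    stop("efficiencies must lie in [0, 1]")
  if (fork_velocity <= 0) stop("fork velocity must be > 0")
  o <- origins[order(origins$chrom, origins$pos), , drop = FALSE]
  rownames(o) <- NULL
  if (is.null(o$name)) o$name <- sprintf("ori%03d", seq_len(nrow(o)))
  structure(list(origins = o,
                 fork_velocity = fork_velocity,
                 s_phase_duration = s_phase_duration),
            class = "OriginProgram")
}

#' @export
print.OriginProgram <- function(x, ...) {
  cat(sprintf(
    "OriginProgram: %d origins on %d chromosome(s); v = %g bp/min, T_S = %g min\n",
    nrow(x$origins), length(unique(x$origins$chrom)),
    x$fork_velocity, x$s_phase_duration))
  invisible(x)
}

#' Validate an origin program against a genome
#'
#' Checks positions against chromosome bounds and, for the deterministic
#' model, that `T_S` is large enough that every locus replicates
#' (`max_x min_i (T_i + |x - x_i|/v) <= T_S`, evaluated at chromosome
#' ends and origin-to-origin midpoints, where the maximum is attained).
#'
#' @param program an `OriginProgram`.
#' @param genome a `GenomeSpec`.
#' @return `program`, invisibly; errors on violation.
#' @export
validate_program <- function(program, genome) {
  stopifnot(inherits(program, "OriginProgram"), inherits(genome, "GenomeSpec"))
  o <- program$origins
  bad <- !(o$chrom %in% genome$chromosomes$name)
  if (any(bad)) stop("origin on unknown chromosome: ", o$chrom[bad][1])
  len <- chrom_length(genome, o$chrom)
  if (any(o$pos < 0 | o$pos >= len))
    stop("origin position outside chromosome bounds")
  tmax <- max_completion_time(program, genome)
  if (tmax > program$s_phase_duration + 1e-9)
    stop(sprintf(
      "S phase too short: latest-replicating locus needs %.2f min > T_S = %g",
      tmax, program$s_phase_duration))
  invisible(program)
}

# Largest deterministic replication time over the genome. The piecewise
# -linear t(x) attains its maxima at chromosome ends and between
# adjacent origins, so checking those points is exact.
max_completion_time <- function(program, genome) {
  v <- program$fork_velocity
  tmax <- 0
  for (ch in genome$chromosomes$name) {
    o <- program$origins[program$origins$chrom == ch, , drop = FALSE]
    if (nrow(o) == 0) next
    L <- chrom_length(genome, ch)
    xs <- sort(unique(c(0, o$pos, L - 1,
                        (utils::head(o$pos, -1) + utils::tail(o$pos, -1)) / 2)))
    t_at <- eval_timeline_at(o$pos, o$firing_time, v, xs)
    tmax <- max(tmax, t_at)
  }
  tmax
}

# min_i (T_i + |x - x_i| / v) for a vector of query positions
eval_timeline_at <- function(ori_pos, ori_time, v, x) {
  t <- rep(Inf, length(x))
  for (i in seq_along(ori_pos))
    t <- pmin(t, ori_time[i] + abs(x - ori_pos[i]) / v)
  t
}

#' Simulate a random origin program
#'
#' Places origins with near-regular spacing (small positional jitter)
#' and draws firing times from a smooth chromosomal timing landscape
#' -- a sinusoidal early/late domain wave with random per-chromosome
#' phase plus a small independent jitter -- emulating the replication
#' -timing domains of real genomes, in which neighbouring origins fire
#' at similar times. Optionally adds "dormant" candidate origins:
#' late-firing origins placed close to an early origin, so that at the
#' reference fork velocity a fork from the early neighbour arrives
#' before they fire (passive replication), while a sufficiently slowed
#' fork lets them fire -- the dormant-origin activation phenotype.
#'
#' @param genome a `GenomeSpec`.
#' @param n_origins total number of primary origins across the genome.
#' @param fork_velocity bp/min.
#' @param t_spread overall firing-time range in minutes: the domain
#'   wave spans `[0, t_spread]` and the independent jitter adds up to
#'   `0.2 * t_spread`.
#' @param n_dormant number of additional dormant candidates.
#' @param efficiency per-cell firing probability given to every origin.
#' @param seed integer seed.
#' @param domain_period wavelength of the timing-domain landscape (bp).
#' @param s_phase_margin `T_S` is set to the deterministic completion
#'   time times this factor.
#' @return an `OriginProgram`, validated against `genome`.
#' @export
random_program <- function(genome, n_origins = 40, fork_velocity = 1500,
                           t_spread = 25, n_dormant = 4, efficiency = 1,
                           seed = 1L, domain_period = 8e5,
                           s_phase_margin = 1.15) {
  stopifnot(inherits(genome, "GenomeSpec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "origin-program"))
  lens <- genome$chromosomes$length
  n_per <- pmax(1L, round(n_origins * lens / sum(lens)))
  rows <- list()
  for (k in seq_along(lens)) {
    L <- lens[k]; n <- n_per[k]
    centers <- (seq_len(n) - 0.5) / n * L
    jitter <- stats::runif(n, -0.1, 0.1) * L / n
    pos <- round(pmin(pmax(centers + jitter, 1), L - 1))
    phase <- stats::runif(1, 0, 2 * pi)
    tt <- t_spread * (0.4 * (1 + sin(2 * pi * pos / domain_period + phase)) +
                        stats::runif(n, 0, 0.2))
    rows[[k]] <- data.frame(chrom = genome$chromosomes$name[k], pos = pos,
                            firing_time = tt, efficiency = efficiency)
  }
  ori <- do.call(rbind, rows)
  if (n_dormant > 0) {
    # attach each dormant candidate ~15-20 kb from a randomly chosen
    # early origin, firing late enough to be passively replicated at
    # the reference velocity (fork covers 20 kb in 20000/v minutes)
    early <- ori[ori$firing_time < stats::median(ori$firing_time), , drop = FALSE]
    idx <- sample(nrow(early), min(n_dormant, nrow(early)))
    host <- early[idx, , drop = FALSE]
    off <- round(stats::runif(nrow(host), 15000, 20000)) *
      sample(c(-1, 1), nrow(host), replace = TRUE)
    dpos <- host$pos + off
    L <- chrom_length(genome, host$chrom)
    dpos <- pmin(pmax(dpos, 1), L - 1)
    arrival <- host$firing_time + abs(dpos - host$pos) / fork_velocity
    dorm <- data.frame(chrom = host$chrom, pos = dpos,
                       firing_time = arrival + stats::runif(nrow(host), 5, 10),
                       efficiency = efficiency)
    ori <- rbind(ori, dorm)
  }
  prog <- origin_program(ori, fork_velocity, s_phase_duration = 1)
  prog$s_phase_duration <- max_completion_time(prog, genome) * s_phase_margin
  validate_program(prog, genome)
  prog
}

#' Write origin positions as BED
#'
#' Six-column BED (0-based half-open single-bp intervals); score column
#' carries the firing efficiency, and the firing time is appended as a
#' seventh column for lossless round-tripping.
#'
#' @param program an `OriginProgram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_program_bed <- function(program, path) {
  o <- program$origins
  bed <- data.frame(chrom = o$chrom, start = o$pos, end = o$pos + 1,
                    name = o$name, score = o$efficiency, strand = ".",
                    firing_time = o$firing_time)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the scalar program parameters as JSON
#' @param program an `OriginProgram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_program_config <- function(program, path) {
  jsonlite::write_json(
    list(fork_velocity = program$fork_velocity,
         s_phase_duration = program$s_phase_duration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an origin program from BED + JSON config
#' @param bed_path BED file written by [write_program_bed()] (or any
#'   BED; missing efficiency/firing-time columns default to 1 and 0).
#' @param config_path JSON with `fork_velocity` and `s_phase_duration`.
#' @return an `OriginProgram`.
#' @export
read_program <- function(bed_path, config_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  ori <- data.frame(
    chrom = as.character(bed[[1]]),
    pos = floor((as.numeric(bed[[2]]) + as.numeric(bed[[3]])) / 2),
    firing_time = if (ncol(bed) >= 7) as.numeric(bed[[7]]) else 0,
    efficiency = if (ncol(bed) >= 5) as.numeric(bed[[5]]) else 1)
  if (ncol(bed) >= 4) ori$name <- as.character(bed[[4]])
  origin_program(ori, cfg$fork_velocity, cfg$s_phase_duration)
}

#' Read reference origin positions from a BED file
#'
#' Intervals collapse to their midpoints (reference origin lists give
#' origins as short intervals; the prediction statistic treats them as
#' points).
#'
#' @param path BED path (>= 3 columns).
#' @return data.frame with `chrom` and `pos`.
#' @export
read_origins_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]),
             pos = floor((as.numeric(bed[[2]]) + as.numeric(bed[[3]])) / 2))
}
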
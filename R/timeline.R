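#' Simulate a replication timeline
#'
#' Core of the fork-progression model. In `deterministic` mode every
#' origin initiates at its programmed time `T_i` and forks move at
#' constant velocity `v`, so a locus at `x` replicates at
#' `t(x) = min_i (T_i + |x - x_i| / v)` over the origins of its
#' chromosome. An origin is *active* if no fork from another origin
#' reaches it strictly before its own firing time (arrival exactly at
#' `T_i` counts as active); otherwise it is passively replicated
#' (dormant in that realization). In `stochastic` mode each simulated
#' cell lets origin `i` fire independently with probability `q_i`;
#' a chromosome where no origin fired is re-drawn (replication must
#' complete); the returned timeline is the per-cell mean (or the full
#' per-cell ensemble).
#'
#' Forks terminate at chromosome ends; there is no telomere-specific
#' behaviour and no fork-fork interaction beyond the minimum.
#'
#' @param genome a `GenomeSpec`.
#' @param program an `OriginProgram` valid for `genome`.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed integer seed (required for stochastic mode).
#' @param positions data.frame with `chrom`, `pos` at which to evaluate
#'   `t(x)`; default an even grid of `resolution` bp per chromosome.
#' @param resolution grid step in bp when `positions` is NULL.
#' @param n_cells number of simulated cells (stochastic mode).
#' @param keep_cells if TRUE, retain the per-cell time matrix.
#' @return object of class `ReplicationTimeline`: list with `positions`
#'   (data.frame `chrom`, `pos`), `time` (minutes, mean over cells in
#'   stochastic mode), `active_origins` (origin names; stochastic mode:
#'   origins active in >= 50% of cells), `active_frequency` (stochastic
#'   only), `mode`, `program`, and optionally `cells` (positions x
#'   cells matrix).
#' @export
simulate_timeline <- function(genome, program,
                              mode = c("deterministic", "stochastic"),
                              seed = NULL, positions = NULL,
                              resolution = 500, n_cells = 200,
                              keep_cells = FALSE) {
  mode <- match.arg(mode)
  validate_program(program, genome)
  if (is.null(positions)) positions <- grid_positions(genome, resolution)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  o <- program$origins
  v <- program$fork_velocity
  chroms <- genome$chromosomes$name
  if (mode == "deterministic") {
    n_per <- table(factor(o$chrom, levels = chroms))
    if (any(n_per == 0))
      stop("chromosome with zero origins in deterministic mode: ",
           names(n_per)[n_per == 0][1], " (replication cannot complete)")
    tm <- rep(NA_real_, nrow(positions))
    active <- logical(nrow(o))
    for (ch in chroms) {
      oc <- which(o$chrom == ch)
      sel <- positions$chrom == ch
      tm[sel] <- eval_timeline_at(o$pos[oc], o$firing_time[oc], v,
                                  positions$pos[sel])
      for (j in oc) {
        others <- setdiff(oc, j)
        arrival <- if (length(others) == 0) Inf else
          min(o$firing_time[others] + abs(o$pos[j] - o$pos[others]) / v)
        active[j] <- arrival >= o$firing_time[j]  # tie counts as active
      }
    }
    res <- list(positions = positions, time = tm,
                active_origins = o$name[active],
                mode = mode, program = program)
  } else {
    if (is.null(seed)) stop("stochastic mode requires a seed")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "stochastic-timeline"))
    tsum <- rep(0, nrow(positions))
    cells <- if (keep_cells)
      matrix(NA_real_, nrow(positions), n_cells) else NULL
    act_n <- integer(nrow(o))
    for (cell in seq_len(n_cells)) {
      fired <- stats::runif(nrow(o)) < o$efficiency
      for (ch in chroms) {
        oc <- which(o$chrom == ch)
        if (length(oc) == 0) next
        while (!any(fired[oc]))  # unreplicated chromosome: re-draw
          fired[oc] <- stats::runif(length(oc)) < o$efficiency[oc]
      }
      tcell <- rep(Inf, nrow(positions))
      for (ch in chroms) {
        oc <- which(o$chrom == ch & fired)
        sel <- positions$chrom == ch
        if (any(sel) && length(oc) > 0)
          tcell[sel] <- eval_timeline_at(o$pos[oc], o$firing_time[oc], v,
                                         positions$pos[sel])
        # per-cell activity: fired and not passively replicated first
        for (j in oc) {
          others <- setdiff(oc, j)
          arrival <- if (length(others) == 0) Inf else
            min(o$firing_time[others] + abs(o$pos[j] - o$pos[others]) / v)
          if (arrival >= o$firing_time[j]) act_n[j] <- act_n[j] + 1L
        }
      }
      tsum <- tsum + tcell
      if (keep_cells) cells[, cell] <- tcell
    }
    freq <- act_n / n_cells
    res <- list(positions = positions, time = tsum / n_cells,
                active_origins = o$name[freq >= 0.5],
                active_frequency = stats::setNames(freq, o$name),
                mode = mode, program = program)
    if (keep_cells) res$cells <- cells
  }
  structure(res, class = "ReplicationTimeline")
}

grid_positions <- function(genome, resolution) {
  do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(k) {
    L <- genome$chromosomes$length[k]
    pos <- seq(0, L - 1, by = resolution)
    data.frame(chrom = genome$chromosomes$name[k], pos = pos)
  }))
}

#' @export
print.ReplicationTimeline <- function(x, ...) {
  cat(sprintf(
    "ReplicationTimeline (%s): %d positions, t in [%.2f, %.2f] min, %d/%d active origins\n",
    x$mode, length(x$time), min(x$time), max(x$time),
    length(x$active_origins), nrow(x$program$origins)))
  invisible(x)
}

#' Population-averaged DNA abundance
#'
#' For cells sampled uniformly across S phase, a locus replicated at
#' time `t` is present in two copies in the fraction `1 - t/T_S` of
#' cells that have passed `t`, and one copy otherwise, giving expected
#' abundance `A(x) = 2 - t(x) / T_S`: 2 for loci replicated at `t = 0`,
#' approaching 1 as `t(x)` approaches `T_S`. This is the signal sorted
#' S-phase sequencing measures, up to depth normalization and noise.
#'
#' @param timeline a `ReplicationTimeline`.
#' @param T_S S-phase duration in minutes; defaults to the program's.
#' @return object of class `AbundanceTrack`: data.frame with `chrom`,
#'   `pos`, `abundance` (in `[1, 2]`).
#' @export
population_abundance <- function(timeline, T_S = NULL) {
  stopifnot(inherits(timeline, "ReplicationTimeline"))
  if (is.null(T_S)) T_S <- timeline$program$s_phase_duration
  if (any(timeline$time > T_S + 1e-9))
    stop(sprintf(
      "locus replicates at %.2f min, after the declared S-phase end T_S = %g",
      max(timeline$time), T_S))
  out <- data.frame(chrom = timeline$positions$chrom,
                    pos = timeline$positions$pos,
                    abundance = 2 - timeline$time / T_S)
  class(out) <- c("AbundanceTrack", "data.frame")
  out
}

#' Export a per-position track as bedGraph
#'
#' Works for `AbundanceTrack` objects and for timelines (via
#' `value_col = "time"` after coercion). Intervals span from each
#' position to the next on the same chromosome.
#'
#' @param track data.frame with `chrom`, `pos` and a value column.
#' @param path output path.
#' @param value_col name of the value column.
#' @param track_name bedGraph track line name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "abundance",
                           track_name = value_col) {
  stopifnot(all(c("chrom", "pos", value_col) %in% names(track)))
  lines <- sprintf("track type=bedGraph name=\"%s\"", track_name)
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    ends <- c(d$pos[-1], d$pos[nrow(d)] + 1)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", ch, as.integer(d$pos),
                              as.integer(ends), d[[value_col]]))
  }
  writeLines(lines, path)
  invisible(path)
}
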
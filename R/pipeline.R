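#' Build a run configuration
#'
#' Collects every tunable knob of every stage, with module defaults
#' filled in for anything not supplied. The configuration is a plain
#' nested list and serializes to JSON losslessly, so a run is fully
#' described by (config, seed).
#'
#' @param ... named overrides, merged recursively into the defaults
#'   (e.g. `counts = list(depth = 1e6)` replaces only the depth).
#' @return a `RunConfig` (named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1,
    out_dir = ".",
    mode = "deterministic",
    genome = list(chrom_lengths = c(8e5, 1.2e6, 1.5e6)),
    program = list(n_origins = 40, n_dormant = 4, fork_velocity = 1500,
                   t_spread = 25, efficiency = 1, s_phase_margin = 1.15),
    strains = list(wildtype = list(v_factor = 1, t_factor = 1, n_reps = 3)),
    counts = list(depth = 2e6, noise = "poisson", nb_size = 20),
    filters = list(min_length = 150, max_zero_experiments = NULL,
                   min_reads = 1e5),
    normalize = list(bandwidth = NULL, floor_quantile = 0.05),
    denoise = list(k = 50, window = 9, polyorder = 3),
    metrics = list(prominence = 0.2, max_lag = 100),
    predict = list(half_width = 5000),
    paths = list())
  cfg <- modify_list(defaults, list(...))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

# positional iteration: `new` may carry the same name twice (preset
# defaults followed by user overrides through `...`), and later entries
# must win
modify_list <- function(base, new) {
  for (i in seq_along(new)) {
    nm <- names(new)[i]
    val <- new[[i]]
    if (is.null(val))
      base[nm] <- list(NULL)  # keep explicit NULLs (JSON null round-trip)
    else if (is.list(val) && is.list(base[[nm]]) && !is.null(names(val)))
      base[[nm]] <- modify_list(base[[nm]], val)
    else base[[nm]] <- val
  }
  base
}

#' Preset configurations for the three qualitative regimes
#'
#' `"wildtype"`: reference fork velocity. `"slow-fork"`: adds a strain
#' with fork velocity divided by 4 on the same origin program — slow
#' forks make passive replication less likely, activate dormant
#' origins and sharpen the profile. `"scaled"`: adds a strain with all
#' firing times doubled and velocity halved — S phase doubles but the
#' normalized profile shape is unchanged (the proportional-scaling
#' regime). `"all"` carries all three strains.
#'
#' Preset-specific choices (the bare [run_config()] keeps the module
#' defaults): the wild-type strain carries 7 replicates and each
#' mutant 3, matching the study design the simulator emulates; 8 of
#' the ~48 origins are dormant candidates so the slow-fork strain
#' gains ~20% called peaks; and the smoothing window is 41 fragments
#' (~10 kb) — an order of magnitude below the ~75 kb inter-origin
#' spacing of the generator, so origin peaks are preserved while
#' fragment-level noise (which rank-capped SVD cannot remove at this
#' experiment count) is suppressed.
#'
#' @param name preset name.
#' @param ... further overrides passed to [run_config()].
#' @return a `RunConfig`.
#' @export
preset_config <- function(name = c("wildtype", "slow-fork", "scaled", "all"),
                          ...) {
  name <- match.arg(name)
  wt <- list(v_factor = 1, t_factor = 1, n_reps = 7)
  slow <- list(v_factor = 0.25, t_factor = 1, n_reps = 3)
  scaled <- list(v_factor = 0.5, t_factor = 2, n_reps = 3)
  strains <- switch(name,
    "wildtype" = list(wildtype = wt),
    "slow-fork" = list(wildtype = wt, slowfork = slow),
    "scaled" = list(wildtype = wt, scaled = scaled),
    "all" = list(wildtype = wt, slowfork = slow, scaled = scaled))
  run_config(strains = strains,
             program = list(n_dormant = 8),
             denoise = list(window = 41), ...)
}

#' Write / read a run configuration (JSON)
#' @param config a `RunConfig`.
#' @param path file path.
#' @return `path` / a `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(run_config, cfg)
}

# rescale one strain's program: firing times x t_factor, velocity x
# v_factor; T_S recomputed so completion is guaranteed with the same
# relative margin
program_variant <- function(program, genome, v_factor = 1, t_factor = 1,
                            margin = 1.15) {
  o <- program$origins
  o$firing_time <- o$firing_time * t_factor
  out <- origin_program(o, program$fork_velocity * v_factor, 1)
  out$s_phase_duration <- max_completion_time(out, genome) * margin
  validate_program(out, genome)
  out
}

#' Simulate a complete multi-strain dataset in memory
#'
#' Draws the genome and the shared origin program, derives each
#' strain's program variant, runs the fork-progression model, and
#' synthesizes one count matrix holding every strain's S-phase
#' replicates and matched G1/G2 controls. All randomness flows from
#' `config$seed` through [derive_seed()] streams.
#'
#' @param config a `RunConfig`.
#' @return list with `genome`, `fragments`, `program` (reference),
#'   `strains` (per strain: `program`, `timeline`, `abundance`),
#'   `matrix` (combined `CountMatrix`), `origins` (data.frame of true
#'   origin positions), `config`.
#' @export
simulate_dataset <- function(config = run_config()) {
  seed <- config$seed
  genome <- random_genome(unlist(config$genome$chrom_lengths),
                          seed = derive_seed(seed, "genome"))
  pr <- config$program
  program <- random_program(genome, n_origins = pr$n_origins,
                            fork_velocity = pr$fork_velocity,
                            t_spread = pr$t_spread,
                            n_dormant = pr$n_dormant,
                            efficiency = pr$efficiency,
                            seed = derive_seed(seed, "program"),
                            s_phase_margin = pr$s_phase_margin)
  fragments <- digest_genome(genome)
  mids <- data.frame(chrom = fragments$chrom,
                     pos = fragment_midpoints(fragments))
  strains <- list()
  vals <- NULL; exps <- NULL
  for (st in names(config$strains)) {
    sc <- config$strains[[st]]
    prog <- program_variant(program, genome,
                            v_factor = sc$v_factor %||% 1,
                            t_factor = sc$t_factor %||% 1,
                            margin = pr$s_phase_margin)
    tl <- simulate_timeline(genome, prog, mode = config$mode,
                            seed = derive_seed(seed, paste0("timeline-", st)),
                            positions = mids)
    ab <- population_abundance(tl)
    n_reps <- sc$n_reps %||% 3
    for (r in seq_len(n_reps)) {
      cm <- synth_counts(ab, fragments, depth = config$counts$depth,
                         noise = config$counts$noise,
                         nb_size = config$counts$nb_size,
                         seed = derive_seed(seed, sprintf("counts-%s-%d", st, r)),
                         s_id = sprintf("%s_S%d", st, r),
                         g_id = sprintf("%s_G%d", st, r),
                         strain = st)
      vals <- cbind(vals, cm$values)
      exps <- rbind(exps, cm$experiments)
    }
    strains[[st]] <- list(program = prog, timeline = tl, abundance = ab)
  }
  list(genome = genome, fragments = fragments, program = program,
       strains = strains,
       matrix = count_matrix(vals, fragments, exps),
       origins = program$origins[, c("chrom", "pos", "name")],
       config = config)
}

#' Simulate a dataset and write it to disk
#'
#' Writes genome FASTA, origin BED + program JSON, the count matrix
#' TSV, per-strain timeline and abundance bedGraphs, the active-origin
#' lists, and the config itself. Re-running with the same config and
#' seed is bit-identical (no timestamps are written).
#'
#' @param config a `RunConfig`; `config$out_dir` is created.
#' @return the in-memory dataset, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0)
    stop("output directory not writable: ", config$out_dir)
  ds <- simulate_dataset(config)
  out <- function(f) file.path(config$out_dir, f)
  write_genome_fasta(ds$genome, out("genome.fasta"))
  write_program_bed(ds$program, out("origins.bed"))
  write_program_config(ds$program, out("program.json"))
  write_count_matrix(ds$matrix, out("counts.tsv"))
  for (st in names(ds$strains)) {
    tl <- ds$strains[[st]]$timeline
    track <- data.frame(chrom = tl$positions$chrom, pos = tl$positions$pos,
                        time = tl$time)
    write_bedgraph(track, out(sprintf("timeline_%s.bedGraph", st)),
                   value_col = "time", track_name = paste0("t_", st))
    write_bedgraph(ds$strains[[st]]$abundance,
                   out(sprintf("abundance_%s.bedGraph", st)),
                   track_name = paste0("A_", st))
    jsonlite::write_json(tl$active_origins,
                         out(sprintf("active_origins_%s.json", st)))
  }
  write_run_config(config, out("config.json"))
  invisible(ds)
}

#' Process a raw count matrix into a normalized, denoised matrix
#'
#' The fixed processing cascade: depth filter (experiments) ->
#' row filters (short / pervasive-zero / blacklist fragments) ->
#' per-chromosome copy-number correction -> length-bias removal (mean
#' -recentred so the control ratio sees positive-scale signal) ->
#' division by the mean G1/G2 control (rows below the control floor
#' dropped) -> per-experiment z-scoring -> rank-k SVD reconstruction.
#' Every stage logs its input/output dimensions.
#'
#' @param matrix raw `CountMatrix`.
#' @param config a `RunConfig` (filter / normalize / denoise knobs).
#' @param blacklist fragment ids to drop.
#' @return list with `matrix` (processed), `reports` (per-stage
#'   `FilterReport`s), `stage_log` (data.frame of dimensions).
#' @export
process_counts <- function(matrix, config = run_config(),
                           blacklist = character()) {
  log_ <- list()
  note <- function(stage, m)
    log_[[length(log_) + 1]] <<- data.frame(stage = stage,
                                            fragments = nrow(m$values),
                                            experiments = ncol(m$values))
  note("input", matrix)
  fe <- filter_experiments(matrix, min_reads = config$filters$min_reads)
  note("filter_experiments", fe$matrix)
  ff <- filter_fragments(fe$matrix, min_length = config$filters$min_length,
                         max_zero_experiments = config$filters$max_zero_experiments,
                         blacklist = blacklist)
  note("filter_fragments", ff$matrix)
  m <- correct_cnv(ff$matrix)
  m <- remove_length_bias(m, bandwidth = config$normalize$bandwidth,
                          recenter = "mean")
  note("normalize", m)
  n_ctrl <- sum(m$experiments$gate == "G1G2")
  m <- ratio_to_control(m, floor_quantile = config$normalize$floor_quantile,
                        rescore = FALSE, drop_controls = n_ctrl == 1)
  bad <- rowSums(is.na(m$values)) > 0
  if (any(bad)) {
    message(sprintf("process_counts: dropping %d fragments flagged at the control ratio",
                    sum(bad)))
    m <- subset_rows(m, !bad)
  }
  note("ratio_to_control", m)
  m <- zscore_experiments(m)
  m <- svd_denoise(m, k = config$denoise$k)
  note("svd_denoise", m)
  list(matrix = m, reports = list(experiments = fe$report,
                                  fragments = ff$report),
       stage_log = do.call(rbind, log_))
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> process -> profile -> metrics -> predict.
#' When `dataset` is NULL the inputs are read from `config$paths`
#' (`counts`, `genome`, `origins`). Outputs are written under
#' `config$out_dir`; any stage error halts the run with the stage name
#' and leaves a `manifest.json` listing completed stages.
#'
#' @param config a `RunConfig`.
#' @param dataset optional in-memory dataset from [simulate_dataset()].
#' @param write write result files (set FALSE for in-memory use).
#' @return list with `processed`, `profiles`, `extrema`, `metrics`
#'   (correlation, acf, sharpness) and `predictions`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         write = TRUE) {
  if (write) dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  stage <- function(name, expr) {
    r <- tryCatch(force(expr), error = function(e) {
      if (write)
        jsonlite::write_json(list(completed = done, failed_stage = name,
                                  error = conditionMessage(e)),
                             file.path(config$out_dir, "manifest.json"),
                             auto_unbox = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    done <<- c(done, name)
    r
  }
  inputs <- stage("load", {
    if (!is.null(dataset)) dataset
    else {
      p <- config$paths
      if (is.null(p$counts)) stop("config$paths$counts is required")
      list(matrix = read_count_matrix(p$counts),
           genome = if (!is.null(p$genome)) read_genome_fasta(p$genome),
           origins = if (!is.null(p$origins)) read_origins_bed(p$origins))
    }
  })
  proc <- stage("process", process_counts(inputs$matrix, config))
  profiles <- stage("profile",
    strain_profiles(proc$matrix, window = config$denoise$window,
                    polyorder = config$denoise$polyorder))
  extrema <- stage("metrics-extrema",
    lapply(profiles, find_extrema,
           min_prominence = config$metrics$prominence))
  metrics <- stage("metrics", {
    res <- list()
    if (length(profiles) >= 2)
      res$correlation <- correlation_matrix(profiles)
    res$acf <- lapply(profiles, autocorrelation,
                      max_lag = config$metrics$max_lag)
    wt <- intersect(c("wildtype", "wt"), names(profiles))[1]
    if (!is.na(wt))
      res$sharpness <- lapply(setdiff(names(profiles), wt), function(st)
        sharpness_summary(profiles[[st]], profiles[[wt]],
                          wt_extrema = extrema[[wt]]))
    res
  })
  predictions <- stage("predict", {
    if (is.null(inputs$origins) || is.null(inputs$genome)) NULL
    else lapply(profiles, evaluate_prediction,
                origins = inputs$origins, genome = inputs$genome,
                half_width = config$predict$half_width,
                min_prominence = config$metrics$prominence)
  })
  if (write) {
    out <- function(f) file.path(config$out_dir, f)
    for (st in names(profiles)) {
      write_profile_bedgraph(profiles[[st]],
                             out(sprintf("profile_%s.bedGraph", st)))
      utils::write.table(extrema[[st]]$maxima,
                         out(sprintf("maxima_%s.tsv", st)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(predictions))
        write_prediction_json(predictions[[st]],
                              out(sprintf("prediction_%s.json", st)))
    }
    if (!is.null(metrics$correlation))
      utils::write.table(metrics$correlation, out("correlation.tsv"),
                         sep = "\t", quote = FALSE)
    utils::write.table(proc$stage_log, out("stage_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(completed = done,
           package_version = as.character(utils::packageVersion("sortseqrep")),
           seed = config$seed,
           config_hash = config_hash(config)),
      out("manifest.json"), auto_unbox = TRUE)
  }
  list(processed = proc, profiles = profiles, extrema = extrema,
       metrics = metrics, predictions = predictions)
}

config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable FNV-style hash; avoids a digest dependency
  h <- 2166136261
  for (b in utf8ToInt(as.character(txt)))
    h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `process`, `metrics`, `predict` (all take
#' `--config <json> [--out <dir>]`), `compare --config <json>` (runs a
#' multi-strain pipeline and reports the correlation matrix). Returns
#' the exit status instead of quitting so it is testable in-process:
#' 0 success, 2 configuration error, 3 stage failure. A thin wrapper
#' script for `Rscript` ships in `inst/cli/sortseqrep-cli.R`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: sortseqrep <simulate|process|metrics|predict|compare> --config <json> [--out <dir>]"
  status <- tryCatch({
    if (length(args) < 1) { message(usage); return(invisible(2L)) }
    cmd <- args[1]
    opt <- parse_flags(args[-1])
    if (!cmd %in% c("simulate", "process", "metrics", "predict", "compare")) {
      message("unknown subcommand: ", cmd); return(invisible(2L))
    }
    if (is.null(opt$config)) { message(usage); return(invisible(2L)) }
    cfg <- tryCatch(read_run_config(opt$config), error = function(e) {
      message("config error: ", conditionMessage(e)); NULL
    })
    if (is.null(cfg)) return(invisible(2L))
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    ok <- tryCatch({
      switch(cmd,
        simulate = run_simulate(cfg),
        process = ,
        metrics = ,
        predict = ,
        compare = {
          ds <- if (length(cfg$paths) == 0) simulate_dataset(cfg) else NULL
          res <- run_pipeline(cfg, dataset = ds)
          if (cmd == "compare" && !is.null(res$metrics$correlation))
            print(round(res$metrics$correlation, 3))
          res
        })
      TRUE
    }, error = function(e) {
      message("stage failure: ", conditionMessage(e)); FALSE
    })
    if (ok) 0L else 3L
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e)); 2L
  })
  invisible(as.integer(status))
}

parse_flags <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opt[[key]] <- args[i + 1]; i <- i + 2
      } else { opt[[key]] <- TRUE; i <- i + 1 }
    } else i <- i + 1
  }
  opt
}
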
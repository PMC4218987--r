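#' Genome specification
#'
#' A light container describing a (typically small, synthetic) genome:
#' chromosome names and lengths, optionally with nucleotide sequence.
#' Sequence is only required for in-silico restriction digestion
#' ([digest_genome()]); all coordinate arithmetic needs lengths only.
#'
#' @param chromosomes data.frame with columns `name` (character, unique)
#'   and `length` (positive integer, base pairs).
#' @param sequences optional named character vector or
#'   [Biostrings::DNAStringSet] of chromosome sequences; names and widths
#'   must agree with `chromosomes`.
#' @return An object of class `GenomeSpec`: a list with elements
#'   `chromosomes` (data.frame) and `sequences` (`DNAStringSet` or `NULL`).
#' @examples
#' gs <- genome_spec(data.frame(name = c("chrI", "chrII"),
#'                              length = c(10000L, 20000L)))
#' genome_length(gs)
#' @export
genome_spec <- function(chromosomes, sequences = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (is.null(names(sequences)) ||
        !setequal(names(sequences), chromosomes$name))
      stop("sequence names must match chromosome names")
    sequences <- sequences[chromosomes$name]
    w <- Biostrings::width(sequences)
    if (!all(w == chromosomes$length))
      stop("sequence widths disagree with declared chromosome lengths")
  }
  structure(list(chromosomes = chromosomes[, c("name", "length")],
                 sequences = sequences),
            class = "GenomeSpec")
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat(sprintf("GenomeSpec: %d chromosome(s), %.0f bp total, sequence: %s\n",
              nrow(x$chromosomes), genome_length(x),
              if (is.null(x$sequences)) "absent" else "present"))
  print(x$chromosomes)
  invisible(x)
}

#' Total genome length in base pairs
#' @param genome a `GenomeSpec`.
#' @return numeric scalar.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "GenomeSpec"))
  sum(genome$chromosomes$length)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]])
  genome$chromosomes$length[i]
}

#' Simulate a random genome with sequence
#'
#' Draws i.i.d. uniform A/C/G/T sequence per chromosome, so GATC sites
#' occur at rate 4^-4 (one per 256 bp on average), giving restriction
#' fragments with approximately exponential length distribution --
#' adequate to exercise every fragment-level processing rule.
#'
#' @param chrom_lengths numeric vector of chromosome lengths (bp); names
#'   used as chromosome names, else `chrI`, `chrII`, ... style labels.
#' @param seed integer seed; all randomness in this package flows from
#'   explicit seeds (see [derive_seed()]).
#' @return a `GenomeSpec` with sequences.
#' @export
random_genome <- function(chrom_lengths = c(8e5, 1.2e6, 1.5e6), seed = 1L) {
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", utils::as.roman(seq_along(chrom_lengths)))
  seqs <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  names(seqs) <- nm
  genome_spec(data.frame(name = nm, length = as.numeric(chrom_lengths)),
              Biostrings::DNAStringSet(seqs))
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic stream splitting: each named consumer of randomness
#' (genome simulation, per-cell firing, per-column count noise, ...)
#' hashes `(seed, key)` into its own 31-bit seed, so adding a consumer
#' never shifts the stream of another. The hash is a Horner scheme over
#' the key bytes modulo the Mersenne prime 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param key character scalar naming the stream.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1, length(key) == 1)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(key)))
    h <- (h * 31 + b) %% m
  as.integer(if (h == 0) 1 else h)
}

#' Write a genome to FASTA
#' @param genome `GenomeSpec` with sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeSpec"))
  if (is.null(genome$sequences)) stop("genome has no sequences")
  Biostrings::writeXStringSet(genome$sequences, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return a `GenomeSpec` with sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_spec(data.frame(name = names(seqs),
                         length = Biostrings::width(seqs)),
              seqs)
}
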
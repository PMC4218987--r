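# sortseqrep

Genome-wide DNA replication profiling from sorted S-phase sequencing
("sort-seq"), for people studying replication timing, origin usage and
fork progression in budding yeast and similar genomes.

In a sort-seq experiment, cells are FACS-sorted by DNA content so that
every sampled cell is mid-replication, and the DNA is sequenced. A locus
replicated at time `t` within an S phase of duration `T_S` is present at
expected copy number

```
A(x) = 2 − t(x) / T_S          (2 = replicated at t = 0, → 1 as t → T_S)
```

in the sorted population, so early-replicating regions are
over-represented and replication origins appear as local maxima of the
normalized read-count profile. This package provides, as tested reusable
components:

* **A fork-progression simulator.** Origins fire at programmed times
  `T_i` (or stochastically with efficiencies `q_i`); forks move at
  velocity `v`; a locus replicates at `t(x) = min_i (T_i + |x − x_i|/v)`.
  An origin reached by another fork strictly before its own firing time
  is passively replicated (dormant). Synthetic fragment-level count
  matrices (S-phase plus G1/G2 control libraries, Poisson or
  negative-binomial noise) make the whole pipeline testable without any
  download.
* **The fragment-level processing cascade.** Reads are grouped by DpnII
  (`GATC`) restriction fragments; fragments shorter than 150 bp,
  fragments with zero counts in too many experiments, blacklisted
  fragments and experiments under 100,000 reads are removed;
  per-chromosome copy-number correction, fragment-length bias removal,
  division by the mean G1/G2 control signal, and per-experiment
  z-scoring (mean 0, population SD 1) follow in a fixed, logged order.
* **Signal conditioning.** Rank-k SVD reconstruction (k = 50 by
  default, capped at matrix rank) and per-chromosome Savitzky–Golay
  smoothing.
* **Profile-shape statistics.** Prominence-based extrema calling,
  activation heights `f_strain(x_i)` at reference origins, sharpness
  summaries of `f_strain − f_wt` at wild-type maxima/minima,
  autocorrelation decay, and between-strain Pearson correlation.
* **Origin prediction scoring.** Profile peaks are matched to a
  reference origin list within 5 kb; with `p` the fraction of the
  genome covered by the 5-kb windows, the enrichment P-value is the
  binomial upper tail

  ```
  P(X ≥ K | H0) = Σ_{i=K}^{N} C(N, i) p^i (1 − p)^(N−i)
  ```

  for `N` predicted and `K` matched origins, computed in log space so
  tails near 10⁻¹⁰⁰ keep full precision.

## Worked example

Three presets reproduce the qualitative regimes of interest in one call
each: `"wildtype"`, `"slow-fork"` (fork velocity ÷ 4 on the same origin
program — passive replication becomes unlikely, dormant origins
activate, the profile sharpens) and `"scaled"` (all firing times × 2,
velocity ÷ 2 — S phase doubles but the normalized profile is
unchanged).

```r
library(sortseqrep)

cfg <- preset_config("slow-fork", seed = 1)
ds  <- simulate_dataset(cfg)          # genome, origin program, counts
ds$matrix
#> CountMatrix: 13664 fragments x 20 experiments (10 S, 10 G1G2)

res <- run_pipeline(cfg, dataset = ds, write = FALSE)

evaluate_prediction(res$profiles$wildtype, ds$origins, ds$genome)
#> PredictionResult: 39/40 peaks within 5000 bp of an origin (coverage p = 0.137), log10 P = -32.11
evaluate_prediction(res$profiles$slowfork, ds$origins, ds$genome)
#> PredictionResult: 40/41 peaks within 5000 bp of an origin (coverage p = 0.137), log10 P = -32.96

sharpness_summary(res$profiles$slowfork, res$profiles$wildtype,
                  res$extrema$wildtype)
#> SharpnessSummary (slowfork vs wildtype)
#>   maxima: n = 40, quartiles = -0.0903 / 0.185 / 0.548
#>   minima: n = 38, quartiles = -0.456 / -0.0122 / 0.191

res$metrics$acf$wildtype$half_decay_lag   # 40 fragments
res$metrics$acf$slowfork$half_decay_lag   # 31 fragments
```

Reading the numbers: the slow-fork strain calls more peaks than
wild-type (41 vs 40; it activates dormant origins), nearly all peaks in
both strains sit within 5 kb of a true origin (`K/N ≈ 1`, binomial
log10 P ≈ −32 against a 13.7% genome coverage null), the median of
`f_slow − f_wt` is positive at wild-type maxima (+0.185) and negative
at minima (−0.012) — higher peaks, deeper troughs — and the slow-fork
autocorrelation decays faster (half-decay after 31 vs 40 fragments):
the profile-sharpening phenotype of slowed forks. The
`preset_config("scaled", ...)` contrast instead leaves peak counts
unchanged and profiles correlated at r > 0.99.

`run_pipeline(cfg)` with an `out_dir` writes profiles (bedGraph),
extrema tables (TSV), prediction reports (JSON), the correlation
matrix, a stage log and a provenance manifest. A command-line wrapper
ships in `inst/cli/sortseqrep-cli.R`:

```sh
Rscript inst/cli/sortseqrep-cli.R simulate --config run.json --out simdir
```

Real data enter through `config$paths`: a count-matrix TSV (or FASTA
genome + BED/SAM alignments digested and counted with
`digest_genome()` / `count_reads_per_fragment()`) and a reference
origin BED.

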
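---
title: "Sort-seq replication profiling: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq replication profiling: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the replication model behind the simulator, each stage of
the processing cascade, the statistics, and — most importantly — the
choices we made where the method left the design genuinely open.

## The fork-progression model

A replication program is a set of origins with positions `x_i`, firing
times `T_i` (minutes into S phase), per-cell firing probabilities
`q_i`, one genome-wide fork velocity `v` (bp/min) and an S-phase
duration `T_S`. In the deterministic model every origin fires at its
programmed time and

```
t(x) = min_i ( T_i + |x − x_i| / v )
```

over the origins of the chromosome. The model is deliberately minimal:
no rate-limiting initiation factors, no licensing dynamics, no
checkpoint signalling; forks never interact except through the
minimum, and they terminate at chromosome ends.

Assumptions worth stating explicitly:

* **Passive replication.** An origin reached by a fork strictly before
  its own `T_i` never fires (it was replicated passively). Arrival
  exactly at `T_i` counts as *active* — a fixed convention; ties are
  measure-zero in continuous parameterizations but must be
  deterministic in code.
* **Stochastic mode** decides firing per simulated cell: origin `i`
  fires with probability `q_i`, independently; a chromosome where
  nothing fired is re-drawn (replication must complete); an origin can
  be active in one cell and passively replicated in another. The
  reported timeline is the per-cell mean; per-origin activity
  frequencies are kept, and `active_origins` is defined as "active in
  at least half the cells". With all `q_i = 1` every cell reproduces
  the deterministic timeline exactly.
* **Abundance.** For cells sampled uniformly across S phase,
  `A(x) = 2 − t(x)/T_S`. Uniform S-phase residence is the simplest
  model consistent with early loci being proportionally
  over-represented; real FACS gates are not perfectly uniform in
  S-phase progression, which rescales the profile monotonically but
  does not move its extrema.

Two consequences the test suite asserts as properties: `t(x)` is
1/v-Lipschitz along a chromosome; and scaling all `T_i` by `c` while
dividing `v` by `c` scales `t(x)` by exactly `c`, so after z-scoring
the profile is unchanged — the proportional-scaling regime that most
S-phase-extending perturbations display.

## What the synthetic generator emulates — and what it does not

`random_program()` places origins with near-regular spacing (±10%
positional jitter around a regular grid) and draws firing times from a
smooth chromosomal landscape: a sinusoid of wavelength 800 kb and
amplitude `0.4 × t_spread` with random per-chromosome phase, plus
independent jitter up to `0.2 × t_spread`. The landscape emulates
replication-timing domains: neighbouring origins fire at similar
times. This matters quantitatively, not just cosmetically. The
sharpness statistics evaluate the mutant profile at *wild-type*
extrema; the meeting point of two converging forks is displaced from
the geometric midpoint by `(T_j − T_i)·v/2`, so with independent
firing times the wild-type minima land far from the slow-fork minima
and the slow profile is systematically sampled off its valley bottoms,
washing the minima-deepening signal out. With spatially correlated
firing times (small `T_j − T_i` between neighbours) the two strains
share valley positions and the fork-velocity mechanism is visible in
the medians. Irregular spacing has a related effect: a handful of
extra-long spans dominate the slow-fork profile's variance and
compress every typical valley after z-scoring.

Default world: 3 chromosomes of 0.8/1.2/1.5 Mb of i.i.d. uniform
A/C/G/T sequence (so GATC fragments average 256 bp), ~40 primary
origins (one per ~85 kb), fork velocity 1500 bp/min, `t_spread` 25
min, and 8 *dormant candidates*: origins placed 15–20 kb from an early
origin with firing times 5–10 min after the reference-velocity fork
would arrive. At `v` they are passively replicated; at `v/4` they
fire. Eight of ~48 mirrors the ~20% increase in called peaks that
motivates the slow-fork contrast. `T_S` is set to the deterministic
completion time times 1.15.

The generator does **not** emulate: mappability structure (the
blacklist is exercised with synthetic ids), GC bias, replication-
dependent copy-number interactions with CNVs, variable origin
licensing across cells beyond the single `q_i`, or read-level
artifacts (duplicates, multi-mappers). A green pipeline test therefore
establishes that the *statistical machinery* behaves as specified on
data whose generative process is known — not that these defaults
describe any particular organism quantitatively. Fork velocities and
firing-time spreads here are free parameters of the simulator, not
measured values.

All randomness flows from one integer seed through
`derive_seed(seed, key)` — a Horner hash of the stream name modulo
2³¹ − 1 — so adding a consumer of randomness never shifts another
consumer's stream, and every artifact is bit-reproducible from
(config, seed).

## The processing cascade

Order is fixed and logged: depth filter → row filters → CNV
correction → length-bias removal → control ratio → z-score → SVD.
Filters use strict inequalities ("shorter than 150 bp", "more than
`max_zero_experiments` zero experiments", "fewer than 100,000 reads").
The zero-experiment threshold of 300 presumes a several-hundred-column
collection; below 300 columns the default becomes 75% of columns.

Numerical choices:

* **Control ratio before z-scoring.** The method description lists
  z-scoring before division by the mean G1/G2 signal, but dividing a
  mean-zero signal elementwise is numerically treacherous (control
  values cross zero). We divide on positive-scale signal and z-score
  afterwards; the intent — cancelling fragment-specific capture
  efficiency — is identical. Relatedly, length-bias removal is
  subtractive (a running mean over length-ranked fragments, bandwidth
  5% of rows), which would centre the signal near zero; the pipeline
  therefore restores each column's pre-subtraction mean
  (`recenter = "mean"`) so the control stays positive. Control means
  below the 5% quantile of positive control means flag the fragment
  as missing rather than dividing by ~0; flagged rows are dropped
  before z-scoring.
* **CNV correction** equalizes per-chromosome medians against the
  genome-wide median, per experiment. The median resists the
  origin-driven skew within a chromosome that a mean would follow.
* **Z-scores** use the population convention (divisor *n*), so a
  z-scored column satisfies mean 0, SD 1 exactly, and re-application
  is the identity.
* **SVD.** Rank-50 reconstruction is the published choice for a
  collection of hundreds of experiments. `k` is capped at the matrix
  rank; for synthetic matrices of 10–20 columns the cap makes the
  step an identity (logged, silent otherwise). Denoising of synthetic
  data therefore rests on replicate averaging and smoothing — see the
  preset discussion below.
* **Savitzky–Golay** smoothing runs per chromosome in fragment-index
  space (uniform taps over fragments of unequal bp length). Origin
  structure spans hundreds of fragments, so index-space smoothing is
  a benign simplification; smoothing in bp space would require
  irregular-grid filters for no measurable gain at these scales. Edge
  handling: the least-squares polynomial of each terminal window is
  evaluated at the edge points (polynomial extrapolation), so
  polynomials up to `polyorder` are reproduced exactly everywhere,
  and the filter is linear. Defaults window 9, polyorder 3.

## Profile statistics

* **Extrema.** A maximum must exceed both neighbours (plateaus yield
  their centre) and have topographic prominence — the drop to the
  highest saddle toward higher terrain, sides searched to the nearest
  higher point or chromosome end — of at least `0.2 ×` profile SD.
  The threshold is not part of the published method; 0.2 SD is
  config-exposed and was chosen so that, at the synthetic noise
  level, called maxima coincide with active origins rather than noise
  bumps. Chromosome-terminal points are never extrema. Retained
  maxima and minima are forced to alternate (within a same-type run
  only the most extreme survives), which downstream summaries rely
  on.
* **Sharpness** evaluates `f_strain − f_wt` at wild-type maxima and,
  separately, minima, reporting quartiles and histograms. Activation
  tables at reference origins are kept separate from extrema-based
  sharpness: the former answer "how active is this known origin
  here", the latter "how peaked is this profile". `f` values are read
  from smoothed profiles; reading unsmoothed values adds noise
  without changing medians.
* **Autocorrelation** is computed per chromosome (mean-removed,
  lag-0-normalized) and averaged across chromosomes weighted by
  length — concatenating chromosomes would manufacture correlation at
  the seams. Decay is summarized as the first lag below 0.5.
* **Prediction scoring.** Peaks match a reference origin within 5 kb
  inclusive; each peak counts once however many origins are nearby.
  The null probability `p` is the fraction of the genome covered by
  the ±5 kb windows (interval union via IRanges, tested for exact
  agreement with per-base marking). The binomial tail is computed
  through `pbinom` in log space and cross-checked against an
  independent term-by-term summation (exact log-factorials, smallest
  terms first) and, in the acceptance suite, a 60-digit
  arbitrary-precision summation. The null treats peaks as
  independent uniform locations — nearby peaks are not independent
  in reality; this approximation is inherited from the method being
  implemented and documented rather than repaired.

## Presets and their rationale

`preset_config()` ships the three regimes as one-liners: `wildtype`,
`slow-fork` (`v ÷ 4`, same origin program) and `scaled` (`T_i × 2`,
`v ÷ 2`). Three preset-level choices deviate from the bare module
defaults and deserve justification:

* **Replicates: 7 wild-type, 3 per mutant** — the replicate structure
  of the study design this emulates.
* **Smoothing window 41 fragments (~10 kb)** instead of the generic
  default 9. With rank-capped SVD an identity at these column counts,
  smoothing must carry the denoising. The window must sit between
  two scales: well above the fragment noise scale, well below the
  ~75–85 kb inter-origin spacing (and the 15–20 kb dormant-to-host
  distance, which must stay resolvable). 41 fragments ≈ 10 kb
  satisfies both with an order of magnitude to spare on the upper
  side. The module default stays 9 because generic users of
  `savgol_smooth()` may have denser origin spacing; the knob is in
  the config either way.
* **Dormant candidates: 8** — chosen once to mirror a ~20% peak-count
  increase in the slow-fork contrast.

## Null calibration

The calibration test draws peaks uniformly at random and checks that
P < 0.05 occurs in 5% ± 1.5% of 1000 runs. The number of random peaks
per run is 2000: the binomial tail is discrete, and with a few hundred
peaks the largest attainable rejection level sits well below 0.05
(the achievable levels step by a factor of ~0.7 near the threshold),
so calibration cannot even be expressed at the stated tolerance. At
2000 peaks the levels are dense enough that the realized rate falls
inside the band whenever the statistic is correctly calibrated.

## Known limitations

* The deterministic model cannot express partial origin efficiency;
  stochastic mode can, but the processing contrast tests run
  deterministic programs for exact ground truth.
* `correct_cnv` equalizes whole-chromosome medians only; segmental
  CNVs pass through.
* The peak caller has no minimum-separation rule beyond prominence
  and alternation; two origins closer than roughly half the smoothing
  window merge into one called peak.
* Real-data mode consumes aligned positions (BED/SAM) and trusts the
  caller's blacklist for mappability; no alignment or duplicate
  handling is included.
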
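# digestion, read counting, filters, normalization

test_that("digestion cuts at every site start and tiles the chromosome", {
  g <- genome_spec(data.frame(name = "c1", length = 14),
                   c(c1 = "AAGATCCCGATCTT"))
  fr <- digest_genome(g)
  expect_equal(fr$start, c(0, 2, 8))
  expect_equal(fr$end, c(2, 8, 14))

  g2 <- genome_spec(data.frame(name = "c1", length = 10),
                    c(c1 = "AAAATTTTCC"))
  fr2 <- digest_genome(g2)
  expect_equal(fr2$start, 0)
  expect_equal(fr2$end, 10)

  # site at position 0: empty leading interval is dropped
  g3 <- genome_spec(data.frame(name = "c1", length = 8),
                    c(c1 = "GATCGATC"))
  fr3 <- digest_genome(g3)
  expect_equal(fr3$start, c(0, 4))
  expect_equal(fr3$end, c(4, 8))

  # ambiguity codes in the subject never match and never crash
  g4 <- genome_spec(data.frame(name = "c1", length = 8),
                    c(c1 = "GATNCAAA"))
  expect_equal(nrow(digest_genome(g4)), 1)

  # property: fragments tile each chromosome exactly
  g5 <- random_genome(c(3e4, 2e4), seed = 4)
  fr5 <- digest_genome(g5)
  lens <- tapply(fr5$length, fr5$chrom, sum)
  expect_equal(as.numeric(lens[g5$chromosomes$name]),
               g5$chromosomes$length)
  expect_true(all(fr5$length > 0))
})

test_that("reads land in the fragment containing their 5' position", {
  fr <- data.frame(chrom = "c1", start = c(0, 2, 8), end = c(2, 8, 14),
                   length = c(2, 6, 6), id = c("a", "b", "c"))
  class(fr) <- c("FragmentTable", "data.frame")
  r <- count_reads_per_fragment(
    data.frame(chrom = "c1", pos = c(0, 1, 5)), fr)
  expect_equal(r$counts, c(2, 1, 0))
  expect_equal(r$assigned, 3)

  # empty stream -> all-zero column
  r0 <- count_reads_per_fragment(
    data.frame(chrom = character(), pos = numeric()), fr)
  expect_equal(r0$counts, c(0, 0, 0))

  # half-open convention: position == fragment start
  r1 <- count_reads_per_fragment(data.frame(chrom = "c1", pos = 8), fr)
  expect_equal(r1$counts, c(0, 0, 1))

  # unknown chromosome is tallied, not fatal; reads are conserved
  expect_message(
    r2 <- count_reads_per_fragment(
      data.frame(chrom = c("c1", "cX"), pos = c(3, 3)), fr),
    "unknown chromosome")
  expect_equal(r2$assigned + r2$unassigned, 2)
  expect_equal(r2$unassigned, 1)
})

test_that("read conservation holds on random inputs", {
  set.seed(20)
  g <- random_genome(2e4, seed = 20)
  fr <- digest_genome(g)
  reads <- data.frame(chrom = sample(c("chrI", "nope"), 500, replace = TRUE,
                                     prob = c(0.95, 0.05)),
                      pos = sample(0:19999, 500, replace = TRUE))
  r <- suppressMessages(count_reads_per_fragment(reads, fr))
  expect_equal(sum(r$counts), r$assigned)
  expect_equal(r$assigned + r$unassigned, nrow(reads))
})

test_that("row filters use strict inequalities and itemized reports", {
  # lengths: strict 'shorter than 150'
  m <- toy_matrix(matrix(5, 3, 2), lengths = c(100L, 150L, 151L))
  f <- filter_fragments(m, min_length = 150, max_zero_experiments = 10)
  expect_equal(nrow(f$matrix$values), 2)
  expect_equal(length(f$report$rules$short_fragment), 1)
  expect_equal(f$report$removed + f$report$retained, f$report$input)

  # zeros: strict 'more than'
  v <- matrix(1, 2, 4)
  v[1, 1:3] <- 0  # zeros in 3 experiments -> removed at threshold 2
  v[2, 1:2] <- 0  # zeros in 2 experiments -> kept
  m2 <- toy_matrix(v, lengths = c(200L, 200L))
  f2 <- filter_fragments(m2, min_length = 150, max_zero_experiments = 2)
  expect_equal(nrow(f2$matrix$values), 1)
  expect_equal(f2$matrix$fragments$id, m2$fragments$id[2])

  # no-op on clean input
  m3 <- toy_matrix(matrix(3, 4, 2), lengths = rep(200L, 4))
  f3 <- filter_fragments(m3, min_length = 150, max_zero_experiments = 1)
  expect_equal(f3$matrix$values, m3$values)
  expect_equal(f3$report$removed, 0)

  # blacklist
  f4 <- filter_fragments(m3, blacklist = m3$fragments$id[2])
  expect_equal(nrow(f4$matrix$values), 3)

  # everything removed -> classed error carrying the report
  err <- tryCatch(filter_fragments(m3, min_length = 1000),
                  ssr_all_removed = function(e) e)
  expect_s3_class(err, "ssr_all_removed")
  expect_equal(err$report$removed, 4)
})

test_that("experiment filter is strict at the read floor", {
  v <- cbind(rep(33333, 3), rep(33334, 3))  # totals 99999 and 100002
  m <- toy_matrix(v)
  f <- filter_experiments(m, min_reads = 100000)
  expect_equal(ncol(f$matrix$values), 1)
  expect_equal(f$matrix$experiments$id, "e2")
  # boundary: exactly min_reads is kept
  v2 <- cbind(rep(25000, 4), rep(1, 4))
  f2 <- filter_experiments(toy_matrix(v2), min_reads = 100000)
  expect_equal(f2$matrix$experiments$id, "e1")
  # min_reads 0 removes nothing
  f3 <- filter_experiments(m, min_reads = 0)
  expect_equal(ncol(f3$matrix$values), 2)
  # all removed -> error
  expect_error(filter_experiments(m, min_reads = 1e9), "all experiments")
})

test_that("row filter rules commute", {
  set.seed(7)
  for (i in 1:5) {
    v <- matrix(rpois(60, 1.2), 10, 6)
    lens <- sample(c(80L, 120L, 200L, 400L), 10, replace = TRUE)
    m <- toy_matrix(v, lengths = lens)
    both <- filter_fragments(m, min_length = 150, max_zero_experiments = 3)
    # length rule then zero rule, as separate passes
    a <- filter_fragments(m, min_length = 150, max_zero_experiments = 1e6)
    b <- tryCatch(
      filter_fragments(a$matrix, min_length = 0, max_zero_experiments = 3),
      ssr_all_removed = function(e) NULL)
    # zero rule then length rule
    c1 <- filter_fragments(m, min_length = 0, max_zero_experiments = 3)
    d <- tryCatch(
      filter_fragments(c1$matrix, min_length = 150, max_zero_experiments = 1e6),
      ssr_all_removed = function(e) NULL)
    if (!is.null(b) && !is.null(d)) {
      expect_identical(b$matrix$fragments$id, both$matrix$fragments$id)
      expect_identical(d$matrix$fragments$id, both$matrix$fragments$id)
    }
  }
})

test_that("CNV correction equalizes per-chromosome medians", {
  set.seed(15)
  base <- rpois(40, 100)
  v <- matrix(c(base[1:20] * 2, base[21:40]), ncol = 1)  # chr1 doubled
  chrom <- rep(c("a", "b"), each = 20)
  m <- toy_matrix(v, lengths = rep(200L, 40), chrom = chrom)
  cc <- correct_cnv(m)
  med <- tapply(cc$values[, 1], cc$fragments$chrom, median)
  expect_equal(as.numeric(med["a"]), as.numeric(med["b"]), tolerance = 1e-9)

  # balanced input is unchanged when medians already agree
  v2 <- matrix(rep(c(90, 100, 110, 100), 10), ncol = 1)
  m2 <- toy_matrix(v2, lengths = rep(200L, 40), chrom = chrom)
  cc2 <- correct_cnv(m2)
  expect_equal(cc2$values, m2$values, tolerance = 1e-9)

  # medians m and 3m -> relative factor 1/3
  v3 <- matrix(c(rep(30, 20), rep(90, 20)), ncol = 1)
  m3 <- toy_matrix(v3, lengths = rep(200L, 40), chrom = chrom)
  cc3 <- correct_cnv(m3)
  fac <- attr(cc3, "cnv_factors")
  expect_equal(as.numeric(fac["b", 1] / fac["a", 1]), 1 / 3, tolerance = 1e-9)
})

test_that("z-scoring hits the population-moment contract", {
  m <- toy_matrix(matrix(c(1, 2, 3), ncol = 1))
  z <- zscore_experiments(m)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)

  set.seed(2)
  m2 <- toy_matrix(matrix(rpois(60, 50), 20, 3))
  z2 <- zscore_experiments(m2)
  expect_true(all(abs(colMeans(z2$values)) < 1e-9))
  psd <- apply(z2$values, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_true(all(abs(psd - 1) < 1e-9))
  # idempotence
  expect_equal(zscore_experiments(z2)$values, z2$values, tolerance = 1e-9)
  # constant column is fatal and names the experiment
  m3 <- toy_matrix(cbind(rpois(5, 10), rep(4, 5)))
  expect_error(zscore_experiments(m3), "e2")
})

test_that("length-bias removal flattens the signal-length relationship", {
  set.seed(31)
  lens <- sample(150:2000, 400, replace = TRUE)
  v <- matrix(0.01 * lens + rnorm(400, sd = 1), ncol = 1)
  m <- toy_matrix(v, lengths = as.integer(lens))
  out <- remove_length_bias(m)
  expect_lt(abs(cor(out$values[, 1], lens)), 0.05)

  # exactly linear, zero noise, equally spaced lengths -> residuals ~ 0
  # everywhere (the running mean reproduces the line exactly)
  lens_eq <- seq(150L, 2145L, by = 5L)
  v2 <- matrix(0.5 * lens_eq + 2, ncol = 1)
  out2 <- remove_length_bias(toy_matrix(v2, lengths = lens_eq))
  expect_true(all(abs(out2$values) < 1e-9))

  # length-independent signal: only an ~constant trend is subtracted
  v3 <- matrix(rep(7, 400), ncol = 1)
  out3 <- remove_length_bias(toy_matrix(v3, lengths = as.integer(lens)))
  expect_true(all(abs(out3$values) < 1e-9))
  out3m <- remove_length_bias(toy_matrix(v3, lengths = as.integer(lens)),
                              recenter = "mean")
  expect_true(all(abs(out3m$values - 7) < 1e-9))

  # bandwidth larger than the row count shrinks with a warning
  m4 <- toy_matrix(matrix(1:5, ncol = 1), lengths = c(150L, 160L, 170L, 180L, 190L))
  expect_warning(remove_length_bias(m4, bandwidth = 99), "shrunk")
})

test_that("control ratio divides by the G1/G2 mean with a floor", {
  # control mean == 2 -> S column halves
  v <- cbind(c(4, 8, 12), c(2, 2, 2))
  m <- toy_matrix(v, gate = c("S", "G1G2"))
  r <- ratio_to_control(m, rescore = FALSE, drop_controls = TRUE,
                        floor_quantile = 0)
  expect_equal(unname(r$values[, 1]), c(2, 4, 6))

  # zero control mean -> flagged missing, not infinite
  v2 <- cbind(c(4, 8, 12), c(2, 0, 2), c(2, 0, 2))
  m2 <- toy_matrix(v2, gate = c("S", "G1G2", "G1G2"))
  expect_message(
    r2 <- ratio_to_control(m2, rescore = FALSE, drop_controls = TRUE,
                           floor_quantile = 0.05),
    "flagged missing")
  expect_true(is.na(r2$values[2, 1]))
  expect_true(all(is.finite(r2$values[c(1, 3), 1])))

  # S identical to the control mean -> constant ratio; re-z-scoring
  # trips the constant-column rule
  v3 <- cbind(c(3, 5, 9), c(3, 5, 9))
  m3 <- toy_matrix(v3, gate = c("S", "G1G2"))
  expect_error(ratio_to_control(m3, rescore = TRUE, drop_controls = TRUE),
               "constant column")
  # missing controls are a hard precondition
  m4 <- toy_matrix(cbind(1:3), gate = "S")
  expect_error(ratio_to_control(m4), "control columns not found")
})

test_that("count matrix TSV round-trips", {
  set.seed(5)
  m <- toy_matrix(matrix(rpois(12, 40), 4, 3), gate = c("S", "S", "G1G2"))
  path <- file.path(tempdir(), "cm.tsv")
  write_count_matrix(m, path)
  m2 <- read_count_matrix(path)
  expect_equal(unname(m2$values), unname(m$values))
  expect_equal(m2$fragments$id, m$fragments$id)
  expect_equal(m2$experiments$gate, m$experiments$gate)
})
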
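# extrema calling, activation heights, sharpness, ACF, correlations

test_that("extrema calling handles canonical shapes", {
  # triangle: one apex, no internal minima
  tri <- toy_profile(c(0:10, 9:0))
  e <- find_extrema(tri)
  expect_equal(nrow(e$maxima), 1)
  expect_equal(e$maxima$row, 11)
  expect_equal(nrow(e$minima), 0)

  # cosine, 3 full periods: 3 maxima alternating with minima
  i <- 1:299
  cosine <- toy_profile(cos(2 * pi * (i - 50) / 100))
  e2 <- find_extrema(cosine)
  expect_equal(nrow(e2$maxima), 3)
  expect_equal(e2$maxima$row, c(50, 150, 250))
  ev <- rbind(data.frame(r = e2$maxima$row, t = "M"),
              data.frame(r = e2$minima$row, t = "m"))
  ev <- ev[order(ev$r), ]
  expect_true(all(ev$t[-1] != ev$t[-nrow(ev)]))

  # monotone: nothing
  e3 <- find_extrema(toy_profile(1:50))
  expect_equal(nrow(e3$maxima) + nrow(e3$minima), 0)

  # plateau yields its centre
  e4 <- find_extrema(toy_profile(c(0, 1, 2, 2, 2, 1, 0)))
  expect_equal(e4$maxima$row, 4)
})

test_that("prominence threshold suppresses sub-threshold ripples", {
  i <- 1:400
  big <- cos(2 * pi * (i - 100) / 200)    # interior peaks at 100 and 300
  e <- find_extrema(toy_profile(big + 0.03 * cos(2 * pi * i / 10)),
                    min_prominence = 0.2)
  expect_equal(e$maxima$row, c(100, 300))
  # a strong ripple under a negligible threshold is called everywhere
  e2 <- find_extrema(toy_profile(big + 0.2 * cos(2 * pi * i / 10)),
                     min_prominence = 1e-6)
  expect_gt(nrow(e2$maxima), 20)
})

test_that("maxima and minima alternate on random smooth profiles", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- as.numeric(stats::filter(rnorm(400), rep(1 / 15, 15), sides = 2))
    x <- x[!is.na(x)]
    e <- find_extrema(toy_profile(x), min_prominence = 0.1)
    ev <- rbind(data.frame(r = e$maxima$row, t = "M"),
                data.frame(r = e$minima$row, t = "m"))
    ev <- ev[order(ev$r), ]
    if (nrow(ev) > 1)
      expect_true(all(ev$t[-1] != ev$t[-nrow(ev)]))
  }
})

test_that("activation heights read the fragment containing each origin", {
  p1 <- toy_profile(seq(0, 9.9, by = 0.1), width = 100)  # fragments of 100 bp
  p2 <- toy_profile(seq(0, 9.9, by = 0.1) + 1, width = 100)
  # origin at a fragment midpoint
  tab <- activation_heights(list(a = p1, b = p2),
                            data.frame(chrom = "chr1", pos = 250))
  expect_equal(tab$f_a, p1$value[3])
  expect_equal(tab$f_b, p2$value[3])
  # identical profiles give identical columns
  tab2 <- activation_heights(list(a = p1, b = p1),
                             data.frame(chrom = "chr1", pos = c(10, 510, 990)))
  expect_equal(tab2$f_a, tab2$f_b)
  # origin inside a filtered gap beyond max_gap -> missing
  fr <- toy_fragments(rep(100L, 200))
  keep <- fr$start < 2000 | fr$start >= 12000  # 10 kb hole
  frg <- fr[keep, ]; class(frg) <- class(fr)
  pg <- replication_profile(frg, rnorm(nrow(frg)))
  tab3 <- activation_heights(list(a = pg),
                             data.frame(chrom = "chr1", pos = 7000),
                             max_gap = 5000)
  expect_true(tab3$missing)
  expect_true(is.na(tab3$f_a))
  # but reachable within max_gap uses the nearest midpoint
  tab4 <- activation_heights(list(a = pg),
                             data.frame(chrom = "chr1", pos = 3000),
                             max_gap = 5000)
  expect_false(tab4$missing)
})

test_that("sharpness differences behave under shift, scale and swap", {
  # z-scored cosine: every prominent maximum sits above the mean and
  # every minimum below, so the scaling sign analysis is exact
  i <- 1:500
  x <- as.numeric(scale(cos(2 * pi * (i - 50) / 100)))
  wt <- toy_profile(x, strain = "wt")
  ext <- find_extrema(wt)
  # identical strain: all differences zero
  s0 <- sharpness_summary(wt, wt, ext)
  expect_equal(s0$maxima$percentiles, c(0, 0, 0))
  # constant shift
  sh <- toy_profile(x + 0.7, strain = "sh")
  s1 <- sharpness_summary(sh, wt, ext)
  expect_equal(unique(round(s1$maxima$diffs, 12)), 0.7)
  expect_equal(unique(round(s1$minima$diffs, 12)), 0.7)
  # doubling a z-scored profile: positive at maxima, negative at minima
  dbl <- toy_profile(2 * x, strain = "dbl")
  s2 <- sharpness_summary(dbl, wt, ext)
  expect_true(all(s2$maxima$diffs > 0))
  expect_true(all(s2$minima$diffs < 0))
  # antisymmetry under swapping roles (same evaluation points)
  s3 <- sharpness_summary(wt, dbl, ext)
  expect_equal(s3$maxima$diffs, -s2$maxima$diffs)
  expect_equal(s3$maxima$percentiles, -rev(s2$maxima$percentiles))
  # no extrema is an error
  flat <- toy_profile(rep(1, 10))
  empty <- find_extrema(toy_profile(1:10))
  expect_error(sharpness_summary(flat, flat, empty), "no extrema")
})

test_that("autocorrelation is normalized and decays as expected", {
  set.seed(51)
  x <- rnorm(2000)
  a <- autocorrelation(toy_profile(x), max_lag = 20)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf[-1]) < 3 / sqrt(2000)))

  # cosine of period P: ACF at P/2 ~ -1 (finite-series taper aside)
  n <- 5000; P <- 100
  cs <- toy_profile(cos(2 * pi * (1:n) / P))
  a2 <- autocorrelation(cs, max_lag = 60)
  expect_equal(a2$acf[P / 2 + 1], -1, tolerance = 0.05)
  expect_equal(a2$half_decay_lag, ceiling(P / 6))  # cos falls below 0.5 at P/6

  # sharper profile decorrelates faster
  slow <- toy_profile(cos(2 * pi * (1:n) / 500))
  fast <- toy_profile(cos(2 * pi * (1:n) / 100))
  expect_lt(autocorrelation(fast, max_lag = 200)$half_decay_lag,
            autocorrelation(slow, max_lag = 200)$half_decay_lag)

  # oversized max_lag is reduced with a warning
  expect_warning(a3 <- autocorrelation(toy_profile(rnorm(30)), max_lag = 50),
                 "reduced")
  expect_equal(length(a3$acf), 30)
})

test_that("ACF averages across chromosomes instead of concatenating", {
  set.seed(52)
  x <- rnorm(500); y <- rnorm(700)
  joint <- autocorrelation(toy_profile_multi(list(x, y)), max_lag = 10)
  ax <- stats::acf(x, lag.max = 10, plot = FALSE)$acf[, 1, 1]
  ay <- stats::acf(y, lag.max = 10, plot = FALSE)$acf[, 1, 1]
  expect_equal(joint$acf, (500 * ax + 700 * ay) / 1200, tolerance = 1e-12)
})

test_that("profile correlation matrix has the Pearson contract", {
  set.seed(53)
  x <- rnorm(1e4)
  p <- toy_profile(x)
  cm <- correlation_matrix(list(a = p, b = p, neg = toy_profile(-x)))
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "neg"], -1)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), c(a = 1, b = 1, neg = 1))
  # independent noise: near-zero correlation
  cm2 <- correlation_matrix(list(a = p, b = toy_profile(rnorm(1e4))))
  expect_lt(abs(cm2["a", "b"]), 0.05)
  # shared-fragment intersection: profiles on different row subsets
  fr <- toy_fragments(rep(100L, 50))
  f1 <- fr[1:40, ]; class(f1) <- class(fr)
  f2 <- fr[11:50, ]; class(f2) <- class(fr)
  q1 <- replication_profile(f1, seq_len(40))
  q2 <- replication_profile(f2, seq(11, 50))
  cm3 <- correlation_matrix(list(u = q1, v = q2))
  expect_equal(cm3["u", "v"], 1)  # identical on the 30 shared fragments
  # fewer than 2 shared fragments is an error
  f3 <- fr[45:50, ]; class(f3) <- class(fr)
  expect_error(correlation_matrix(list(u = q1, w = replication_profile(f3, 1:6))),
               "shared fragments")
})
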
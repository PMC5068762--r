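test_that("nearest-rank strict-threshold selection on distinct lengths", {
  # 20 peaks of lengths 1..20 kb: the 95th-percentile nearest rank is the
  # 19th order statistic (19 kb), so only the 20 kb peak is selected
  ps <- peak_set(rep("chr1", 20), (0:19) * 1e5, (0:19) * 1e5 + 1000 * (1:20))
  sel <- select_broadest(ps, 0.05)
  expect_equal(nrow(sel$peaks), 1L)
  expect_equal(peak_length(sel$peaks), 20000)
  expect_equal(sel$summary$percentile_threshold, 19000)
  expect_equal(sel$summary$n_peaks, 1L)
})

test_that("tie-degenerate input yields an empty selection with a warning", {
  ps <- peak_set(rep("chr1", 30), (0:29) * 1e4, (0:29) * 1e4 + 500)
  expect_warning(sel <- select_broadest(ps, 0.1), "empty selection")
  expect_equal(nrow(sel$peaks), 0L)
})

test_that("selection equals the sort-then-filter oracle on log-normal lengths", {
  set.seed(3)
  n <- 10000
  len <- pmax(round(rlnorm(n, log(1200), 0.6)), 50)
  start <- seq(0, by = 40000, length.out = n)
  ps <- peak_set(rep("chr1", n), start, start + len)
  sel <- select_broadest(ps, 0.05)
  # independent oracle: sort lengths, take the nearest-rank percentile,
  # keep strictly larger
  srt <- sort(peak_length(ps))
  thr <- srt[ceiling(0.95 * n)]
  expect_equal(sel$summary$percentile_threshold, thr)
  expect_equal(sort(peak_length(sel$peaks)), srt[srt > thr])
  frac <- nrow(sel$peaks) / n
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.05)
})

test_that("selection is scale-equivariant and nested across fractions", {
  set.seed(9)
  n <- 2000
  len <- pmax(round(rlnorm(n, log(1000), 0.5)), 50)
  start <- seq(0, by = 30000, length.out = n)
  ps <- peak_set(rep("chr1", n), start, start + len)
  ps3 <- peak_set(rep("chr1", n), 3 * start, 3 * start + 3 * len)
  sel <- select_broadest(ps, 0.05)
  sel3 <- select_broadest(ps3, 0.05)
  expect_equal(sel3$summary$percentile_threshold,
               3 * sel$summary$percentile_threshold)
  expect_equal(sel3$peaks$start, 3 * sel$peaks$start)   # same membership
  # top 1% is a subset of the top 5%
  sel1 <- select_broadest(ps, 0.01)
  keys5 <- paste(sel$peaks$chrom, sel$peaks$start)
  keys1 <- paste(sel1$peaks$chrom, sel1$peaks$start)
  expect_true(all(keys1 %in% keys5))
})

test_that("select_broadest validates its inputs", {
  ps <- peak_set(rep("chr1", 10), (0:9) * 1e4, (0:9) * 1e4 + 100 * (1:10))
  expect_error(select_broadest(ps[0, ]), "empty")
  expect_error(select_broadest(ps, 1.5), "fraction")
  expect_error(select_broadest(ps, 0), "fraction")
  expect_error(select_broadest(ps, 0.05), "at least 20")
})

test_that("breadth_ratio reproduces the ~3.6-fold broad/all contrast", {
  # identical summaries give 1
  s <- summarize_breadth(peak_set("chr1", 0, 1500))
  expect_equal(breadth_ratio(s, s), 1.0)
  # printed magnitudes: top-5% mean 5.4 kb over overall mean 1.5 kb
  broad <- summarize_breadth(peak_set("chr1", 0, 5400))
  all_p <- summarize_breadth(peak_set("chr1", 0, 1500))
  expect_equal(breadth_ratio(broad, all_p), 3.6)
})

test_that("breadth_ratio recovers a planted ratio on synthetic lengths", {
  set.seed(21)
  n <- 5000
  # plant: 95% of peaks ~1 kb, 5% broad tail calibrated for ratio ~3
  base_mean <- 1000
  len <- ifelse(runif(n) < 0.055,
                round(rlnorm(n, log(3200), 0.25)),
                round(rlnorm(n, log(base_mean) - 0.125, 0.5)))
  start <- seq(0, by = 50000, length.out = n)
  ps <- peak_set(rep("chr1", n), start, start + pmax(len, 50))
  sel <- select_broadest(ps, 0.05)
  ratio <- breadth_ratio(sel$summary, summarize_breadth(ps))
  planted <- mean(sort(len, decreasing = TRUE)[seq_len(floor(0.05 * n))]) /
    mean(len)
  expect_lt(abs(ratio - planted), 0.2)
})

test_that("rank-by-score selects the tallest peaks instead", {
  set.seed(2)
  ps <- random_peaks(100)
  ps$score <- sample.int(1e5, 100)
  sel <- select_broadest(ps, 0.05, rank_by = "score")
  expect_equal(sort(sel$peaks$score, decreasing = TRUE),
               sort(ps$score, decreasing = TRUE)[1:5])
})
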
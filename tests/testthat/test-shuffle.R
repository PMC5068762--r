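test_that("shuffles stay in bounds and preserve the length multiset", {
  layout <- genome_layout("chr1", 1000)
  one <- peak_set("chr1", 0, 100)
  for (s in 1:50) {
    sh <- shuffle_intervals(one, layout, seed = s)
    expect_gte(sh$start, 0)
    expect_lte(sh$end, 1000)
    expect_equal(peak_length(sh), 100)
  }
  set.seed(1)
  layout3 <- test_layout()
  ps <- random_peaks(200, layout3)
  sh <- shuffle_intervals(ps, layout3, seed = 99)
  expect_equal(sort(peak_length(sh)), sort(peak_length(ps)))
  expect_equal(table(sh$chrom), table(ps$chrom))
  # same seed, same placement
  expect_equal(shuffle_intervals(ps, layout3, seed = 7),
               shuffle_intervals(ps, layout3, seed = 7))
  expect_error(shuffle_intervals(peak_set("chr1", 0, 2000), layout,
                                 seed = 1), "longer than")
})

test_that("shuffled starts are uniform over their support", {
  layout <- genome_layout("chr1", 10000)
  one <- peak_set("chr1", 0, 100)   # start support [0, 9900]
  set.seed(42)
  starts <- vapply(seq_len(10000), function(i)
    shuffle_intervals(one, layout)$start, numeric(1))
  bins <- table(cut(starts, breaks = seq(0, 9901, length.out = 11),
                    include.lowest = TRUE))
  chi <- sum((bins - 1000)^2 / 1000)
  expect_gt(pchisq(chi, df = 9, lower.tail = FALSE), 0.001)
})

test_that("cross-chromosome shuffling respects feasibility and weights", {
  layout <- genome_layout(c("chr1", "chr2"), c(10000, 500))
  long <- peak_set("chr2", 0, 400)
  set.seed(8)
  dest <- replicate(200, shuffle_intervals(
    long, layout, within_chromosome = FALSE)$chrom)
  expect_true(all(dest %in% c("chr1", "chr2")))
  expect_gt(mean(dest == "chr1"), 0.8)  # length-weighted
  expect_error(
    shuffle_intervals(peak_set("chr1", 0, 20000), layout,
                      within_chromosome = FALSE),
    "longer than every chromosome")
})

test_that("permutation test saturates when the reference tiles the genome", {
  layout <- test_layout(2, 1e5)
  ref <- peak_set(c("chr1", "chr2"), c(0, 0), c(1e5, 1e5))
  set.seed(14)
  q <- random_peaks(30, layout, max_len = 1000)
  res <- permutation_overlap_test(q, ref, layout, n_perm = 100, seed = 4)
  expect_equal(res$observed, 30L)
  expect_equal(res$p_empirical, 1.0)
  expect_equal(res$fold, 1.0)
})

test_that("a perfect overlap with a sparse reference is maximally significant", {
  layout <- genome_layout("chr1", 1e7)
  # query identical to a reference covering <1% of the genome
  q <- peak_set(rep("chr1", 20), (0:19) * 5e5, (0:19) * 5e5 + 2000)
  res <- permutation_overlap_test(q, q, layout, n_perm = 999, seed = 2)
  expect_equal(res$observed, 20L)
  expect_lte(res$p_empirical, 5 / 1000)  # near the attainable floor
  expect_gte(res$p_empirical, 1 / 1000)  # add-one: never zero
  expect_gt(res$fold, 5)
})

test_that("fast permutation counting equals the GRanges-based count", {
  set.seed(33)
  layout <- test_layout()
  q <- random_peaks(80, layout)
  r <- random_peaks(150, layout)
  # one shuffle with a fixed seed, counted both ways
  sh <- shuffle_intervals(q, layout, seed = 55)
  slow <- intersect_count(sh, r)
  ref <- broaddomain:::reduce_reference(r)
  fast <- 0L
  for (ch in unique(sh$chrom)) {
    p <- sh[sh$chrom == ch, ]
    fast <- fast + sum(broaddomain:::hits_reduced(p$start, p$end, ref[[ch]]))
  }
  expect_equal(fast, slow)
  # and the full test is reproducible under a seed
  r1 <- permutation_overlap_test(q, r, layout, n_perm = 100, seed = 9)
  r2 <- permutation_overlap_test(q, r, layout, n_perm = 100, seed = 9)
  expect_equal(r1$perm_counts, r2$perm_counts)
  expect_equal(r1$p_empirical, r2$p_empirical)
})

test_that("fold approaches 1 under an independent-placement null", {
  # dense query/reference so the observed count has small relative noise
  set.seed(77)
  layout <- genome_layout(paste0("chr", 1:5), rep(1e7 / 5, 5))
  q <- random_peaks(400, layout, max_len = 3000)
  r <- random_peaks(2000, layout, max_len = 3000)
  res <- permutation_overlap_test(q, r, layout, n_perm = 5000, seed = 3)
  expect_lt(abs(res$fold - 1), 0.1)
})

test_that("permutation test rejects bad inputs", {
  layout <- test_layout()
  q <- random_peaks(10, layout)
  expect_error(permutation_overlap_test(q[0, ], q, layout, 100), "empty")
  expect_error(permutation_overlap_test(q, q, layout, n_perm = 10),
               "n_perm")
})
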
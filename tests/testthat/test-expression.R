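make_expr <- function(values_gray, values_white, n_pairs = 6) {
  ng <- nrow(values_gray)
  subjects <- sprintf("S%02d", seq_len(n_pairs))
  meta <- data.frame(sample = c(paste0(subjects, "_g"), paste0(subjects, "_w")),
                     subject = rep(subjects, 2),
                     compartment = rep(c("gray", "white"), each = n_pairs))
  vals <- cbind(values_gray, values_white)
  dimnames(vals) <- list(sprintf("gene%03d", seq_len(ng)), meta$sample)
  expression_matrix(vals, meta)
}

test_that("paired test is antisymmetric under compartment relabelling", {
  set.seed(9)
  ng <- 60
  g <- matrix(rlnorm(ng * 6, 2, 1), ng)
  w <- matrix(rlnorm(ng * 6, 1.3, 1), ng)
  fwd <- paired_compartment_test(make_expr(g, w))
  rev <- paired_compartment_test(make_expr(w, g))
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$median_log_ratio, -rev$median_log_ratio)
  expect_equal(fwd$n_pairs, 6L)
})

test_that("degenerate all-equal matrix reports no signal", {
  v <- matrix(5, nrow = 20, ncol = 6)
  expect_error(paired_compartment_test(make_expr(v, v)), "no signal")
  bad <- make_expr(matrix(rlnorm(120), 20), matrix(rlnorm(120), 20))
  expect_error(paired_compartment_test(bad, "nope"), "not in expression")
})

test_that("a planted 1-log2 gray effect over 475 genes is detected", {
  set.seed(9)
  ng <- 475
  base <- rnorm(ng, 4, 1)
  g <- matrix(2^(base + 1 + rnorm(ng * 6, 0, 0.5)), ng)
  w <- matrix(2^(base + rnorm(ng * 6, 0, 0.5)), ng)
  res <- paired_compartment_test(make_expr(g, w))
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$median_log_ratio, 0.5)
})

test_that("signed-rank p matches exact enumeration for small gene sets", {
  set.seed(15)
  for (i in 1:20) {
    ng <- sample(8:18, 1)
    base <- rnorm(ng, 3, 1)
    g <- matrix(2^(base + rnorm(ng * 6, 0.3, 0.6)), ng)
    w <- matrix(2^(base + rnorm(ng * 6, 0, 0.6)), ng)
    expr <- make_expr(g, w)
    res <- paired_compartment_test(expr)
    diffs <- rowMeans(g) - rowMeans(w)
    expect_equal(res$p_value, oracle_signed_rank_p(diffs),
                 tolerance = 1e-10)
  }
})

test_that("planted null effect gives calibrated p-values over seeds", {
  set.seed(30)
  ps <- replicate(400, {
    ng <- 50
    base <- rnorm(ng, 3, 1)
    g <- matrix(2^(base + rnorm(ng * 6, 0, 0.5)), ng)
    w <- matrix(2^(base + rnorm(ng * 6, 0, 0.5)), ng)
    paired_compartment_test(make_expr(g, w))$p_value
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("sample correlations behave like Spearman's rho", {
  set.seed(12)
  m <- matrix(rlnorm(5 * 40), nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  m[2, ] <- m[1, ]                       # duplicated sample
  cc <- sample_correlation(m)
  expect_equal(cc[1, 2], 1.0)
  expect_true(isSymmetric(cc))
  expect_equal(diag(cc), setNames(rep(1, 5), rownames(m)))
  # rank reversal
  m[3, ] <- max(m[1, ]) + 1 - m[1, ]
  expect_equal(sample_correlation(m)[1, 3], -1.0)
  # invariance under a strictly increasing transform of one sample
  cc0 <- sample_correlation(m)
  m2 <- m
  m2[4, ] <- exp(m2[4, ] / max(m2[4, ]))
  cc2 <- sample_correlation(m2)
  expect_equal(cc2[4, ], cc0[4, ], tolerance = 1e-12)
  # naive rank-then-Pearson oracle
  oracle <- cor(apply(t(m), 2, rank))
  expect_equal(unname(cc0), unname(oracle), tolerance = 1e-12)
  # all-constant sample flagged undefined
  m[5, ] <- 7
  expect_warning(cc3 <- sample_correlation(m), "all-constant")
  expect_true(all(is.na(cc3[5, -5])))
})

test_that("within-cell-type correlations exceed between-type correlations", {
  set.seed(18)
  gm <- random_genes(15)
  layout <- test_layout()
  # two cell types: each type's samples are noisy copies of a type profile
  type_profile <- function() random_peaks(400, layout)
  noisy <- function(p) {
    keep <- runif(nrow(p)) > 0.15
    jit <- round(rnorm(sum(keep), 0, 150))
    peak_set(p$chrom[keep], pmax(p$start[keep] + jit, 0),
             p$end[keep] + jit, layout = layout)
  }
  tA <- type_profile(); tB <- type_profile()
  sets <- list(A1 = noisy(tA), A2 = noisy(tA), A3 = noisy(tA),
               B1 = noisy(tB), B2 = noisy(tB), B3 = noisy(tB))
  feats <- peak_gene_coverage(sets, gm)
  cc <- sample_correlation(feats)
  within <- c(cc["A1", "A2"], cc["A1", "A3"], cc["A2", "A3"],
              cc["B1", "B2"], cc["B1", "B3"], cc["B2", "B3"])
  between <- as.vector(cc[1:3, 4:6])
  expect_gt(mean(within), mean(between))
})
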
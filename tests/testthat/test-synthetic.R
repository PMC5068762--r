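# smaller-than-default study so unit tests stay fast; planted structure is
# unchanged
small_config <- function(seed, ...) {
  synthetic_config(seed, n_peaks = 4000L, n_peaks_other = 3000L,
                   n_genes = 400L, n_shared = 200L,
                   net_nodes = 400L, net_hubs = 20L, ...)
}

test_that("config validation rejects impossible plants", {
  expect_error(synthetic_config(1, enrichment_rho = 5,
                                specific_fraction_all = 0.27),
               "infeasible")
  expect_error(synthetic_config(1, tss_proximity_broad = 1.2), "0, 1")
  expect_error(synthetic_config(1, nonsense = 3), "unknown config field")
})

test_that("the universe is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  u1 <- generate_universe(small_config(5), d1)
  u2 <- generate_universe(small_config(5), d2)
  for (f in c("cohort1", "cohort2", "NeuN-", "blood", "chrom_sizes",
              "genes", "broad_specific1", "broad_specific2")) {
    expect_identical(readLines(u1$paths[[f]]), readLines(u2$paths[[f]]),
                     info = f)
  }
  u3 <- generate_universe(small_config(6), withr::local_tempdir())
  expect_false(identical(readLines(u3$paths$cohort1),
                         readLines(u1$paths$cohort1)))
})

test_that("generator outputs pass the package readers without warnings", {
  d <- withr::local_tempdir()
  u <- generate_universe(small_config(2), d)
  expect_no_warning({
    layout <- read_chrom_sizes(u$paths$chrom_sizes)
    genes <- read_gene_models(u$paths$genes)
    c1 <- read_bed(u$paths$cohort1)
    nn <- read_bed(u$paths[["NeuN-"]])
  })
  expect_equal(nrow(c1), 4000L)
  expect_equal(c1$start, u$cohort1$start)
  expect_equal(sum(unclass(layout)), 5e7)
})

test_that("planted cohort sharing is recovered exactly from the truth sets", {
  d <- withr::local_tempdir()
  u <- generate_universe(small_config(3), d)
  bs1 <- read_bed(u$paths$broad_specific1)
  bs2 <- read_bed(u$paths$broad_specific2)
  rep <- suppressMessages(cohort_reproducibility(bs1, bs2))
  expect_equal(rep$count, u$truth$k_shared)
})

test_that("a null specificity plant (rho = 1) yields fold near 1", {
  d <- withr::local_tempdir()
  u <- generate_universe(small_config(1, enrichment_rho = 1), d)
  sel <- select_broadest(u$cohort1, 0.05)
  spec <- call_cell_type_specific(u$cohort1, u$others)
  keys <- paste(spec$chrom, spec$start, spec$end)
  a <- sum(paste(sel$peaks$chrom, sel$peaks$start, sel$peaks$end) %in% keys)
  enr <- specificity_enrichment(a, nrow(sel$peaks), nrow(spec),
                                nrow(u$cohort1))
  expect_lt(abs(enr$fold - 1), 0.25)   # n = 4000; the n = 20000 recovery
                                       # bands are checked in acceptance
})

test_that("species sets realize the planted conservation geometry", {
  d <- withr::local_tempdir()
  cfg <- small_config(4)
  u <- generate_universe(cfg, d)

  # planted conserved fraction with full dropout: exactly the shared core
  sp <- generate_species_sets(small_config(4, species_dropout = 1), u, d)
  shared <- shared_across(unname(sp$sets))
  cons <- conservation_summary(shared, u$cohort1[u$flags1$broad, ])
  expect_lt(abs(cons$percent_matched - 24), 4)

  # no dropout and conserved_fraction 1: every shared peak matches
  sp0 <- generate_species_sets(
    small_config(4, species_dropout = 0, conserved_fraction = 1), u, d)
  shared0 <- shared_across(unname(sp0$sets))
  cons0 <- conservation_summary(shared0, u$cohort1[u$flags1$broad, ])
  expect_equal(cons0$percent_matched, 100)

  # full dropout with nothing shared: empty sets, clean error downstream
  spE <- generate_species_sets(
    small_config(4, species_dropout = 1, n_shared = 0L), u, d)
  expect_true(all(vapply(spE$sets, nrow, integer(1)) == 0L))
  expect_error(conservation_summary(shared_across(unname(spE$sets)),
                                    u$cohort1), "empty")
})

test_that("network generator plants recoverable hubs and respects m = 1", {
  d <- withr::local_tempdir()
  cfg <- small_config(21, net_nodes = 2000L, net_hubs = 40L, net_m = 1L)
  hubs_pool <- sprintf("G%04d", 1:100)
  net1 <- generate_network(cfg, hubs_pool, out_dir = d)
  expect_equal(igraph::ecount(net1$net), 1999L)   # m = 1 forces a tree
  expect_true(igraph::is_connected(net1$net))
  net2 <- generate_network(cfg, hubs_pool, out_dir = withr::local_tempdir())
  expect_identical(readLines(net1$paths$edges), readLines(net2$paths$edges))

  cfg2 <- small_config(21, net_nodes = 2000L, net_hubs = 40L, net_m = 2L)
  net <- generate_network(cfg2, hubs_pool, out_dir = d)
  ns <- node_stats(largest_component(net$net))
  cmp <- compare_groups(ns, net$hubs, "degree")
  expect_gt(cmp$ratio, 2)
  expect_lt(cmp$p_value, 0.01)
})

test_that("expression generator: non-negative, powered, and calibrated", {
  d <- withr::local_tempdir()
  genes <- sprintf("G%04d", 1:475)
  cfg <- small_config(9)
  ex <- generate_expression(cfg, genes[1:300], genes, d)
  expect_true(all(ex$expr$values >= 0))
  res <- paired_compartment_test(ex$expr, genes[1:300])
  expect_lt(res$p_value, 1e-4)

  # with no planted effect the test is calibrated across generator seeds
  ps <- vapply(1:500, function(s) {
    cfg0 <- synthetic_config(1000 + s, effect_log2 = 0, n_pairs = 6L)
    ex0 <- generate_expression(cfg0, sprintf("g%02d", 1:10),
                               sprintf("g%02d", 1:50),
                               withr::local_tempdir())
    paired_compartment_test(ex0$expr, sprintf("g%02d", 1:50))$p_value
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})
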
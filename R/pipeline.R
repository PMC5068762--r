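# Coordinate key used to match peaks across subsets of one universe.
.peak_key <- function(peaks) paste(peaks$chrom, peaks$start, peaks$end)

#' Run the full analysis chain on a synthetic study
#'
#' Generates the synthetic universe (unless `sim_dir` already holds one
#' from the same config), reads every input back through the package's
#' file readers, and chains all stages: breadth selection per cohort,
#' cell-type-specificity calling and enrichment, cross-cohort
#' reproducibility with a shuffle permutation test, TSS-window annotation,
#' cross-species conservation, network-topology group comparison, and the
#' paired gray/white expression test.  Planted-truth recoveries are
#' reported next to the planted values.
#'
#' @param out_dir output directory; simulation inputs go to
#'   `out_dir/sim`, results to `out_dir/results.json`.
#' @param seed master seed (flows to every stage).
#' @param config optional [synthetic_config()]; default uses `seed` with
#'   the default planted parameters.
#' @param n_perm shuffles for the reproducibility permutation test.
#' @return list of per-stage results (also written as JSON).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL, n_perm = 200L) {
  if (is.null(config)) config <- synthetic_config(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "sim")
  sim <- simulate_all(config, sim_dir)
  uni <- sim$universe

  # read every input back from disk through the io layer
  layout <- read_chrom_sizes(uni$paths$chrom_sizes)
  genes <- read_gene_models(uni$paths$genes)
  cohort1 <- read_bed(uni$paths$cohort1, cell_type = "NeuN+", cohort = "cohort1")
  cohort2 <- read_bed(uni$paths$cohort2, cell_type = "NeuN+", cohort = "cohort2")
  others <- lapply(config$other_cell_types, function(ct)
    read_bed(uni$paths[[ct]], cell_type = ct))
  net <- read_edge_list(sim$network$paths$edges)
  meta <- read.delim(sim$expression$paths$meta, stringsAsFactors = FALSE)
  expr <- read_expression(sim$expression$paths$fpkm, meta)
  species <- lapply(sim$species$paths[config$species], read_bed)

  analyze_cohort <- function(target, cohort_name) {
    all_sum <- summarize_breadth(target)
    sel <- select_broadest(target, config$fraction)
    spec <- call_cell_type_specific(target, others)
    spec_keys <- .peak_key(spec)
    broad_spec <- sel$peaks[.peak_key(sel$peaks) %in% spec_keys, ,
                            drop = FALSE]
    enr <- specificity_enrichment(nrow(broad_spec), nrow(sel$peaks),
                                  nrow(spec), nrow(target))
    list(name = cohort_name, all_summary = all_sum, broadest = sel,
         specific = spec, broad_specific = broad_spec, enrichment = enr,
         breadth_ratio = breadth_ratio(sel$summary, all_sum))
  }
  a1 <- analyze_cohort(cohort1, "cohort1")
  a2 <- analyze_cohort(cohort2, "cohort2")

  repro <- cohort_reproducibility(a1$broad_specific, a2$broad_specific)
  perm <- permutation_overlap_test(a1$broad_specific, a2$broad_specific,
                                   layout, n_perm = n_perm,
                                   seed = stage_seed(config$seed, "shuffle"))

  both_broadest <- peak_set(
    c(a1$broadest$peaks$chrom, a2$broadest$peaks$chrom),
    c(a1$broadest$peaks$start, a2$broadest$peaks$start),
    c(a1$broadest$peaks$end, a2$broadest$peaks$end),
    cell_type = "NeuN+", provenance = "broadest, both cohorts")
  tss_frac <- tss_window_fraction(both_broadest, genes,
                                  windows = c(1000, 2000, 3000, 4000))
  anno <- classify_peaks(repro$peaks, genes, promoter_window = 4000)
  assoc_genes <- sort(unique(anno$gene_id[!is.na(anno$tss_distance) &
                                            abs(anno$tss_distance) <= 4000]))

  shared <- shared_across(unname(species))
  cons <- if (nrow(shared)) {
    conservation_summary(shared, a1$broadest$peaks)
  } else NULL

  comp <- largest_component(net)
  ns <- node_stats(comp)
  group <- intersect(assoc_genes, ns$node)
  net_cmp <- if (length(group) && length(group) < nrow(ns)) {
    lapply(setNames(nm = c("degree", "stress", "betweenness",
                           "eccentricity", "avg_shortest_path")),
           function(m) compare_groups(ns, group, m))
  } else NULL

  expr_genes <- intersect(assoc_genes, rownames(expr$values))
  expr_test <- paired_compartment_test(expr, expr_genes)

  results <- list(
    seed = seed,
    cohort1 = list(
      n_peaks = nrow(cohort1), n_broadest = nrow(a1$broadest$peaks),
      mean_length_all = a1$all_summary$mean_length,
      mean_length_broadest = a1$broadest$summary$mean_length,
      breadth_ratio = a1$breadth_ratio,
      threshold = a1$broadest$summary$percentile_threshold,
      n_specific = nrow(a1$specific),
      n_broad_specific = nrow(a1$broad_specific),
      enrichment_fold = a1$enrichment$fold,
      enrichment_p = a1$enrichment$p_value),
    cohort2 = list(
      n_peaks = nrow(cohort2), n_broadest = nrow(a2$broadest$peaks),
      breadth_ratio = a2$breadth_ratio,
      n_specific = nrow(a2$specific),
      n_broad_specific = nrow(a2$broad_specific),
      enrichment_fold = a2$enrichment$fold,
      enrichment_p = a2$enrichment$p_value),
    reproducibility = list(count = repro$count,
                           planted_k = uni$truth$k_shared,
                           permutation_p = perm$p_empirical,
                           permutation_fold = perm$fold),
    annotation = list(tss_window_fraction = as.list(tss_frac),
                      planted_proximity = config$tss_proximity_broad,
                      n_associated_genes = length(assoc_genes)),
    conservation = if (!is.null(cons)) list(
      n_shared_nonhuman = cons$n_shared_nonhuman,
      n_matched_human = cons$n_matched_human,
      percent_matched = cons$percent_matched,
      planted_percent = 100 * config$conserved_fraction) else NULL,
    network = if (!is.null(net_cmp)) list(
      n_component = nrow(ns), n_group = length(group),
      degree_ratio = net_cmp$degree$ratio,
      degree_p = net_cmp$degree$p_value,
      median_stress_group = net_cmp$stress$median_group,
      stress_ratio = net_cmp$stress$ratio,
      betweenness_ratio = net_cmp$betweenness$ratio,
      avg_path_group = net_cmp$avg_shortest_path$median_group,
      avg_path_rest = net_cmp$avg_shortest_path$median_rest) else NULL,
    expression = list(n_genes = expr_test$n_genes,
                      n_pairs = expr_test$n_pairs,
                      p_value = expr_test$p_value,
                      median_log_ratio = expr_test$median_log_ratio)
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
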
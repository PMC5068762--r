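#' Paired gray/white compartment expression test
#'
#' For each gene in `genes`, averages FPKM across subjects separately for
#' the gray and white compartments, then applies a two-sided Wilcoxon
#' matched-pairs signed-rank test over genes of gray vs white means.  Zero
#' differences are dropped (the standard signed-rank convention); the
#' exact null distribution is used for up to 25 non-zero differences
#' without ties, a normal approximation with continuity and tie correction
#' above.  The median log2 gray/white ratio uses a 0.1 FPKM pseudocount.
#'
#' @param expr an [expression_matrix()] with at least 6 subject pairs.
#' @param genes character vector of gene ids (subset of the matrix genes).
#' @return list with `statistic` (signed-rank V), `p_value`, `n_genes`,
#'   `n_pairs` (subject pairs), `median_log_ratio`.
#' @export
paired_compartment_test <- function(expr, genes = rownames(expr$values)) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing_genes <- setdiff(genes, rownames(expr$values))
  if (length(missing_genes)) {
    stop("gene not in expression matrix: ", missing_genes[1L])
  }
  meta <- expr$meta
  paired_subjects <- intersect(meta$subject[meta$compartment == "gray"],
                               meta$subject[meta$compartment == "white"])
  if (length(paired_subjects) < 6L) {
    stop("need at least 6 subjects with both gray and white samples, got ",
         length(paired_subjects))
  }
  keep <- meta$subject %in% paired_subjects
  gray_cols <- meta$sample[keep & meta$compartment == "gray"]
  white_cols <- meta$sample[keep & meta$compartment == "white"]
  v <- expr$values[genes, , drop = FALSE]
  gray <- rowMeans(v[, gray_cols, drop = FALSE])
  white <- rowMeans(v[, white_cols, drop = FALSE])
  diffs <- gray - white
  nz <- sum(diffs != 0)
  if (nz < 2L) {
    stop("no signal: fewer than 2 genes with a non-zero gray/white difference")
  }
  use_exact <- nz <= 25L && !any(duplicated(abs(diffs[diffs != 0])))
  wt <- suppressWarnings(wilcox.test(gray, white, paired = TRUE,
                                     alternative = "two.sided",
                                     exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       n_genes = length(genes),
       n_pairs = length(paired_subjects),
       median_log_ratio = median(log2((gray + 0.1) / (white + 0.1))))
}

#' Pairwise Spearman correlation between samples
#'
#' Rank correlation (average ranks on ties) for every pair of rows of a
#' samples x features matrix — the standard ChIP-seq/RNA-seq sample QC in
#' which replicates of one cell type correlate more strongly with each
#' other than with other cell types.  A sample with a constant feature
#' vector has undefined correlations (`NA`), with a warning.
#'
#' @param m samples x features numeric matrix (>= 2 samples, >= 3
#'   features), non-negative.
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (ncol(m) < 3L) stop("need at least 3 features")
  constant <- apply(m, 1L, function(r) length(unique(r)) == 1L)
  if (any(constant)) {
    warning("all-constant sample(s): ",
            paste(rownames(m)[constant], collapse = ", "),
            "; correlations undefined (NA)")
  }
  cc <- suppressWarnings(cor(t(m), method = "spearman"))
  diag(cc) <- 1
  cc
}

#' Per-gene peak coverage features for correlation QC
#'
#' Builds a samples x genes feature matrix from peak sets: for each gene,
#' the total number of peak base pairs overlapping the gene span extended
#' by `flank` bp on both sides.  This provides an epigenomic-landscape
#' feature vector per sample for [sample_correlation()] without read-level
#' data.
#'
#' @param peak_sets named list of [peak_set()]s, one per sample.
#' @param models a [gene_models()] table.
#' @param flank extension of the gene span in bp (default 4000).
#' @return samples x genes numeric matrix of covered base pairs.
#' @export
peak_gene_coverage <- function(peak_sets, models, flank = 4000) {
  stopifnot(is.list(peak_sets), inherits(models, "gene_models"))
  lo <- pmin(models$tss, models$tes) - flank
  hi <- pmax(models$tss, models$tes) + flank
  lv <- unique(c(models$chrom,
                 unlist(lapply(peak_sets, function(p) unique(p$chrom)))))
  genes_gr <- GenomicRanges::GRanges(
    factor(models$chrom, levels = lv),
    IRanges::IRanges(start = pmax(lo, 0) + 1, end = hi))
  out <- matrix(0, nrow = length(peak_sets), ncol = nrow(models),
                dimnames = list(names(peak_sets), models$gene_id))
  for (i in seq_along(peak_sets)) {
    pg <- as_granges(peak_sets[[i]], lv)
    ov <- GenomicRanges::findOverlaps(genes_gr, pg)
    if (length(ov)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        genes_gr[S4Vectors::queryHits(ov)], pg[S4Vectors::subjectHits(ov)]))
      cov <- rowsum(w, S4Vectors::queryHits(ov))
      out[i, as.integer(rownames(cov))] <- cov[, 1L]
    }
  }
  out
}
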
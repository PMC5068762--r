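# Merge a peak set into disjoint sorted intervals per chromosome, for the
# fast overlap counter used inside the permutation loop.
reduce_reference <- function(reference) {
  out <- list()
  for (ch in unique(reference$chrom)) {
    p <- reference[reference$chrom == ch, , drop = FALSE]
    o <- order(p$start, p$end)
    s <- p$start[o]; e <- p$end[o]
    merged_s <- numeric(0); merged_e <- numeric(0)
    cs <- s[1L]; ce <- e[1L]
    if (length(s) > 1L) {
      for (i in 2L:length(s)) {
        if (s[i] <= ce) {            # touching counts as merged (half-open)
          ce <- max(ce, e[i])
        } else {
          merged_s <- c(merged_s, cs); merged_e <- c(merged_e, ce)
          cs <- s[i]; ce <- e[i]
        }
      }
    }
    out[[ch]] <- list(start = c(merged_s, cs), end = c(merged_e, ce))
  }
  out
}

# Vectorised: do intervals [start, end) overlap the merged reference on one
# chromosome by >= 1 bp?
hits_reduced <- function(start, end, ref) {
  if (is.null(ref)) return(rep(FALSE, length(start)))
  i <- findInterval(start, ref$start)
  n <- length(ref$start)
  left <- i >= 1L & ifelse(i >= 1L, ref$end[pmax(i, 1L)] > start, FALSE)
  right <- i < n & ref$start[pmin(i + 1L, n)] < end
  left | right
}

#' Length-preserving random shuffle of a peak set
#'
#' Re-places every peak uniformly at random within chromosome bounds,
#' preserving the multiset of peak lengths exactly.  With
#' `within_chromosome = TRUE` (the default) each peak stays on its own
#' chromosome, so per-chromosome counts are preserved too; otherwise the
#' destination chromosome is drawn with probability proportional to
#' chromosome length among chromosomes long enough to hold the peak.
#' Shuffled peaks may overlap each other: no collision rejection is
#' applied, keeping the null exactly uniform.
#'
#' @param peaks a [peak_set()].
#' @param genome a [genome_layout()] covering every peak's chromosome.
#' @param seed optional integer; when given, the shuffle is reproducible.
#' @param within_chromosome keep each peak on its own chromosome.
#' @return a shuffled [peak_set()].
#' @export
shuffle_intervals <- function(peaks, genome, seed = NULL,
                              within_chromosome = TRUE) {
  stopifnot(inherits(genome, "genome_layout"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(peaks) == 0L) return(peaks)
  L <- unclass(genome)
  missing_chr <- setdiff(peaks$chrom, names(L))
  if (length(missing_chr)) stop("chromosome not in layout: ", missing_chr[1L])
  len <- peak_length(peaks)
  if (within_chromosome) {
    chrom <- peaks$chrom
    cap <- L[chrom]
    if (any(len > cap)) {
      stop("peak longer than its chromosome at record ", which(len > cap)[1L])
    }
  } else {
    fits <- outer(len, L, FUN = "<=")      # n x n_chrom feasibility
    if (any(rowSums(fits) == 0L)) {
      stop("a peak is longer than every chromosome")
    }
    chrom <- character(length(len))
    for (i in seq_along(len)) {
      ok <- names(L)[fits[i, ]]
      w <- L[ok]
      chrom[i] <- sample(ok, 1L, prob = w / sum(w))
    }
    cap <- L[chrom]
  }
  new_start <- floor(runif(length(len)) * (cap - len + 1))
  peak_set(chrom, new_start, new_start + len, name = peaks$name,
           score = peaks$score, strand = peaks$strand,
           cell_type = peaks$cell_type, cohort = peaks$cohort,
           provenance = paste0(attr(peaks, "provenance"), " [shuffled]"))
}

#' Permutation test of interval-set association
#'
#' Compares the observed number of query peaks overlapping a reference set
#' against a null distribution obtained by repeatedly shuffling the query
#' peaks uniformly within chromosome bounds (lengths and per-chromosome
#' counts preserved).  The empirical p-value uses the add-one estimator
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`, so it is never zero, and
#' the fold is `observed / mean(perm counts)`.
#'
#' @param query nonempty [peak_set()] whose placement is randomized.
#' @param reference fixed [peak_set()] of annotation intervals.
#' @param genome a [genome_layout()].
#' @param n_perm number of shuffles (>= 100).
#' @param seed optional integer for reproducibility.
#' @param min_bp minimum overlap in bp (the fast permutation path requires
#'   the default 1; larger values fall back to per-shuffle counting).
#' @return list of class `permutation_result` with `observed`,
#'   `expected_mean`, `expected_sd`, `fold`, `p_empirical`, `n_perm`,
#'   `seed`, and the vector `perm_counts`.
#' @export
permutation_overlap_test <- function(query, reference, genome,
                                     n_perm = 1000, seed = NULL,
                                     min_bp = 1) {
  stopifnot(inherits(genome, "genome_layout"))
  if (nrow(query) == 0L) stop("empty query peak set")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  observed <- intersect_count(query, reference, min_bp = min_bp)
  L <- unclass(genome)
  missing_chr <- setdiff(query$chrom, names(L))
  if (length(missing_chr)) stop("chromosome not in layout: ", missing_chr[1L])

  if (min_bp == 1) {
    ref <- reduce_reference(reference)
    counts <- numeric(n_perm)
    for (ch in unique(query$chrom)) {
      len <- peak_length(query[query$chrom == ch, , drop = FALSE])
      if (any(len > L[[ch]])) stop("peak longer than its chromosome")
      ns <- length(len)
      starts <- floor(runif(n_perm * ns) * rep(L[[ch]] - len + 1, n_perm))
      lens <- rep(len, n_perm)
      hit <- hits_reduced(starts, starts + lens, ref[[ch]])
      counts <- counts + rowsum(as.numeric(hit),
                                rep(seq_len(n_perm), each = ns))[, 1L]
    }
    perm_counts <- as.integer(counts)
  } else {
    perm_counts <- vapply(seq_len(n_perm), function(i) {
      sh <- shuffle_intervals(query, genome, within_chromosome = TRUE)
      intersect_count(sh, reference, min_bp = min_bp)
    }, integer(1))
  }
  expected_mean <- mean(perm_counts)
  fold <- if (expected_mean > 0) observed / expected_mean else {
    if (observed > 0) Inf else NaN
  }
  structure(list(
    observed = observed,
    expected_mean = expected_mean,
    expected_sd = stats::sd(perm_counts),
    fold = fold,
    p_empirical = (1 + sum(perm_counts >= observed)) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed,
    perm_counts = perm_counts
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed = ", x$observed,
      ", expected = ", round(x$expected_mean, 2),
      " +/- ", round(x$expected_sd, 2),
      ", fold = ", signif(x$fold, 4),
      ", empirical p = ", format(x$p_empirical, digits = 3),
      " (", x$n_perm, " shuffles)\n", sep = "")
  invisible(x)
}
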
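#' Configuration for the synthetic-data generator
#'
#' Bundles every planted parameter of the synthetic universe.  Defaults
#' emulate the magnitudes seen in sorted-neuron H3K4me3 data: a ~1.5 kb
#' mean peak length with a heavy broad tail (top-5% mean ~5 kb, capped at
#' 12.5 kb), ~85% of the broadest peaks within 4 kb of a TSS, a 2-fold
#' specificity enrichment among the broadest peaks, ~70% cross-cohort
#' sharing of broad specific peaks, a 24% conserved fraction among
#' non-human shared broadest peaks, a scale-free-like gene network whose
#' earliest (hub) nodes carry broad-peak genes, and a 1 log2-unit
#' gray-over-white expression effect for broad-peak genes in 6 subject
#' pairs.
#'
#' @param seed master integer seed; every stage derives its own
#'   sub-stream from it.
#' @param ... overrides for any default field (see Details in the package
#'   vignette).  Unknown fields are an error.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome & genes
    n_chrom = 5L, chrom_length = 1e7, n_genes = 1200L,
    tss_spacing = 20000, edge_margin = 60000,
    # peaks
    n_peaks = 20000L, n_peaks_other = 12000L,
    other_cell_types = c("NeuN-", "blood"),
    length_meanlog = log(1100), length_sdlog = 0.5,
    broad_weight = 0.06, broad_meanlog = log(5200), broad_sdlog = 0.3,
    min_length = 250, max_length = 12500,
    fraction = 0.05,
    # specificity
    specific_fraction_all = 0.27, enrichment_rho = 2.0,
    tss_proximity_broad = 0.85, tss_proximity_base = 0.75,
    proximal_offset = 3600, uniform_tss_zone = 18000,
    cohort_shared_fraction = 0.70, jitter = 100, mask_margin = 300,
    # species / pseudo-liftover
    species = c("chimp", "macaque", "mouse"),
    n_shared = 500L, conserved_fraction = 0.24,
    species_dropout = 0.8, species_offset_max = 300,
    # network
    net_nodes = 2000L, net_m = 2L, net_hubs = 50L,
    # expression
    n_pairs = 6L, effect_log2 = 1.0, noise_sd = 0.5,
    baseline_log2_mean = 4, baseline_log2_sd = 1, subject_sd = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1L])
  cfg[names(dots)] <- dots
  props <- c("broad_weight", "fraction", "specific_fraction_all",
             "tss_proximity_broad", "tss_proximity_base",
             "conserved_fraction", "species_dropout")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$enrichment_rho < 0) stop("enrichment_rho must be >= 0")
  if (cfg$enrichment_rho * cfg$specific_fraction_all > 1) {
    stop("infeasible config: enrichment_rho * specific_fraction_all > 1")
  }
  structure(cfg, class = "synthetic_config")
}

# ---- internal placement helpers ------------------------------------------

# plant a proportion as an exact count: round(n * p) randomly chosen TRUEs,
# so recoveries measure placement fidelity rather than Bernoulli noise
.exact_flags <- function(n, p) {
  f <- rep(FALSE, n)
  k <- min(round(n * p), n)
  if (k > 0) f[sample.int(n, k)] <- TRUE
  f
}

.draw_lengths <- function(n, cfg) {
  broad <- runif(n) < cfg$broad_weight
  len <- numeric(n)
  len[!broad] <- rlnorm(sum(!broad), cfg$length_meanlog, cfg$length_sdlog)
  len[broad] <- rlnorm(sum(broad), cfg$broad_meanlog, cfg$broad_sdlog)
  # truncate the tails by redraw so the support is [min_length, max_length]
  for (it in 1:100) {
    bad <- len > cfg$max_length
    if (!any(bad)) break
    len[bad & !broad] <- rlnorm(sum(bad & !broad), cfg$length_meanlog,
                                cfg$length_sdlog)
    len[bad & broad] <- rlnorm(sum(bad & broad), cfg$broad_meanlog,
                               cfg$broad_sdlog)
  }
  pmax(round(pmin(len, cfg$max_length)), cfg$min_length)
}

.tss_index <- function(genes) {
  lapply(split(genes$tss, genes$chrom), sort)
}

.min_tss_dist <- function(chrom, mid, tssidx) {
  out <- rep(Inf, length(mid))
  for (ch in unique(chrom)) {
    pos <- tssidx[[ch]]
    idx <- which(chrom == ch)
    if (is.null(pos) || !length(pos)) next
    i <- findInterval(mid[idx], pos)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(pos))
    out[idx] <- pmin(abs(mid[idx] - pos[lo]), abs(mid[idx] - pos[hi]))
  }
  out
}

# Uniform placement with rejection: midpoints at least `zone` bp from every
# TSS and (optionally) no overlap with `mask` intervals grown by `margin`.
.place_uniform <- function(lens, layout, tssidx, zone, mask = NULL,
                           margin = 0, max_iter = 3000L) {
  n <- length(lens)
  L <- unclass(layout)
  chrom <- character(n); start <- numeric(n)
  mask_idx <- if (!is.null(mask) && nrow(mask)) {
    reduce_reference(data.frame(chrom = mask$chrom,
                                start = pmax(mask$start - margin, 0),
                                end = mask$end + margin))
  } else NULL
  todo <- seq_len(n)
  for (it in seq_len(max_iter)) {
    if (!length(todo)) break
    cand_chrom <- names(L)[sample.int(length(L), length(todo), replace = TRUE,
                                      prob = L / sum(L))]
    cap <- L[cand_chrom] - lens[todo] + 1
    cand_start <- floor(runif(length(todo)) * cap)
    mid <- floor(cand_start + lens[todo] / 2)
    ok <- .min_tss_dist(cand_chrom, mid, tssidx) > zone
    if (!is.null(mask_idx)) {
      hit <- rep(FALSE, length(todo))
      for (ch in unique(cand_chrom)) {
        ii <- which(cand_chrom == ch)
        hit[ii] <- hits_reduced(cand_start[ii], cand_start[ii] + lens[todo][ii],
                                mask_idx[[ch]])
      }
      ok <- ok & !hit
    }
    chrom[todo[ok]] <- cand_chrom[ok]
    start[todo[ok]] <- cand_start[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) stop("uniform placement failed to converge; genome too crowded")
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

# Sequential placement of mutually non-overlapping uniform intervals
# (used for broad specific peaks so planted cohort sharing stays exact).
.place_uniform_exclusive <- function(lens, layout, tssidx, zone, mask_df,
                                     margin, max_iter = 10000L) {
  L <- unclass(layout)
  mchrom <- mask_df$chrom; mstart <- mask_df$start - margin
  mend <- mask_df$end + margin
  n <- length(lens)
  chrom <- character(n); start <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (it in seq_len(max_iter)) {
      ch <- names(L)[sample.int(length(L), 1L, prob = L / sum(L))]
      s <- floor(runif(1) * (L[[ch]] - lens[i] + 1))
      e <- s + lens[i]
      if (.min_tss_dist(ch, floor(s + lens[i] / 2), tssidx) <= zone) next
      sel <- mchrom == ch
      if (any(sel & (pmax(s, mstart) < pmin(e, mend)))) next
      chrom[i] <- ch; start[i] <- s
      mchrom <- c(mchrom, ch); mstart <- c(mstart, s - margin)
      mend <- c(mend, e + margin)
      placed <- TRUE
      break
    }
    if (!placed) stop("exclusive placement failed; genome too crowded")
  }
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

.place_at_tss <- function(genes, gene_ids, lens, offset_max) {
  gi <- match(gene_ids, genes$gene_id)
  offset <- round(runif(length(lens), -offset_max, offset_max))
  mid <- genes$tss[gi] + offset
  start <- mid - floor(lens / 2)
  data.frame(chrom = genes$chrom[gi], start = start, end = start + lens,
             gene_id = gene_ids, stringsAsFactors = FALSE)
}

.jitter_copy <- function(df, jitter, layout) {
  len <- df$end - df$start
  j <- round(runif(nrow(df), -1, 1) * pmin(jitter, floor((len - 1) / 2)))
  L <- unclass(layout)
  s <- pmin(pmax(df$start + j, 0), L[df$chrom] - len)
  data.frame(chrom = df$chrom, start = s, end = s + len,
             stringsAsFactors = FALSE)
}

# ---- universe -------------------------------------------------------------

.gen_genes <- function(cfg) {
  per_chrom <- rep(cfg$n_genes %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_genes %% cfg$n_chrom
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  rows <- list()
  gid <- 0L
  for (k in seq_len(cfg$n_chrom)) {
    nk <- per_chrom[k]
    span <- cfg$chrom_length - 2 * cfg$edge_margin
    free <- span - (nk - 1) * cfg$tss_spacing
    if (free <= 0) stop("too many genes for the TSS spacing")
    u <- sort(runif(nk, 0, free))
    tss <- round(cfg$edge_margin + u + cfg$tss_spacing * (seq_len(nk) - 1))
    strand <- sample(c("+", "-"), nk, replace = TRUE)
    glen <- round(runif(nk, 5000, 50000))
    tes <- ifelse(strand == "+", tss + glen, tss - glen)
    tes <- pmin(pmax(tes, 100), cfg$chrom_length - 100)
    for (i in seq_len(nk)) {
      gid <- gid + 1L
      lo <- min(tss[i], tes[i]); hi <- max(tss[i], tes[i])
      nex <- sample(3:8, 1L)
      cuts <- sort(sample(seq(lo, hi - 1), 2L * nex))
      rows[[gid]] <- list(gene_id = sprintf("G%04d", gid), chrom = chroms[k],
                          strand = strand[i], tss = tss[i], tes = tes[i],
                          exon_starts = cuts[seq(1L, 2L * nex, 2L)],
                          exon_ends = cuts[seq(2L, 2L * nex, 2L)])
    }
  }
  gene_models(
    vapply(rows, `[[`, "", "gene_id"),
    vapply(rows, `[[`, "", "chrom"),
    vapply(rows, `[[`, "", "strand"),
    vapply(rows, `[[`, 0, "tss"),
    vapply(rows, `[[`, 0, "tes"),
    lapply(rows, `[[`, "exon_starts"),
    lapply(rows, `[[`, "exon_ends")
  )
}

#' Generate the synthetic peak universe
#'
#' Builds a genome layout, gene models, and per-cell-type peak BED files
#' for two target-cell-type cohorts plus the other cell types, with
#' planted truth: a heavy-tailed length mixture; a configured fraction of
#' broad/other peaks placed with midpoints within 4 kb of a TSS (the rest
#' strictly farther away); cell-type-specific peaks planted so that the
#' specificity probability among broad peaks is `enrichment_rho` times
#' the overall specificity probability; and a configured fraction of broad
#' specific peaks shared (as overlapping copies) between the cohorts.
#' Non-specific target peaks receive an overlapping mirror peak in one
#' other cell type; other-cell-type background peaks avoid all planted
#' specific peaks.  Every planted quantity is recorded in a truth
#' manifest.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the layout, gene models, peak sets,
#'   planted truth and file paths; files are written under `out_dir`.
#' @export
generate_universe <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(cfg$seed, "universe"))

  layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                          rep(cfg$chrom_length, cfg$n_chrom))
  genes <- .gen_genes(cfg)
  tssidx <- .tss_index(genes)
  # size the TSS pools from the planted design: broad specific peaks (both
  # cohorts) need distinct specific-pool promoters, broad non-specific
  # peaks distinct shared-pool promoters
  n_broad_exp <- ceiling(cfg$fraction * cfg$n_peaks)
  p_broad_exp <- min(cfg$enrichment_rho * cfg$specific_fraction_all, 1)
  need_spec <- ceiling(cfg$tss_proximity_broad * p_broad_exp *
                         n_broad_exp * 1.3) + 30
  need_shared <- ceiling(cfg$tss_proximity_broad * (1 - p_broad_exp) *
                           n_broad_exp * 1.1) + 30
  if (need_spec + need_shared > nrow(genes)) {
    stop("n_genes too small for the planted design: need at least ",
         need_spec + need_shared)
  }
  specific_pool <- sort(sample(genes$gene_id, need_spec))
  shared_pool <- setdiff(genes$gene_id, specific_pool)

  draw_cohort_flags <- function() {
    len <- .draw_lengths(cfg$n_peaks, cfg)
    thr <- sort(len)[ceiling((1 - cfg$fraction) * cfg$n_peaks)]
    broad <- len > thr
    w <- mean(broad)
    p_broad <- cfg$enrichment_rho * cfg$specific_fraction_all
    p_base <- cfg$specific_fraction_all * (1 - cfg$enrichment_rho * w) /
      (1 - w)
    if (p_base < 0 || p_broad > 1) {
      stop("infeasible specificity plant for realized broad fraction ", w)
    }
    specific <- logical(cfg$n_peaks)
    proximal <- logical(cfg$n_peaks)
    specific[broad] <- .exact_flags(sum(broad), p_broad)
    specific[!broad] <- .exact_flags(sum(!broad), p_base)
    proximal[broad] <- .exact_flags(sum(broad), cfg$tss_proximity_broad)
    proximal[!broad] <- .exact_flags(sum(!broad), cfg$tss_proximity_base)
    list(len = len, broad = broad, specific = specific, proximal = proximal,
         threshold = thr, p_broad = p_broad, p_base = p_base)
  }

  c1 <- draw_cohort_flags()
  c2 <- draw_cohort_flags()

  blank_pos <- function(n) data.frame(chrom = rep(NA_character_, n),
                                      start = rep(NA_real_, n),
                                      end = rep(NA_real_, n),
                                      stringsAsFactors = FALSE)
  pos1 <- blank_pos(cfg$n_peaks); pos2 <- blank_pos(cfg$n_peaks)
  gene_of1 <- rep(NA_character_, cfg$n_peaks)
  gene_of2 <- rep(NA_character_, cfg$n_peaks)

  # --- cohort 1 specific placements ---------------------------------------
  i_bsp1 <- which(c1$broad & c1$specific & c1$proximal)
  if (length(i_bsp1) > length(specific_pool)) {
    stop("specific TSS pool too small for the broad specific peaks")
  }
  tss_bsp1 <- sample(specific_pool, length(i_bsp1))
  pl <- .place_at_tss(genes, tss_bsp1, c1$len[i_bsp1], cfg$proximal_offset)
  pos1[i_bsp1, ] <- pl[, 1:3]; gene_of1[i_bsp1] <- pl$gene_id

  i_xsp1 <- which(!c1$broad & c1$specific & c1$proximal)
  tss_xsp1 <- sample(specific_pool, length(i_xsp1), replace = TRUE)
  pl <- .place_at_tss(genes, tss_xsp1, c1$len[i_xsp1], cfg$proximal_offset)
  pos1[i_xsp1, ] <- pl[, 1:3]; gene_of1[i_xsp1] <- pl$gene_id

  i_bsu1 <- which(c1$broad & c1$specific & !c1$proximal)
  pl <- .place_uniform_exclusive(c1$len[i_bsu1], layout, tssidx,
                                 cfg$uniform_tss_zone,
                                 pos1[i_bsp1, , drop = FALSE],
                                 cfg$mask_margin)
  pos1[i_bsu1, ] <- pl

  i_xsu1 <- which(!c1$broad & c1$specific & !c1$proximal)
  pos1[i_xsu1, ] <- .place_uniform(c1$len[i_xsu1], layout, tssidx,
                                   cfg$uniform_tss_zone)

  # --- cohort 2 specific placements (shared copies + fresh) ---------------
  i_bs2 <- which(c2$broad & c2$specific)
  n_bs1 <- sum(c1$broad & c1$specific)
  k_shared <- round(cfg$cohort_shared_fraction * min(n_bs1, length(i_bs2)))
  src <- sample(which(c1$broad & c1$specific), k_shared)
  copy_slots <- sample(i_bs2, k_shared)
  cp <- .jitter_copy(pos1[src, , drop = FALSE], cfg$jitter, layout)
  pos2[copy_slots, ] <- cp
  c2$len[copy_slots] <- cp$end - cp$start
  gene_of2[copy_slots] <- gene_of1[src]
  # recompute cohort-2 broad threshold on the realized lengths
  c2$threshold <- sort(c2$len)[ceiling((1 - cfg$fraction) * cfg$n_peaks)]
  c2$broad <- c2$len > c2$threshold

  fresh2 <- setdiff(i_bs2, copy_slots)
  fresh2_prox <- fresh2[c2$proximal[fresh2]]
  pool2 <- setdiff(specific_pool, tss_bsp1)
  if (length(fresh2_prox) > length(pool2)) {
    stop("specific TSS pool too small for cohort-2 fresh broad peaks")
  }
  tss_bsp2 <- sample(pool2, length(fresh2_prox))
  pl <- .place_at_tss(genes, tss_bsp2, c2$len[fresh2_prox],
                      cfg$proximal_offset)
  pos2[fresh2_prox, ] <- pl[, 1:3]; gene_of2[fresh2_prox] <- pl$gene_id

  fresh2_uni <- fresh2[!c2$proximal[fresh2]]
  bs_mask <- rbind(pos1[c(i_bsp1, i_bsu1), c("chrom", "start", "end")],
                   pos2[c(copy_slots, fresh2_prox), c("chrom", "start", "end")])
  pl <- .place_uniform_exclusive(c2$len[fresh2_uni], layout, tssidx,
                                 cfg$uniform_tss_zone, bs_mask,
                                 cfg$mask_margin)
  pos2[fresh2_uni, ] <- pl

  # remaining (base-style) specific slots, placed after the threshold
  # recompute so borderline slots cannot fall through
  i_xsp2 <- which(c2$specific & c2$proximal & is.na(pos2$chrom))
  tss_xsp2 <- sample(specific_pool, length(i_xsp2), replace = TRUE)
  pl <- .place_at_tss(genes, tss_xsp2, c2$len[i_xsp2], cfg$proximal_offset)
  pos2[i_xsp2, ] <- pl[, 1:3]; gene_of2[i_xsp2] <- pl$gene_id

  i_xsu2 <- which(c2$specific & !c2$proximal & is.na(pos2$chrom))
  pos2[i_xsu2, ] <- .place_uniform(c2$len[i_xsu2], layout, tssidx,
                                   cfg$uniform_tss_zone)

  # --- non-specific placements (need the full specific mask first) --------
  spec_mask <- rbind(pos1[c1$specific, c("chrom", "start", "end")],
                     pos2[c2$specific & !is.na(pos2$chrom),
                          c("chrom", "start", "end")])

  place_nonspecific <- function(flags, pos, gene_of) {
    # broad peaks get distinct TSSs so broad peaks of one cohort never
    # stack (stacking would blur peak-level set arithmetic downstream);
    # the short base peaks may share promoters freely
    i_npb <- which(!flags$specific & flags$proximal & flags$broad)
    if (length(i_npb) > length(shared_pool)) {
      stop("shared TSS pool too small for the broad non-specific peaks")
    }
    tss_npb <- sample(shared_pool, length(i_npb))
    pl <- .place_at_tss(genes, tss_npb, flags$len[i_npb],
                        cfg$proximal_offset)
    pos[i_npb, ] <- pl[, 1:3]; gene_of[i_npb] <- pl$gene_id
    i_np <- which(!flags$specific & flags$proximal & !flags$broad)
    tss_np <- sample(shared_pool, length(i_np), replace = TRUE)
    pl <- .place_at_tss(genes, tss_np, flags$len[i_np], cfg$proximal_offset)
    pos[i_np, ] <- pl[, 1:3]; gene_of[i_np] <- pl$gene_id
    i_nu <- which(!flags$specific & !flags$proximal)
    pos[i_nu, ] <- .place_uniform(flags$len[i_nu], layout, tssidx,
                                  cfg$uniform_tss_zone, mask = spec_mask,
                                  margin = cfg$mask_margin)
    list(pos = pos, gene_of = gene_of)
  }
  r <- place_nonspecific(c1, pos1, gene_of1); pos1 <- r$pos; gene_of1 <- r$gene_of
  r <- place_nonspecific(c2, pos2, gene_of2); pos2 <- r$pos; gene_of2 <- r$gene_of

  # --- other cell types: mirrors + background -----------------------------
  others_rows <- setNames(vector("list", length(cfg$other_cell_types)),
                          cfg$other_cell_types)
  add_mirrors <- function(flags, pos) {
    i_ns <- which(!flags$specific)
    dest <- sample(cfg$other_cell_types, length(i_ns), replace = TRUE)
    for (ct in cfg$other_cell_types) {
      m <- .jitter_copy(pos[i_ns[dest == ct], , drop = FALSE], cfg$jitter,
                        layout)
      others_rows[[ct]] <<- rbind(others_rows[[ct]], m)
    }
  }
  add_mirrors(c1, pos1)
  add_mirrors(c2, pos2)

  for (ct in cfg$other_cell_types) {
    n_bg <- max(cfg$n_peaks_other - nrow(others_rows[[ct]]), 0L)
    if (n_bg > 0L) {
      lens <- .draw_lengths(n_bg, cfg)
      prox <- runif(n_bg) < cfg$tss_proximity_base
      bg <- blank_pos(n_bg)
      if (any(prox)) {
        tssg <- sample(shared_pool, sum(prox), replace = TRUE)
        bg[prox, ] <- .place_at_tss(genes, tssg, lens[prox],
                                    cfg$proximal_offset)[, 1:3]
      }
      if (any(!prox)) {
        bg[!prox, ] <- .place_uniform(lens[!prox], layout, tssidx, zone = 0,
                                      mask = spec_mask,
                                      margin = cfg$mask_margin)
      }
      others_rows[[ct]] <- rbind(others_rows[[ct]], bg)
    }
  }

  # --- assemble peak sets and write ---------------------------------------
  mk_target <- function(pos, cohort) {
    peak_set(pos$chrom, pos$start, pos$end,
             name = sprintf("%s_peak_%05d", cohort, seq_len(nrow(pos))),
             cell_type = "NeuN+", cohort = cohort,
             provenance = paste0("synthetic ", cohort), layout = layout)
  }
  cohort1 <- mk_target(pos1, "cohort1")
  cohort2 <- mk_target(pos2, "cohort2")
  others <- lapply(cfg$other_cell_types, function(ct) {
    df <- others_rows[[ct]]
    peak_set(df$chrom, df$start, df$end,
             name = sprintf("%s_peak_%05d", ct, seq_len(nrow(df))),
             cell_type = ct, provenance = paste0("synthetic ", ct),
             layout = layout)
  })
  names(others) <- cfg$other_cell_types

  planted_set <- function(pos, idx, cohort) {
    peak_set(pos$chrom[idx], pos$start[idx], pos$end[idx],
             cell_type = "NeuN+", cohort = cohort,
             provenance = paste0("planted broad specific ", cohort),
             layout = layout)
  }
  # cohort-2 planted broad-specific slots are fixed at plant time (copies +
  # fresh); the recomputed threshold may reclassify a borderline copy, but
  # the planted truth is the planted slots.
  bs2_idx <- sort(c(copy_slots, fresh2))
  bs1 <- planted_set(pos1, which(c1$broad & c1$specific), "cohort1")
  bs2 <- planted_set(pos2, bs2_idx, "cohort2")

  paths <- list(
    chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
    genes = file.path(out_dir, "genes.tsv"),
    cohort1 = file.path(out_dir, "cohort1_NeuN+.bed"),
    cohort2 = file.path(out_dir, "cohort2_NeuN+.bed"),
    broad_specific1 = file.path(out_dir, "planted_broad_specific_cohort1.bed"),
    broad_specific2 = file.path(out_dir, "planted_broad_specific_cohort2.bed"),
    manifest = file.path(out_dir, "truth_manifest.json")
  )
  for (ct in cfg$other_cell_types) {
    paths[[ct]] <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9+-]", "_", ct),
                                             ".bed"))
  }
  write_chrom_sizes(layout, paths$chrom_sizes)
  write_gene_models(genes, paths$genes)
  write_bed(cohort1, paths$cohort1)
  write_bed(cohort2, paths$cohort2)
  write_bed(bs1, paths$broad_specific1)
  write_bed(bs2, paths$broad_specific2)
  for (ct in cfg$other_cell_types) write_bed(others[[ct]], paths[[ct]])

  target_genes <- sort(unique(gene_of1[c1$broad & c1$specific &
                                         !is.na(gene_of1)]))
  shared_target_genes <- sort(unique(gene_of1[src][!is.na(gene_of1[src])]))

  truth <- list(
    seed = cfg$seed,
    enrichment_rho = cfg$enrichment_rho,
    specific_fraction_all = cfg$specific_fraction_all,
    p_broad = c1$p_broad, p_base = c1$p_base,
    tss_proximity_broad = cfg$tss_proximity_broad,
    n_peaks = cfg$n_peaks,
    cohort1 = list(n_broad = sum(c1$broad), n_specific = sum(c1$specific),
                   n_broad_specific = sum(c1$broad & c1$specific),
                   threshold = c1$threshold),
    cohort2 = list(n_broad = sum(c2$broad), n_specific = sum(c2$specific),
                   n_broad_specific = length(bs2_idx),
                   threshold = c2$threshold),
    k_shared = k_shared,
    target_genes = target_genes,
    shared_target_genes = shared_target_genes
  )
  manifest <- list(stage = "universe", config = unclass(cfg), truth = truth,
                   paths = lapply(paths, normalizePath, mustWork = FALSE))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # the peak_set constructor sorts by coordinates; realign the per-peak
  # planted flags (generation order) with the sorted sets via the peak
  # names, which carry the generation index
  realign <- function(flags, gene_of, set) {
    idx <- as.integer(sub(".*_peak_", "", set$name))
    stopifnot(!anyNA(idx), length(idx) == length(flags$len))
    list(len = flags$len[idx], broad = flags$broad[idx],
         specific = flags$specific[idx], proximal = flags$proximal[idx],
         threshold = flags$threshold, p_broad = flags$p_broad,
         p_base = flags$p_base, gene_of = gene_of[idx])
  }
  invisible(list(layout = layout, genes = genes,
                 cohort1 = cohort1, cohort2 = cohort2, others = others,
                 broad_specific1 = bs1, broad_specific2 = bs2,
                 flags1 = realign(c1, gene_of1, cohort1),
                 flags2 = realign(c2, gene_of2, cohort2),
                 truth = truth, paths = paths))
}

# ---- species --------------------------------------------------------------

#' Generate pseudo-lifted multi-species broadest-peak sets
#'
#' Emulates cross-species liftover into the human coordinate frame: a
#' planted conserved subset of the human broadest peaks plus a set of
#' novel non-human-only shared intervals are present in every species;
#' the remaining human broadest peaks are retained per species
#' independently with probability `1 - species_dropout` ("unmappable"
#' fraction).  Each species gets a per-chromosome affine offset and
#' per-peak jitter.  With the defaults the peaks shared by all species
#' match the human broadest set at ~`conserved_fraction`.
#'
#' @param config a [synthetic_config()].
#' @param universe result of [generate_universe()].
#' @param out_dir output directory.
#' @return (invisibly) list with per-species [peak_set()]s, the planted
#'   truth and the file paths.
#' @export
generate_species_sets <- function(config, universe, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(cfg$seed, "species"))
  layout <- universe$layout
  L <- unclass(layout)
  human_broad <- universe$cohort1[universe$flags1$broad, , drop = FALSE]

  n_conserved <- round(cfg$conserved_fraction * cfg$n_shared)
  n_conserved <- min(n_conserved, nrow(human_broad))
  idx_cons <- if (n_conserved > 0) sample(nrow(human_broad), n_conserved)
              else integer(0)
  conserved <- human_broad[idx_cons, c("chrom", "start", "end")]

  n_novel <- cfg$n_shared - n_conserved
  novel <- if (n_novel > 0) {
    lens <- pmax(round(pmin(rlnorm(n_novel, cfg$broad_meanlog,
                                   cfg$broad_sdlog), cfg$max_length)),
                 cfg$min_length)
    .place_uniform(lens, layout, .tss_index(universe$genes), zone = 0,
                   mask = human_broad, margin = cfg$mask_margin)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  shared_core <- rbind(conserved, novel)

  rest <- human_broad[setdiff(seq_len(nrow(human_broad)), idx_cons),
                      c("chrom", "start", "end")]
  sets <- list(); paths <- list()
  for (sp in cfg$species) {
    keep <- runif(nrow(rest)) < (1 - cfg$species_dropout)
    df <- rbind(shared_core, rest[keep, , drop = FALSE])
    if (nrow(df)) {
      offs <- setNames(round(runif(length(L), -cfg$species_offset_max,
                                   cfg$species_offset_max)), names(L))
      len <- df$end - df$start
      jit <- round(runif(nrow(df), -cfg$jitter, cfg$jitter))
      s <- df$start + offs[df$chrom] + jit
      s <- pmin(pmax(s, 0), L[df$chrom] - len)
      df <- data.frame(chrom = df$chrom, start = s, end = s + len,
                       stringsAsFactors = FALSE)
    }
    ps <- peak_set(df$chrom, df$start, df$end, cell_type = sp,
                   provenance = paste0("synthetic ", sp, " (human frame)"),
                   layout = layout)
    sets[[sp]] <- ps
    paths[[sp]] <- file.path(out_dir, paste0(sp, "_hg_frame.bed"))
    write_bed(ps, paths[[sp]])
  }
  truth <- list(n_shared = cfg$n_shared, n_conserved = n_conserved,
                conserved_fraction = cfg$conserved_fraction,
                species_dropout = cfg$species_dropout,
                n_human_broad = nrow(human_broad))
  paths$manifest <- file.path(out_dir, "species_manifest.json")
  jsonlite::write_json(list(stage = "species", truth = truth,
                            paths = lapply(paths, normalizePath,
                                           mustWork = FALSE)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(sets = sets, truth = truth, paths = paths))
}

# ---- network --------------------------------------------------------------

#' Generate a scale-free-like gene network with planted hub genes
#'
#' Grows a preferential-attachment graph (each new node attaches to
#' `net_m` existing nodes with probability proportional to degree + 1, so
#' the graph is connected by construction) and names its earliest —
#' hence highest-degree — `net_hubs` nodes with planted hub gene ids.
#'
#' @param config a [synthetic_config()].
#' @param hub_genes gene ids for the planted hub nodes (at least
#'   `net_hubs` of them; a random subset is used).
#' @param filler_genes optional gene ids for non-hub nodes; ids must be
#'   disjoint from `hub_genes`.  Remaining nodes get synthetic `N#####`
#'   ids.
#' @param out_dir output directory.
#' @return (invisibly) list with the [igraph::igraph] `net`, the planted
#'   `hubs` and the file paths.
#' @export
generate_network <- function(config, hub_genes, filler_genes = character(0),
                             out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (cfg$net_nodes < 10L) stop("need at least 10 nodes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(cfg$seed, "network"))
  n_hubs <- min(cfg$net_hubs, length(hub_genes))
  hubs <- sort(sample(hub_genes, n_hubs))
  filler_genes <- setdiff(filler_genes, hubs)
  n_rest <- cfg$net_nodes - n_hubs
  rest_ids <- c(filler_genes[seq_len(min(length(filler_genes), n_rest))],
                sprintf("N%05d", seq_len(max(n_rest - length(filler_genes),
                                             0L))))
  g <- igraph::sample_pa(cfg$net_nodes, power = 1, m = cfg$net_m,
                         zero.appeal = 1, directed = FALSE)
  igraph::V(g)$name <- c(hubs, rest_ids)
  paths <- list(edges = file.path(out_dir, "network_edges.tsv"),
                hubs = file.path(out_dir, "planted_hubs.txt"))
  write_edge_list(g, paths$edges)
  writeLines(hubs, paths$hubs)
  invisible(list(net = g, hubs = hubs, paths = paths))
}

# ---- expression -----------------------------------------------------------

#' Generate paired gray/white FPKM expression with a planted effect
#'
#' Log-normal baseline per gene, a shared subject random effect per pair,
#' Gaussian log2 noise, and `effect_log2` added to the target genes in
#' the gray compartment only — emulating neuron-enriched expression of
#' broad-peak genes in gray matter.
#'
#' @param config a [synthetic_config()].
#' @param target_genes genes carrying the planted gray-over-white effect.
#' @param all_genes full gene universe of the matrix (must contain
#'   `target_genes`).
#' @param out_dir output directory.
#' @return (invisibly) list with the [expression_matrix()] `expr`, the
#'   planted truth and the file paths.
#' @export
generate_expression <- function(config, target_genes, all_genes, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (!length(target_genes)) stop("target_genes must be nonempty")
  if (!all(target_genes %in% all_genes)) {
    stop("target_genes must be a subset of all_genes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(cfg$seed, "expression"))
  subjects <- sprintf("S%02d", seq_len(cfg$n_pairs))
  meta <- data.frame(
    sample = c(paste0(subjects, "_gray"), paste0(subjects, "_white")),
    subject = rep(subjects, 2L),
    compartment = rep(c("gray", "white"), each = cfg$n_pairs),
    stringsAsFactors = FALSE
  )
  ng <- length(all_genes)
  baseline <- rnorm(ng, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  subj_eff <- rnorm(cfg$n_pairs, 0, cfg$subject_sd)
  is_target <- all_genes %in% target_genes
  values <- matrix(0, nrow = ng, ncol = nrow(meta),
                   dimnames = list(all_genes, meta$sample))
  for (j in seq_len(nrow(meta))) {
    subj <- match(meta$subject[j], subjects)
    shift <- if (meta$compartment[j] == "gray") cfg$effect_log2 * is_target
             else 0
    values[, j] <- round(2 ^ (baseline + subj_eff[subj] + shift +
                                rnorm(ng, 0, cfg$noise_sd)), 4)
  }
  expr <- expression_matrix(values, meta)
  paths <- list(fpkm = file.path(out_dir, "expression_fpkm.tsv"),
                meta = file.path(out_dir, "expression_samples.tsv"))
  write_expression(expr, paths$fpkm, paths$meta)
  truth <- list(effect_log2 = cfg$effect_log2, n_pairs = cfg$n_pairs,
                n_target = length(target_genes))
  invisible(list(expr = expr, truth = truth, paths = paths,
                 target_genes = target_genes))
}

#' Generate the complete synthetic study
#'
#' Runs [generate_universe()], [generate_species_sets()],
#' [generate_network()] (hubs drawn from the cohort-shared broad-peak
#' genes) and [generate_expression()] (effect planted on all broad
#' specific peak genes), writing everything plus a combined truth
#' manifest under `out_dir`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory.
#' @return (invisibly) list with all stage results and `manifest` path.
#' @export
simulate_all <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uni <- generate_universe(config, out_dir)
  spe <- generate_species_sets(config, uni, out_dir)
  hub_pool <- uni$truth$shared_target_genes
  if (length(hub_pool) < config$net_hubs) hub_pool <- uni$truth$target_genes
  net <- generate_network(config, hub_pool,
                          filler_genes = setdiff(uni$genes$gene_id,
                                                 uni$truth$target_genes),
                          out_dir = out_dir)
  expr <- generate_expression(config, uni$truth$target_genes,
                              uni$genes$gene_id, out_dir)
  manifest_path <- file.path(out_dir, "truth_manifest_all.json")
  jsonlite::write_json(
    list(config = unclass(config),
         universe = uni$truth, species = spe$truth,
         network = list(hubs = net$hubs), expression = expr$truth),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(universe = uni, species = spe, network = net,
                 expression = expr, manifest = manifest_path))
}
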
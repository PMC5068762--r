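#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in BED convention
#' (0-based, half-open) with cell-type and cohort provenance.  Peaks are
#' sorted by (chrom, start, end) and exact duplicates are dropped.
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; `start < end` is required.
#' @param name optional peak names (default `"."`).
#' @param score optional numeric scores (default 0), e.g. peak height.
#' @param strand optional strand; peaks are unstranded and this is carried
#'   only for round-tripping BED6.
#' @param cell_type,cohort provenance labels attached to every peak.
#' @param provenance free-text label for the whole set.
#' @param layout optional [genome_layout()]; when given, `end` must not
#'   exceed the chromosome length.
#' @return A data frame of class `peak_set`.
#' @examples
#' peak_set("chr1", 100, 200, cell_type = "NeuN+")
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     strand = NULL, cell_type = NA_character_,
                     cohort = NA_character_, provenance = "",
                     layout = NULL) {
  n <- length(chrom)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != n || length(end) != n) stop("chrom/start/end lengths differ")
  if (n > 0L) {
    if (anyNA(chrom) || anyNA(start) || anyNA(end)) stop("NA in peak coordinates")
    if (any(start < 0)) stop("negative start coordinate")
    bad <- which(start >= end)
    if (length(bad)) {
      stop("invalid interval (start >= end) at record ", bad[1L], ": ",
           chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]])
    }
  }
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(0, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    cell_type = rep_len(as.character(cell_type), if (n) n else 0L),
    cohort = rep_len(as.character(cohort), if (n) n else 0L),
    stringsAsFactors = FALSE
  )
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "genome_layout"))
    missing_chr <- setdiff(df$chrom, names(layout))
    if (length(missing_chr)) stop("chromosome not in layout: ", missing_chr[1L])
    over <- df$end > unclass(layout)[df$chrom]
    if (any(over)) {
      stop("peak end exceeds chromosome length at record ", which(over)[1L])
    }
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end", "name", "score",
                           "strand", "cell_type", "cohort")])
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x), " peaks", sep = "")
  if (nrow(x)) {
    cat(" on ", length(unique(x$chrom)), " chromosome(s); mean length ",
        round(mean(peak_length(x))), " bp", sep = "")
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(" [", prov, "]", sep = "")
  cat("\n")
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}

# Subsetting keeps the class and provenance.
#' @export
`[.peak_set` <- function(x, i, ...) {
  prov <- attr(x, "provenance")
  out <- NextMethod()
  if (is.data.frame(out)) {
    rownames(out) <- NULL
    attr(out, "provenance") <- prov
    class(out) <- c("peak_set", "data.frame")
  }
  out
}

#' Peak length in base pairs
#'
#' Breadth of each peak, `end - start`; the quantity all breadth ranking is
#' based on.
#'
#' @param peaks a [peak_set()] (or any data frame with start/end columns).
#' @return numeric vector of lengths in bp.
#' @export
peak_length <- function(peaks) {
  peaks$end - peaks$start
}

#' Peak midpoint (floor of the interval centre)
#' @param peaks a [peak_set()].
#' @return numeric vector of midpoints.
#' @export
peak_midpoint <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}

# 1-based closed GRanges view of a 0-based half-open peak set.  `levels`
# lets two compared sets share one seqlevel universe, so overlap queries
# across sets with different chromosome complements stay silent.
as_granges <- function(peaks, levels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = levels),
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  )
}

#' Do two peaks overlap by at least `min_bp` bases?
#'
#' Half-open convention: abutting intervals (`end == start`) do not overlap.
#'
#' @param a,b single peaks: one-row [peak_set()]s or lists with
#'   `chrom`, `start`, `end`.
#' @param min_bp minimum overlap in bp (>= 1).
#' @return logical scalar.
#' @examples
#' a <- peak_set("chr1", 0, 100); b <- peak_set("chr1", 99, 200)
#' peaks_overlap(a, b)       # TRUE, 1 bp
#' @export
peaks_overlap <- function(a, b, min_bp = 1) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (a$chrom[1L] != b$chrom[1L]) return(FALSE)
  (min(a$end[1L], b$end[1L]) - max(a$start[1L], b$start[1L])) >= min_bp
}

#' Count query peaks overlapping a reference set
#'
#' Number of query peaks that overlap at least one reference peak by at
#' least `min_bp` bases; each query peak is counted at most once.  This is
#' the peak-level overlap statistic used for cohort reproducibility and for
#' the permutation association test.
#'
#' @param query,reference [peak_set()]s.
#' @param min_bp minimum per-pair overlap in bp.
#' @return integer count.
#' @export
intersect_count <- function(query, reference, min_bp = 1) {
  sum(overlaps_any(query, reference, min_bp = min_bp))
}

# Logical vector: which query peaks overlap >= 1 reference peak by >= min_bp.
overlaps_any <- function(query, reference, min_bp = 1) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(reference) == 0L) return(rep(FALSE, nrow(query)))
  lv <- union(unique(query$chrom), unique(reference$chrom))
  GenomicRanges::countOverlaps(as_granges(query, lv),
                               as_granges(reference, lv),
                               minoverlap = min_bp) > 0L
}

#' Signed distance from peak midpoints to the nearest anchor
#'
#' For each peak, the signed base-pair distance from the peak midpoint
#' (`floor((start + end)/2)`) to the nearest anchor position on the same
#' chromosome.  The sign follows the anchor's strand: negative when the
#' midpoint lies 5' of the anchor (upstream on a `+` strand anchor).  Peaks
#' on chromosomes without anchors get `NA` ("no anchor").  Ties in absolute
#' distance break toward the lexicographically smallest anchor id.
#'
#' @param peaks a [peak_set()].
#' @param anchors data frame with columns `chrom`, `pos`, `strand`
#'   (`+`/`-`) and `id`.
#' @return data frame with columns `distance` (signed bp) and `id` (nearest
#'   anchor id).
#' @export
nearest_distance <- function(peaks, anchors) {
  stopifnot(all(c("chrom", "pos", "strand", "id") %in% names(anchors)))
  n <- nrow(peaks)
  out <- data.frame(distance = rep(NA_real_, n), id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(anchors) == 0L) return(out)
  mid <- peak_midpoint(peaks)
  for (ch in unique(peaks$chrom)) {
    qi <- which(peaks$chrom == ch)
    ai <- which(anchors$chrom == ch)
    if (!length(ai)) next
    a <- anchors[ai, , drop = FALSE]
    # order by position, then id, so the findInterval tie-break is stable
    a <- a[order(a$pos, a$id), , drop = FALSE]
    pos <- a$pos
    lo <- findInterval(mid[qi], pos)          # rightmost pos <= mid
    hi <- pmin(lo + 1L, nrow(a))
    lo <- pmax(lo, 1L)
    dlo <- abs(mid[qi] - pos[lo])
    dhi <- abs(mid[qi] - pos[hi])
    pick <- ifelse(dhi < dlo, hi,
            ifelse(dlo < dhi, lo,
                   # equal absolute distance: smaller id wins
                   ifelse(a$id[lo] <= a$id[hi], lo, hi)))
    # among anchors at the exact same position, the id-sorted order already
    # puts the smallest id first; findInterval returns the last duplicate,
    # so walk back to the first anchor with that position.
    first_at <- match(pos[pick], pos)
    pick <- ifelse(abs(mid[qi] - pos[pick]) == abs(mid[qi] - pos[first_at]) &
                     a$id[first_at] < a$id[pick], first_at, pick)
    raw <- mid[qi] - pos[pick]
    out$distance[qi] <- ifelse(a$strand[pick] == "-", -raw, raw)
    out$id[qi] <- a$id[pick]
  }
  out
}
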
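#' Genome layout: ordered chromosome name -> length map
#'
#' A genome layout defines the coordinate frame for all interval operations,
#' in particular the support of the length-preserving shuffle null.
#'
#' @param chrom character vector of unique, non-empty chromosome names.
#' @param length positive integer lengths in base pairs, same order.
#' @return A named numeric vector of class `genome_layout`, in input order.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1000, 500))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("no chromosomes")
  if (anyNA(chrom) || any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ", chrom[duplicated(chrom)][1L])
  }
  if (anyNA(length) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(setNames(length, chrom), class = "genome_layout")
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#' Malformed lines are rejected with their line number; duplicate names and
#' non-positive lengths are validation errors.
#'
#' @param path path to a chrom.sizes file.
#' @return A [genome_layout()] in file order.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop("malformed chrom.sizes line ", bad, " in ", path,
         ": expected 2 fields, got ", nf[bad])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    stop("malformed chrom.sizes line ", which(is.na(len))[1L], " in ", path,
         ": length is not a number")
  }
  genome_layout(chrom, len)
}

#' Write a genome layout as a chrom.sizes file
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(paste(names(layout), format(unclass(layout), scientific = FALSE,
                                         trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosomes, ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
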
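#' Read a BED3/BED6 peak file
#'
#' Coordinates are taken as 0-based half-open (the BED standard).  Passing
#' `one_based = TRUE` interprets the file as browser-style 1-based
#' fully-closed coordinates and converts on input.  Malformed records are
#' rejected with their line number; inverted intervals are validation
#' errors, never silently repaired.
#'
#' @param path path to a BED file.
#' @param cell_type,cohort provenance labels attached to every peak.
#' @param one_based interpret input as 1-based fully-closed coordinates.
#' @param normalize_chr strip/ignore a leading `"chr"` mismatch is *not*
#'   attempted; when `TRUE`, names without the `"chr"` prefix get one.
#' @return A [peak_set()], sorted, with name/score/strand preserved when
#'   present.
#' @export
read_bed <- function(path, cell_type = NA_character_, cohort = NA_character_,
                     one_based = FALSE, normalize_chr = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(peak_set(character(0), numeric(0), numeric(0),
                    cell_type = cell_type, cohort = cohort,
                    provenance = basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop("BED parse error at line ", lineno[bad], " of ", path,
         ": fewer than 3 columns")
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else default, "")
  }
  chrom <- get(1L, "")
  start <- suppressWarnings(as.numeric(get(2L, "")))
  end <- suppressWarnings(as.numeric(get(3L, "")))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("BED parse error at line ", lineno[bad], " of ", path,
         ": non-numeric coordinate")
  }
  if (one_based) start <- start - 1
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED validation error at line ", lineno[bad[1L]], " of ", path,
         ": start >= end")
  }
  if (normalize_chr) {
    noch <- !startsWith(chrom, "chr")
    chrom[noch] <- paste0("chr", chrom[noch])
  }
  name <- get(4L, ".")
  score <- suppressWarnings(as.numeric(get(5L, "0")))
  score[is.na(score)] <- 0
  strand <- get(6L, ".")
  peak_set(chrom, start, end, name = name, score = score, strand = strand,
           cell_type = cell_type, cohort = cohort, provenance = basename(path))
}

#' Write a peak set as BED6
#'
#' Tab-separated, sorted, newline-terminated; missing names become `"."`
#' and missing scores 0.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(peaks)) {
    writeLines(paste(peaks$chrom,
                     format(peaks$start, scientific = FALSE, trim = TRUE),
                     format(peaks$end, scientific = FALSE, trim = TRUE),
                     peaks$name, format(peaks$score, trim = TRUE),
                     peaks$strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an undirected gene-network edge list
#'
#' TSV with two gene-id columns per line.  Self-loops are dropped with a
#' warning; duplicate and reversed duplicate edges are collapsed, yielding
#' a simple undirected graph.
#'
#' @param path path to the edge list.
#' @return an [igraph::igraph] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty edge list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("edge list parse error at line ", lineno[bad], " of ", path,
         ": expected 2 tab-separated gene ids")
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  blank <- !nzchar(a) | !nzchar(b)
  if (any(blank)) {
    stop("edge list parse error at line ", lineno[which(blank)[1L]], " of ",
         path, ": blank gene id")
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from ", basename(path))
  }
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!self], to = b[!self], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an igraph network as a two-column TSV edge list
#' @param net an igraph object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a gene x sample FPKM expression table
#'
#' First column gene id, remaining columns per-sample FPKM (non-negative).
#' Every sample column must appear in `metadata`, which pairs samples by
#' subject and assigns them to the gray or white compartment.
#'
#' @param path TSV with header; first column gene ids.
#' @param metadata data frame with columns `sample`, `subject`,
#'   `compartment` (values `"gray"`/`"white"`).
#' @return An object of class `expression_matrix`: list with `values`
#'   (genes x samples numeric matrix) and `meta` (one row per sample, in
#'   column order).
#' @export
read_expression <- function(path, metadata) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a gene column plus samples")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (anyNA(values)) stop("missing value in expression table")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative FPKM for gene ", genes[bad[1L]])
  }
  expression_matrix(values, metadata)
}

#' Construct an expression matrix with compartment-paired metadata
#'
#' @param values genes x samples non-negative numeric matrix with dimnames.
#' @param metadata data frame with columns `sample`, `subject`,
#'   `compartment`; every matrix column must have a metadata row, and each
#'   subject contributes at most one gray and one white sample.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("FPKM values must be non-negative")
  need <- c("sample", "subject", "compartment")
  if (!all(need %in% names(metadata))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(colnames(values), metadata$sample)
  if (length(missing_meta)) {
    stop("sample missing from metadata: ", missing_meta[1L])
  }
  meta <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  if (!all(meta$compartment %in% c("gray", "white"))) {
    stop("compartment must be 'gray' or 'white'")
  }
  if (anyDuplicated(meta[, c("subject", "compartment")])) {
    stop("a subject contributes more than one sample per compartment")
  }
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' Write an expression matrix (and optionally its metadata) as TSV
#' @param expr an `expression_matrix`.
#' @param path output TSV for the FPKM table.
#' @param meta_path optional output TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, meta_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$meta$compartment == "gray"), " gray, ",
      sum(x$meta$compartment == "white"), " white)\n", sep = "")
  invisible(x)
}

#' Read a reduced gene-model table (refFlat-style TSV)
#'
#' Seven columns: `gene_id`, `chrom`, `strand`, `tss`, `tes`,
#' `exon_starts`, `exon_ends` (comma-separated half-open block lists).
#' Exon blocks must be sorted, non-overlapping and contained in the gene
#' span.
#'
#' @param path TSV path (with header).
#' @return data frame of class `gene_models` with list columns
#'   `exon_starts`/`exon_ends`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(tab))) {
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  }
  parse_blocks <- function(s) {
    lapply(strsplit(as.character(s), ",", fixed = TRUE),
           function(v) as.numeric(v[nzchar(v)]))
  }
  gene_models(tab$gene_id, tab$chrom, tab$strand, tab$tss, tab$tes,
              parse_blocks(tab$exon_starts), parse_blocks(tab$exon_ends))
}

#' Construct a gene-model table
#' @param gene_id,chrom,strand,tss,tes per-gene fields; `strand` in `+`/`-`;
#'   `tss`/`tes` transcription start/end positions (bp).
#' @param exon_starts,exon_ends lists of numeric vectors of half-open exon
#'   blocks per gene.
#' @return data frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes,
                        exon_starts, exon_ends) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene id")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- as.numeric(tss); tes <- as.numeric(tes)
  for (i in seq_along(gene_id)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee)) stop("exon block mismatch for ", gene_id[i])
    if (length(es)) {
      if (any(es >= ee)) stop("empty exon block for ", gene_id[i])
      if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1L])) {
        stop("exon blocks must be sorted and non-overlapping for ", gene_id[i])
      }
      lo <- min(tss[i], tes[i]); hi <- max(tss[i], tes[i])
      if (min(es) < lo || max(ee) > hi) {
        stop("exon blocks outside gene span for ", gene_id[i])
      }
    }
  }
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   strand = as.character(strand), tss = tss, tes = tes,
                   stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write a gene-model table as TSV
#' @param models a `gene_models` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  join <- function(v) vapply(v, function(x)
    paste(format(x, scientific = FALSE, trim = TRUE), collapse = ","), "")
  tab <- data.frame(gene_id = models$gene_id, chrom = models$chrom,
                    strand = models$strand,
                    tss = format(models$tss, scientific = FALSE, trim = TRUE),
                    tes = format(models$tes, scientific = FALSE, trim = TRUE),
                    exon_starts = join(models$exon_starts),
                    exon_ends = join(models$exon_ends),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
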
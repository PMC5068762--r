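#' Peaks shared across every set
#'
#' Given two or more peak sets already mapped into one coordinate frame
#' (e.g. non-human peak sets lifted to the human assembly), returns the
#' peaks of the first set that are overlapped by at least one peak in
#' every other set.
#'
#' @param sets list of two or more [peak_set()]s in a shared frame.
#' @param min_bp minimum overlap in bp.
#' @return a [peak_set()]: the shared subset of `sets[[1]]`.
#' @export
shared_across <- function(sets, min_bp = 1) {
  if (!is.list(sets) || length(sets) < 2L) stop("need at least 2 peak sets")
  first <- sets[[1L]]
  if (nrow(first) == 0L) return(first)
  keep <- rep(TRUE, nrow(first))
  for (s in sets[-1L]) {
    keep <- keep & overlaps_any(first, s, min_bp = min_bp)
  }
  first[keep, , drop = FALSE]
}

#' Summarize cross-species conservation against the human broadest peaks
#'
#' Of the peaks shared by the non-human species, how many match (overlap)
#' the human broadest-peak set.  The published comparison found 131 of
#' 544 shared non-human broadest peaks (24%) matching the human top-5%
#' broadest neuronal peaks.
#'
#' @param shared_nonhuman nonempty [peak_set()] of peaks shared by all
#'   non-human species, in human coordinates.
#' @param human_broadest the human broadest-peak [peak_set()].
#' @param min_bp minimum overlap in bp.
#' @return list of class `conservation_summary` with
#'   `n_shared_nonhuman`, `n_matched_human`, `percent_matched`.
#' @export
conservation_summary <- function(shared_nonhuman, human_broadest,
                                 min_bp = 1) {
  if (nrow(shared_nonhuman) == 0L) stop("empty shared peak set")
  matched <- intersect_count(shared_nonhuman, human_broadest,
                             min_bp = min_bp)
  structure(list(
    n_shared_nonhuman = nrow(shared_nonhuman),
    n_matched_human = matched,
    percent_matched = 100 * matched / nrow(shared_nonhuman)
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("<conservation_summary> ", x$n_matched_human, "/",
      x$n_shared_nonhuman, " shared non-human peaks match the human set (",
      round(x$percent_matched, 1), "%)\n", sep = "")
  invisible(x)
}
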
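# Release breadth of a strain: compare the metabolite complement of its
# cell extract against its spent minimal medium. Metabolites present in
# the extract but absent from the spent medium argue against cell lysis
# as the release mechanism.

#' Classify metabolites by extract/spent-medium detection
#'
#' Per metabolite, mean areas are computed in the cell extract, the spent
#' minimal medium and the uninoculated control medium. The control mean
#' is subtracted from the spent mean (floored at zero) so medium
#' background never reads as release. Classes at threshold
#' `detect_area`: `extract_only` (extract detected, adjusted spent not),
#' `released` (both detected), `medium_only` (adjusted spent only),
#' `absent` (neither). Release breadth is
#' released / (released + extract_only) — the fraction of
#' intracellularly detected metabolites that also appear outside.
#'
#' @param extract,spent,control Metabolite x replicate area matrices (or
#'   vectors) over a common metabolite universe (shared row names).
#' @param detect_area Detection threshold in counts (default 1000).
#' @return Object of class `release_profile`: data.frame `table`
#'   (metabolite_id, extract_area, spent_area, spent_raw, class), plus
#'   `release_breadth`, `counts` and `detect_area`.
#' @export
classify_release <- function(extract, spent, control,
                             detect_area = 1000) {
  stopifnot(detect_area > 0)
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1L,
                                dimnames = list(names(x), NULL))
    else as.matrix(x)
  }
  extract <- as_mat(extract); spent <- as_mat(spent)
  control <- as_mat(control)
  ids <- rownames(extract)
  if (is.null(ids) || nrow(extract) == 0L) {
    stop("empty metabolite universe")
  }
  if (!identical(ids, rownames(spent)) ||
      !identical(ids, rownames(control))) {
    stop("extract, spent and control must share the metabolite universe")
  }
  me <- rowMeans(extract)
  ms_raw <- rowMeans(spent)
  ms <- pmax(ms_raw - rowMeans(control), 0)
  class <- ifelse(me >= detect_area & ms >= detect_area, "released",
           ifelse(me >= detect_area, "extract_only",
           ifelse(ms >= detect_area, "medium_only", "absent")))
  tab <- data.frame(metabolite_id = ids, extract_area = me,
                    spent_area = ms, spent_raw = ms_raw, class = class,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  counts <- table(factor(tab$class, levels = c("extract_only",
                                               "released",
                                               "medium_only",
                                               "absent")))
  denom <- counts[["released"]] + counts[["extract_only"]]
  structure(list(
    table = tab,
    release_breadth = if (denom > 0) counts[["released"]] / denom
                      else NA_real_,
    counts = counts,
    detect_area = detect_area
  ), class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat("<release_profile> ", nrow(x$table), " metabolites; breadth ",
      signif(x$release_breadth, 3), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Rank-abundance table for a mirror plot
#'
#' Metabolites sorted by descending cell-extract area (ties by
#' metabolite_id), with the paired spent-medium areas preserved —
#' the data behind an extract-vs-spent mirror plot.
#'
#' @param profile A [classify_release()] result.
#' @return data.frame with columns rank, metabolite_id, extract_area,
#'   spent_area, class.
#' @export
rank_abundance_table <- function(profile) {
  tab <- profile$table
  ord <- order(-tab$extract_area, tab$metabolite_id)
  out <- tab[ord, c("metabolite_id", "extract_area", "spent_area",
                    "class")]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
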
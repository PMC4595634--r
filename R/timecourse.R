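# Soil-water metabolite dynamics after wetting a desiccated biocrust:
# per-metabolite trend tests between the first and last timepoint,
# cross-referenced against isolate capabilities to flag depleted
# metabolites that no tested isolate takes up.

#' Per-metabolite trend between two timepoints
#'
#' Two-sided pooled-variance Student's t-test between the replicate
#' areas at `t_first` and `t_last` (independent replicate sets). A
#' metabolite is `depleted` when the last-timepoint mean is
#' significantly lower, `accumulated` when significantly higher, else
#' `flat`. `dilution_factor` multiplies the last-timepoint areas to
#' correct for water replenishment between timepoints; 1 (the default)
#' is the identity.
#'
#' @param abundance Metabolite x sample area matrix of soil-water
#'   samples.
#' @param meta Sample metadata with role `soil_water` and numeric
#'   `timepoint` (minutes after wetting).
#' @param t_first,t_last Timepoints to compare; default the earliest and
#'   latest present.
#' @param alpha Significance level (default 0.05).
#' @param dilution_factor Multiplier applied to `t_last` areas.
#' @return Object of class `timecourse_result`: data.frame `table` with
#'   per-metabolite means at every timepoint, p_value, trend; plus the
#'   comparison metadata.
#' @export
timepoint_trend <- function(abundance, meta, t_first = NULL,
                            t_last = NULL, alpha = 0.05,
                            dilution_factor = 1) {
  sw <- meta[meta$role == "soil_water", , drop = FALSE]
  if (nrow(sw) == 0L) stop("no soil_water samples in metadata")
  tps <- sort(unique(as.numeric(sw$timepoint)))
  if (is.null(t_first)) t_first <- tps[1L]
  if (is.null(t_last)) t_last <- tps[length(tps)]
  if (!(t_first %in% tps)) stop("missing timepoint: ", t_first)
  if (!(t_last %in% tps)) stop("missing timepoint: ", t_last)
  if (t_first >= t_last) stop("t_first must precede t_last")
  cols <- function(tp) {
    ids <- sw$sample_id[as.numeric(sw$timepoint) == tp]
    ids <- intersect(ids, colnames(abundance))
    if (length(ids) < 2L) stop("fewer than 2 replicates at ", tp,
                               " min")
    ids
  }
  A <- abundance[, cols(t_first), drop = FALSE]
  B <- abundance[, cols(t_last), drop = FALSE] * dilution_factor
  tt <- .row_t(B, A)   # statistic > 0 means increase over time
  trend <- ifelse(tt$p.value < alpha & tt$mean_a < tt$mean_b,
                  "depleted",
           ifelse(tt$p.value < alpha & tt$mean_a > tt$mean_b,
                  "accumulated", "flat"))
  means <- vapply(tps, function(tp) {
    rowMeans(abundance[, cols(tp), drop = FALSE])
  }, numeric(nrow(abundance)))
  colnames(means) <- paste0("mean_t", tps)
  tab <- data.frame(metabolite_id = rownames(abundance), means,
                    p_value = tt$p.value, trend = trend,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, t_first = t_first, t_last = t_last,
                 alpha = alpha, dilution_factor = dilution_factor,
                 dilution_corrected = dilution_factor != 1),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat("<timecourse_result> ", nrow(x$table), " metabolites, ",
      x$t_first, " vs ", x$t_last, " min\n", sep = "")
  print(table(x$table$trend))
  invisible(x)
}

#' Match metabolites between two experiments
#'
#' Pairs metabolite records of two independently processed experiments
#' (e.g. soil water vs supplemented media) by polarity, m/z and
#' retention time of their characteristic ions. A record matching
#' several partners is paired with the nearest m/z and flagged
#' `"ambiguous_match"`.
#'
#' @param a,b Metabolite record data.frames with columns metabolite_id,
#'   mz, rt, polarity.
#' @param mz_tol m/z tolerance in Da.
#' @param rt_tol Retention-time tolerance in minutes.
#' @return data.frame with columns id_a, id_b, d_mz, d_rt, flags.
#' @export
match_metabolites <- function(a, b, mz_tol = 0.02, rt_tol = 0.3) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    cand <- which(b$polarity == a$polarity[i] &
                    abs(b$mz - a$mz[i]) <= mz_tol &
                    abs(b$rt - a$rt[i]) <= rt_tol)
    if (length(cand) == 0L) next
    d <- abs(b$mz[cand] - a$mz[i])
    j <- cand[order(d, b$metabolite_id[cand])][1L]
    out[[length(out) + 1L]] <- data.frame(
      id_a = as.character(a$metabolite_id[i]),
      id_b = as.character(b$metabolite_id[j]),
      d_mz = abs(b$mz[j] - a$mz[i]),
      d_rt = abs(b$rt[j] - a$rt[i]),
      flags = if (length(cand) > 1L) "ambiguous_match" else "",
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      d_mz = numeric(0), d_rt = numeric(0),
                      flags = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Depleted soil-water metabolites unused by any isolate
#'
#' Metabolites depleted over the wetting time course whose matched
#' column in the isolate utilization matrix contains no uptake call —
#' depletion attributable only to community members outside the tested
#' isolate panel; candidates to guide isolation of microbes occupying
#' other metabolite niches.
#'
#' @param trend A [timepoint_trend()] result on soil-water data.
#' @param um A [build_utilization_matrix()] result from the isolate
#'   experiment.
#' @param mapping Soil-water to isolate-experiment metabolite mapping
#'   ([match_metabolites()] output; id_a = soil-water id, id_b =
#'   experiment id).
#' @return data.frame of the qualifying soil-water metabolites with
#'   their experiment counterparts and p-values.
#' @export
unused_but_depleted <- function(trend, um, mapping) {
  dep <- trend$table[trend$table$trend == "depleted", , drop = FALSE]
  hit <- mapping[mapping$id_a %in% dep$metabolite_id, , drop = FALSE]
  hit <- hit[hit$id_b %in% colnames(um$calls), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(soil_id = character(0),
                      experiment_id = character(0),
                      p_value = numeric(0), flags = character(0)))
  }
  n_up <- colSums(um$calls == "uptake")
  keep <- n_up[hit$id_b] == 0L
  out <- data.frame(
    soil_id = hit$id_a[keep],
    experiment_id = hit$id_b[keep],
    p_value = dep$p_value[match(hit$id_a[keep], dep$metabolite_id)],
    flags = hit$flags[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Media vs soil-water abundance comparability
#'
#' Per shared metabolite, the log10 ratio of the mean control-medium
#' area to the mean soil-water area at the first timepoint; summarised
#' as the fraction of shared metabolites within one order of magnitude
#' (|log10 ratio| <= 1).
#'
#' @param media_abundance Metabolite x sample matrix of the media
#'   experiment (control samples are selected via `media_meta`).
#' @param media_meta Metadata of the media experiment.
#' @param soil_abundance Metabolite x sample matrix of soil-water
#'   samples.
#' @param soil_meta Metadata of the soil-water experiment.
#' @param mapping [match_metabolites()] output (id_a = media experiment,
#'   id_b = soil water).
#' @param t_first Soil-water timepoint to compare (default earliest).
#' @return List with `table` (id_a, id_b, log10_ratio) and
#'   `fraction_within_order` (metabolites with both means positive).
#' @export
media_vs_soilwater_comparability <- function(media_abundance,
                                             media_meta,
                                             soil_abundance, soil_meta,
                                             mapping, t_first = NULL) {
  ctrl <- media_meta$sample_id[media_meta$role == "control"]
  ctrl <- intersect(ctrl, colnames(media_abundance))
  if (length(ctrl) == 0L) stop("no control samples in media metadata")
  sw <- soil_meta[soil_meta$role == "soil_water", , drop = FALSE]
  tps <- sort(unique(as.numeric(sw$timepoint)))
  if (is.null(t_first)) t_first <- tps[1L]
  sw_ids <- intersect(sw$sample_id[as.numeric(sw$timepoint) == t_first],
                      colnames(soil_abundance))
  m_media <- rowMeans(media_abundance[, ctrl, drop = FALSE])
  m_soil <- rowMeans(soil_abundance[, sw_ids, drop = FALSE])
  a <- m_media[mapping$id_a]
  b <- m_soil[mapping$id_b]
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  tab <- data.frame(id_a = mapping$id_a[ok], id_b = mapping$id_b[ok],
                    log10_ratio = log10(a[ok] / b[ok]),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       fraction_within_order =
         if (nrow(tab)) mean(abs(tab$log10_ratio) <= 1) else NA_real_)
}
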
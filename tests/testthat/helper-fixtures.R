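# In-code fixtures shared across test files.

# minimal feature table: features given as list(mz, rt, polarity,
# intensities-vector); sample ids generated
make_ft <- function(..., sample_ids = NULL) {
  specs <- list(...)
  ns <- length(specs[[1L]]$intensities)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ns))
  feats <- data.frame(
    feature_id = sprintf("f%02d", seq_along(specs)),
    mz = vapply(specs, `[[`, numeric(1L), "mz"),
    rt = vapply(specs, `[[`, numeric(1L), "rt"),
    polarity = vapply(specs, function(s) {
      if (is.null(s$polarity)) "positive" else s$polarity
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  intens <- do.call(rbind, lapply(specs, `[[`, "intensities"))
  colnames(intens) <- sample_ids
  feature_table(feats, intens)
}

# a bare annotated ion-group record for direct operation tests
make_group <- function(mzs, polarity = "positive", rt = 5,
                       annotations = NULL) {
  ids <- names(mzs)
  if (is.null(ids)) {
    ids <- sprintf("f%02d", seq_along(mzs))
    names(mzs) <- ids
  }
  if (is.null(annotations)) {
    annotations <- stats::setNames(rep(NA_character_, length(mzs)), ids)
  }
  list(group_id = "G0001", polarity = polarity, rt_center = rt,
       feature_ids = ids, mz = mzs,
       rt = stats::setNames(rep(rt, length(mzs)), ids),
       ion_annotations = annotations, neutral_mass = NA_real_,
       characteristic_feature_id = NA_character_, flags = character(0))
}

# small two-medium metadata block: n_iso isolates, 3 reps, one control
# group per medium
make_meta <- function(n_iso = 2L, media = "m1", n_rep = 3L) {
  rows <- list()
  for (m in media) {
    gid <- paste0("ctrl_", m)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("c_%s_r%d", m, seq_len(n_rep)),
      role = "control", isolate_id = NA_character_, medium_id = m,
      control_group_id = gid, timepoint = NA_real_,
      replicate_index = seq_len(n_rep), stringsAsFactors = FALSE)
    for (i in seq_len(n_iso)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("s_%s_i%d_r%d", m, i, seq_len(n_rep)),
        role = "spent", isolate_id = paste0("iso", i), medium_id = m,
        control_group_id = gid, timepoint = NA_real_,
        replicate_index = seq_len(n_rep), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# consensus-call data.frame from a compact class matrix
consensus_from_matrix <- function(mat) {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(isolate_id = rownames(mat)[i],
               metabolite_id = colnames(mat),
               call = mat[i, ], p_value = 0.01, fold_change = 1,
               flags = "", stringsAsFactors = FALSE)
  }))
}
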
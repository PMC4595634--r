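# Resolving redundant spectral features into putative metabolites.
#
# One metabolite typically yields several ions (adducts, multimers,
# in-source fragments, isotopologues). Features that co-elute and whose
# intensities are correlated across samples are grouped; ion types are
# then assigned within each group from characteristic mass differences,
# a neutral mass is inferred, and positive/negative-mode groups of the
# same neutral molecule are merged into one metabolite record.

#' Group co-eluting, intensity-correlated features
#'
#' Partitions the feature set by single-linkage transitive closure over a
#' pairwise gate: two features are linked when they share polarity, their
#' retention times differ by at most `rt_tol`, and the Pearson correlation
#' of their raw intensity vectors — computed over samples where at least
#' one of the pair is non-zero, requiring at least 3 such samples — is at
#' least `corr_min`. Features with all-zero intensity vectors cannot be
#' correlated and become singleton groups flagged `"all_zero"`.
#'
#' The result is deterministic and independent of input row order:
#' features are canonically ordered by (polarity, rt, mz, feature_id) and
#' groups are numbered by (rt_center, lowest member m/z).
#'
#' @param ft A [feature_table()].
#' @param rt_tol Retention-time tolerance in minutes (> 0).
#' @param corr_min Minimum Pearson correlation in (0, 1].
#' @return Object of class `ion_groups`: list with `groups` (list of group
#'   records) and `assignments` (feature_id -> group_id data.frame).
#' @export
group_coeluting_features <- function(ft, rt_tol = 0.3, corr_min = 0.9) {
  stopifnot(inherits(ft, "feature_table"), rt_tol > 0,
            corr_min > 0, corr_min <= 1)
  feats <- ft$features
  if (nrow(feats) < 1L) stop("no features to group")
  ord <- order(feats$polarity, feats$rt, feats$mz, feats$feature_id)
  feats <- feats[ord, , drop = FALSE]
  intens <- ft$intensities[feats$feature_id, , drop = FALSE]
  n <- nrow(feats)
  all_zero <- rowSums(intens > 0) == 0L

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  # features are rt-sorted within polarity; only scan the rt window ahead
  for (i in seq_len(n - 1L)) {
    if (all_zero[i]) next
    xi <- intens[i, ]
    j <- i + 1L
    while (j <= n && feats$polarity[j] == feats$polarity[i] &&
           feats$rt[j] - feats$rt[i] <= rt_tol) {
      if (!all_zero[j]) {
        xj <- intens[j, ]
        keep <- xi > 0 | xj > 0
        if (sum(keep) >= 3L) {
          a <- xi[keep]; b <- xj[keep]
          if (stats::sd(a) > 0 && stats::sd(b) > 0) {
            r <- stats::cor(a, b)
            if (!is.na(r) && r >= corr_min) union(i, j)
          }
        }
      }
      j <- j + 1L
    }
  }

  roots <- vapply(seq_len(n), find, integer(1L))
  split_idx <- split(seq_len(n), roots)
  groups <- lapply(split_idx, function(idx) {
    m <- feats[idx, , drop = FALSE]
    m <- m[order(m$mz, m$feature_id), , drop = FALSE]
    flags <- character(0)
    if (length(idx) == 1L && all_zero[idx]) flags <- "all_zero"
    list(
      group_id = NA_character_,
      polarity = m$polarity[1L],
      rt_center = mean(m$rt),
      feature_ids = m$feature_id,
      mz = stats::setNames(m$mz, m$feature_id),
      rt = stats::setNames(m$rt, m$feature_id),
      ion_annotations = stats::setNames(
        rep(NA_character_, nrow(m)), m$feature_id),
      neutral_mass = NA_real_,
      characteristic_feature_id = NA_character_,
      flags = flags
    )
  })
  g_ord <- order(vapply(groups, `[[`, numeric(1L), "rt_center"),
                 vapply(groups, function(g) min(g$mz), numeric(1L)),
                 vapply(groups, `[[`, character(1L), "polarity"))
  groups <- groups[g_ord]
  width <- max(4L, nchar(length(groups)))
  for (k in seq_along(groups)) {
    groups[[k]]$group_id <- sprintf(paste0("G%0", width, "d"), k)
  }
  assignments <- do.call(rbind, lapply(groups, function(g) {
    data.frame(feature_id = g$feature_ids, group_id = g$group_id,
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  structure(list(groups = groups, assignments = assignments),
            class = "ion_groups")
}

#' @export
print.ion_groups <- function(x, ...) {
  sizes <- lengths(lapply(x$groups, `[[`, "feature_ids"))
  cat("<ion_groups> ", length(x$groups), " groups over ",
      sum(sizes), " features (max size ", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' Assign ion types within a group and infer the neutral mass
#'
#' Searches for the neutral mass M that lets the adduct rule set explain
#' the largest number of group members within `mz_tol`: every member/rule
#' combination proposes a candidate M = (mz * charge - mass_shift) /
#' multiplicity, candidates are scored by how many members some rule
#' explains (a member one 13C shift above an explained member counts as
#' a supporting M+1 isotopologue), and the winner annotates its
#' explained members with the
#' first (highest-priority) matching rule. Remaining members within
#' `mz_tol` of an explained member's m/z + 1.00335 are annotated as M+1
#' isotopologues; all others become `"unassigned fragment"`. When two
#' distinct candidate masses explain equally many members the one proposed
#' by the higher-priority rule wins (then the one proposed by the
#' higher-m/z member — in-source fragments lie below their intact ion)
#' and the group is flagged `"ambiguous_mass"`.
#'
#' @param group One group record from [group_coeluting_features()].
#' @param rules Adduct rule table in priority order
#'   ([default_adduct_rules()]).
#' @param mz_tol m/z tolerance in Da (default 0.02, i.e. 20 mDa).
#' @return The group with `ion_annotations` filled and `neutral_mass` set
#'   (NA when no rule matches any member).
#' @export
assign_ion_types <- function(group, rules = default_adduct_rules(),
                             mz_tol = 0.02) {
  stopifnot(mz_tol > 0)
  validate_adduct_rules(rules)
  rules <- rules[rules$polarity == group$polarity, , drop = FALSE]
  mzs <- group$mz
  ann <- stats::setNames(rep("unassigned fragment", length(mzs)),
                         names(mzs))
  group$neutral_mass <- NA_real_
  if (nrow(rules) == 0L) {
    group$ion_annotations <- ann
    return(group)
  }
  # candidate neutral masses, in (member, rule-priority) order
  cand <- expand.grid(rule = seq_len(nrow(rules)),
                      member = seq_along(mzs), KEEP.OUT.ATTRS = FALSE)
  cand$M <- (mzs[cand$member] * rules$charge[cand$rule] -
               rules$mass_shift[cand$rule]) / rules$multiplicity[cand$rule]
  cand <- cand[cand$M > 0, , drop = FALSE]
  if (nrow(cand) == 0L) {
    group$ion_annotations <- ann
    return(group)
  }
  explain <- function(M) {
    # first rule (priority order) explaining each member, NA if none
    hit <- rep(NA_integer_, length(mzs))
    for (r in seq_len(nrow(rules))) {
      pred <- (rules$multiplicity[r] * M + rules$mass_shift[r]) /
        rules$charge[r]
      ok <- is.na(hit) & abs(mzs - pred) <= mz_tol
      hit[ok] <- r
    }
    hit
  }
  # a member sitting one 13C shift above an explained member supports
  # the candidate mass as its M+1 isotopologue
  n_isotopes <- function(hit) {
    expl_mz <- mzs[!is.na(hit)]
    if (length(expl_mz) == 0L) return(0L)
    sum(vapply(which(is.na(hit)), function(i) {
      any(abs(mzs[i] - (expl_mz + .C13_SHIFT)) <= mz_tol)
    }, logical(1L)))
  }
  hits <- lapply(cand$M, explain)
  counts <- vapply(hits, function(h) {
    sum(!is.na(h)) + n_isotopes(h)
  }, integer(1L))
  best_n <- max(counts)
  if (best_n == 0L) {
    group$ion_annotations <- ann
    return(group)
  }
  # candidates ordered by rule priority then descending member m/z;
  # first max wins
  ord <- order(cand$rule, -mzs[cand$member])
  winner <- ord[which(counts[ord] == best_n)[1L]]
  hit <- hits[[winner]]
  # distinct runner-up mass explaining as many members -> ambiguous
  tied <- which(counts == best_n)
  if (any(abs(cand$M[tied] - cand$M[winner]) > mz_tol)) {
    group$flags <- union(group$flags, "ambiguous_mass")
  }
  expl <- which(!is.na(hit))
  ann[expl] <- rules$name[hit[expl]]
  # refined neutral mass: mean of the masses implied by explained members
  implied <- (mzs[expl] * rules$charge[hit[expl]] -
                rules$mass_shift[hit[expl]]) /
    rules$multiplicity[hit[expl]]
  group$neutral_mass <- mean(implied)
  # isotope pass: unexplained members one 13C shift above an explained one
  for (i in seq_along(mzs)) {
    if (!is.na(hit[i])) next
    if (any(abs(mzs[i] - (mzs[expl] + .C13_SHIFT)) <= mz_tol)) {
      ann[i] <- "isotope (M+1)"
    }
  }
  group$ion_annotations <- ann
  group
}

#' Select the characteristic (quantification) ion of a group
#'
#' Prefers members annotated with a primary rule (protonated,
#' deprotonated or ammoniated molecule); among those, the one with the
#' highest median intensity across all samples wins. When no member
#' carries a primary annotation the highest-median member overall is
#' used. Ties break deterministically by lower m/z, then feature_id.
#'
#' @param group An annotated group (see [assign_ion_types()]).
#' @param ft The [feature_table()] the group came from.
#' @param rules Adduct rule table (for the `primary` flag).
#' @return The chosen feature_id (character scalar).
#' @export
select_characteristic_ion <- function(group, ft,
                                      rules = default_adduct_rules()) {
  ids <- group$feature_ids
  med <- apply(ft$intensities[ids, , drop = FALSE], 1L, stats::median)
  primary_names <- rules$name[rules$primary]
  cand <- ids[group$ion_annotations[ids] %in% primary_names]
  if (length(cand) == 0L) cand <- ids
  m <- med[cand]
  best <- cand[m == max(m)]
  if (length(best) > 1L) {
    best <- best[order(group$mz[best], best)][1L]
  }
  best
}

#' Merge positive- and negative-mode groups into metabolite records
#'
#' Fast polarity switching detects many metabolites in both ionisation
#' modes. A positive and a negative group are merged into one metabolite
#' record when both carry a neutral mass, the masses agree within
#' `mass_tol` and the retention-time centers within `rt_tol`. Matching is
#' greedy by ascending mass difference; a group with more than one
#' admissible partner is merged with the nearest mass and flagged
#' `"ambiguous_merge"`. Unmerged groups become single-polarity records.
#' Records are numbered sequentially (the "metabolite number") by
#' retention time, then characteristic m/z.
#'
#' @param groups An `ion_groups` object whose groups are annotated and
#'   have characteristic ions assigned (see [resolve_metabolites()] for
#'   the one-call wrapper).
#' @param ft The [feature_table()].
#' @param mass_tol Neutral-mass tolerance in Da.
#' @param rt_tol Retention-time tolerance in minutes.
#' @return data.frame of metabolite records: metabolite_id, mz, polarity,
#'   rt, neutral_mass, formula, identity, characteristic_feature_id,
#'   n_member_ions, source_groups, flags.
#' @export
merge_polarities <- function(groups, ft, mass_tol = 0.005, rt_tol = 0.3) {
  stopifnot(mass_tol > 0, rt_tol > 0)
  gl <- groups$groups
  med_of <- function(g) {
    stats::median(ft$intensities[g$characteristic_feature_id, ])
  }
  pos <- which(vapply(gl, function(g)
    g$polarity == "positive" && !is.na(g$neutral_mass), logical(1L)))
  neg <- which(vapply(gl, function(g)
    g$polarity == "negative" && !is.na(g$neutral_mass), logical(1L)))
  cand <- NULL
  if (length(pos) && length(neg)) {
    grid <- expand.grid(p = pos, q = neg, KEEP.OUT.ATTRS = FALSE)
    dm <- abs(vapply(gl[grid$p], `[[`, numeric(1L), "neutral_mass") -
                vapply(gl[grid$q], `[[`, numeric(1L), "neutral_mass"))
    dr <- abs(vapply(gl[grid$p], `[[`, numeric(1L), "rt_center") -
                vapply(gl[grid$q], `[[`, numeric(1L), "rt_center"))
    keep <- dm <= mass_tol & dr <= rt_tol
    if (any(keep)) {
      cand <- grid[keep, , drop = FALSE]
      cand$dm <- dm[keep]
    }
  }
  partner <- rep(NA_integer_, length(gl))
  ambiguous <- integer(0)
  if (!is.null(cand)) {
    multi <- c(cand$p[duplicated(cand$p) | duplicated(cand$p,
                                                      fromLast = TRUE)],
               cand$q[duplicated(cand$q) | duplicated(cand$q,
                                                      fromLast = TRUE)])
    ambiguous <- unique(multi)
    cand <- cand[order(cand$dm, cand$p, cand$q), , drop = FALSE]
    used <- logical(length(gl))
    for (k in seq_len(nrow(cand))) {
      p <- cand$p[k]; q <- cand$q[k]
      if (!used[p] && !used[q]) {
        partner[p] <- q
        partner[q] <- p
        used[p] <- TRUE
        used[q] <- TRUE
      }
    }
  }
  recs <- list()
  consumed <- logical(length(gl))
  for (i in seq_along(gl)) {
    if (consumed[i]) next
    g <- gl[[i]]
    j <- partner[i]
    if (!is.na(j)) {
      h <- gl[[j]]
      consumed[j] <- TRUE
      # canonical order: the positive-mode group is g
      if (g$polarity == "negative") {
        tmp <- g; g <- h; h <- tmp
      }
      # characteristic ion: the more intense of the two groups' choices
      gm <- med_of(g); hm <- med_of(h)
      lead <- if (gm > hm || (gm == hm &&
                   g$mz[g$characteristic_feature_id] <=
                   h$mz[h$characteristic_feature_id])) g else h
      flags <- union(union(g$flags, h$flags),
                     if (i %in% ambiguous || j %in% ambiguous)
                       "ambiguous_merge" else character(0))
      recs[[length(recs) + 1L]] <- data.frame(
        mz = unname(lead$mz[lead$characteristic_feature_id]),
        polarity = lead$polarity,
        rt = mean(c(g$rt_center, h$rt_center)),
        neutral_mass = mean(c(g$neutral_mass, h$neutral_mass)),
        characteristic_feature_id = lead$characteristic_feature_id,
        n_member_ions = length(g$feature_ids) + length(h$feature_ids),
        source_groups = paste(g$group_id, h$group_id, sep = ","),
        flags = paste(flags, collapse = ";"),
        stringsAsFactors = FALSE
      )
    } else {
      flags <- union(g$flags,
                     if (i %in% ambiguous) "ambiguous_merge"
                     else character(0))
      recs[[length(recs) + 1L]] <- data.frame(
        mz = unname(g$mz[g$characteristic_feature_id]),
        polarity = g$polarity,
        rt = g$rt_center,
        neutral_mass = g$neutral_mass,
        characteristic_feature_id = g$characteristic_feature_id,
        n_member_ions = length(g$feature_ids),
        source_groups = g$group_id,
        flags = paste(flags, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
    consumed[i] <- TRUE
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$rt, out$mz), , drop = FALSE]
  out <- cbind(metabolite_id = seq_len(nrow(out)), out)
  out$formula <- NA_character_
  out$identity <- NA_character_
  rownames(out) <- NULL
  out[, c("metabolite_id", "mz", "polarity", "rt", "neutral_mass",
          "formula", "identity", "characteristic_feature_id",
          "n_member_ions", "source_groups", "flags")]
}

#' Observed M+1/M ratio for a group's characteristic ion
#'
#' @param group Annotated group with a characteristic ion.
#' @param ft The [feature_table()].
#' @param mz_tol m/z tolerance in Da.
#' @return Median across samples of the isotopologue/monoisotopic area
#'   ratio, or NA when no M+1 member exists.
#' @export
observed_m1_ratio <- function(group, ft, mz_tol = 0.02) {
  cid <- group$characteristic_feature_id
  if (is.na(cid)) return(NA_real_)
  iso <- names(group$mz)[
    group$ion_annotations == "isotope (M+1)" &
      abs(group$mz - (group$mz[cid] + .C13_SHIFT)) <= mz_tol]
  if (length(iso) == 0L) return(NA_real_)
  iso <- iso[1L]
  m0 <- stats::median(ft$intensities[cid, ])
  m1 <- stats::median(ft$intensities[iso, ])
  if (m0 <= 0) return(NA_real_)
  m1 / m0
}

#' Resolve a feature table into metabolite records
#'
#' One-call wrapper over the ion-grouping stage: groups co-eluting
#' correlated features, annotates ion types and neutral masses, selects
#' characteristic ions, merges polarities into metabolite records and
#' (optionally) assigns molecular formulas from accurate mass plus the
#' observed M+1 ratio.
#'
#' @inheritParams group_coeluting_features
#' @inheritParams assign_ion_types
#' @param mass_tol Neutral-mass tolerance for the polarity merge (Da).
#' @param assign_formulas Run CHNOPS formula assignment per record.
#' @param mass_tol_ppm Formula-assignment mass tolerance (ppm).
#' @return List with `metabolites` (record data.frame), `groups`
#'   (`ion_groups`, annotated) and `abundance` (metabolite x sample matrix
#'   of characteristic-ion areas).
#' @export
resolve_metabolites <- function(ft, rules = default_adduct_rules(),
                                rt_tol = 0.3, corr_min = 0.9,
                                mz_tol = 0.02, mass_tol = 0.005,
                                assign_formulas = FALSE,
                                mass_tol_ppm = 5) {
  groups <- group_coeluting_features(ft, rt_tol = rt_tol,
                                     corr_min = corr_min)
  groups$groups <- lapply(groups$groups, function(g) {
    g <- assign_ion_types(g, rules = rules, mz_tol = mz_tol)
    g$characteristic_feature_id <-
      select_characteristic_ion(g, ft, rules = rules)
    g
  })
  mets <- merge_polarities(groups, ft, mass_tol = mass_tol,
                           rt_tol = rt_tol)
  if (assign_formulas) {
    gid <- stats::setNames(seq_along(groups$groups),
                           vapply(groups$groups, `[[`, character(1L),
                                  "group_id"))
    for (i in seq_len(nrow(mets))) {
      nm <- mets$neutral_mass[i]
      if (is.na(nm)) next
      src <- strsplit(mets$source_groups[i], ",")[[1L]][1L]
      m1 <- observed_m1_ratio(groups$groups[[gid[[src]]]], ft,
                              mz_tol = mz_tol)
      cands <- assign_formula(nm, m1_ratio = m1,
                              mass_tol_ppm = mass_tol_ppm)
      if (nrow(cands)) mets$formula[i] <- cands$formula[1L]
    }
  }
  abund <- ft$intensities[mets$characteristic_feature_id, , drop = FALSE]
  rownames(abund) <- as.character(mets$metabolite_id)
  list(metabolites = mets, groups = groups, abundance = abund)
}

#' Write the metabolite record table
#'
#' @param metabolites Metabolite record data.frame.
#' @param path Output path (TSV).
#' @export
write_metabolite_table <- function(metabolites, path) {
  utils::write.table(metabolites, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
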
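# Uptake / release classification: compare characteristic-ion peak areas
# in spent media against the matched uninoculated control media.

#' Filter metabolites to the abundant ("available") set
#'
#' A metabolite counts as available when the peak area of its
#' characteristic ion reaches `min_area` counts in at least one
#' control-medium sample (any medium); alternatively, when
#' `mode = "group_mean"`, when any control group's mean reaches it.
#'
#' @param abundance Metabolite x sample matrix of characteristic-ion
#'   areas.
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param min_area Abundance threshold in counts (default 5000).
#' @param mode `"any_sample"` (default) or `"group_mean"`.
#' @return Character vector of abundant metabolite ids (row names).
#' @export
filter_abundant <- function(abundance, meta, min_area = 5000,
                            mode = c("any_sample", "group_mean")) {
  mode <- match.arg(mode)
  stopifnot(min_area >= 0)
  ctrl <- meta$sample_id[meta$role == "control"]
  ctrl <- intersect(ctrl, colnames(abundance))
  if (length(ctrl) == 0L) {
    stop("no control samples present; cannot define the available set")
  }
  sub <- abundance[, ctrl, drop = FALSE]
  if (mode == "any_sample") {
    keep <- apply(sub, 1L, max) >= min_area
  } else {
    grp <- meta$control_group_id[match(ctrl, meta$sample_id)]
    means <- vapply(unique(grp), function(g) {
      rowMeans(sub[, grp == g, drop = FALSE])
    }, numeric(nrow(sub)))
    keep <- apply(as.matrix(means), 1L, max) >= min_area
  }
  rownames(abundance)[keep]
}

#' Two-sample pooled-variance Student's t-test
#'
#' Two-sided test with the pooled-variance (classical Student) statistic
#' and |a| + |b| - 2 degrees of freedom. Degenerate inputs with zero
#' pooled variance return p = 1 when the means are equal and p = 0
#' (flagged) when they differ.
#'
#' @param a,b Numeric vectors of replicate areas, each of length >= 2.
#' @return List with `statistic`, `p.value`, `df` and logical
#'   `degenerate`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (d == 0) {
      return(list(statistic = 0, p.value = 1, df = df,
                  degenerate = TRUE))
    }
    return(list(statistic = sign(d) * Inf, p.value = 0, df = df,
                degenerate = TRUE))
  }
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tt, p.value = 2 * stats::pt(-abs(tt), df),
       df = df, degenerate = FALSE)
}

# vectorised row-wise pooled t over two column subsets of a matrix
.row_t <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  df <- n1 + n2 - 2L
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (n1 - 1)
  vB <- rowSums((B - mB)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * vA + (n2 - 1) * vB) / df
  d <- mA - mB
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df)
  deg <- sp2 <= 0
  p[deg & d == 0] <- 1
  tt[deg & d == 0] <- 0
  p[deg & d != 0] <- 0
  tt[deg & d != 0] <- sign(d[deg & d != 0]) * Inf
  list(statistic = tt, p.value = p, mean_a = mA, mean_b = mB,
       degenerate = deg)
}

.tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Classify utilization of one metabolite by one isolate in one medium
#'
#' Decision rule, with C the matched control areas and S the spent areas:
#' when `max(C) < min_area` the metabolite was not available in this
#' medium — the call is `not_available` unless `mean(S) >= detect_area`,
#' in which case it is `release` (released into a medium where it was
#' undetected). Otherwise a two-sided pooled t-test of S against C makes
#' the call: significant depletion is `uptake`, significant increase
#' `release`, anything else `unchanged`.
#'
#' @param metabolite_id Row name into `abundance`.
#' @param isolate_id,medium_id Spent-sample selectors in `meta`.
#' @param abundance Metabolite x sample area matrix.
#' @param meta Sample metadata.
#' @param alpha Significance level (default 0.05).
#' @param min_area Availability threshold on control areas (default 5000).
#' @param detect_area Detection threshold for release-from-nothing
#'   (default 1000).
#' @return One-row data.frame (a UtilizationCall): isolate_id,
#'   metabolite_id, medium_id, call, p_value, fold_change, mean_control,
#'   mean_spent, tier, flags.
#' @export
classify_utilization <- function(metabolite_id, isolate_id, medium_id,
                                 abundance, meta, alpha = 0.05,
                                 min_area = 5000, detect_area = 1000) {
  sel <- .spent_control_samples(meta, isolate_id, medium_id)
  S <- abundance[metabolite_id, sel$spent]
  C <- abundance[metabolite_id, sel$control]
  if (any(c(S, C) < 0)) stop("negative areas")
  tt <- two_sample_t(S, C)
  .make_call(metabolite_id, isolate_id, medium_id,
             mean_spent = mean(S), mean_control = mean(C),
             max_control = max(C), p = tt$p.value,
             degenerate = tt$degenerate, alpha = alpha,
             min_area = min_area, detect_area = detect_area)
}

.make_call <- function(metabolite_id, isolate_id, medium_id, mean_spent,
                       mean_control, max_control, p, degenerate, alpha,
                       min_area, detect_area) {
  flags <- character(0)
  if (max_control < min_area) {
    if (mean_spent >= detect_area) {
      call <- "release"
      if (degenerate) flags <- c(flags, "degenerate")
      flags <- c(flags, "novel_release")
    } else {
      call <- "not_available"
    }
  } else if (p < alpha && mean_spent < mean_control) {
    call <- "uptake"
    if (degenerate) flags <- c(flags, "degenerate")
  } else if (p < alpha && mean_spent > mean_control) {
    call <- "release"
    if (degenerate) flags <- c(flags, "degenerate")
  } else {
    call <- "unchanged"
  }
  data.frame(
    isolate_id = isolate_id, metabolite_id = metabolite_id,
    medium_id = medium_id, call = call, p_value = p,
    fold_change = if (mean_control > 0) mean_spent / mean_control
                  else Inf,
    mean_control = mean_control, mean_spent = mean_spent,
    tier = .tier(p), flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

.spent_control_samples <- function(meta, isolate_id, medium_id) {
  sp <- meta[meta$role == "spent" & meta$isolate_id == isolate_id &
               meta$medium_id == medium_id, , drop = FALSE]
  if (nrow(sp) < 2L) {
    stop("need >= 2 spent replicates for ", isolate_id, " in ",
         medium_id)
  }
  grp <- unique(sp$control_group_id)
  if (length(grp) != 1L || is.na(grp)) {
    stop("spent samples of ", isolate_id, " in ", medium_id,
         " lack a unique control_group_id")
  }
  ctrl <- meta$sample_id[meta$role == "control" &
                           meta$control_group_id %in% grp]
  if (length(ctrl) < 2L) {
    stop("control group '", grp, "' has fewer than 2 samples")
  }
  list(spent = sp$sample_id, control = ctrl)
}

#' Classify all isolate x metabolite x medium combinations
#'
#' Vectorised application of the [classify_utilization()] rule to every
#' metabolite for every (isolate, medium) with spent samples.
#'
#' @inheritParams classify_utilization
#' @return data.frame of UtilizationCalls, one row per isolate x
#'   metabolite x medium.
#' @export
classify_all <- function(abundance, meta, alpha = 0.05, min_area = 5000,
                         detect_area = 1000) {
  if (any(abundance < 0)) stop("negative areas")
  spent <- meta[meta$role == "spent", , drop = FALSE]
  if (nrow(spent) == 0L) stop("no spent samples in metadata")
  combos <- unique(spent[, c("isolate_id", "medium_id")])
  combos <- combos[order(combos$isolate_id, combos$medium_id), ,
                   drop = FALSE]
  res <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    sel <- .spent_control_samples(meta, combos$isolate_id[k],
                                  combos$medium_id[k])
    S <- abundance[, sel$spent, drop = FALSE]
    C <- abundance[, sel$control, drop = FALSE]
    tt <- .row_t(S, C)
    maxC <- apply(C, 1L, max)
    rows <- lapply(seq_len(nrow(abundance)), function(i) {
      .make_call(rownames(abundance)[i], combos$isolate_id[k],
                 combos$medium_id[k], mean_spent = tt$mean_a[i],
                 mean_control = tt$mean_b[i], max_control = maxC[i],
                 p = tt$p.value[i], degenerate = tt$degenerate[i],
                 alpha = alpha, min_area = min_area,
                 detect_area = detect_area)
    })
    res[[k]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Consensus call across medium formulations
#'
#' Combines the per-medium calls of one isolate x metabolite pair:
#' `not_available` calls are uninformative and dropped; agreeing calls
#' carry over; a mix such as {uptake, unchanged} scores as use in any
#' medium, so the directional call wins; a genuine uptake/release
#' conflict resolves to the smaller p-value and is flagged `"conflict"`.
#'
#' @param calls data.frame of UtilizationCalls (any number of isolate x
#'   metabolite pairs; grouped internally).
#' @return data.frame of consensus calls: isolate_id, metabolite_id,
#'   call, p_value, fold_change, flags.
#' @export
combine_across_media <- function(calls) {
  if (nrow(calls) == 0L) stop("empty calls table")
  key <- paste(calls$isolate_id, calls$metabolite_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    cc <- calls[idx, , drop = FALSE]
    inf <- cc[cc$call != "not_available", , drop = FALSE]
    flags <- character(0)
    if (nrow(inf) == 0L) {
      win <- cc[1L, , drop = FALSE]
      win$call <- "not_available"
    } else {
      has_up <- any(inf$call == "uptake")
      has_rel <- any(inf$call == "release")
      if (has_up && has_rel) {
        dir_ <- inf[inf$call %in% c("uptake", "release"), , drop = FALSE]
        win <- dir_[which.min(dir_$p_value), , drop = FALSE]
        flags <- "conflict"
      } else if (has_up) {
        up <- inf[inf$call == "uptake", , drop = FALSE]
        win <- up[which.min(up$p_value), , drop = FALSE]
      } else if (has_rel) {
        rel <- inf[inf$call == "release", , drop = FALSE]
        win <- rel[which.min(rel$p_value), , drop = FALSE]
      } else {
        win <- inf[which.min(inf$p_value), , drop = FALSE]
        win$call <- "unchanged"
      }
    }
    data.frame(isolate_id = win$isolate_id,
               metabolite_id = win$metabolite_id, call = win$call,
               p_value = win$p_value, fold_change = win$fold_change,
               flags = paste(c(win$flags[win$flags != ""], flags),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$isolate_id,
                   suppressWarnings(as.numeric(out$metabolite_id)),
                   out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a utilization calls table
#' @param calls Calls or consensus data.frame.
#' @param path Output TSV path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
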
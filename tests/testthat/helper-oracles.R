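# Independent oracles, coded separately from the package internals.

# textbook pooled-variance two-sample t
oracle_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tt, p.value = 2 * stats::pt(-abs(tt), df))
}

# brute-force grouping: full pairwise gate matrix, then connected
# components by breadth-first search (no union-find, no rt windowing)
oracle_group <- function(ft, rt_tol, corr_min) {
  feats <- ft$features
  n <- nrow(feats)
  intens <- ft$intensities[feats$feature_id, , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (feats$polarity[i] != feats$polarity[j]) next
      if (abs(feats$rt[i] - feats$rt[j]) > rt_tol) next
      xi <- intens[i, ]; xj <- intens[j, ]
      if (all(xi == 0) || all(xj == 0)) next
      keep <- xi > 0 | xj > 0
      if (sum(keep) < 3) next
      if (stats::sd(xi[keep]) == 0 || stats::sd(xj[keep]) == 0) next
      r <- stats::cor(xi[keep], xj[keep])
      if (!is.na(r) && r >= corr_min) adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # canonical form: sorted member sets, sorted lexicographically
  parts <- unname(split(feats$feature_id, comp))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, character(1L), 1L))]
}

# canonical partition of a grouping result, comparable with the oracle
partition_of <- function(groups) {
  parts <- unname(lapply(groups$groups, function(g) sort(g$feature_ids)))
  parts[order(vapply(parts, `[`, character(1L), 1L))]
}

# exhaustive CHNO(PS) formula enumeration by expand.grid over explicit
# bounds; same chemistry filters as the implementation, independent code
oracle_enumerate <- function(mass, bounds, tol_ppm) {
  am <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
          O = 15.9949146196, P = 30.97376163, S = 31.97207100)
  g <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                   N = 0:bounds[["N"]], O = 0:bounds[["O"]],
                   P = 0:bounds[["P"]], S = 0:bounds[["S"]])
  m <- g$C * am["C"] + g$H * am["H"] + g$N * am["N"] +
    g$O * am["O"] + g$P * am["P"] + g$S * am["S"]
  keep <- abs(m - mass) <= mass * tol_ppm * 1e-6
  g <- g[keep, , drop = FALSE]
  rdbe <- g$C + 1 + (g$N + g$P) / 2 - g$H / 2
  g <- g[rdbe >= 0 & rdbe %% 1 == 0, , drop = FALSE]
  hasC <- g$C > 0
  g <- g[!hasC | (g$H <= 6 * g$C & g$N <= 1.3 * g$C &
                    g$O <= 1.2 * g$C & g$P <= 0.3 * g$C &
                    g$S <= 0.8 * g$C), , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  sort(apply(g, 1L, function(x) {
    exoniche::format_formula(c(C = x[["C"]], H = x[["H"]], N = x[["N"]],
                               O = x[["O"]], P = x[["P"]],
                               S = x[["S"]]))
  }))
}
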
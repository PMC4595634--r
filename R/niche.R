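# Niche-partitioning statistics over the isolates x metabolites
# utilization matrix: used fractions, shared-use distribution,
# competition and cross-feeding candidate sets, pairwise overlap and the
# bipartite isolate-metabolite network.

#' Round a fraction to integer percent, half away from zero
#'
#' The reporting convention for used fractions: e.g. 70 of 372 is
#' 18.8%, printed as 19%.
#'
#' @param x Numeric fraction(s) in [-1, 1].
#' @return Integer percent(s).
#' @examples
#' percent_round(70 / 372) # 19
#' @export
percent_round <- function(x) {
  as.integer(sign(x) * floor(abs(x) * 100 + 0.5))
}

#' Build the utilization matrix
#'
#' Arranges consensus calls into an isolates x metabolites matrix over
#' the abundant (available) metabolite set. Metabolites outside the
#' abundant set that carry a release call are tracked separately as the
#' `released_novel` set: they were released into media where they were
#' never available, so they do not enter availability-based fractions.
#'
#' @param consensus Consensus calls from [combine_across_media()].
#' @param abundant Character vector of abundant metabolite ids.
#' @param isolates Character vector of isolate ids (row order).
#' @return Object of class `utilization_matrix`: list with `calls`
#'   (character matrix isolates x metabolites), `conflict` (logical
#'   matrix), `denominator` (|abundant|) and `released_novel`.
#' @export
build_utilization_matrix <- function(consensus, abundant, isolates) {
  if (length(isolates) == 0L) stop("empty isolate list")
  abundant <- as.character(abundant)
  consensus$metabolite_id <- as.character(consensus$metabolite_id)
  key <- paste(consensus$isolate_id, consensus$metabolite_id,
               sep = "\r")
  if (anyDuplicated(key)) stop("duplicate consensus calls")
  want <- expand.grid(isolate_id = isolates, metabolite_id = abundant,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  wkey <- paste(want$isolate_id, want$metabolite_id, sep = "\r")
  hit <- match(wkey, key)
  if (anyNA(hit)) {
    gaps <- utils::head(want[is.na(hit), , drop = FALSE], 5L)
    stop("missing consensus call(s) for: ",
         paste(gaps$isolate_id, gaps$metabolite_id, sep = "/",
               collapse = ", "))
  }
  calls <- matrix(consensus$call[hit], nrow = length(isolates),
                  dimnames = list(isolates, abundant))
  confl <- matrix(grepl("conflict", consensus$flags[hit]),
                  nrow = length(isolates),
                  dimnames = list(isolates, abundant))
  novel <- unique(consensus$metabolite_id[
    !(consensus$metabolite_id %in% abundant) &
      consensus$call == "release"])
  structure(list(calls = calls, conflict = confl,
                 denominator = length(abundant),
                 released_novel = novel),
            class = "utilization_matrix")
}

#' @export
print.utilization_matrix <- function(x, ...) {
  cat("<utilization_matrix> ", nrow(x$calls), " isolates x ",
      ncol(x$calls), " abundant metabolites; ",
      length(x$released_novel), " released-novel\n", sep = "")
  print(table(as.vector(x$calls)))
  invisible(x)
}

# uptake indicator with the configured conflict policy
.uptake_matrix <- function(um, conflict_policy) {
  up <- um$calls == "uptake"
  if (conflict_policy == "exclude") up[um$conflict] <- FALSE
  up
}

#' Fraction of available metabolites used per isolate
#'
#' @param um A [build_utilization_matrix()] result.
#' @param conflict_policy `"as_uptake_if_resolved_uptake"` (default;
#'   conflicted cells whose resolved call is uptake count as used) or
#'   `"exclude"`.
#' @return Named numeric vector, fraction of the abundant set taken up
#'   by each isolate.
#' @export
per_isolate_fraction <- function(um,
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  conflict_policy <- match.arg(conflict_policy)
  rowSums(.uptake_matrix(um, conflict_policy)) / um$denominator
}

#' Shared-use distribution
#'
#' For each metabolite, the number of isolates taking it up; returned as
#' a histogram over k = 0..n_isolates (counts sum to the abundant-set
#' size) plus cumulative counts for "used by at least K isolates"
#' queries.
#'
#' @inheritParams per_isolate_fraction
#' @return List with `histogram` (named integer vector over 0..n),
#'   `cumulative` (count of metabolites used by >= k isolates) and
#'   `per_metabolite` (named integer vector).
#' @export
shared_use_distribution <- function(um,
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  conflict_policy <- match.arg(conflict_policy)
  k <- colSums(.uptake_matrix(um, conflict_policy))
  n <- nrow(um$calls)
  hist <- vapply(0:n, function(i) sum(k == i), integer(1L))
  names(hist) <- as.character(0:n)
  cum <- rev(cumsum(rev(hist)))
  names(cum) <- names(hist)
  list(histogram = hist, cumulative = cum, per_metabolite = k)
}

#' Competition candidate metabolites
#'
#' Metabolites taken up by at least two isolates and released by none:
#' direct competition for a shared, unreplenished resource.
#'
#' @inheritParams per_isolate_fraction
#' @return Character vector of metabolite ids.
#' @export
competition_candidates <- function(um,
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  conflict_policy <- match.arg(conflict_policy)
  up <- colSums(.uptake_matrix(um, conflict_policy))
  rel <- colSums(um$calls == "release")
  colnames(um$calls)[up >= 2L & rel == 0L]
}

#' Cross-feeding candidate metabolites
#'
#' Metabolites taken up by at least one isolate and released by at least
#' one *different* isolate. Disjoint from [competition_candidates()] by
#' construction (those require zero releases).
#'
#' @inheritParams per_isolate_fraction
#' @return Character vector of metabolite ids.
#' @export
crossfeeding_candidates <- function(um,
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  conflict_policy <- match.arg(conflict_policy)
  up <- .uptake_matrix(um, conflict_policy)
  rel <- um$calls == "release"
  # a cell holds one consensus call, so an uptake and a release on the
  # same metabolite necessarily come from different isolates
  colnames(um$calls)[colSums(up) >= 1L & colSums(rel) >= 1L]
}

#' Pairwise niche overlap between isolates
#'
#' Overlap of the uptake (substrate) sets of each isolate pair. Jaccard
#' is |A n B| / |A u B| (0 when both sets are empty); Simpson is
#' |A n B| / min(|A|, |B|), the overlap relative to the narrower niche.
#' Diagonal entries are 1 for isolates with a non-empty uptake set.
#'
#' @inheritParams per_isolate_fraction
#' @param method `"jaccard"` or `"simpson"`.
#' @return Symmetric numeric matrix, isolates x isolates, in [0, 1].
#' @export
pairwise_overlap <- function(um, method = c("jaccard", "simpson"),
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  method <- match.arg(method)
  conflict_policy <- match.arg(conflict_policy)
  up <- .uptake_matrix(um, conflict_policy)
  n <- nrow(up)
  out <- matrix(0, n, n, dimnames = list(rownames(up), rownames(up)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- up[i, ]; b <- up[j, ]
      inter <- sum(a & b)
      if (method == "jaccard") {
        uni <- sum(a | b)
        out[i, j] <- if (uni == 0L) 0 else inter / uni
      } else {
        m <- min(sum(a), sum(b))
        out[i, j] <- if (m == 0L) 0 else inter / m
      }
    }
  }
  out
}

#' Export the bipartite isolate-metabolite network
#'
#' One edge per uptake (type `"utilization"`) or release (type
#' `"release"`) cell of the utilization matrix.
#'
#' @inheritParams per_isolate_fraction
#' @param metabolite_annotations Optional data.frame keyed by
#'   `metabolite_id` (e.g. formula, identity) copied onto metabolite
#'   nodes.
#' @param isolate_annotations Optional data.frame keyed by `isolate_id`
#'   (e.g. taxonomy) copied onto isolate nodes.
#' @param path Optional GraphML output path.
#' @return List with `edges` (data.frame isolate_id, metabolite_id,
#'   type) and `graph` (igraph bipartite graph).
#' @export
export_bipartite <- function(um, metabolite_annotations = NULL,
                             isolate_annotations = NULL, path = NULL) {
  idx <- which(um$calls == "uptake" | um$calls == "release",
               arr.ind = TRUE)
  edges <- data.frame(
    isolate_id = rownames(um$calls)[idx[, 1L]],
    metabolite_id = colnames(um$calls)[idx[, 2L]],
    type = ifelse(um$calls[idx] == "uptake", "utilization", "release"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$isolate_id, edges$metabolite_id,
                       edges$type), , drop = FALSE]
  rownames(edges) <- NULL
  iso <- rownames(um$calls)
  met <- colnames(um$calls)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(iso), name = iso,
                            kind = "isolate", type = FALSE)
  g <- igraph::add_vertices(g, length(met),
                            name = paste0("met_", met),
                            kind = "metabolite", type = TRUE)
  if (nrow(edges)) {
    g <- igraph::add_edges(
      g,
      rbind(match(edges$isolate_id, iso),
            length(iso) + match(edges$metabolite_id, met)),
      type = edges$type
    )
  }
  .attach_node_attrs <- function(g, tab, key, ids, offset) {
    if (is.null(tab)) return(g)
    hit <- match(ids, as.character(tab[[key]]))
    for (col in setdiff(names(tab), key)) {
      g <- igraph::set_vertex_attr(
        g, col, index = offset + seq_along(ids),
        value = as.character(tab[[col]])[hit])
    }
    g
  }
  g <- .attach_node_attrs(g, isolate_annotations, "isolate_id", iso, 0L)
  g <- .attach_node_attrs(g, metabolite_annotations, "metabolite_id",
                          met, length(iso))
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
  }
  list(edges = edges, graph = g)
}

#' Niche summary
#'
#' Bundles the niche statistics into one report object.
#'
#' @inheritParams per_isolate_fraction
#' @return List: per_isolate_used_fraction, per_isolate_used_percent,
#'   shared_use_histogram, cumulative_use, unused_fraction,
#'   competition_set, crossfeed_set, pairwise_jaccard,
#'   pairwise_simpson, denominator, released_novel.
#' @export
niche_summary <- function(um,
    conflict_policy = c("as_uptake_if_resolved_uptake", "exclude")) {
  conflict_policy <- match.arg(conflict_policy)
  frac <- per_isolate_fraction(um, conflict_policy)
  sh <- shared_use_distribution(um, conflict_policy)
  list(
    per_isolate_used_fraction = frac,
    per_isolate_used_percent = percent_round(frac),
    shared_use_histogram = sh$histogram,
    cumulative_use = sh$cumulative,
    unused_fraction = unname(sh$histogram["0"]) / um$denominator,
    competition_set = competition_candidates(um, conflict_policy),
    crossfeed_set = crossfeeding_candidates(um, conflict_policy),
    pairwise_jaccard = pairwise_overlap(um, "jaccard", conflict_policy),
    pairwise_simpson = pairwise_overlap(um, "simpson", conflict_policy),
    denominator = um$denominator,
    released_novel = um$released_novel
  )
}
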
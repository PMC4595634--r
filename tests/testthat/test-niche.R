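test_that("percent rounding follows the half-away-from-zero convention", {
  expect_identical(percent_round(70 / 372), 19L)
  expect_identical(percent_round(0.125), 13L)
  expect_identical(percent_round(0), 0L)
  expect_identical(percent_round(1), 100L)
})

test_that("utilization matrix construction and released-novel tracking", {
  mat <- rbind(A = c("uptake", "uptake", "unchanged"),
               B = c("unchanged", "uptake", "release"))
  colnames(mat) <- c("1", "2", "3")
  cons <- consensus_from_matrix(mat)
  # an extra non-abundant metabolite released by A
  cons <- rbind(cons, data.frame(
    isolate_id = "A", metabolite_id = "9", call = "release",
    p_value = 0.001, fold_change = Inf, flags = "novel_release"))
  cons <- rbind(cons, data.frame(
    isolate_id = "B", metabolite_id = "9", call = "not_available",
    p_value = 0.9, fold_change = 1, flags = ""))
  um <- build_utilization_matrix(cons, c("1", "2", "3"), c("A", "B"))
  expect_identical(dim(um$calls), c(2L, 3L))
  expect_identical(um$denominator, 3L)
  expect_identical(um$released_novel, "9")

  expect_error(build_utilization_matrix(cons, c("1", "2", "4"),
                                        c("A", "B")), "missing")
  expect_error(build_utilization_matrix(cons, c("1"), character(0)),
               "empty isolate")
})

test_that("per-isolate fractions and matrix edge cases", {
  mat <- matrix("unchanged", 2, 10,
                dimnames = list(c("A", "B"), as.character(1:10)))
  mat["A", 1:4] <- "uptake"
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:10), c("A", "B"))
  fr <- per_isolate_fraction(um)
  expect_equal(unname(fr["A"]), 0.4)
  expect_equal(unname(fr["B"]), 0)
})

test_that("shared-use distribution counts and conserves", {
  mat <- rbind(A = c("unchanged", "uptake", "uptake"),
               B = c("unchanged", "uptake", "uptake"))
  colnames(mat) <- as.character(1:3)
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:3), c("A", "B"))
  sh <- shared_use_distribution(um)
  expect_identical(unname(sh$histogram), c(1L, 0L, 2L))
  expect_identical(sum(sh$histogram), um$denominator)
  expect_identical(unname(sh$cumulative["1"]), 2L)
})

test_that("competition and cross-feeding sets follow their definitions", {
  mat <- rbind(A = c("uptake", "uptake", "release", "unchanged"),
               B = c("uptake", "uptake", "uptake", "unchanged"),
               C = c("unchanged", "release", "unchanged", "unchanged"))
  colnames(mat) <- as.character(1:4)
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:4), c("A", "B", "C"))
  expect_identical(competition_candidates(um), "1")
  expect_setequal(crossfeeding_candidates(um), c("2", "3"))
  expect_length(intersect(competition_candidates(um),
                          crossfeeding_candidates(um)), 0L)
})

test_that("disjointness and conservation hold on random matrices", {
  set.seed(51)
  for (rep in 1:20) {
    n_iso <- sample(2:6, 1L)
    n_met <- sample(5:40, 1L)
    mat <- matrix(sample(c("uptake", "release", "unchanged",
                           "not_available"),
                         n_iso * n_met, replace = TRUE,
                         prob = c(0.3, 0.15, 0.45, 0.1)),
                  n_iso, n_met,
                  dimnames = list(paste0("i", seq_len(n_iso)),
                                  as.character(seq_len(n_met))))
    um <- build_utilization_matrix(consensus_from_matrix(mat),
                                   colnames(mat), rownames(mat))
    sh <- shared_use_distribution(um)
    expect_identical(sum(sh$histogram), um$denominator)
    expect_length(intersect(competition_candidates(um),
                            crossfeeding_candidates(um)), 0L)
    j <- pairwise_overlap(um, "jaccard")
    s <- pairwise_overlap(um, "simpson")
    expect_true(all(j >= 0 & j <= 1))
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(s - j >= -1e-12))
    expect_equal(j, t(j))
  }
})

test_that("overlap values match hand-computed examples", {
  mat <- rbind(A = c("uptake", "uptake", "uptake", "unchanged"),
               B = c("unchanged", "unchanged", "uptake", "uptake"))
  colnames(mat) <- as.character(1:4)
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:4), c("A", "B"))
  j <- pairwise_overlap(um, "jaccard")
  expect_equal(j["A", "B"], 0.25)  # {1,2,3} vs {3,4}
  expect_equal(j["A", "A"], 1)
  s <- pairwise_overlap(um, "simpson")
  expect_equal(s["A", "B"], 0.5)   # 1 / min(3, 2)

  # disjoint and empty sets
  mat2 <- rbind(A = c("uptake", "unchanged"),
                B = c("unchanged", "uptake"),
                C = c("unchanged", "unchanged"))
  colnames(mat2) <- as.character(1:2)
  um2 <- build_utilization_matrix(consensus_from_matrix(mat2),
                                  as.character(1:2), c("A", "B", "C"))
  j2 <- pairwise_overlap(um2, "jaccard")
  expect_equal(j2["A", "B"], 0)
  expect_equal(j2["C", "C"], 0)  # empty uptake set
})

test_that("bipartite export conserves edge counts and writes GraphML", {
  mat <- rbind(A = c("uptake", "release"),
               B = c("not_available", "unchanged"))
  colnames(mat) <- as.character(1:2)
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:2), c("A", "B"))
  path <- withr::local_tempfile(fileext = ".graphml")
  bp <- export_bipartite(um, path = path)
  expect_identical(nrow(bp$edges), 2L)
  expect_setequal(bp$edges$type, c("utilization", "release"))
  expect_equal(igraph::ecount(bp$graph), 2)
  expect_true(file.exists(path) && file.size(path) > 0)

  # all not_available -> zero edges
  mat2 <- matrix("not_available", 2, 2,
                 dimnames = list(c("A", "B"), as.character(1:2)))
  um2 <- build_utilization_matrix(consensus_from_matrix(mat2),
                                  as.character(1:2), c("A", "B"))
  expect_identical(nrow(export_bipartite(um2)$edges), 0L)
})

test_that("edge count equals uptake plus release cells on synthetic runs", {
  cfg <- synthetic_config(n_metabolites = 40L, n_abundant = 32L,
                          n_isolates = 3L, seed = 52L)
  sim <- generate_experiment(cfg)
  um <- truth_utilization_matrix(sim$truth)
  bp <- export_bipartite(um)
  expect_identical(nrow(bp$edges),
                   sum(um$calls %in% c("uptake", "release")))
})
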
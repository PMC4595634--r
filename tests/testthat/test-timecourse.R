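sw_meta <- function(tps = c(3, 540, 1080), n_rep = 8L) {
  do.call(rbind, lapply(tps, function(tp) {
    data.frame(sample_id = sprintf("sw_t%d_r%d", tp, seq_len(n_rep)),
               role = "soil_water", isolate_id = NA_character_,
               medium_id = NA_character_,
               control_group_id = NA_character_, timepoint = tp,
               replicate_index = seq_len(n_rep),
               stringsAsFactors = FALSE)
  }))
}

test_that("strong depletion and flat profiles are called correctly", {
  meta <- sw_meta()
  t0 <- c(9000, 10000, 11000, 10000, 9000, 10000, 11000, 10000)
  t18 <- c(1000, 1200, 900, 1100, 1000, 800, 1200, 1000)
  abund <- rbind(dep = c(t0, t0 * 0.6, t18),
                 flat = c(t0, t0, t0))
  colnames(abund) <- meta$sample_id
  res <- timepoint_trend(abund, meta)
  expect_identical(res$table$trend,
                   c("depleted", "flat"))
  expect_lt(res$table$p_value[1L], 0.001)
  expect_identical(res$t_first, 3)
  expect_identical(res$t_last, 1080)
})

test_that("dilution correction with factor 1 is the identity", {
  meta <- sw_meta()
  set.seed(71)
  abund <- matrix(10^runif(20, 3, 5) * exp(rnorm(20 * 24, 0, 0.25)),
                  nrow = 20,
                  dimnames = list(sprintf("m%02d", 1:20),
                                  meta$sample_id))
  a <- timepoint_trend(abund, meta, dilution_factor = 1)
  b <- timepoint_trend(abund, meta)
  expect_identical(a$table, b$table)
  expect_false(a$dilution_corrected)
  # a factor can flip a borderline depletion
  c2 <- timepoint_trend(abund, meta, dilution_factor = 1.8)
  expect_true(c2$dilution_corrected)
})

test_that("trend calls partition the metabolite set and obey direction", {
  cfg <- synthetic_config(n_soil_metabolites = 120L, n_depleted = 25L,
                          n_accumulated = 5L, seed = 72L)
  tc <- generate_timecourse(cfg)
  res <- timepoint_trend(tc$abundance, tc$meta)
  expect_identical(nrow(res$table), 120L)
  expect_identical(sum(table(res$table$trend)), 120L)
  first_col <- paste0("mean_t", res$t_first)
  last_col <- paste0("mean_t", res$t_last)
  dep <- res$table[res$table$trend == "depleted", ]
  expect_true(all(dep[[last_col]] < dep[[first_col]]))
  acc <- res$table[res$table$trend == "accumulated", ]
  expect_true(all(acc[[last_col]] > acc[[first_col]]))
})

test_that("planted depleted set size is recovered", {
  cfg <- synthetic_config(seed = 73L)  # 400 metabolites, 65 depleted
  tc <- generate_timecourse(cfg)
  res <- timepoint_trend(tc$abundance, tc$meta)
  n_dep <- sum(res$table$trend == "depleted")
  expect_gte(n_dep, 55L)
  expect_lte(n_dep, 75L)
  planted <- tc$truth$metabolite_id[tc$truth$trend == "depleted"]
  called <- res$table$metabolite_id[res$table$trend == "depleted"]
  expect_gte(length(intersect(called, planted)) / length(planted),
             0.95)
})

test_that("missing timepoints are rejected", {
  meta <- sw_meta(tps = c(3, 1080))
  abund <- matrix(1000, 2, nrow(meta),
                  dimnames = list(c("a", "b"), meta$sample_id))
  expect_error(timepoint_trend(abund, meta, t_first = 3, t_last = 540),
               "missing timepoint")
})

test_that("cross-experiment matching pairs by mz/rt/polarity", {
  a <- data.frame(metabolite_id = c("s1", "s2", "s3"),
                  mz = c(100.05, 200.10, 300.15),
                  rt = c(5, 10, 15),
                  polarity = c("positive", "positive", "negative"),
                  stringsAsFactors = FALSE)
  b <- data.frame(metabolite_id = c("e1", "e2", "e3", "e4"),
                  mz = c(100.051, 200.30, 300.151, 300.152),
                  rt = c(5.1, 10, 15.05, 15.08),
                  polarity = c("positive", "positive", "negative",
                               "negative"),
                  stringsAsFactors = FALSE)
  mp <- match_metabolites(a, b, mz_tol = 0.02, rt_tol = 0.3)
  expect_identical(mp$id_b[mp$id_a == "s1"], "e1")
  expect_false("s2" %in% mp$id_a)  # 0.2 Da off
  amb <- mp[mp$id_a == "s3", ]
  expect_identical(amb$id_b, "e3")  # nearest m/z wins
  expect_identical(amb$flags, "ambiguous_match")
})

test_that("unused-but-depleted cross-references trend with the matrix", {
  mat <- rbind(A = c("unchanged", "uptake", "unchanged"),
               B = c("unchanged", "unchanged", "release"))
  colnames(mat) <- as.character(1:3)
  um <- build_utilization_matrix(consensus_from_matrix(mat),
                                 as.character(1:3), c("A", "B"))
  trend <- structure(list(table = data.frame(
    metabolite_id = c("s1", "s2", "s3"),
    p_value = c(0.001, 0.002, 0.3),
    trend = c("depleted", "depleted", "flat"),
    stringsAsFactors = FALSE)), class = "timecourse_result")
  mapping <- data.frame(id_a = c("s1", "s2", "s3"),
                        id_b = c("1", "2", "3"),
                        d_mz = 0, d_rt = 0, flags = "",
                        stringsAsFactors = FALSE)
  got <- unused_but_depleted(trend, um, mapping)
  # s1 -> column 1 (no uptake): in; s2 -> column 2 (uptake by A): out;
  # s3 flat: out
  expect_identical(got$soil_id, "s1")
  expect_identical(got$experiment_id, "1")
})

test_that("order-of-magnitude comparability is computed correctly", {
  media_meta <- make_meta(n_iso = 1L)
  media_ab <- matrix(c(1000, 5000, 100), 3, nrow(media_meta),
                     dimnames = list(c("1", "2", "3"),
                                     media_meta$sample_id))
  soil_meta <- sw_meta(n_rep = 2L)
  soil_ab <- matrix(c(1000, 40000, 100000), 3, nrow(soil_meta),
                    dimnames = list(c("s1", "s2", "s3"),
                                    soil_meta$sample_id))
  mapping <- data.frame(id_a = c("1", "2", "3"),
                        id_b = c("s1", "s2", "s3"),
                        d_mz = 0, d_rt = 0, flags = "",
                        stringsAsFactors = FALSE)
  got <- media_vs_soilwater_comparability(media_ab, media_meta,
                                          soil_ab, soil_meta, mapping)
  expect_equal(got$table$log10_ratio[1L], 0)
  expect_equal(got$table$log10_ratio[2L], log10(5000 / 40000))
  # 1.0, 0.90, 3.0 -> two of three within one order
  expect_equal(got$fraction_within_order, 2 / 3)
})
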
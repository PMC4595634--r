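test_that("abundance filter applies a strict any-sample threshold", {
  meta <- make_meta(n_iso = 1L)
  abund <- rbind(
    m1 = c(4999, 4998, 4500, 0, 0, 0),
    m2 = c(0, 0, 6000, 0, 0, 0),
    m3 = c(5000, 100, 100, 9999, 9999, 9999)
  )
  colnames(abund) <- meta$sample_id
  got <- filter_abundant(abund, meta, min_area = 5000)
  expect_setequal(got, c("m2", "m3"))  # m1 just misses; spent ignored
  expect_error(
    filter_abundant(abund, meta[meta$role != "control", ]),
    "control")
})

test_that("planted abundant set is recovered exactly from truth areas", {
  cfg <- synthetic_config(n_metabolites = 60L, n_abundant = 45L,
                          n_isolates = 3L, seed = 31L)
  sim <- generate_experiment(cfg)
  # characteristic-ion areas straight from the planted envelope
  prim <- sim$truth$features[sim$truth$features$rel_abund == 1, ]
  abund <- sim$feature_table$intensities[prim$feature_id, , drop = FALSE]
  rownames(abund) <- as.character(prim$metabolite)
  got <- filter_abundant(abund, sim$meta, min_area = 5000)
  planted <- as.character(
    sim$truth$metabolites$metabolite[sim$truth$metabolites$abundant])
  expect_setequal(got, planted)
})

test_that("pooled t-test matches the closed form and is symmetric", {
  expect_equal(two_sample_t(c(10, 11, 9), c(10, 11, 9))$p.value, 1,
               tolerance = 1e-12)
  r <- two_sample_t(c(10000, 11000, 9000), c(100, 120, 90))
  o <- oracle_t(c(10000, 11000, 9000), c(100, 120, 90))
  expect_lt(r$p.value, 0.001)
  expect_equal(r$p.value, o$p.value, tolerance = 1e-10)
  a <- two_sample_t(c(5, 6), c(5.5, 6.5))
  b <- two_sample_t(c(5.5, 6.5), c(5, 6))
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
})

test_that("t-test agrees with independent computations on random draws", {
  set.seed(41)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1L), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1L), mean = runif(1, -2, 2))
    r <- two_sample_t(a, b)
    o <- oracle_t(a, b)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(r$p.value, o$p.value, tolerance = 1e-10)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(r$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance inputs are handled explicitly", {
  eq <- two_sample_t(c(5, 5, 5), c(5, 5, 5))
  expect_identical(eq$p.value, 1)
  expect_true(eq$degenerate)
  ne <- two_sample_t(c(5, 5, 5), c(7, 7, 7))
  expect_identical(ne$p.value, 0)
  expect_true(ne$degenerate)
})

test_that("utilization calls follow the decision rule", {
  meta <- make_meta(n_iso = 1L)
  mk_abund <- function(ctrl, spent) {
    m <- matrix(c(ctrl, spent), nrow = 1,
                dimnames = list("m1", meta$sample_id))
    m
  }
  up <- classify_utilization("m1", "iso1", "m1",
                             mk_abund(c(10000, 11000, 9000),
                                      c(100, 120, 90)), meta)
  expect_identical(up$call, "uptake")
  expect_identical(up$tier, "***")
  expect_lt(up$fold_change, 1)

  rel <- classify_utilization("m1", "iso1", "m1",
                              mk_abund(c(0, 0, 0),
                                       c(8000, 9000, 7000)), meta)
  expect_identical(rel$call, "release")
  expect_true(grepl("novel_release", rel$flags))
  expect_identical(rel$fold_change, Inf)

  un <- classify_utilization("m1", "iso1", "m1",
                             mk_abund(c(10000, 11000, 9000),
                                      c(9500, 10500, 9800)), meta)
  expect_identical(un$call, "unchanged")

  na <- classify_utilization("m1", "iso1", "m1",
                             mk_abund(c(100, 120, 90),
                                      c(110, 100, 95)), meta)
  expect_identical(na$call, "not_available")
})

test_that("calls never violate their direction invariants", {
  cfg <- synthetic_config(n_metabolites = 50L, n_abundant = 40L,
                          n_isolates = 3L, seed = 32L)
  sim <- generate_experiment(cfg)
  res <- resolve_metabolites(sim$feature_table)
  calls <- classify_all(res$abundance, sim$meta)
  up <- calls[calls$call == "uptake", ]
  expect_true(all(up$mean_spent < up$mean_control))
  expect_true(all(up$p_value < 0.05))
  rel <- calls[calls$call == "release" &
                 !grepl("novel_release", calls$flags), ]
  expect_true(all(rel$mean_spent > rel$mean_control))
  expect_true(all(rel$p_value < 0.05))
})

test_that("raising alpha never demotes a directional call", {
  meta <- make_meta(n_iso = 1L)
  set.seed(43)
  abund <- matrix(10^runif(60, 3, 5) * exp(rnorm(60 * 6, 0, 0.4)),
                  nrow = 60,
                  dimnames = list(sprintf("m%02d", 1:60),
                                  meta$sample_id))
  lo <- classify_all(abund, meta, alpha = 0.01, min_area = 0)
  hi <- classify_all(abund, meta, alpha = 0.10, min_area = 0)
  directional <- lo$call %in% c("uptake", "release")
  expect_identical(lo$call[directional], hi$call[directional])
})

test_that("consensus across media follows the combination rules", {
  base <- data.frame(
    isolate_id = "iso1", metabolite_id = "m1",
    medium_id = c("a", "b"), p_value = c(0.001, 0.5),
    fold_change = c(0.2, 1.0), mean_control = 1, mean_spent = 1,
    tier = "*", flags = "", stringsAsFactors = FALSE)

  x <- base; x$call <- c("uptake", "unchanged")
  expect_identical(combine_across_media(x)$call, "uptake")

  y <- base; y$call <- c("uptake", "release")
  y$p_value <- c(0.01, 0.04)
  got <- combine_across_media(y)
  expect_identical(got$call, "uptake")
  expect_true(grepl("conflict", got$flags))

  z <- base; z$call <- c("not_available", "release")
  z$p_value <- c(0.9, 0.002)
  expect_identical(combine_across_media(z)$call, "release")

  w <- base; w$call <- c("not_available", "not_available")
  expect_identical(combine_across_media(w)$call, "not_available")

  expect_error(combine_across_media(base[0, ]), "empty")
})

test_that("classification recovers planted classes on a small experiment", {
  cfg <- synthetic_config(n_metabolites = 120L, n_abundant = 95L,
                          n_isolates = 4L, seed = 33L)
  sim <- generate_experiment(cfg)
  res <- resolve_metabolites(sim$feature_table)
  calls <- classify_all(res$abundance, sim$meta)
  rec <- evaluate_recovery(calls, res$metabolites, sim$truth)
  expect_gte(rec$sensitivity_uptake, 0.8)
  expect_gte(rec$sensitivity_release, 0.8)
  expect_lte(rec$fpr_unchanged, 0.08)
})
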
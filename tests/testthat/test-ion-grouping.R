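test_that("proportional co-eluting features group; distant RT splits", {
  ft <- make_ft(
    list(mz = 300.1, rt = 10.0, intensities = c(1000, 2000, 3000)),
    list(mz = 322.1, rt = 10.1, intensities = c(100, 200, 300))
  )
  g <- group_coeluting_features(ft, rt_tol = 0.3, corr_min = 0.9)
  expect_length(g$groups, 1L)
  expect_setequal(g$groups[[1L]]$feature_ids, c("f01", "f02"))

  ft2 <- make_ft(
    list(mz = 300.1, rt = 10.0, intensities = c(1000, 2000, 3000)),
    list(mz = 322.1, rt = 12.0, intensities = c(100, 200, 300))
  )
  g2 <- group_coeluting_features(ft2, rt_tol = 0.3, corr_min = 0.9)
  expect_length(g2$groups, 2L)
})

test_that("polarity and correlation gates block grouping", {
  ft <- make_ft(
    list(mz = 300.1, rt = 10.0, intensities = c(1000, 2000, 3000)),
    list(mz = 298.1, rt = 10.0, polarity = "negative",
         intensities = c(100, 200, 300)),
    list(mz = 310.1, rt = 10.0, intensities = c(3000, 2000, 1000))
  )
  g <- group_coeluting_features(ft, rt_tol = 0.3, corr_min = 0.9)
  expect_length(g$groups, 3L)  # opposite polarity; anti-correlated
})

test_that("all-zero features become flagged singletons", {
  ft <- make_ft(
    list(mz = 300.1, rt = 10.0, intensities = c(1000, 2000, 3000)),
    list(mz = 301.1, rt = 10.0, intensities = c(0, 0, 0))
  )
  g <- group_coeluting_features(ft)
  expect_length(g$groups, 2L)
  zero_grp <- Filter(function(x) "all_zero" %in% x$flags, g$groups)
  expect_length(zero_grp, 1L)
  expect_identical(zero_grp[[1L]]$feature_ids, "f02")
})

test_that("grouping equals brute-force closure on planted envelopes", {
  # 12 features from 4 planted metabolites, 3 adducts each, CV 5%
  set.seed(21)
  specs <- list()
  for (m in 1:4) {
    base <- 10^runif(1, 3, 5) * exp(rnorm(8, 0, 0.5))
    rt <- runif(1, 2, 28)
    for (a in 1:3) {
      rel <- c(1, 0.4, 0.1)[a]
      specs[[length(specs) + 1L]] <- list(
        mz = 100 * m + c(0, 21.98, 17.03)[a],
        rt = rt + rnorm(1, 0, 0.02),
        intensities = base * rel * exp(rnorm(8, 0, 0.05)))
    }
  }
  ft <- do.call(make_ft, specs)
  g <- group_coeluting_features(ft, rt_tol = 0.3, corr_min = 0.9)
  expect_identical(partition_of(g),
                   oracle_group(ft, rt_tol = 0.3, corr_min = 0.9))
  expect_length(g$groups, 4L)
})

test_that("grouping matches the oracle on random small instances", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(3:20, 1L)
    specs <- lapply(seq_len(n), function(i) {
      list(mz = runif(1, 80, 900),
           rt = runif(1, 0, 6),
           polarity = sample(c("positive", "negative"), 1L),
           intensities = round(10^runif(1, 2, 5) *
                                 exp(rnorm(6, 0, runif(1, 0.05, 1)))) *
             rbinom(6, 1, 0.9))
    })
    ft <- do.call(make_ft, specs)
    rt_tol <- runif(1, 0.2, 1.5)
    corr_min <- runif(1, 0.5, 0.99)
    g <- group_coeluting_features(ft, rt_tol, corr_min)
    expect_identical(partition_of(g), oracle_group(ft, rt_tol, corr_min))
    # partition property
    expect_setequal(unlist(lapply(g$groups, `[[`, "feature_ids")),
                    ft$features$feature_id)
    expect_identical(sum(lengths(lapply(g$groups, `[[`,
                                        "feature_ids"))),
                     n_features(ft))
  }
})

test_that("grouping is invariant to input row order", {
  set.seed(23)
  specs <- lapply(1:10, function(i) {
    list(mz = runif(1, 80, 500), rt = runif(1, 0, 3),
         intensities = 10^runif(1, 2, 5) * exp(rnorm(5, 0, 0.3)))
  })
  ft <- do.call(make_ft, specs)
  perm <- sample(nrow(ft$features))
  ft2 <- feature_table(ft$features[perm, ],
                       ft$intensities[perm, , drop = FALSE])
  g1 <- group_coeluting_features(ft)
  g2 <- group_coeluting_features(ft2)
  expect_identical(partition_of(g1), partition_of(g2))
})

test_that("ion-type assignment recovers neutral mass from adduct pairs", {
  # protonated + ammoniated molecule, 17.0265 Da apart
  g <- assign_ion_types(make_group(c(a = 331.1445, b = 348.1710)))
  expect_equal(g$neutral_mass, 330.1372, tolerance = 2e-4)
  expect_identical(unname(g$ion_annotations[c("a", "b")]),
                   c("[M+H]+", "[M+NH4]+"))

  # single protonated ion
  g1 <- assign_ion_types(make_group(c(a = 330.1445)))
  expect_equal(g1$neutral_mass, 329.1372, tolerance = 2e-4)

  # monomer + proton-bound dimer of a hexose-mass molecule
  g2 <- assign_ion_types(make_group(c(a = 181.0707, b = 361.1341)))
  expect_equal(g2$neutral_mass, 180.0634, tolerance = 2e-4)
  expect_identical(unname(g2$ion_annotations[c("a", "b")]),
                   c("[M+H]+", "[2M+H]+"))
})

test_that("negative mode uses its own rules", {
  g <- assign_ion_types(make_group(c(a = 146.0459), polarity = "negative"))
  expect_identical(unname(g$ion_annotations[["a"]]), "[M-H]-")
  expect_equal(g$neutral_mass, 147.0532, tolerance = 2e-4)
})

test_that("unexplained co-eluting members become fragments or isotopes", {
  g <- assign_ion_types(make_group(c(a = 181.0707, b = 182.0741,
                                     c = 163.0601)))
  expect_identical(unname(g$ion_annotations[["a"]]), "[M+H]+")
  expect_identical(unname(g$ion_annotations[["b"]]), "isotope (M+1)")
  expect_identical(unname(g$ion_annotations[["c"]]),
                   "unassigned fragment")
})

test_that("round trip: planted adduct envelopes recover the mass exactly", {
  rules <- default_adduct_rules()
  set.seed(24)
  for (rep in 1:20) {
    M <- runif(1, 80, 900)
    pol <- sample(c("positive", "negative"), 1L)
    rr <- rules[rules$polarity == pol, ]
    take <- rr[sample(nrow(rr), sample(2:nrow(rr), 1L)), ]
    mzs <- (take$multiplicity * M + take$mass_shift) / take$charge
    names(mzs) <- sprintf("f%02d", seq_along(mzs))
    g <- assign_ion_types(make_group(mzs, polarity = pol))
    expect_lt(abs(g$neutral_mass - M), 1e-9)
    expect_true(all(g$ion_annotations %in% take$name))
  }
})

test_that("characteristic ion selection prefers intense primary adducts", {
  ft <- make_ft(
    list(mz = 181.0707, rt = 5, intensities = rep(10000, 4)),
    list(mz = 198.0972, rt = 5, intensities = rep(2000, 4))
  )
  g <- assign_ion_types(make_group(c(f01 = 181.0707, f02 = 198.0972)))
  expect_identical(select_characteristic_ion(g, ft), "f01")

  # fallback: no primary annotations -> highest median overall
  ft2 <- make_ft(
    list(mz = 200.1, rt = 5, intensities = rep(500, 4)),
    list(mz = 300.2, rt = 5, intensities = rep(700, 4))
  )
  g2 <- make_group(c(f01 = 200.1, f02 = 300.2),
                   annotations = c(f01 = "unassigned fragment",
                                   f02 = "unassigned fragment"))
  expect_identical(select_characteristic_ion(g2, ft2), "f02")

  # exact tie -> lower m/z
  ft3 <- make_ft(
    list(mz = 300.2, rt = 5, intensities = rep(5000, 4)),
    list(mz = 200.1, rt = 5, intensities = rep(5000, 4))
  )
  g3 <- make_group(c(f01 = 300.2, f02 = 200.1),
                   annotations = c(f01 = "unassigned fragment",
                                   f02 = "unassigned fragment"))
  expect_identical(select_characteristic_ion(g3, ft3), "f02")
})

test_that("polarity merge obeys mass and RT gates", {
  mk <- function(id, pol, M, rt, mz, cid) {
    g <- make_group(stats::setNames(mz, cid), polarity = pol, rt = rt)
    g$group_id <- id
    g$neutral_mass <- M
    g$characteristic_feature_id <- cid
    g
  }
  ft <- make_ft(
    list(mz = 148.0604, rt = 8.0, intensities = rep(1e4, 3)),
    list(mz = 146.0459, rt = 8.05, polarity = "negative",
         intensities = rep(5e3, 3))
  )
  gl <- structure(list(groups = list(
    mk("G1", "positive", 147.0532, 8.0, 148.0604, "f01"),
    mk("G2", "negative", 147.0531, 8.05, 146.0459, "f02")
  ), assignments = NULL), class = "ion_groups")
  recs <- merge_polarities(gl, ft, mass_tol = 0.005, rt_tol = 0.3)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$n_member_ions, 2L)
  expect_identical(recs$source_groups, "G1,G2")

  # same masses but 1 min apart: no merge
  gl2 <- structure(list(groups = list(
    mk("G1", "positive", 147.0532, 8.0, 148.0604, "f01"),
    mk("G2", "negative", 147.0531, 9.0, 146.0459, "f02")
  ), assignments = NULL), class = "ion_groups")
  expect_identical(nrow(merge_polarities(gl2, ft)), 2L)

  # pairwise-distinct masses: N records
  gl3 <- structure(list(groups = list(
    mk("G1", "positive", 147.0532, 8.0, 148.0604, "f01"),
    mk("G2", "negative", 199.9, 8.0, 146.0459, "f02")
  ), assignments = NULL), class = "ion_groups")
  expect_identical(nrow(merge_polarities(gl3, ft)), 2L)
})

test_that("resolution assigns each feature to exactly one metabolite", {
  cfg <- synthetic_config(n_metabolites = 30L, n_abundant = 24L,
                          n_isolates = 3L, seed = 5L)
  sim <- generate_experiment(cfg)
  res <- resolve_metabolites(sim$feature_table)
  counted <- sum(lengths(lapply(res$groups$groups, `[[`,
                                "feature_ids")))
  expect_identical(counted, n_features(sim$feature_table))
  expect_identical(anyDuplicated(res$groups$assignments$feature_id), 0L)
  expect_identical(rownames(res$abundance),
                   as.character(res$metabolites$metabolite_id))
})
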
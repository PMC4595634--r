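# Synthetic exometabolomic experiments with planted ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# several hundred metabolites, each emitting a small envelope of
# adduct/multimer/isotopologue ion features with intensities correlated
# across samples; replicate media samples with multiplicative lognormal
# noise; an abundance structure that makes the availability filter bite;
# and planted per-isolate uptake/release classes with known effect
# multipliers, enabling recovery and calibration tests without any
# deposited data.

.ln_sigma <- function(cv) sqrt(log(1 + cv^2))

# mean-1 lognormal multiplier noise
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- .ln_sigma(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Configuration for the synthetic-experiment generator
#'
#' Defaults mirror the study design the pipeline targets: 470
#' metabolites of which 372 are abundant, 7 isolates, two supplemented
#' media with n = 3 replicate control and spent samples (the
#' longest-cultured isolate gets its own control set), per-isolate used
#' fractions of 13-35% of the abundant set with 40% of metabolites used
#' by nobody, lognormal replicate noise with CV 0.2, uptake effect
#' multipliers of 0.02-0.5 and release multipliers of 2-50, and a
#' soil-water wetting time course of 8 replicates at 3 min, 9 h and
#' 18 h with 65 of 400 metabolites depleted.
#'
#' @param n_metabolites Number of distinct metabolites.
#' @param n_abundant Number whose control areas exceed the availability
#'   threshold.
#' @param n_isolates Number of isolates (isolate 1 plays the
#'   long-culture phototroph and gets separate controls).
#' @param used_fraction_range Per-isolate planted used fraction range.
#' @param unused_fraction Fraction of abundant metabolites planted as
#'   used by no isolate.
#' @param release_fraction Per-isolate fraction of abundant metabolites
#'   planted as released.
#' @param novel_release_fraction Fraction of non-abundant metabolites
#'   released by some isolate.
#' @param n_rep_media Replicates per control group / spent condition.
#' @param n_rep_soil Replicates per soil-water timepoint.
#' @param noise_cv Replicate (per metabolite x sample) lognormal CV.
#' @param feature_cv Additional per-feature lognormal CV. Co-eluting
#'   ions of one metabolite share the replicate-level term, so their
#'   intensity correlation across samples is governed by
#'   noise_cv^2 / (noise_cv^2 + feature_cv^2).
#' @param soil_noise_cv Replicate CV of the soil-water time course.
#' @param uptake_mult_range Uptake multipliers (uniform draw, < 1).
#' @param release_mult_range Release multipliers (log-uniform, > 1).
#' @param n_soil_metabolites,n_depleted,n_accumulated Time-course
#'   composition.
#' @param depletion_factor_range,accumulation_factor_range Fold changes
#'   planted over the full time course (log-uniform).
#' @param timepoints_min Soil-water sampling timepoints, minutes after
#'   wetting.
#' @param abundant_area_range,low_area_range Log-uniform base-area
#'   ranges (counts) for abundant and non-abundant metabolites; chosen
#'   so replicate noise cannot carry a metabolite across the 5000-count
#'   availability threshold.
#' @param detection_floor Areas below this are reported as 0 (not
#'   detected).
#' @param mz_sigma_ppm Mass-accuracy noise on feature m/z (ppm).
#' @param rt_jitter_sd Retention-time jitter between co-eluting
#'   features (minutes).
#' @param both_polarity_prob Probability a metabolite is also detected
#'   in the opposite ionisation mode.
#' @param isotope_prob Probability the M+1 isotopologue feature is
#'   detected.
#' @param adducts Adduct rule table used to build ion envelopes.
#' @param seed Integer RNG seed; every generator output is a pure
#'   function of the config including this seed.
#' @return Validated config list of class `exoniche_config`.
#' @export
synthetic_config <- function(n_metabolites = 470L,
                             n_abundant = 372L,
                             n_isolates = 7L,
                             used_fraction_range = c(0.13, 0.35),
                             unused_fraction = 0.40,
                             release_fraction = 0.08,
                             novel_release_fraction = 0.10,
                             n_rep_media = 3L,
                             n_rep_soil = 8L,
                             noise_cv = 0.2,
                             feature_cv = 0.05,
                             soil_noise_cv = 0.25,
                             uptake_mult_range = c(0.02, 0.5),
                             release_mult_range = c(2, 50),
                             n_soil_metabolites = 400L,
                             n_depleted = 65L,
                             n_accumulated = 10L,
                             depletion_factor_range = c(5, 50),
                             accumulation_factor_range = c(3, 10),
                             timepoints_min = c(3, 540, 1080),
                             abundant_area_range = c(2e4, 1e6),
                             low_area_range = c(1e2, 2e3),
                             detection_floor = 100,
                             mz_sigma_ppm = 1,
                             rt_jitter_sd = 0.01,
                             both_polarity_prob = 0.3,
                             isotope_prob = 0.8,
                             adducts = default_adduct_rules(),
                             seed = 42L) {
  cfg <- list(
    n_metabolites = as.integer(n_metabolites),
    n_abundant = as.integer(n_abundant),
    n_isolates = as.integer(n_isolates),
    used_fraction_range = used_fraction_range,
    unused_fraction = unused_fraction,
    release_fraction = release_fraction,
    novel_release_fraction = novel_release_fraction,
    n_rep_media = as.integer(n_rep_media),
    n_rep_soil = as.integer(n_rep_soil),
    noise_cv = noise_cv, feature_cv = feature_cv,
    soil_noise_cv = soil_noise_cv,
    uptake_mult_range = uptake_mult_range,
    release_mult_range = release_mult_range,
    n_soil_metabolites = as.integer(n_soil_metabolites),
    n_depleted = as.integer(n_depleted),
    n_accumulated = as.integer(n_accumulated),
    depletion_factor_range = depletion_factor_range,
    accumulation_factor_range = accumulation_factor_range,
    timepoints_min = timepoints_min,
    abundant_area_range = abundant_area_range,
    low_area_range = low_area_range,
    detection_floor = detection_floor,
    mz_sigma_ppm = mz_sigma_ppm,
    rt_jitter_sd = rt_jitter_sd,
    both_polarity_prob = both_polarity_prob,
    isotope_prob = isotope_prob,
    adducts = adducts,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "exoniche_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_metabolites >= 1L,
            cfg$n_abundant >= 0L,
            cfg$n_abundant <= cfg$n_metabolites,
            cfg$n_isolates >= 1L,
            cfg$n_rep_media >= 2L, cfg$n_rep_soil >= 2L,
            cfg$noise_cv >= 0, cfg$feature_cv >= 0,
            all(cfg$used_fraction_range >= 0),
            all(cfg$used_fraction_range <= 1),
            diff(cfg$used_fraction_range) >= 0,
            cfg$unused_fraction >= 0, cfg$unused_fraction <= 1,
            all(cfg$uptake_mult_range < 1),
            all(cfg$uptake_mult_range > 0),
            all(cfg$release_mult_range > 1),
            cfg$n_depleted + cfg$n_accumulated <=
              cfg$n_soil_metabolites,
            length(cfg$timepoints_min) >= 2L,
            !is.unsorted(cfg$timepoints_min, strictly = TRUE))
  if (cfg$used_fraction_range[2L] > 1 - cfg$unused_fraction + 1e-12) {
    stop("infeasible config: per-isolate used fraction up to ",
         cfg$used_fraction_range[2L], " cannot be drawn from the ",
         1 - cfg$unused_fraction,
         " of metabolites allowed to be used by anyone")
  }
  validate_adduct_rules(cfg$adducts)
  invisible(cfg)
}

# random CHNO formula with mass in [80, 900] Da, integer RDBE >= 0
# (nitrogen rule) and element ratios inside the empirical plausibility
# ranges of natural products
.draw_formula <- function() {
  repeat {
    cc <- sample(4:30, 1L)
    nn <- sample(0:min(6L, floor(1.3 * cc)), 1L)
    oo <- sample(0:min(12L, floor(1.2 * cc)), 1L)
    hh <- sample(0:(2L * cc + 2L + nn), 1L)
    if ((hh + nn) %% 2L == 1L) hh <- if (hh > 0L) hh - 1L else hh + 1L
    counts <- c(C = cc, H = hh, N = nn, O = oo, P = 0L, S = 0L)
    m <- monoisotopic_mass(counts)
    if (m >= 80 && m <= 900) {
      return(list(counts = counts, mass = m,
                  formula = format_formula(counts)))
    }
  }
}

.rule_tag <- function(name) gsub("[^A-Za-z0-9]", "", name)

#' Generate a complete synthetic isolate experiment
#'
#' Produces a feature table, sample metadata and planted ground truth
#' for a two-medium exometabolomic experiment: per medium, control
#' groups (a standard one and a separate one for the long-cultured
#' isolate 1) and spent media for every isolate, all with
#' `n_rep_media` replicates. Each metabolite carries a CHNO formula,
#' retention time, ionisation mode and an ion envelope of 1-5 features
#' (characteristic adduct, optional further adducts/multimers, an M+1
#' isotopologue at the formula-implied ratio, and optionally the
#' primary adduct of the opposite mode). Spent-sample areas are the
#' medium base area times the planted class multiplier; all areas carry
#' shared replicate-level and per-feature lognormal noise and fall to 0
#' below the detection floor.
#'
#' @param config A [synthetic_config()].
#' @return List with `feature_table`, `meta` (sample metadata),
#'   `truth` (class `exoniche_truth`).
#' @export
generate_experiment <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_metabolites
  media <- c("medium_het", "medium_cyano")

  forms <- lapply(seq_len(n), function(i) .draw_formula())
  mets <- data.frame(
    metabolite = seq_len(n),
    formula = vapply(forms, `[[`, character(1L), "formula"),
    neutral_mass = vapply(forms, `[[`, numeric(1L), "mass"),
    rt = stats::runif(n, 1, 30),
    polarity = sample(c("positive", "negative"), n, replace = TRUE,
                      prob = c(0.6, 0.4)),
    abundant = FALSE,
    stringsAsFactors = FALSE
  )
  mets$abundant[sample.int(n, config$n_abundant)] <- TRUE
  base <- matrix(NA_real_, n, length(media),
                 dimnames = list(NULL, media))
  for (m in media) {
    lo <- ifelse(mets$abundant, config$abundant_area_range[1L],
                 config$low_area_range[1L])
    hi <- ifelse(mets$abundant, config$abundant_area_range[2L],
                 config$low_area_range[2L])
    base[, m] <- 10^stats::runif(n, log10(lo), log10(hi))
  }

  # planted classes: isolates x metabolites, identical across media
  class_mat <- matrix("unchanged", config$n_isolates, n)
  mult_mat <- matrix(1, config$n_isolates, n)
  ab_idx <- which(mets$abundant)
  n_ab <- length(ab_idx)
  unused <- sample(ab_idx, round(config$unused_fraction * n_ab))
  usable <- setdiff(ab_idx, unused)
  used_frac <- stats::runif(config$n_isolates,
                            config$used_fraction_range[1L],
                            config$used_fraction_range[2L])
  for (i in seq_len(config$n_isolates)) {
    n_up <- min(round(used_frac[i] * n_ab), length(usable))
    up <- sample(usable, n_up)
    class_mat[i, up] <- "uptake"
    mult_mat[i, up] <- stats::runif(n_up, config$uptake_mult_range[1L],
                                    config$uptake_mult_range[2L])
    pool <- setdiff(ab_idx, up)
    n_rel <- min(round(config$release_fraction * n_ab), length(pool))
    rel <- sample(pool, n_rel)
    class_mat[i, rel] <- "release"
    mult_mat[i, rel] <- exp(stats::runif(
      n_rel, log(config$release_mult_range[1L]),
      log(config$release_mult_range[2L])))
  }
  low_idx <- which(!mets$abundant)
  n_novel <- round(config$novel_release_fraction * length(low_idx))
  novel <- if (n_novel > 0) sample(low_idx, n_novel) else integer(0)
  for (m_i in novel) {
    who <- sample.int(config$n_isolates, sample(1:3, 1L))
    class_mat[who, m_i] <- "release"
    # released into a medium where the metabolite is near-absent:
    # multiplier lifts the low base well past the detection threshold
    mult_mat[who, m_i] <- 10^stats::runif(length(who), 1.5, 3)
  }

  # ion envelopes
  rules <- config$adducts
  primary_of <- function(pol) {
    rules[rules$polarity == pol & rules$primary, , drop = FALSE][1L, ]
  }
  feat_rows <- list()
  for (i in seq_len(n)) {
    pol <- mets$polarity[i]
    pr <- primary_of(pol)
    env <- data.frame(metabolite = i, ion_type = pr$name,
                      polarity = pol, rel_abund = 1,
                      mz_theory = (pr$multiplicity * mets$neutral_mass[i] +
                                     pr$mass_shift) / pr$charge,
                      stringsAsFactors = FALSE)
    extras <- rules[rules$polarity == pol & !rules$primary |
                      (rules$polarity == pol & rules$primary &
                         rules$name != pr$name), , drop = FALSE]
    n_extra <- sample(0:min(2L, nrow(extras)), 1L)
    if (n_extra > 0) {
      ex <- extras[sample.int(nrow(extras), n_extra), , drop = FALSE]
      env <- rbind(env, data.frame(
        metabolite = i, ion_type = ex$name, polarity = pol,
        rel_abund = stats::runif(n_extra, 0.05, 0.5),
        mz_theory = (ex$multiplicity * mets$neutral_mass[i] +
                       ex$mass_shift) / ex$charge,
        stringsAsFactors = FALSE))
    }
    if (stats::runif(1) < config$isotope_prob) {
      counts <- parse_formula(mets$formula[i])
      env <- rbind(env, data.frame(
        metabolite = i, ion_type = "isotope (M+1)", polarity = pol,
        rel_abund = predict_m1_ratio(counts),
        mz_theory = env$mz_theory[1L] + .C13_SHIFT,
        stringsAsFactors = FALSE))
    }
    if (nrow(env) < 5L &&
        stats::runif(1) < config$both_polarity_prob) {
      opp <- setdiff(c("positive", "negative"), pol)
      po <- primary_of(opp)
      env <- rbind(env, data.frame(
        metabolite = i, ion_type = po$name, polarity = opp,
        rel_abund = stats::runif(1, 0.2, 0.8),
        mz_theory = (po$multiplicity * mets$neutral_mass[i] +
                       po$mass_shift) / po$charge,
        stringsAsFactors = FALSE))
    }
    feat_rows[[i]] <- env
  }
  feats <- do.call(rbind, feat_rows)
  feats$feature_id <- sprintf("F%04d_%s", feats$metabolite,
                              vapply(feats$ion_type, .rule_tag,
                                     character(1L)))
  feats$feature_id <- make.unique(feats$feature_id, sep = "_")
  feats$mz <- feats$mz_theory *
    (1 + stats::rnorm(nrow(feats), 0, config$mz_sigma_ppm * 1e-6))
  feats$rt <- mets$rt[feats$metabolite] +
    stats::rnorm(nrow(feats), 0, config$rt_jitter_sd)
  feats$rt <- pmax(feats$rt, 0)

  # sample metadata
  meta_rows <- list()
  iso_ids <- sprintf("iso%02d", seq_len(config$n_isolates))
  for (m in media) {
    for (grp in c("std", "long")) {
      gid <- paste("ctrl", m, grp, sep = "_")
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", gid, seq_len(config$n_rep_media)),
        role = "control", isolate_id = NA_character_, medium_id = m,
        control_group_id = gid, timepoint = NA_real_,
        replicate_index = seq_len(config$n_rep_media),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$n_isolates)) {
      gid <- paste("ctrl", m, if (i == 1L) "long" else "std",
                   sep = "_")
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = sprintf("sp_%s_%s_r%d", m, iso_ids[i],
                            seq_len(config$n_rep_media)),
        role = "spent", isolate_id = iso_ids[i], medium_id = m,
        control_group_id = gid, timepoint = NA_real_,
        replicate_index = seq_len(config$n_rep_media),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL

  # expected metabolite amount per sample, then feature intensities
  amount <- matrix(NA_real_, n, nrow(meta),
                   dimnames = list(NULL, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    b <- base[, meta$medium_id[s]]
    if (meta$role[s] == "spent") {
      i <- match(meta$isolate_id[s], iso_ids)
      b <- b * mult_mat[i, ]
    }
    amount[, s] <- b
  }
  shared <- matrix(.ln_noise(length(amount), config$noise_cv),
                   nrow = n)
  amount <- amount * shared
  intens <- amount[feats$metabolite, , drop = FALSE] *
    feats$rel_abund *
    matrix(.ln_noise(nrow(feats) * nrow(meta), config$feature_cv),
           nrow = nrow(feats))
  intens[intens < config$detection_floor] <- 0
  rownames(intens) <- feats$feature_id

  ft <- feature_table(
    feats[, c("feature_id", "mz", "rt", "polarity")], intens)

  classes <- do.call(rbind, lapply(media, function(m) {
    data.frame(
      isolate_id = rep(iso_ids, times = n),
      metabolite = rep(seq_len(n), each = config$n_isolates),
      medium_id = m,
      class = as.vector(class_mat),
      multiplier = as.vector(mult_mat),
      stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  truth_mets <- cbind(mets, as.data.frame(base))
  names(truth_mets)[names(truth_mets) %in% media] <-
    paste0("base_", media)
  truth <- structure(list(
    metabolites = truth_mets,
    features = feats[, c("feature_id", "metabolite", "ion_type",
                         "polarity", "rel_abund", "mz_theory")],
    classes = classes,
    isolates = iso_ids,
    media = media,
    seed = config$seed
  ), class = "exoniche_truth")
  list(feature_table = ft, meta = meta, truth = truth)
}

#' Generate a synthetic soil-water wetting time course
#'
#' `n_rep_soil` replicate soil-water samples at each timepoint; planted
#' trends: `n_depleted` metabolites decay geometrically to
#' 1/depletion_factor of their base area by the last timepoint,
#' `n_accumulated` rise analogously, the rest stay flat; replicate
#' areas carry lognormal noise with `soil_noise_cv`.
#'
#' @param config A [synthetic_config()].
#' @param records Optional metabolite record data.frame (metabolite_id,
#'   mz, rt, polarity) to reuse identities from another experiment
#'   (e.g. to test cross-experiment matching); defaults to freshly
#'   drawn metabolites.
#' @return List with `abundance` (metabolite x sample matrix), `meta`,
#'   `records` and `truth` (data.frame with planted trend and factor).
#' @export
generate_timecourse <- function(config = synthetic_config(),
                                records = NULL) {
  validate_synthetic_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_soil_metabolites
  if (is.null(records)) {
    forms <- lapply(seq_len(n), function(i) .draw_formula())
    pol <- sample(c("positive", "negative"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
    pr <- vapply(pol, function(p) {
      r <- config$adducts[config$adducts$polarity == p &
                            config$adducts$primary, , drop = FALSE][1L, ]
      r$mass_shift
    }, numeric(1L))
    records <- data.frame(
      metabolite_id = sprintf("sw%03d", seq_len(n)),
      mz = vapply(forms, `[[`, numeric(1L), "mass") + pr,
      rt = stats::runif(n, 1, 30),
      polarity = pol,
      stringsAsFactors = FALSE)
  } else {
    if (nrow(records) < n) n <- nrow(records)
    records <- records[seq_len(n),
                       c("metabolite_id", "mz", "rt", "polarity")]
    records$metabolite_id <- as.character(records$metabolite_id)
  }
  # planted trend counts scale with the (possibly smaller) universe
  scale_ <- min(1, n / config$n_soil_metabolites)
  n_dep <- min(round(config$n_depleted * scale_), n)
  n_acc <- min(round(config$n_accumulated * scale_), n - n_dep)
  trend <- rep("flat", n)
  pick <- sample.int(n, n_dep + n_acc)
  dep <- pick[seq_len(n_dep)]
  acc <- setdiff(pick, dep)
  trend[dep] <- "depleted"
  trend[acc] <- "accumulated"
  fac <- rep(1, n)
  fac[dep] <- 1 / exp(stats::runif(length(dep),
                                   log(config$depletion_factor_range[1L]),
                                   log(config$depletion_factor_range[2L])))
  fac[acc] <- exp(stats::runif(length(acc),
                               log(config$accumulation_factor_range[1L]),
                               log(config$accumulation_factor_range[2L])))
  base <- 10^stats::runif(n, log10(5e3), 6)

  tps <- config$timepoints_min
  K <- length(tps)
  meta_rows <- lapply(seq_along(tps), function(k) {
    data.frame(
      sample_id = sprintf("sw_t%d_r%d", tps[k],
                          seq_len(config$n_rep_soil)),
      role = "soil_water", isolate_id = NA_character_,
      medium_id = NA_character_, control_group_id = NA_character_,
      timepoint = tps[k],
      replicate_index = seq_len(config$n_rep_soil),
      stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  abund <- matrix(NA_real_, n, nrow(meta),
                  dimnames = list(records$metabolite_id,
                                  meta$sample_id))
  for (k in seq_along(tps)) {
    prog <- (k - 1) / (K - 1)
    mu <- base * fac^prog
    cols <- meta$timepoint == tps[k]
    abund[, cols] <- mu *
      matrix(.ln_noise(n * sum(cols), config$soil_noise_cv), nrow = n)
  }
  abund[abund < config$detection_floor] <- 0
  truth <- data.frame(metabolite_id = records$metabolite_id,
                      trend = trend, factor = fac, base_area = base,
                      stringsAsFactors = FALSE)
  list(abundance = abund, meta = meta, records = records,
       truth = truth)
}

#' Generate synthetic cell-extract / spent-minimal-medium data
#'
#' Inputs for the release-breadth analysis: per metabolite, replicate
#' areas in the cell extract, the strain's spent minimal medium and the
#' uninoculated control medium, with a planted class among
#' `extract_only`, `released`, `medium_only` and `absent`.
#'
#' @param config A [synthetic_config()].
#' @param detect_area Detection threshold the classes are planted
#'   against.
#' @return List with `extract`, `spent`, `control` (metabolite x
#'   replicate matrices) and `truth` (metabolite_id, class).
#' @export
generate_release_data <- function(config = synthetic_config(),
                                  detect_area = 1000) {
  validate_synthetic_config(config)
  set.seed(config$seed + 2L)
  n <- config$n_metabolites
  ids <- as.character(seq_len(n))
  class <- sample(c("released", "extract_only", "medium_only",
                    "absent"), n, replace = TRUE,
                  prob = c(0.45, 0.08, 0.05, 0.42))
  r <- config$n_rep_media
  draw <- function(on, lo, hi) {
    mu <- ifelse(on, 10^stats::runif(n, log10(lo), log10(hi)), 0)
    mat <- matrix(mu, n, r) *
      matrix(.ln_noise(n * r, config$noise_cv), n)
    mat[mat < config$detection_floor] <- 0
    rownames(mat) <- ids
    mat
  }
  extract <- draw(class %in% c("released", "extract_only"),
                  5 * detect_area, 1e6)
  spent <- draw(class %in% c("released", "medium_only"),
                5 * detect_area, 5e5)
  control <- draw(rep(TRUE, n), 1, 200)
  list(extract = extract, spent = spent, control = control,
       truth = data.frame(metabolite_id = ids, class = class,
                          stringsAsFactors = FALSE))
}

#' Degrade a feature table
#'
#' Robustness harness: randomly zeroes intensities with probability
#' `missingness` and multiplies the survivors by lognormal noise with
#' CV `noise_cv`. The planted truth of the source experiment is
#' unchanged.
#'
#' @param ft A [feature_table()].
#' @param missingness Dropout probability in [0, 1).
#' @param noise_cv Extra lognormal CV (0 = none).
#' @return The degraded `feature_table`.
#' @export
degrade <- function(ft, missingness = 0, noise_cv = 0) {
  stopifnot(missingness >= 0, missingness < 1, noise_cv >= 0)
  intens <- ft$intensities
  if (missingness > 0) {
    drop <- stats::runif(length(intens)) < missingness
    intens[drop] <- 0
  }
  if (noise_cv > 0) {
    intens <- intens * matrix(.ln_noise(length(intens), noise_cv),
                              nrow = nrow(intens))
  }
  feature_table(ft$features, intens)
}

#' Serialize / restore planted truth
#'
#' Truth objects round-trip losslessly through JSON (full double
#' precision).
#'
#' @param truth An `exoniche_truth` object.
#' @param path JSON path.
#' @return `read_truth()` returns the restored truth object.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$metabolites <- as.data.frame(x$metabolites)
  x$features <- as.data.frame(x$features)
  x$classes <- as.data.frame(x$classes)
  x$seed <- as.integer(x$seed)
  structure(x, class = "exoniche_truth")
}

#' @export
print.exoniche_truth <- function(x, ...) {
  cat("<exoniche_truth> ", nrow(x$metabolites), " metabolites, ",
      length(x$isolates), " isolates, ",
      nrow(x$features), " planted features\n", sep = "")
  invisible(x)
}
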
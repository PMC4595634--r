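# End-to-end orchestration: feature table -> metabolite resolution ->
# availability filter -> uptake/release calls -> consensus -> niche
# statistics, with every stage intermediate persisted as TSV/JSON so
# stages can be re-run and inspected independently.

#' Pipeline configuration
#'
#' @param features,metadata Paths to a feature table and sample
#'   metadata (ignored when `simulate = TRUE`).
#' @param adduct_rules Optional path to an adduct rule CSV/YAML;
#'   default rules otherwise.
#' @param simulate Generate the inputs with the synthetic module
#'   instead of reading files.
#' @param synthetic List of [synthetic_config()] overrides used when
#'   `simulate = TRUE`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed forwarded to the synthetic generator.
#' @param rt_tol,corr_min,mz_tol,mass_tol Ion-grouping parameters (see
#'   [resolve_metabolites()]).
#' @param alpha,min_area,detect_area Classification parameters (see
#'   [classify_all()]).
#' @param abundant_mode Availability filter mode (see
#'   [filter_abundant()]).
#' @param conflict_policy Conflict handling in niche statistics.
#' @param assign_formulas Run formula assignment on resolved records.
#' @param run_release,run_timecourse Include the release-profile /
#'   wetting time-course stages (simulated inputs; only honoured when
#'   `simulate = TRUE`).
#' @return Validated config list of class `exoniche_pipeline_config`.
#' @export
pipeline_config <- function(features = NULL, metadata = NULL,
                            adduct_rules = NULL, simulate = FALSE,
                            synthetic = list(), out_dir = "exoniche_out",
                            seed = 42L, rt_tol = 0.3, corr_min = 0.9,
                            mz_tol = 0.02, mass_tol = 0.005,
                            alpha = 0.05, min_area = 5000,
                            detect_area = 1000,
                            abundant_mode = "any_sample",
                            conflict_policy =
                              "as_uptake_if_resolved_uptake",
                            assign_formulas = TRUE,
                            run_release = TRUE,
                            run_timecourse = TRUE) {
  cfg <- list(features = features, metadata = metadata,
              adduct_rules = adduct_rules, simulate = simulate,
              synthetic = synthetic, out_dir = out_dir,
              seed = as.integer(seed), rt_tol = rt_tol,
              corr_min = corr_min, mz_tol = mz_tol,
              mass_tol = mass_tol, alpha = alpha,
              min_area = min_area, detect_area = detect_area,
              abundant_mode = abundant_mode,
              conflict_policy = conflict_policy,
              assign_formulas = assign_formulas,
              run_release = run_release,
              run_timecourse = run_timecourse)
  if (!cfg$simulate &&
      (is.null(cfg$features) || is.null(cfg$metadata))) {
    stop("either set simulate = TRUE or provide features and metadata",
         " paths")
  }
  structure(cfg, class = "exoniche_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return An `exoniche_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, lst)
}

#' Run the full analysis pipeline
#'
#' Executes metabolite resolution, availability filtering,
#' per-medium classification, cross-media consensus and the niche
#' statistics; in simulation mode also the release-profile and
#' wetting-time-course stages plus a recovery evaluation against the
#' planted truth. All stage outputs are written under
#' `config$out_dir`; the returned report (also `report.json`) restates
#' the headline numbers. Fully reproducible: identical configs produce
#' identical outputs.
#'
#' @param config An `exoniche_pipeline_config` (or path to its YAML).
#' @return The report, invisibly a list; see `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "exoniche_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  rules <- if (!is.null(config$adduct_rules)) {
    read_adduct_rules(config$adduct_rules)
  } else {
    default_adduct_rules()
  }

  truth <- NULL
  if (config$simulate) {
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- config$seed
    syn <- do.call(synthetic_config, syn_args)
    syn$adducts <- rules
    sim <- generate_experiment(syn)
    ft <- sim$feature_table
    meta <- sim$meta
    truth <- sim$truth
    write_truth(truth, out("truth.json"))
    write_sample_metadata(meta, out("sample_metadata.tsv"))
  } else {
    ft <- read_feature_table(config$features)
    meta <- read_sample_metadata(config$metadata)
  }
  if (!any(meta$role == "control")) {
    stop("no control samples; refusing to run the pipeline")
  }

  res <- resolve_metabolites(ft, rules = rules,
                             rt_tol = config$rt_tol,
                             corr_min = config$corr_min,
                             mz_tol = config$mz_tol,
                             mass_tol = config$mass_tol,
                             assign_formulas = config$assign_formulas)
  write_metabolite_table(res$metabolites, out("metabolites.tsv"))
  utils::write.table(
    data.frame(metabolite_id = rownames(res$abundance),
               res$abundance, check.names = FALSE),
    out("abundance.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

  abundant <- filter_abundant(res$abundance, meta,
                              min_area = config$min_area,
                              mode = config$abundant_mode)
  calls <- classify_all(res$abundance, meta, alpha = config$alpha,
                        min_area = config$min_area,
                        detect_area = config$detect_area)
  write_calls(calls, out("calls.tsv"))
  consensus <- combine_across_media(calls)
  write_calls(consensus, out("consensus.tsv"))

  isolates <- sort(unique(meta$isolate_id[meta$role == "spent"]))
  um <- build_utilization_matrix(consensus, abundant, isolates)
  utils::write.table(
    data.frame(isolate_id = rownames(um$calls), um$calls,
               check.names = FALSE),
    out("utilization_matrix.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  summ <- niche_summary(um, conflict_policy = config$conflict_policy)
  jsonlite::write_json(summ, out("niche_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  bp <- export_bipartite(
    um,
    metabolite_annotations = res$metabolites[
      , c("metabolite_id", "mz", "rt", "neutral_mass", "formula")],
    path = out("bipartite.graphml"))
  utils::write.table(bp$edges, out("bipartite_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  report <- list(
    n_features = n_features(ft),
    n_samples = n_samples(ft),
    n_metabolites = nrow(res$metabolites),
    n_abundant = length(abundant),
    per_isolate_used_fraction = summ$per_isolate_used_fraction,
    per_isolate_used_percent = summ$per_isolate_used_percent,
    shared_use_histogram = summ$shared_use_histogram,
    unused_fraction = summ$unused_fraction,
    n_competition = length(summ$competition_set),
    n_crossfeeding = length(summ$crossfeed_set),
    n_released_novel = length(summ$released_novel),
    seed = config$seed
  )

  if (config$simulate) {
    rec <- evaluate_recovery(calls, res$metabolites, truth)
    report$recovery <- rec[c("sensitivity_uptake",
                             "sensitivity_release", "fpr_unchanged",
                             "n_uptake_planted", "n_release_planted",
                             "n_unchanged_planted")]
    if (config$run_release) {
      rel <- generate_release_data(syn,
                                   detect_area = config$detect_area)
      prof <- classify_release(rel$extract, rel$spent, rel$control,
                               detect_area = config$detect_area)
      utils::write.table(rank_abundance_table(prof),
                         out("release_profile.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      report$release_breadth <- prof$release_breadth
      report$release_counts <- as.list(prof$counts)
    }
    if (config$run_timecourse) {
      tc_records <- res$metabolites[
        , c("metabolite_id", "mz", "rt", "polarity")]
      tc <- generate_timecourse(syn, records = tc_records)
      trend <- timepoint_trend(tc$abundance, tc$meta,
                               alpha = config$alpha)
      utils::write.table(trend$table, out("timecourse.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      mapping <- data.frame(id_a = tc$records$metabolite_id,
                            id_b = tc$records$metabolite_id,
                            d_mz = 0, d_rt = 0, flags = "",
                            stringsAsFactors = FALSE)
      ubd <- unused_but_depleted(trend, um, mapping)
      utils::write.table(ubd, out("unused_but_depleted.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      report$n_depleted <- sum(trend$table$trend == "depleted")
      report$n_unused_but_depleted <- nrow(ubd)
    }
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(report)
}

#' Evaluate classification recovery against planted truth
#'
#' Joins the per-medium utilization calls to the planted classes of a
#' synthetic experiment (via each resolved metabolite's characteristic
#' feature) and computes uptake/release sensitivity and the false
#' positive rate on planted-unchanged metabolites. The evaluation is
#' restricted to planted-abundant (available) metabolites — the task
#' the availability filter defines.
#'
#' @param calls Per-medium calls from [classify_all()].
#' @param metabolites Resolved metabolite records (for the
#'   characteristic-feature mapping).
#' @param truth The `exoniche_truth` of the generating experiment.
#' @return List: sensitivity_uptake, sensitivity_release,
#'   fpr_unchanged, planted counts, and `p_unchanged` (the p-values of
#'   calls on planted-unchanged metabolites, for calibration checks).
#' @export
evaluate_recovery <- function(calls, metabolites, truth) {
  feat2met <- stats::setNames(truth$features$metabolite,
                              truth$features$feature_id)
  pid2truth <- stats::setNames(
    feat2met[metabolites$characteristic_feature_id],
    as.character(metabolites$metabolite_id))
  truth_met <- pid2truth[as.character(calls$metabolite_id)]
  tkey <- paste(truth$classes$isolate_id, truth$classes$metabolite,
                truth$classes$medium_id, sep = "\r")
  ckey <- paste(calls$isolate_id, truth_met, calls$medium_id,
                sep = "\r")
  planted <- truth$classes$class[match(ckey, tkey)]
  abundant_truth <- truth$metabolites$metabolite[
    truth$metabolites$abundant]
  keep <- !is.na(planted) & truth_met %in% abundant_truth
  cc <- calls[keep, , drop = FALSE]
  planted <- planted[keep]
  sens <- function(cls) {
    idx <- planted == cls
    if (!any(idx)) return(NA_real_)
    mean(cc$call[idx] == cls)
  }
  unch <- planted == "unchanged"
  list(
    sensitivity_uptake = sens("uptake"),
    sensitivity_release = sens("release"),
    fpr_unchanged = if (any(unch)) {
      mean(cc$call[unch] %in% c("uptake", "release"))
    } else NA_real_,
    n_uptake_planted = sum(planted == "uptake"),
    n_release_planted = sum(planted == "release"),
    n_unchanged_planted = sum(unch),
    # calibration vector: genuine (non-degenerate) t-tests on available
    # metabolites only
    p_unchanged = cc$p_value[unch & cc$call != "not_available" &
                               !grepl("degenerate", cc$flags)]
  )
}

#' Utilization matrix straight from planted truth
#'
#' Bypasses classification: plants the truth classes as consensus
#' calls and builds the utilization matrix from them. Used for
#' truth-identity checks of the niche statistics.
#'
#' @param truth An `exoniche_truth`.
#' @return A `utilization_matrix` over the planted-abundant set.
#' @export
truth_utilization_matrix <- function(truth) {
  cls <- truth$classes[truth$classes$medium_id == truth$media[1L], ]
  consensus <- data.frame(
    isolate_id = cls$isolate_id,
    metabolite_id = as.character(cls$metabolite),
    call = cls$class, p_value = NA_real_, fold_change = NA_real_,
    flags = "", stringsAsFactors = FALSE)
  abundant <- as.character(
    truth$metabolites$metabolite[truth$metabolites$abundant])
  build_utilization_matrix(consensus, abundant,
                           sort(unique(cls$isolate_id)))
}
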
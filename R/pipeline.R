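#' Run the full study pipeline
#'
#' Orchestrates the end-to-end analysis on a synthetic cohort: generate the
#' cohort, screen it with the legacy and proposed rules, compute overall and
#' gestational-age-stratified performance and the retrieval reduction, run
#' the Monte Carlo threshold search and summarize the proposed-family
#' feasible region, run the PCA and export biplot data, and classify the
#' 26-case historical fixture. Every number in the report is recomputed from
#' the emitted CSVs' contents; a manifest records the seed, a hash of the
#' configuration and md5 checksums of all outputs, so two runs with the same
#' configuration produce identical files.
#'
#' @param output_dir Directory for outputs (created if needed).
#' @param config A [generator_config()].
#' @param spec A [search_spec()]; reduce `n_iterations` for quick runs.
#' @param thresholds A [threshold_set()] for the proposed rule.
#' @param fixture_seed Seed for the historical fixture stage.
#' @param quiet Suppress progress messages (written to stderr)?
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_full_study <- function(output_dir,
                           config = generator_config(),
                           spec = search_spec(),
                           thresholds = threshold_set(),
                           fixture_seed = 1L,
                           quiet = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cahscreen] ", ...)
  pth <- function(f) file.path(output_dir, f)
  constants <- config$constants

  say("generating cohort (n=", config$n_total, ", seed=", config$seed, ")")
  cohort <- generate_cohort(config)
  write_cohort(cohort, pth("cohort.csv"))

  say("screening: legacy and proposed rules")
  legacy <- evaluate_legacy(cohort)
  proposed <- evaluate_proposed(cohort, thresholds, constants)
  write_results <- function(res, f) {
    out <- as.data.frame(res)
    utils::write.csv(out, pth(f), row.names = FALSE, quote = FALSE, na = "")
  }
  write_results(legacy, "legacy_results.csv")
  write_results(proposed, "proposed_results.csv")

  metric_block <- function(res) {
    m <- screen_metrics(confusion(res, cohort))
    strata <- stratify_by_ga(cohort, res,
                             cutoff_weeks = constants$preterm_ga_cutoff)
    flat <- function(pm) if (is.null(pm)) NULL else
      list(counts = unclass(pm$counts), n_positive = pm$n_positive,
           ppv = pm$ppv, npv = pm$npv, sensitivity = pm$sensitivity,
           specificity = pm$specificity,
           ppv_printed = format_percent(pm$ppv, 1))
    list(overall = flat(m),
         preterm = flat(strata$preterm), term = flat(strata$term),
         ga_excluded_n = strata$excluded_n)
  }
  say("computing performance metrics")
  reduction <- retrieval_reduction(sum(legacy$positive),
                                   sum(proposed$positive))
  metrics <- list(
    legacy = metric_block(legacy),
    proposed = metric_block(proposed),
    retrieval_reduction_percent = reduction,
    retrieval_reduction_printed = format_percent(reduction / 100, 0)
  )

  say("Monte Carlo threshold search (", spec$n_iterations,
      " iterations x ", length(spec$algorithms), " algorithms)")
  sims <- run_search(cohort, spec, constants)
  utils::write.csv(as.data.frame(sims), pth("sims.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  proposed_family <- if ("ohp17_df21_gated" %in% sims$algorithm_id)
    "ohp17_df21_gated" else sims$algorithm_id[1]
  region <- feasible_region(sims, proposed_family)
  region_out <- region[c("algorithm_id", "n_feasible", "fraction_feasible",
                         "bounds")]
  jsonlite::write_json(region_out, pth("feasible_region.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  say("PCA of the steroid panel")
  pca <- run_pca(prepare_matrix(cohort, constants))
  biplot_export(pca, cohort, pth("pca_scores.csv"), pth("pca_loadings.csv"))
  jsonlite::write_json(
    list(variance_explained = pca$variance_explained,
         pc1_pc2 = sum(pca$variance_explained[1:2]),
         transform_spec = pca$transform_spec),
    pth("pca_summary.json"), auto_unbox = TRUE, digits = NA)

  say("historical fixture classification")
  fixture <- generate_historical_fixture(fixture_seed, constants)
  write_cohort(fixture, pth("historical_fixture.csv"))
  fix_res <- evaluate_proposed(fixture, thresholds, constants)
  historical <- list(
    sw_positive = sum(fix_res$positive & fixture$diagnosis == "SW_CAH"),
    sv_positive = sum(fix_res$positive & fixture$diagnosis == "SV_CAH"),
    variant_negative = sum(!fix_res$positive &
                             fixture$diagnosis %in%
                               c("NC_CAH", "BOHSD3", "BOHD11"))
  )

  report <- list(metrics = metrics,
                 feasible_region = region_out,
                 pca = list(variance_explained = pca$variance_explained,
                            pc1_pc2 = sum(pca$variance_explained[1:2])),
                 historical = historical)
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  files <- c("cohort.csv", "legacy_results.csv", "proposed_results.csv",
             "sims.csv", "feasible_region.json", "pca_scores.csv",
             "pca_loadings.csv", "pca_summary.json",
             "historical_fixture.csv", "report.json")
  cfg_file <- pth("config.json")
  jsonlite::write_json(list(n_total = config$n_total,
                            seed = config$seed,
                            fixture_seed = as.integer(fixture_seed),
                            search_seed = spec$seed,
                            n_iterations = spec$n_iterations,
                            class_prevalences =
                              as.list(config$class_prevalences),
                            preterm_fraction_overall =
                              config$preterm_fraction_overall),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, files))), files)),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("cahscreen"))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  say("done: ", length(files), " output files in ", output_dir)
  invisible(report)
}
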
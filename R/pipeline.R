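#' @title End-to-end pipeline: simulate, phenotype, spectra, compare
#' @description A single entry point that runs the whole analysis with
#'   deterministic seeding and writes every stage output plus a run
#'   manifest (config hash, seed, row counts, collected warnings).
#' @name pipeline
NULL

#' Assemble a full run configuration
#'
#' @param out_dir output directory (created if missing).
#' @param cohort a [cohort_config()].
#' @param welch a [welch_config()].
#' @param contrasts phenotype contrasts to run (subset of
#'   `c("iap", "ap")`).
#' @param metrics spectral metrics to test (default all four).
#' @param fdr_threshold BH-FDR significance threshold, in (0, 1).
#' @param seed optional override of `cohort$seed`.
#' @param write_series also write every subject's ROI series matrix under
#'   `out_dir/series/` (large at full scale; default `FALSE`).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       welch = welch_config(),
                       contrasts = c("iap", "ap"),
                       metrics = c("total_alpha_power", "total_theta_power",
                                   "paf_speed", "paf_power"),
                       fdr_threshold = 0.05,
                       seed = NULL,
                       write_series = FALSE) {
  contrasts <- match.arg(contrasts, c("iap", "ap"), several.ok = TRUE)
  metrics <- match.arg(metrics, .metric_names, several.ok = TRUE)
  stopifnot_scalar_number(fdr_threshold, "fdr_threshold")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    abort_painattn("`fdr_threshold` must lie in (0, 1)", "invalid_config")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, cohort = cohort, welch = welch,
                 contrasts = contrasts, metrics = metrics,
                 fdr_threshold = fdr_threshold,
                 write_series = isTRUE(write_series)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The document has optional `cohort`, `welch`, and `pipeline` sections
#' whose keys map onto the arguments of [cohort_config()],
#' [welch_config()], and [run_config()]. Unknown keys are errors
#' (fail-fast) rather than being silently ignored.
#'
#' @param path YAML file path.
#' @param out_dir output directory (overrides `pipeline$out_dir`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("cohort", "welch", "pipeline"))
  if (length(unknown))
    abort_painattn(paste0("unknown config section(s): ",
                          paste(unknown, collapse = ", ")), "invalid_config")
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      abort_painattn(sprintf("unknown key(s) in `%s`: %s", section,
                             paste(bad, collapse = ", ")), "invalid_config")
    # YAML maps come in as named lists; group-valued args need vectors
    args <- lapply(args, function(a)
      if (is.list(a) && all(vapply(a, is.numeric, logical(1)))) unlist(a)
      else a)
    do.call(fn, args)
  }
  cohort <- take("cohort", cohort_config)
  welch <- take("welch", welch_config)
  pl <- raw$pipeline
  if (is.null(pl)) pl <- list()
  bad <- setdiff(names(pl), c("out_dir", "contrasts", "metrics",
                              "fdr_threshold", "seed", "write_series"))
  if (length(bad))
    abort_painattn(paste0("unknown key(s) in `pipeline`: ",
                          paste(bad, collapse = ", ")), "invalid_config")
  if (!is.null(out_dir)) pl$out_dir <- out_dir
  if (is.null(pl$out_dir))
    abort_painattn("no output directory given (pipeline$out_dir)",
                   "invalid_config")
  do.call(run_config, c(list(cohort = cohort, welch = welch), pl))
}

# Hash of the scientific configuration (the output location is excluded so
# identical analyses into different directories produce identical manifests).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(cfg, unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages: (1) simulate the synthetic cohort and write the behavioral
#' tables (and, optionally, all ROI series); (2) compute per-subject
#' phenotypes; (3) compute per-subject x ROI spectral metrics; (4) run the
#' group comparisons and brain-behavior correlations per contrast. A stage
#' failure aborts with the stage name prefixed to the cause. All outputs
#' are tab-separated tables under `config$out_dir`; the manifest
#' (`manifest.json`) records the package version, seed, config hash,
#' per-output row counts, boundary-phenotype warnings, and the number of
#' edge-flagged PAF estimates. The manifest contains no timestamps, so a
#' fixed seed reproduces it byte-identically.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config"))
    abort_painattn("`config` must come from run_config()", "invalid_config")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  warnings_log <- character()
  collect <- withCallingHandlers
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_painattn(sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "stage_error")
    })
  }

  say("stage simulate: generating cohort")
  cohort <- stage("simulate", simulate_cohort(config$cohort))
  write_tsv(cohort$experience, file.path(out, "experience.tsv"))
  write_tsv(cohort$ni_trials, file.path(out, "ni_trials.tsv"))
  if (config$write_series) {
    sdir <- file.path(out, "series")
    for (sid in cohort$truth$subject_id)
      write_roi_series(subject_series_matrix(cohort, sid),
                       fs = cohort$config$fs, subject_id = sid, dir = sdir)
  }

  say("stage phenotype: IAP scores and A/P types")
  phenotypes <- stage("phenotype",
                      phenotype_table(cohort$experience, cohort$ni_trials))
  write_tsv(phenotypes, file.path(out, "phenotypes.tsv"))

  say("stage spectra: Welch band metrics per subject x ROI")
  metrics <- stage("spectra",
                   compute_cohort_metrics(cohort, config = config$welch))
  write_tsv(metrics, file.path(out, "metrics.tsv"))

  say("stage compare: group statistics")
  comparisons <- list()
  correlations <- list()
  for (ct in config$contrasts) {
    pred <- switch(ct, iap = "iap_score", ap = "delta_rt_mean")
    res <- stage(paste0("compare_", ct), collect(
      {
        cmp <- run_group_comparison(metrics, phenotypes, contrast = ct,
                                    metric = config$metrics,
                                    fdr_threshold = config$fdr_threshold)
        cor <- run_correlations(metrics, phenotypes, predictor = pred,
                                metric = config$metrics,
                                fdr_threshold = config$fdr_threshold)
        list(cmp = cmp, cor = cor)
      },
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    comparisons[[ct]] <- res$cmp
    correlations[[ct]] <- res$cor
    write_tsv(res$cmp, file.path(out, sprintf("comparison_%s.tsv", ct)))
    write_tsv(res$cor, file.path(out, sprintf("correlations_%s.tsv", ct)))
  }

  manifest <- list(
    package = "painattn",
    version = as.character(utils::packageVersion("painattn")),
    seed = config$cohort$seed,
    config_hash = config_hash(config),
    fdr_threshold = config$fdr_threshold,
    contrasts = config$contrasts,
    n_subjects = nrow(cohort$truth),
    rows = c(list(experience = nrow(cohort$experience),
                  ni_trials = nrow(cohort$ni_trials),
                  phenotypes = nrow(phenotypes),
                  metrics = nrow(metrics)),
             stats::setNames(lapply(comparisons, nrow),
                             paste0("comparison_", names(comparisons)))),
    n_boundary_iap = sum(phenotypes$iap_group == "boundary", na.rm = TRUE),
    n_boundary_ap = sum(phenotypes$ap_type == "boundary", na.rm = TRUE),
    n_paf_edge_flagged = sum(metrics$paf_at_band_edge),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in ", out)
  invisible(manifest)
}
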
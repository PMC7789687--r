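#' Configuration for a full validation experiment
#'
#' @param params a [generator_params()] object (the synthetic cohort).
#' @param presets model presets to run, a subset of
#'   `c("RAN", "PHQ-BIN", "PHQ-ORD", "ALL-BIN", "ALL-ORD")`; at least one.
#' @param m imputations per preset (study design: 100).
#' @param burn_in FCS cycles per imputation.
#' @param seed master seed; every stage (generation, random assignment, each
#'   preset's imputation streams) draws its sub-seed from it.
#' @param target masked depression item, default `"phq9"`.
#' @param interval parenthetical spread for the diagnostic report:
#'   `"percentile"` (2.5-97.5 across imputations) or `"range"` (min-max).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(params = generator_params(),
                              presets = PRESETS,
                              m = 100, burn_in = 10, seed = 1L,
                              target = "phq9",
                              interval = c("percentile", "range")) {
  validate_generator_params(params)
  if (length(presets) < 1 || !all(presets %in% PRESETS))
    stop("presets must be a non-empty subset of ", paste(PRESETS, collapse = ", "))
  if (!target %in% PHQ_ITEMS) stop("unknown target item: ", target)
  structure(list(params = params, presets = presets, m = as.integer(m),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 target = target, interval = match.arg(interval)),
            class = "experiment_config")
}

#' Run the full validation experiment
#'
#' Orchestrates generate -> exclude fully-missing waves -> mask the target at
#' wave 2 -> impute per preset -> pooled confusion-matrix diagnostics ->
#' Rubin-pooled association recovery, and assembles a report bundle. Every
#' preset shares the same masked table and held-out truth, differing only in
#' its imputation model. The random-assignment baseline contributes a
#' diagnostics column but no association models (its values are unrelated to
#' outcomes by construction). Deterministic: the same configuration and seed
#' reproduce the bundle byte for byte.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the bundle's tables are
#'   written as CSV, per-imputation statistics as JSON, and a manifest.
#' @return object of class `experiment_bundle`: `n`, `prevalence` (observed
#'   dichotomized truth prevalence at wave 2, percent), `diagnostics` (named
#'   `diagnostic_summary` list), `table1` (formatted report), `associations`
#'   (per outcome: self-report AORs, pooled per-model `aor_result`s, report
#'   table), `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage_seeds <- derive_stream_seeds(config$seed, 2 + length(config$presets))
  names(stage_seeds) <- c("generator", "ran", config$presets)

  params <- config$params
  params$seed <- stage_seeds[["generator"]]
  message("stage: generating cohort (n = ", params$n_participants, ")")
  cohort <- exclude_empty_waves(generate_cohort(params))$table
  target <- config$target

  w2 <- cohort$wave == "W2"
  truth_bin <- dichotomize_ideation(cohort[[target]][w2])
  n <- sum(w2)
  prev <- mean(truth_bin)

  informed <- setdiff(config$presets, "RAN")
  outcomes <- c("smoking", "sleep_cat")
  benchmarks <- NULL
  if (length(informed)) {
    message("stage: self-report benchmark associations")
    benchmarks <- lapply(outcomes, function(oc) {
      sp <- association_spec(oc)
      aor_from_fit(fit_association(cohort, truth_bin, sp))
    })
    names(benchmarks) <- outcomes
  }

  diagnostics <- list()
  assoc <- setNames(vector("list", length(outcomes)), outcomes)
  for (preset in config$presets) {
    message("stage: ", preset)
    if (preset == "RAN") {
      per <- evaluate_ran(truth_bin, p = prev, m = config$m,
                          seed = stage_seeds[["RAN"]])
      diagnostics[[preset]] <- pool_diagnostics(per)
      next
    }
    ps <- apply_preset(preset, target)
    tbl <- cohort
    if (ps$target_level == "binary")
      tbl[[target]] <- dichotomize_ideation(tbl[[target]])
    mk <- mask_wave_item(tbl, target, "W2")
    cfg <- imputation_config(preset = preset, m = config$m,
                             burn_in = config$burn_in,
                             visit_sequence = ps$visit_sequence,
                             seed = stage_seeds[[preset]])
    cs <- fit_fcs(mk$table, ps$specs, cfg)
    diagnostics[[preset]] <- pool_diagnostics(
      evaluate_completed(cs, truth_bin, target))
    for (oc in outcomes)
      assoc[[oc]][[preset]] <- pooled_aor(cs, target, association_spec(oc),
                                          benchmark = benchmarks[[oc]])
  }

  associations <- NULL
  if (length(informed)) {
    associations <- lapply(outcomes, function(oc)
      list(self_report = benchmarks[[oc]], pooled = assoc[[oc]],
           report = association_report(benchmarks[[oc]], assoc[[oc]])))
    names(associations) <- outcomes
  }

  bundle <- structure(list(
    n = n,
    prevalence = 100 * prev,
    diagnostics = diagnostics,
    table1 = diagnostics_report(diagnostics, truth_bin,
                                interval = config$interval),
    associations = associations,
    manifest = list(package = "wavegap",
                    version = as.character(utils::packageVersion("wavegap")),
                    seed = config$seed, stage_seeds = stage_seeds,
                    m = config$m, burn_in = config$burn_in,
                    target = target, presets = config$presets,
                    n_participants = params$n_participants)),
    class = "experiment_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Re-run the experiment with a different masked item
#'
#' Identical pipeline with another of the nine depression items masked at
#' wave 2 and the remaining eight as the PHQ predictor set -- e.g. the
#' commonly endorsed "feeling tired" item (`phq4`, ~43% prevalence) as a
#' contrast to the rare ideation item.
#'
#' @param config an [experiment_config()].
#' @param target_item one of `phq1..phq9`.
#' @param out_dir optional output directory, as in [run_experiment()].
#' @return an `experiment_bundle`.
#' @export
run_alternate_target <- function(config, target_item, out_dir = NULL) {
  if (!is.character(target_item) || length(target_item) != 1 ||
      !target_item %in% PHQ_ITEMS)
    stop("target_item must be one of ", paste(PHQ_ITEMS, collapse = ", "))
  config$target <- target_item
  run_experiment(config, out_dir = out_dir)
}

#' Write an experiment bundle to disk
#'
#' Emits `table1.csv` (diagnostics), `table2_smoking.csv` and
#' `table3_sleep.csv` (associations, when present), `per_imputation.json`
#' (all per-imputation statistics) and `manifest.json`.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$table1, file.path(dir, "table1.csv"), row.names = FALSE)
  if (!is.null(bundle$associations)) {
    utils::write.csv(bundle$associations$smoking$report,
                     file.path(dir, "table2_smoking.csv"), row.names = FALSE)
    utils::write.csv(bundle$associations$sleep_cat$report,
                     file.path(dir, "table3_sleep.csv"), row.names = FALSE)
  }
  per_imp <- lapply(bundle$diagnostics, function(s) s$per_imputation)
  jsonlite::write_json(per_imp, file.path(dir, "per_imputation.json"),
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment configuration from JSON or YAML
#'
#' File fields mirror the [experiment_config()] and [generator_params()]
#' arguments; unknown fields are rejected. YAML requires the optional
#' \pkg{yaml} package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  gp_args <- x$params %||% list()
  known <- names(formals(generator_params))
  bad <- setdiff(names(gp_args), known)
  if (length(bad)) stop("unknown generator fields: ", paste(bad, collapse = ", "))
  ec_args <- x[setdiff(names(x), "params")]
  known_ec <- setdiff(names(formals(experiment_config)), "params")
  bad <- setdiff(names(ec_args), known_ec)
  if (length(bad)) stop("unknown experiment fields: ", paste(bad, collapse = ", "))
  do.call(experiment_config,
          c(list(params = do.call(generator_params, gp_args)), ec_args))
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Validation experiment: n = %d, truth prevalence %.2f%%\n",
              x$n, x$prevalence))
  cat("Diagnostics (pooled):\n")
  print(x$table1, row.names = FALSE)
  if (!is.null(x$associations)) {
    cat("\nSmoking associations (AOR, 95% CI; * = no overlap with self-report):\n")
    print(x$associations$smoking$report, row.names = FALSE)
    cat("\nSleep associations:\n")
    print(x$associations$sleep_cat$report, row.names = FALSE)
  }
  invisible(x)
}
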
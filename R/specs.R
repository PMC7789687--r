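#' Variable specifications for the imputation engine
#'
#' Each modeled variable gets exactly one spec: its measurement level, the
#' univariate imputation form used when it has missing cells, and its role.
#' Binary/ordinal/nominal variables are imputed with the discriminant-function
#' imputer; continuous variables with Bayesian linear regression.
#'
#' @param name variable (column) name.
#' @param level one of `"binary"`, `"ordinal4"` (4-level, numeric-scored),
#'   `"ordinal"` (other numeric-scored ordinal ranges), `"nominal"`,
#'   `"continuous"`.
#' @param imputation_form `"discriminant"` or `"linear"`; defaults from the
#'   level.
#' @param role `"target"`, `"predictor"` or `"excluded"`.
#' @return one-row `data.frame`.
#' @export
variable_spec <- function(name,
                          level = c("binary", "ordinal4", "ordinal", "nominal", "continuous"),
                          imputation_form = NULL,
                          role = c("predictor", "target", "excluded")) {
  level <- match.arg(level)
  role <- match.arg(role)
  if (is.null(imputation_form))
    imputation_form <- if (level == "continuous") "linear" else "discriminant"
  stopifnot(imputation_form %in% c("discriminant", "linear"))
  data.frame(name = name, level = level, imputation_form = imputation_form,
             role = role, stringsAsFactors = FALSE)
}

bind_specs <- function(...) {
  s <- do.call(rbind, list(...))
  if (anyDuplicated(s$name)) stop("every modeled variable must have exactly one spec")
  s
}

PRESETS <- c("RAN", "PHQ-BIN", "PHQ-ORD", "ALL-BIN", "ALL-ORD")

#' Imputation-model presets
#'
#' Returns the variable specs and visit sequence for one of the named model
#' presets. `PHQ-*` presets use only the 8 remaining depression items as
#' predictors; `ALL-*` add sex, age group, race/ethnicity, marital status,
#' education, the 10 physical-functioning items, the 17 PCL-C items plus the
#' PTSD screening composite, smoking status, sleep duration (continuous in
#' imputation), and the 5 alcohol items -- 48 predictors in all. `*-BIN`
#' presets impute the target dichotomized; `*-ORD` impute it on its 4-level
#' scale (dichotomization happens after imputation, in evaluation). The 8
#' depression-item predictors are always handled as 4-level numeric-scored
#' ordinal variables.
#'
#' @param preset one of `"PHQ-BIN"`, `"PHQ-ORD"`, `"ALL-BIN"`, `"ALL-ORD"`,
#'   or `"custom"` (supply `predictors`).
#' @param target the masked depression item (default `"phq9"`, the
#'   suicidal-ideation item); any of `phq1..phq9` is allowed, with the
#'   remaining 8 items as the PHQ predictor set.
#' @param predictors character vector, only for `preset = "custom"`; must be
#'   non-empty.
#' @return list with `target`, `target_level`, `predictors`, `specs`
#'   (data.frame of [variable_spec()] rows) and `visit_sequence`.
#' @export
apply_preset <- function(preset, target = "phq9", predictors = NULL) {
  if (!preset %in% c(setdiff(PRESETS, "RAN"), "custom"))
    stop("unknown preset: ", preset)
  if (!target %in% PHQ_ITEMS) stop("target must be one of ", paste(PHQ_ITEMS, collapse = ", "))
  phq_rest <- setdiff(PHQ_ITEMS, target)
  if (preset == "custom") {
    if (is.null(predictors) || length(predictors) == 0)
      stop("custom preset requires a non-empty predictor set")
    target_level <- "binary"
  } else {
    predictors <- if (startsWith(preset, "PHQ")) phq_rest
                  else c(phq_rest, DEMO_VARS, PF_ITEMS, PCL_ITEMS, "ptsd_screen",
                         "smoking", "sleep_hours", ALC_ITEMS)
    target_level <- if (endsWith(preset, "BIN")) "binary" else "ordinal4"
  }
  level_of <- function(v) {
    if (v %in% PHQ_ITEMS) "ordinal4"
    else if (v %in% c(PCL_ITEMS, PF_ITEMS)) "ordinal"
    else if (v %in% c("ptsd_screen", ALC_ITEMS)) "binary"
    else if (v %in% c(DEMO_VARS, "smoking", "sleep_cat")) "nominal"
    else if (v == "sleep_hours") "continuous"
    else "continuous"
  }
  specs <- do.call(bind_specs, c(
    list(variable_spec(target, target_level, role = "target")),
    lapply(predictors, function(v) variable_spec(v, level_of(v), role = "predictor"))))
  list(target = target, target_level = target_level, predictors = predictors,
       specs = specs, visit_sequence = c(predictors, target))
}

#' Imputation run configuration
#'
#' @param preset preset name (informational once specs are built).
#' @param m number of imputations (>= 2; the study design uses 100).
#' @param burn_in FCS cycles per imputation before the stored draw
#'   (default 10; with a single incomplete variable the chain is stationary
#'   after the first cycle, but the cycles are run as configured).
#' @param visit_sequence optional ordered variable names; defaults to the
#'   spec order, target last.
#' @param seed master seed; spawns one independent stream per imputation.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(preset = "custom", m = 100, burn_in = 10,
                              visit_sequence = NULL, seed = 1L) {
  if (!(is.numeric(m) && m >= 2)) stop("m_imputations must be at least 2 for pooling")
  if (!(is.numeric(burn_in) && burn_in >= 1)) stop("burn_in_cycles must be positive")
  structure(list(preset = preset, m = as.integer(m), burn_in = as.integer(burn_in),
                 visit_sequence = visit_sequence, seed = as.integer(seed)),
            class = "imputation_config")
}
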
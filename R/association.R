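#' Specification of an association-recovery model
#'
#' Multinomial logistic model of a related-construct outcome on dichotomized
#' ideation, adjusted for the fixed covariate set. Reference levels are
#' fixed: never-smoker for smoking, 7-9 hours for sleep category.
#'
#' @param outcome `"smoking"` or `"sleep_cat"`.
#' @param covariates adjustment set (default: sex, age group,
#'   race/ethnicity, marital status, education).
#' @return object of class `association_spec`.
#' @export
association_spec <- function(outcome = c("smoking", "sleep_cat"),
                             covariates = DEMO_VARS) {
  outcome <- match.arg(outcome)
  ref <- if (outcome == "smoking") "never" else SLEEP_REF
  structure(list(outcome = outcome, ref = ref, covariates = covariates),
            class = "association_spec")
}

# fit the association model on one completed (or truth) table at one wave
fit_association <- function(table, exposure_bin, spec, wave = "W2") {
  d <- table[table$wave == wave, , drop = FALSE]
  stopifnot(length(exposure_bin) == nrow(d))
  d$ideation <- exposure_bin
  form <- stats::reformulate(c("ideation", spec$covariates),
                             response = spec$outcome)
  fit_multinomial(form, d, ref = spec$ref)
}

#' Adjusted odds ratios from a single fit
#'
#' @param fit a `multinom_fit`.
#' @param term coefficient of interest (default `"ideation"`).
#' @return data.frame with `level`, `aor`, `lo`, `hi` (Wald 95% CI on the
#'   log-odds scale, exponentiated).
#' @export
aor_from_fit <- function(fit, term = "ideation") {
  cs <- coef_se_for(fit, term)
  se <- sqrt(cs$var)
  data.frame(level = cs$levels,
             aor = exp(cs$est),
             lo = exp(cs$est - stats::qnorm(0.975) * se),
             hi = exp(cs$est + stats::qnorm(0.975) * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rubin-pooled adjusted odds ratios over a completed set
#'
#' Fits the association model on every completed dataset (target-wave rows
#' only, exposure = imputed target dichotomized after imputation), pools the
#' per-dataset log-odds and their variances by Rubin's rules, exponentiates
#' the pooled point and interval, and, when a benchmark is supplied, flags
#' whether each pooled 95% CI overlaps the benchmark's.
#'
#' @param completed a `completed_set` from [fit_fcs()].
#' @param target target variable name in the completed tables.
#' @param spec an [association_spec()].
#' @param benchmark optional data.frame from [aor_from_fit()] on the
#'   self-reported exposure, aligned by outcome level.
#' @param wave analysis wave (default `"W2"`).
#' @return object of class `aor_result`: data.frame with `level`, `aor`,
#'   `lo`, `hi` and (with a benchmark) `overlap`; pooled-effect details in
#'   `attr(, "pooled")`. Any per-dataset fit failure is reported with its
#'   dataset index.
#' @export
pooled_aor <- function(completed, target, spec, benchmark = NULL, wave = "W2") {
  stopifnot(inherits(completed, "completed_set"), inherits(spec, "association_spec"))
  m <- length(completed$imputations)
  if (m < 2) stop("pooling requires m >= 2 completed tables")
  fits <- vector("list", m)
  for (i in seq_len(m)) {
    d <- completed$imputations[[i]]
    expo <- dichotomize_ideation(d[[target]][d$wave == wave])
    fits[[i]] <- tryCatch(
      coef_se_for(fit_association(d, expo, spec, wave), "ideation"),
      error = function(e) stop(sprintf("association fit failed on dataset %d: %s",
                                       i, conditionMessage(e)), call. = FALSE))
  }
  levels_ <- fits[[1]]$levels
  pooled <- lapply(seq_along(levels_), function(k)
    pool_rubin(vapply(fits, function(f) f$est[k], numeric(1)),
               vapply(fits, function(f) f$var[k], numeric(1))))
  out <- data.frame(level = levels_,
                    aor = vapply(pooled, function(p) exp(p$point), numeric(1)),
                    lo = vapply(pooled, function(p) exp(p$ci95[1]), numeric(1)),
                    hi = vapply(pooled, function(p) exp(p$ci95[2]), numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(benchmark)) {
    bm <- benchmark[match(out$level, benchmark$level), , drop = FALSE]
    out$overlap <- mapply(function(l1, h1, l2, h2) ci_overlap(c(l1, h1), c(l2, h2)),
                          out$lo, out$hi, bm$lo, bm$hi)
  }
  attr(out, "pooled") <- pooled
  class(out) <- c("aor_result", "data.frame")
  out
}

#' Do two 95% confidence intervals overlap?
#'
#' True iff `max(low_a, low_b) <= min(high_a, high_b)`; a shared endpoint
#' counts as overlap. Symmetric in its arguments.
#'
#' @param ci_a,ci_b numeric length-2 intervals `c(low, high)`.
#' @return logical.
#' @examples
#' ci_overlap(c(1.12, 1.36), c(1.05, 1.44))  # TRUE
#' ci_overlap(c(4.87, 6.07), c(6.30, 7.71))  # FALSE
#' @export
ci_overlap <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == 2, length(ci_b) == 2)
  if (ci_a[1] > ci_a[2] || ci_b[1] > ci_b[2]) stop("inverted interval")
  max(ci_a[1], ci_b[1]) <= min(ci_a[2], ci_b[2])
}

#' Association report table
#'
#' One row per exposure source (self-report first, then each imputation
#' model), AOR with 95% CI per non-reference outcome level, and the overlap
#' flag against the self-report benchmark.
#'
#' @param self_report data.frame from [aor_from_fit()].
#' @param pooled named list of `aor_result` objects (by model).
#' @return data.frame of formatted strings.
#' @export
association_report <- function(self_report, pooled) {
  fmt <- function(df) {
    v <- sprintf("%.2f (%.2f, %.2f)", df$aor, df$lo, df$hi)
    if (!is.null(df$overlap)) v <- paste0(v, ifelse(df$overlap, "", " *"))
    setNames(v, df$level)
  }
  rows <- c(list(`Self-reported` = fmt(self_report)), lapply(pooled, fmt))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out <- cbind(model = names(rows), out)
  rownames(out) <- NULL
  out
}
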
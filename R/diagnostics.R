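#' Confusion counts of imputed versus held-out truth
#'
#' Standard 2x2 tabulation; truth defines the positive class.
#'
#' @param imputed binary 0/1 vector (one imputed dataset's target values).
#' @param truth binary 0/1 vector of held-out true values, same length.
#' @return object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `tn`, `fn` summing to the number of evaluated participants.
#' @export
confusion <- function(imputed, truth) {
  if (length(imputed) != length(truth)) stop("imputed and truth lengths differ")
  if (anyNA(imputed) || anyNA(truth)) stop("missing values are not allowed")
  if (!all(imputed %in% 0:1) || !all(truth %in% 0:1))
    stop("imputed and truth must be binary 0/1")
  structure(list(tp = sum(imputed == 1 & truth == 1),
                 fp = sum(imputed == 1 & truth == 0),
                 tn = sum(imputed == 0 & truth == 0),
                 fn = sum(imputed == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Diagnostic statistics from confusion counts, in percent
#'
#' Computes imputed-series prevalence `100 (tp + fp) / n`, truth prevalence
#' `100 (tp + fn) / n`, sensitivity `100 tp / (tp + fn)`, specificity
#' `100 tn / (tn + fp)`, positive predictive value `100 tp / (tp + fp)` and
#' negative predictive value `100 tn / (tn + fn)`. A zero denominator yields
#' `NA` with a warning -- never a silent zero.
#'
#' @param counts a `confusion_counts` object, or a list/vector with fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @return named numeric vector `prevalence`, `true_prevalence`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percent).
#' @examples
#' diag_stats(list(tp = 1689, fn = 865, tn = 58137, fp = 2338))
#' @export
diag_stats <- function(counts) {
  cc <- lapply(c("tp", "fp", "tn", "fn"), function(f) {
    v <- counts[[f]]
    if (is.null(v) || is.na(v) || v < 0) stop("invalid count field: ", f)
    as.numeric(v)
  })
  names(cc) <- c("tp", "fp", "tn", "fn")
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); return(NA_real_) }
    100 * num / den
  }
  c(prevalence      = ratio(cc$tp + cc$fp, n, "prevalence"),
    true_prevalence = ratio(cc$tp + cc$fn, n, "true prevalence"),
    sensitivity     = ratio(cc$tp, cc$tp + cc$fn, "sensitivity"),
    specificity     = ratio(cc$tn, cc$tn + cc$fp, "specificity"),
    ppv             = ratio(cc$tp, cc$tp + cc$fp, "PPV"),
    npv             = ratio(cc$tn, cc$tn + cc$fn, "NPV"))
}

#' Score a completed set against held-out truth
#'
#' Dichotomizes each imputed dataset's target at the evaluation wave and
#' tabulates it against the held-out truth, one confusion matrix and one set
#' of diagnostic statistics per imputation.
#'
#' @param completed a `completed_set` from [fit_fcs()], or a list of binary
#'   vectors / an `n x m` 0-1 matrix of per-imputation values.
#' @param truth_bin binary truth vector for the evaluated participants.
#' @param target target variable name (needed for `completed_set` input).
#' @param wave evaluation wave (default `"W2"`).
#' @return list of per-imputation records, each with `counts` and `stats`.
#' @export
evaluate_completed <- function(completed, truth_bin, target = NULL, wave = "W2") {
  series <- if (inherits(completed, "completed_set")) {
    stopifnot(!is.null(target))
    lapply(completed$imputations, function(d)
      dichotomize_ideation(d[[target]][d$wave == wave]))
  } else if (is.matrix(completed)) {
    lapply(seq_len(ncol(completed)), function(j) completed[, j])
  } else completed
  lapply(series, function(v) {
    cc <- confusion(v, truth_bin)
    list(counts = cc, stats = diag_stats(cc))
  })
}

#' Random-assignment baseline evaluation
#'
#' Draws `m` independent random assignments at rate `p` (one per
#' pseudo-imputation, mirroring pooling across imputed datasets) and scores
#' each against the truth.
#'
#' @param truth_bin binary truth vector.
#' @param p assignment rate; default: the observed truth prevalence.
#' @param m number of pseudo-imputations.
#' @param seed master seed for the assignment streams.
#' @return list of per-imputation records as in [evaluate_completed()].
#' @export
evaluate_ran <- function(truth_bin, p = mean(truth_bin), m = 100, seed = 1L) {
  seeds <- derive_stream_seeds(seed, m)
  lapply(seq_len(m), function(i) {
    v <- ran_assign(length(truth_bin), p, seed = seeds[i])
    cc <- confusion(v, truth_bin)
    list(counts = cc, stats = diag_stats(cc))
  })
}

#' Pool per-imputation diagnostics
#'
#' Pooled value = arithmetic mean across imputations; the headline interval
#' is the 2.5th-97.5th percentile across imputations, with the min-max range
#' also available. Report rounding (integer percents for
#' sensitivity/specificity/PPV/NPV, two decimals for prevalence) is applied
#' by the report writer, not here; full precision is retained.
#'
#' @param per_dataset list from [evaluate_completed()] / [evaluate_ran()]
#'   (`m >= 2`).
#' @return object of class `diagnostic_summary`: matrices `stats` and
#'   `counts` with rows `mean`, `q2.5`, `q97.5`, `min`, `max`, plus `m`.
#' @export
pool_diagnostics <- function(per_dataset) {
  m <- length(per_dataset)
  if (m < 2) stop("pooling requires m >= 2 imputed datasets")
  stat_m <- do.call(rbind, lapply(per_dataset, `[[`, "stats"))
  cnt_m <- do.call(rbind, lapply(per_dataset, function(r)
    unlist(r$counts[c("tp", "fp", "tn", "fn")])))
  summarize <- function(mat) {
    apply(mat, 2, function(col)
      c(mean = mean(col),
        q2.5 = unname(stats::quantile(col, 0.025, na.rm = TRUE)),
        q97.5 = unname(stats::quantile(col, 0.975, na.rm = TRUE)),
        min = min(col), max = max(col)))
  }
  structure(list(stats = summarize(stat_m), counts = summarize(cnt_m),
                 per_imputation = list(stats = stat_m, counts = cnt_m), m = m),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("Pooled diagnostics over m = %d imputations\n", x$m))
  s <- x$stats
  for (nm in colnames(s))
    cat(sprintf("  %-16s %6.2f  (%.2f-%.2f)\n", nm,
                s["mean", nm], s["q2.5", nm], s["q97.5", nm]))
  invisible(x)
}

#' Diagnostic report table (one column per model)
#'
#' Formats pooled counts and statistics the way validation reports print
#' them: count means with across-imputation intervals, prevalence to two
#' decimals, sensitivity/specificity/PPV/NPV as integer percents (half-up
#' rounding). The self-report column carries the truth counts and prevalence.
#'
#' @param summaries named list of `diagnostic_summary` objects (by model).
#' @param truth_bin binary truth vector (for the self-report column).
#' @param interval `"percentile"` (default) or `"range"` for the
#'   parenthetical spread.
#' @return data.frame of formatted strings, rows = counts and statistics.
#' @export
diagnostics_report <- function(summaries, truth_bin, interval = c("percentile", "range")) {
  interval <- match.arg(interval)
  lo_row <- if (interval == "percentile") "q2.5" else "min"
  hi_row <- if (interval == "percentile") "q97.5" else "max"
  n <- length(truth_bin)
  pos <- sum(truth_bin)
  fmt_cnt <- function(s, f) sprintf("%d (%d-%d)",
                                    round_half_up(s["mean", f]),
                                    round_half_up(s[lo_row, f]),
                                    round_half_up(s[hi_row, f]))
  fmt_pct <- function(s, f, d) sprintf(paste0("%.", d, "f (%.", d, "f-%.", d, "f)"),
                                       round_half_up(s["mean", f], d),
                                       round_half_up(s[lo_row, f], d),
                                       round_half_up(s[hi_row, f], d))
  rows <- c("True negative", "True positive", "False negative", "False positive",
            "Prevalence", "Sensitivity", "Specificity", "PPV", "NPV")
  out <- data.frame(statistic = rows, stringsAsFactors = FALSE)
  out[["Self-reported"]] <- c(format(n - pos), format(pos), "-", "-",
                              sprintf("%.2f", round_half_up(100 * pos / n, 2)),
                              "-", "-", "-", "-")
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    out[[nm]] <- c(fmt_cnt(s$counts, "tn"), fmt_cnt(s$counts, "tp"),
                   fmt_cnt(s$counts, "fn"), fmt_cnt(s$counts, "fp"),
                   fmt_pct(s$stats, "prevalence", 2),
                   fmt_pct(s$stats, "sensitivity", 0),
                   fmt_pct(s$stats, "specificity", 0),
                   fmt_pct(s$stats, "ppv", 0),
                   fmt_pct(s$stats, "npv", 0))
  }
  out
}
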
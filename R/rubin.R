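#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines `m` complete-data estimates and their variances: point estimate
#' `Qbar = mean(estimates)`, within-imputation variance `W = mean(variances)`,
#' between-imputation variance `B = var(estimates)`, total variance
#' `T = W + (1 + 1/m) B`, degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`, and a 95% confidence interval
#' from the t quantile with `df` degrees of freedom (normal quantile when
#' `B = 0`, where `df` is infinite). The classic large-`m` df is used without
#' the small-sample adjustment, which is negligible at the study's `m = 100`.
#'
#' @param estimates numeric vector of per-imputation estimates (`m >= 2`).
#' @param variances numeric vector of per-imputation squared standard errors.
#' @return object of class `pooled_effect` with fields `point`, `within`,
#'   `between`, `total`, `df`, `m`, `ci95`.
#' @examples
#' pool_rubin(c(0, 1), c(1, 1))  # Qbar 0.5, W 1, B 0.5, T 1.75
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2 estimates")
  if (length(variances) != m) stop("estimates and variances lengths differ")
  if (!all(is.finite(estimates)) || !all(is.finite(variances)))
    stop("estimates and variances must be finite")
  if (any(variances < 0)) stop("variances must be nonnegative")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  tq <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  ci <- qbar + c(-1, 1) * tq * sqrt(total)
  structure(list(point = qbar, within = W, between = B, total = total,
                 df = df, m = m, ci95 = ci),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over m = %d imputations\n", x$m))
  cat(sprintf("  point %.5g  (95%% CI %.5g to %.5g)\n", x$point, x$ci95[1], x$ci95[2]))
  cat(sprintf("  within %.4g  between %.4g  total %.4g  df %.4g\n",
              x$within, x$between, x$total, x$df))
  invisible(x)
}
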
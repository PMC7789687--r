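#' Baseline-category multinomial logistic regression
#'
#' Maximum-likelihood fit of a multinomial (baseline-category) logit by full
#' Newton-Raphson with analytic gradient and Hessian, iterated to a gradient
#' max-norm below `tol` (default `1e-8`) with step-halving. The covariance
#' matrix is the inverse observed information at the optimum. With a 2-level
#' outcome the model is exactly binary logistic regression.
#'
#' Complete separation is reported as an error (detected when any coefficient
#' diverges beyond `max_abs_coef`); a rank-deficient design is rejected up
#' front.
#'
#' @param formula model formula; the response is coerced to a factor.
#' @param data data.frame.
#' @param ref reference (baseline) outcome level; default: first factor level.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @param max_abs_coef divergence bound for separation detection.
#' @return object of class `multinom_fit`: `coefficients` (`p x (K-1)`
#'   matrix, columns = non-reference levels), `vcov` (covariance of
#'   `as.vector(coefficients)`), `levels`, `ref`, `loglik`, `iterations`,
#'   `converged`.
#' @examples
#' d <- data.frame(y = factor(rep(c("a", "b", "c"), c(30, 40, 30))),
#'                 x = rnorm(100))
#' fit <- fit_multinomial(y ~ x, d)
#' coef(fit)
#' @export
fit_multinomial <- function(formula, data, ref = NULL, tol = 1e-8,
                            max_iter = 200, max_abs_coef = 30) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- factor(stats::model.response(mf))
  if (!is.null(ref)) y <- stats::relevel(y, ref)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  K <- nlevels(y)
  if (K < 2) stop("outcome needs at least 2 levels")
  yi <- as.integer(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1

  probs <- function(B) {
    eta <- cbind(0, X %*% B)
    softmax_rows(eta)
  }
  loglik <- function(P) sum(log(pmax(P[cbind(seq_len(n), yi)], 1e-300)))

  B <- matrix(0, p, K - 1)
  P <- probs(B)
  ll <- loglik(P)
  H <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    G <- crossprod(X, Y[, -1, drop = FALSE] - P[, -1, drop = FALSE])
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
      if (l < k) next
      w <- if (k == l) P[, k + 1] * (1 - P[, k + 1]) else -P[, k + 1] * P[, l + 1]
      blk <- crossprod(X, X * w)
      rk <- (k - 1) * p + seq_len(p); rl <- (l - 1) * p + seq_len(p)
      H[rk, rl] <- blk
      if (l > k) H[rl, rk] <- blk
    }
    delta <- tryCatch(solve(H, as.vector(G)),
                      error = function(e) solve(H + diag(1e-8, nrow(H)), as.vector(G)))
    step <- 1
    repeat {
      Bnew <- B + matrix(step * delta, p, K - 1)
      Pnew <- probs(Bnew)
      llnew <- loglik(Pnew)
      if (llnew >= ll - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    B <- Bnew; P <- Pnew; ll <- llnew
    if (max(abs(B)) > max_abs_coef)
      stop("complete separation suspected: a coefficient diverged beyond ",
           max_abs_coef)
  }
  if (!converged)
    warning("Newton iterations reached max_iter without meeting the gradient tolerance")
  # observed information at the optimum for the covariance
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
    if (l < k) next
    w <- if (k == l) P[, k + 1] * (1 - P[, k + 1]) else -P[, k + 1] * P[, l + 1]
    blk <- crossprod(X, X * w)
    rk <- (k - 1) * p + seq_len(p); rl <- (l - 1) * p + seq_len(p)
    H[rk, rl] <- blk
    if (l > k) H[rl, rk] <- blk
  }
  V <- solve(H)
  cn <- colnames(X)
  lev <- levels(y)
  dimnames(B) <- list(cn, lev[-1])
  dimnames(V) <- rep(list(paste(rep(lev[-1], each = p), cn, sep = ":")), 2)
  structure(list(coefficients = B, vcov = V, levels = lev, ref = lev[1],
                 loglik = ll, iterations = it, converged = converged, n = n),
            class = "multinom_fit")
}

#' @export
coef.multinom_fit <- function(object, ...) object$coefficients

#' @export
vcov.multinom_fit <- function(object, ...) object$vcov

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit (baseline '%s'), n = %d, logLik %.2f, %d iterations\n",
              x$ref, x$n, x$loglik, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

# coefficient and variance of one predictor row for each non-reference level
coef_se_for <- function(fit, term) {
  B <- fit$coefficients
  if (!term %in% rownames(B)) stop("term not in model: ", term)
  p <- nrow(B)
  j <- match(term, rownames(B))
  ks <- seq_len(ncol(B))
  idx <- (ks - 1) * p + j
  list(est = B[j, ], var = diag(fit$vcov)[idx], levels = colnames(B))
}
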
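#' Linear-discriminant fit for categorical imputation
#'
#' Fits class-conditional Gaussian discriminant scores with proportional
#' priors and a pooled within-class covariance, the model behind the
#' discriminant-function imputer: a missing categorical value is drawn from
#' the class posterior at its predictor values.
#'
#' Numerics: the pooled covariance gets a ridge of `ridge` on its diagonal
#' against singularity; discriminant scores are then computed on a
#' reduced-rank whitened basis, dropping eigendirections whose (ridged)
#' eigenvalue falls below `rank_tol` times the largest. The ridge is applied
#' before the rank cut so that directions with zero within-class variance but
#' real between-class separation (e.g. a predictor that copies the target)
#' are retained and dominate the posterior, as they should.
#'
#' @param x numeric predictor matrix (rows = complete cases).
#' @param y class labels (factor or coercible); at least 2 observed classes.
#' @param ridge diagonal ridge on the pooled covariance (default `1e-6`).
#' @param rank_tol relative eigenvalue tolerance (default `1e-10`).
#' @return object of class `discriminant_fit`.
#' @seealso [discriminant_posterior()]
#' @export
discriminant_fit <- function(x, y, ridge = 1e-6, rank_tol = 1e-10) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  G <- nlevels(y)
  if (G < 2) stop("cannot fit a discriminant model with fewer than 2 observed classes")
  n <- nrow(x)
  if (n != length(y)) stop("x and y lengths differ")
  counts <- tabulate(as.integer(y), G)
  if (any(counts == 0)) stop("a class level is absent from the complete rows")
  if (ncol(x) == 0) {
    # no predictors: posterior is the prior
    return(structure(list(proj = matrix(0, 0, 0), z_mu = matrix(0, G, 0),
                          logprior = log(counts / n), classes = levels(y)),
                     class = "discriminant_fit"))
  }
  mu <- rowsum(x, y) / counts
  resid <- x - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(resid) / max(n - G, 1)
  ee <- eigen(S, symmetric = TRUE)
  vals <- ee$values + ridge
  keep <- vals > rank_tol * max(vals)
  proj <- ee$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(vals[keep]), sum(keep))
  structure(list(proj = proj, z_mu = mu %*% proj,
                 logprior = log(counts / n), classes = levels(y)),
            class = "discriminant_fit")
}

#' Class posteriors from a discriminant fit
#'
#' @param fit a [discriminant_fit()] object.
#' @param newx numeric matrix of predictor rows to score.
#' @return `nrow(newx) x G` matrix of class posterior probabilities; columns
#'   named by class.
#' @export
discriminant_posterior <- function(fit, newx) {
  stopifnot(inherits(fit, "discriminant_fit"))
  newx <- as.matrix(newx)
  G <- length(fit$classes)
  n <- nrow(newx)
  if (ncol(fit$proj) == 0) {
    lp <- matrix(fit$logprior, n, G, byrow = TRUE)
  } else {
    z <- newx %*% fit$proj
    d2 <- matrix(rowSums(z^2), n, G) - 2 * z %*% t(fit$z_mu) +
      matrix(rowSums(fit$z_mu^2), n, G, byrow = TRUE)
    lp <- sweep(-0.5 * d2, 2, fit$logprior, "+")
  }
  lp <- lp - apply(lp, 1, max)
  p <- exp(lp)
  p <- p / rowSums(p)
  colnames(p) <- fit$classes
  p
}

# bootstrap indices of the training rows, retried so every class survives the
# resample (parameter-uncertainty propagation must not lose a class); after
# `tries` failures falls back to the original sample.
bootstrap_preserving_classes <- function(y, tries = 25) {
  n <- length(y)
  lev <- unique(y)
  for (i in seq_len(tries)) {
    b <- sample.int(n, n, replace = TRUE)
    if (all(lev %in% y[b])) return(b)
  }
  seq_len(n)
}
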
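#' Round half away from zero
#'
#' Report-mode rounding used for the diagnostic tables: halves round up
#' (2.5 -> 3), matching conventional clinical-table formatting rather than
#' banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Spawn `m` reproducible sub-seeds from one master seed. Each consumer calls
# set.seed() on its own sub-seed, so streams are order-independent and a run
# can be parallelised over imputations without changing results.
derive_stream_seeds <- function(seed, m) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, m)
}

# vectorised draw from row-wise category probabilities (n x K matrix)
sample_categorical <- function(prob) {
  stopifnot(is.matrix(prob), all(prob >= -1e-12))
  K <- ncol(prob)
  cp <- prob
  for (k in seq_len(K)[-1]) cp[, k] <- cp[, k - 1] + cp[, k]
  u <- stats::runif(nrow(prob)) * cp[, K]
  rowSums(u > cp) + 1L
}

softmax_rows <- function(eta) {
  m <- eta[, 1]
  for (k in seq_len(ncol(eta))[-1]) m <- pmax(m, eta[, k])
  e <- exp(eta - m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
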
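# Shared fixtures, built in code at test time.

# small cohort parameters; elevated ideation prevalence keeps all four levels
# of the target populated at small n
small_params <- function(n = 400, seed = 1, prev = 0.2, ...) {
  generator_params(n_participants = n, seed = seed,
                   target_ideation_prevalence = prev, ...)
}

# minimal two-wave long table with a binary predictor `a` and a target `t`
# that copies it exactly; `extra` appends an independent noise predictor
copy_target_table <- function(n = 150, seed = 42, extra = TRUE) {
  set.seed(seed)
  a <- rbinom(2 * n, 1, 0.4)
  d <- data.frame(participant_id = rep(sprintf("P%04d", seq_len(n)), each = 2),
                  wave = rep(c("W1", "W2"), n),
                  a = a, t = a, stringsAsFactors = FALSE)
  if (extra) d$z <- rnorm(2 * n)
  d
}

copy_target_specs <- function(extra = TRUE) {
  sp <- list(variable_spec("t", "binary", role = "target"),
             variable_spec("a", "binary", role = "predictor"))
  if (extra) sp <- c(sp, list(variable_spec("z", "continuous", role = "predictor")))
  do.call(rbind, sp)
}

# direct Bayes-rule posterior under the linear-discriminant model: priors
# from class counts, class means, pooled covariance + ridge, full solve() --
# an implementation independent of the package's whitened-eigenbasis path
oracle_lda_posterior <- function(x, y, newx, ridge = 1e-6) {
  y <- factor(y)
  G <- nlevels(y)
  n <- nrow(x)
  counts <- table(y)
  mu <- do.call(rbind, lapply(levels(y), function(g)
    colMeans(x[y == g, , drop = FALSE])))
  resid <- x - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(resid) / (n - G) + diag(ridge, ncol(x))
  Sinv <- solve(S)
  lp <- sapply(seq_len(G), function(g) {
    dx <- sweep(newx, 2, mu[g, ])
    -0.5 * rowSums((dx %*% Sinv) * dx) + log(counts[g] / n)
  })
  lp <- lp - apply(lp, 1, max)
  p <- exp(lp)
  p / rowSums(p)
}
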
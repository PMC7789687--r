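# Fully-conditional-specification multiple imputation engine.
#
# Each incomplete modeled variable is imputed from a univariate model given
# all other modeled variables, cycling in the visit sequence; after the
# configured burn-in cycles the current draw is stored as one completed
# dataset. Categorical variables use the discriminant-function imputer
# (linear-discriminant posteriors fit on a bootstrap resample of the complete
# rows, then a posterior class draw); continuous variables use Bayesian
# linear regression (posterior draws of coefficients and residual variance,
# then a predictive draw).

# numeric encoding of predictors: ordinal/binary/continuous as numeric
# scores, nominal as dummy indicators (first level dropped)
encode_predictors <- function(data, predictors, specs) {
  if (length(predictors) == 0) return(matrix(0, nrow(data), 0))
  cols <- lapply(predictors, function(v) {
    lv <- specs$level[specs$name == v]
    x <- data[[v]]
    if (lv == "nominal") {
      f <- if (is.factor(x)) x else factor(x)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, "_", levels(f)[-1])
      mm
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      m
    }
  })
  do.call(cbind, cols)
}

# one Bayesian linear-regression predictive draw (ridge-stabilised normal
# model, standard proper-imputation draw: sigma^2 from the scaled inverse
# chi-square, coefficients from their normal posterior, then residual noise)
bayes_lm_draw <- function(X, y, Xmis, ridge = 1e-6) {
  X1 <- cbind(1, X)
  p <- ncol(X1); n <- nrow(X1)
  ch <- chol(crossprod(X1) + diag(ridge, p))
  betahat <- backsolve(ch, forwardsolve(t(ch), crossprod(X1, y)))
  res <- y - X1 %*% betahat
  df <- max(n - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta <- betahat + backsolve(ch, stats::rnorm(p)) * sqrt(sigma2)
  as.vector(cbind(1, Xmis) %*% beta + stats::rnorm(nrow(Xmis)) * sqrt(sigma2))
}

#' Fit FCS multiple imputation
#'
#' Produces `m` completed copies of `masked`: observed cells are bit-identical
#' to the input in every copy; only originally missing cells vary. Each
#' imputation runs on its own RNG stream spawned from `config$seed`, so
#' results are reproducible and order-independent.
#'
#' Per imputation: missing cells are initialized by draws from the observed
#' margin of their variable; then for `burn_in` cycles the incomplete
#' variables are visited in sequence, the variable's univariate imputation
#' model is refit on the originally observed rows (with current values of the
#' other variables as predictors) and its missing cells are redrawn; the last
#' cycle's values are stored.
#'
#' @param masked data.frame (typically a long `cohort_table` after
#'   [mask_wave_item()]).
#' @param specs variable specs, e.g. from [apply_preset()]`$specs`.
#' @param config an [imputation_config()].
#' @return object of class `completed_set`: list with `imputations` (list of
#'   `m` completed data.frames), `variables` (imputed variable names),
#'   `seeds`, `config`, `specs`.
#' @export
fit_fcs <- function(masked, specs, config) {
  stopifnot(inherits(config, "imputation_config"))
  modeled <- specs$name[specs$role %in% c("target", "predictor")]
  missing_cols <- setdiff(modeled, names(masked))
  if (length(missing_cols))
    stop("modeled variables absent from table: ", paste(missing_cols, collapse = ", "))
  miss_idx <- lapply(modeled, function(v) which(is.na(masked[[v]])))
  names(miss_idx) <- modeled
  incomplete <- modeled[lengths(miss_idx) > 0]
  seeds <- derive_stream_seeds(config$seed, config$m)

  if (length(incomplete) == 0) {
    return(structure(list(imputations = replicate(config$m, masked, simplify = FALSE),
                          variables = character(0), seeds = seeds,
                          config = config, specs = specs),
                     class = "completed_set"))
  }

  visit <- config$visit_sequence %||% specs$name
  visit <- visit[visit %in% incomplete]
  if (!setequal(visit, incomplete))
    stop("visit_sequence must cover every incomplete modeled variable")

  level_of <- function(v) specs$level[specs$name == v]
  form_of <- function(v) specs$imputation_form[specs$name == v]

  restore_type <- function(template, values) {
    if (is.factor(template)) factor(values, levels = levels(template))
    else if (is.integer(template)) as.integer(values)
    else as.numeric(values)
  }

  imputations <- vector("list", config$m)
  for (i in seq_len(config$m)) {
    set.seed(seeds[i])
    d <- masked
    for (v in incomplete) {
      obs <- d[[v]][-miss_idx[[v]]]
      d[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]), replace = TRUE)
    }
    for (cyc in seq_len(config$burn_in)) {
      for (v in visit) {
        idx <- miss_idx[[v]]
        preds <- setdiff(modeled, v)
        X <- encode_predictors(d, preds, specs)
        train <- setdiff(seq_len(nrow(d)), idx)
        if (form_of(v) == "discriminant") {
          ytr <- d[[v]][train]
          if (length(unique(ytr)) < 2)
            stop(sprintf("cannot fit '%s': fewer than 2 class levels among complete rows", v))
          boot <- bootstrap_preserving_classes(ytr)
          fit <- discriminant_fit(X[train, , drop = FALSE][boot, , drop = FALSE],
                                  ytr[boot])
          post <- discriminant_posterior(fit, X[idx, , drop = FALSE])
          draw <- fit$classes[sample_categorical(post)]
          d[[v]][idx] <- restore_type(masked[[v]], draw)
        } else {
          ytr <- as.numeric(d[[v]][train])
          d[[v]][idx] <- bayes_lm_draw(X[train, , drop = FALSE], ytr,
                                       X[idx, , drop = FALSE])
        }
      }
    }
    imputations[[i]] <- d
  }
  structure(list(imputations = imputations, variables = incomplete,
                 seeds = seeds, config = config, specs = specs),
            class = "completed_set")
}

#' @export
print.completed_set <- function(x, ...) {
  cat(sprintf("Completed set: m = %d imputations (preset %s)\n",
              length(x$imputations), x$config$preset))
  if (length(x$variables))
    cat("  imputed variables:", paste(x$variables, collapse = ", "), "\n")
  else cat("  input had no missing cells\n")
  invisible(x)
}

#' Random-assignment baseline
#'
#' Assigns the target at random at rate `p`, independent of everything --
#' the uninformed comparator whose expected sensitivity and positive
#' predictive value equal `100 * p` and the truth prevalence respectively.
#'
#' @param n number of draws.
#' @param p assignment probability in `[0, 1]`.
#' @param seed optional seed for this draw.
#' @return integer 0/1 vector of length `n`.
#' @export
ran_assign <- function(n, p, seed = NULL) {
  if (!(is.numeric(p) && length(p) == 1 && p >= 0 && p <= 1))
    stop("p must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::rbinom(n, 1L, p)
}

#' Persist a completed set as CSV files plus a JSON manifest
#'
#' @param completed a `completed_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_completed_set <- function(completed, dir) {
  stopifnot(inherits(completed, "completed_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- length(completed$imputations)
  for (i in seq_len(m))
    utils::write.csv(completed$imputations[[i]],
                     file.path(dir, sprintf("imputation_%03d.csv", i)),
                     row.names = FALSE, na = "")
  manifest <- list(m = m, variables = completed$variables,
                   seeds = completed$seeds,
                   config = unclass(completed$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
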
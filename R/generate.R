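#' Generate a synthetic two-wave cohort
#'
#' Simulates a long-format cohort (one row per participant per wave) with the
#' statistical structure the imputation validation assumes: a latent
#' depression severity per person-wave, bivariate normal across waves, driving
#' nine 4-level ordinal items through a graded-response cut; a correlated PTSD
#' latent driving seventeen 5-level PCL-C items plus the DSM-IV screening
#' composite; physical-functioning and alcohol-problem latents; demographic
#' covariates drawn from configured marginals; and smoking status and
#' sleep-duration category drawn from multinomial-logit models whose
#' dichotomized-ideation coefficients are the log of the configured odds
#' ratios.
#'
#' @param params a [generator_params()] object.
#' @return a `data.frame` of class `cohort_table`, `2 * n_participants` rows,
#'   sorted by participant then wave, with columns `participant_id`, `wave`,
#'   the demographic factors, `phq1..phq9` (0-3), `pcl1..pcl17` (0-4),
#'   `ptsd_screen` (0/1), `pf1..pf10` (0-2), `alc1..alc5` (0/1), `smoking`,
#'   `sleep_hours`, `sleep_cat`.
#' @examples
#' co <- generate_cohort(generator_params(n_participants = 200, seed = 7))
#' table(co$wave)
#' mean(dichotomize_ideation(co$phq9[co$wave == "W2"]))
#' @export
generate_cohort <- function(params) {
  validate_generator_params(params)
  set.seed(params$seed)
  n <- as.integer(params$n_participants)
  pid <- sprintf("P%06d", seq_len(n))

  demo <- lapply(names(params$covariate_marginals), function(v) {
    pm <- params$covariate_marginals[[v]]
    factor(sample(names(pm), n, TRUE, prob = pm), levels = names(pm))
  })
  names(demo) <- names(params$covariate_marginals)

  shift <- numeric(n)
  for (v in names(params$covariate_effects))
    shift <- shift + unname(params$covariate_effects[[v]][as.character(demo[[v]])])

  draw_pair <- function(rho) {
    x1 <- stats::rnorm(n)
    cbind(x1, rho * x1 + sqrt(1 - rho^2) * stats::rnorm(n))
  }
  rho <- params$cross_wave_rho
  u  <- draw_pair(rho)                    # depression innovations
  vq <- draw_pair(rho)                    # PTSD-specific innovations
  vp <- draw_pair(rho)                    # physical-functioning-specific
  va <- draw_pair(rho)                    # alcohol-specific
  z  <- shift + u                          # latent depression severity
  q  <- params$ptsd_rho   * u + sqrt(1 - params$ptsd_rho^2)   * vq
  pf <- params$pf_rho     * u + sqrt(1 - params$pf_rho^2)     * vp
  al <- params$alcohol_rho * u + sqrt(1 - params$alcohol_rho^2) * va

  alpha_smk <- solve_outcome_intercepts(params$smoking_marginals,
                                        log(params$smoking_aors), "never",
                                        params$target_ideation_prevalence)
  alpha_slp <- solve_outcome_intercepts(params$sleep_marginals,
                                        log(params$sleep_aors), SLEEP_REF,
                                        params$target_ideation_prevalence)

  make_wave <- function(w) {
    zi <- z[, w]; qi <- q[, w]; pfi <- pf[, w]; ali <- al[, w]
    df <- data.frame(participant_id = pid, wave = WAVES[w],
                     demo, stringsAsFactors = FALSE)
    for (j in 1:9)
      df[[PHQ_ITEMS[j]]] <- ordinal_cut(params$item_loadings[j] * zi + stats::rnorm(n),
                                        params$item_thresholds[[j]])
    for (j in 1:17)
      df[[PCL_ITEMS[j]]] <- ordinal_cut(params$pcl_loadings[j] * qi + stats::rnorm(n),
                                        params$pcl_thresholds[[j]])
    df$ptsd_screen <- screen_ptsd(as.matrix(df[PCL_ITEMS]))
    for (j in 1:10)
      df[[PF_ITEMS[j]]] <- ordinal_cut(params$pf_loadings[j] * pfi + stats::rnorm(n),
                                       params$pf_thresholds[[j]])
    for (j in 1:5) {
      tau <- stats::qnorm(1 - params$alcohol_prevalence[j]) * sqrt(2)
      df[[ALC_ITEMS[j]]] <- as.integer(ali + stats::rnorm(n) > tau)
    }
    expo <- dichotomize_ideation(df$phq9)
    df$smoking <- draw_outcome(alpha_smk, log(params$smoking_aors), expo,
                               params$smoking_covariate_coefs, df, SMOKING_LEVELS)
    slp_cat <- draw_outcome(alpha_slp, log(params$sleep_aors), expo,
                            params$sleep_covariate_coefs, df, SLEEP_LEVELS)
    df$sleep_hours <- draw_sleep_hours(slp_cat)
    df$sleep_cat <- categorize_sleep(df$sleep_hours)
    df
  }

  out <- rbind(make_wave(1), make_wave(2))
  out <- out[order(out$participant_id, out$wave), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# graded-response cut: number of strictly increasing thresholds exceeded
ordinal_cut <- function(lat, thresholds) {
  findInterval(lat, thresholds)
}

draw_outcome <- function(alpha, log_or, expo, covariate_coefs, df, levels_) {
  n <- length(expo)
  eta <- matrix(rep(alpha, each = n), n, length(levels_),
                dimnames = list(NULL, names(alpha)))
  beta <- setNames(numeric(length(levels_)), names(alpha))
  beta[names(log_or)] <- log_or
  eta <- eta + outer(expo, beta)
  for (lev in names(covariate_coefs)) {
    co <- covariate_coefs[[lev]]
    for (v in intersect(DEMO_VARS, names(df))) {
      add <- unname(co[as.character(df[[v]])])
      add[is.na(add)] <- 0      # categories without a configured coefficient
      eta[, lev] <- eta[, lev] + add
    }
  }
  idx <- sample_categorical(softmax_rows(eta))
  factor(levels_[idx], levels = levels_)
}

# self-reported whole hours consistent with the category bands
draw_sleep_hours <- function(cat) {
  n <- length(cat)
  h <- integer(n)
  i <- cat == "le5";   h[i] <- sample(c(3L, 4L, 5L), sum(i), TRUE, prob = c(0.15, 0.35, 0.50))
  i <- cat == "h6";    h[i] <- 6L
  i <- cat == "h7to9"; h[i] <- sample(7:9, sum(i), TRUE, prob = c(0.45, 0.40, 0.15))
  i <- cat == "ge10";  h[i] <- sample(10:12, sum(i), TRUE, prob = c(0.70, 0.20, 0.10))
  as.numeric(h)
}

#' Categorize sleep hours into the analysis bands
#'
#' Bands: 5 or fewer hours, 6, 7-9 (reference), 10 or more. Sleep enters the
#' imputation models as continuous hours and analyses as this category.
#'
#' @param hours nonnegative numeric vector.
#' @return factor with levels `le5`, `h6`, `h7to9`, `ge10`.
#' @export
categorize_sleep <- function(hours) {
  stopifnot(all(hours >= 0))
  cut(hours, breaks = c(-Inf, 5, 6.999, 9.999, Inf),
      labels = SLEEP_LEVELS, right = TRUE)
}

#' DSM-IV sensitive PTSD screen from 17 PCL-C items
#'
#' Positive when "moderate or greater" (code >= 2 on the 0-4 coding) is
#' endorsed on at least 1 intrusion item (items 1-5), 3 avoidance items
#' (6-12), and 2 hyperarousal items (13-17) simultaneously.
#'
#' @param pcl_items integer vector of 17 item codes (0-4), or an
#'   `n x 17` matrix.
#' @return integer 0/1 (vector of length `n` for matrix input).
#' @export
screen_ptsd <- function(pcl_items) {
  if (is.null(dim(pcl_items))) pcl_items <- matrix(pcl_items, nrow = 1)
  if (ncol(pcl_items) != 17) stop("expected 17 PCL-C items")
  if (any(pcl_items < 0 | pcl_items > 4)) stop("PCL-C codes must lie in 0-4")
  mod <- pcl_items >= 2
  out <- as.integer(rowSums(mod[, PCL_INTRUSION, drop = FALSE]) >= 1 &
                    rowSums(mod[, PCL_AVOIDANCE, drop = FALSE]) >= 3 &
                    rowSums(mod[, PCL_HYPERAROUSAL, drop = FALSE]) >= 2)
  out
}

#' Dichotomize a 4-level depression item
#'
#' Present if reported "several days" or more, i.e. code >= 1 on the 0-3
#' coding ("not at all" = 0).
#'
#' @param level integer vector with values in 0-3 (`NA` passed through).
#' @return integer 0/1 vector.
#' @export
dichotomize_ideation <- function(level) {
  lv <- level[!is.na(level)]
  if (length(lv) && (any(lv < 0) || any(lv > 3)))
    stop("item codes must lie in 0-3")
  as.integer(level >= 1)
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- length(unique(x$participant_id))
  cat(sprintf("Two-wave cohort: %d participants, %d rows (long format)\n",
              n, nrow(x)))
  miss <- vapply(x, function(col) sum(is.na(col)), integer(1))
  if (any(miss > 0)) {
    mm <- miss[miss > 0]
    cat("  missing cells:", paste(sprintf("%s=%d", names(mm), mm), collapse = ", "), "\n")
  }
  w2 <- x$wave == "W2"
  if (!anyNA(x$phq9[w2]))
    cat(sprintf("  dichotomized ideation prevalence (W2): %.2f%%\n",
                100 * mean(dichotomize_ideation(x$phq9[w2]))))
  invisible(x)
}
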
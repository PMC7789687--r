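test_that("model presets expose the documented predictor sets", {
  pb <- apply_preset("PHQ-BIN")
  expect_length(pb$predictors, 8)
  expect_setequal(pb$predictors, paste0("phq", 1:8))
  expect_equal(pb$target_level, "binary")

  ao <- apply_preset("ALL-ORD")
  expect_length(ao$predictors, 48)
  expect_equal(ao$target_level, "ordinal4")
  expect_true(all(c("ptsd_screen", "smoking", "sleep_hours") %in% ao$predictors))
  expect_true(all(paste0("pcl", 1:17) %in% ao$predictors))
  expect_equal(sum(ao$specs$level == "continuous"), 1)  # sleep is continuous

  # alternate target: the remaining 8 items (including phq9) are predictors
  alt <- apply_preset("ALL-BIN", target = "phq4")
  expect_true("phq9" %in% alt$predictors)
  expect_false("phq4" %in% alt$predictors)

  expect_error(apply_preset("custom", predictors = character(0)), "non-empty")
  expect_error(apply_preset("NOPE"), "unknown preset")
  expect_error(imputation_config(m = 1), "at least 2")
})

test_that("a fully observed input returns m identical copies", {
  d <- copy_target_table(n = 40)
  cs <- fit_fcs(d, copy_target_specs(), imputation_config(m = 3, seed = 1))
  expect_length(cs$imputations, 3)
  for (imp in cs$imputations) expect_identical(imp, d)
})

test_that("a target copying an observed predictor is recovered almost perfectly", {
  d <- copy_target_table(n = 200, seed = 9)
  mk <- mask_wave_item(d, "t", "W2")
  truth <- mk$mask_record$truth
  cs <- fit_fcs(mk$table, copy_target_specs(),
                imputation_config(m = 5, burn_in = 3, seed = 2))
  # oracle: the Bayes classifier under the generating rule is the copied
  # predictor itself, with accuracy 1; the imputer must get >= 0.95
  for (imp in cs$imputations) {
    acc <- mean(imp$t[imp$wave == "W2"] == truth)
    expect_gte(acc, 0.95)
  }
})

test_that("a target independent of its predictors reproduces the observed margin", {
  p <- generator_params(n_participants = 3000, seed = 17,
                        item_loadings = c(rep(1, 8), 0),
                        target_ideation_prevalence = 0.2)
  co <- generate_cohort(p)
  w1_prev <- mean(dichotomize_ideation(co$phq9[co$wave == "W1"]))
  ps <- apply_preset("PHQ-BIN")
  co$phq9 <- dichotomize_ideation(co$phq9)
  mk <- mask_wave_item(co, "phq9", "W2")
  cs <- fit_fcs(mk$table, ps$specs,
                imputation_config(m = 10, burn_in = 3, seed = 3))
  imp_prev <- mean(sapply(cs$imputations, function(d)
    mean(d$phq9[d$wave == "W2"])))
  # marginal-draw oracle: with no signal the posterior is the W1 margin;
  # 3 binomial MC sd at n = 3000 x 10 imputations, plus estimation noise
  expect_lt(abs(imp_prev - w1_prev), 0.025)
})

test_that("observed cells are preserved bit-identically and runs reproduce", {
  co <- generate_cohort(small_params(n = 150, seed = 23))
  ps <- apply_preset("ALL-ORD")
  mk <- mask_wave_item(co, "phq9", "W2")
  cfg <- imputation_config(m = 3, burn_in = 2, seed = 11)
  cs <- fit_fcs(mk$table, ps$specs, cfg)
  obs <- !is.na(mk$table$phq9)
  for (imp in cs$imputations) {
    expect_identical(imp$phq9[obs], mk$table$phq9[obs])
    expect_identical(imp[setdiff(names(imp), "phq9")],
                     mk$table[setdiff(names(mk$table), "phq9")])
    expect_false(anyNA(imp$phq9))
    expect_true(all(imp$phq9[!obs] %in% 0:3))
  }
  cs2 <- fit_fcs(mk$table, ps$specs, cfg)
  expect_identical(cs$imputations, cs2$imputations)
  # different seed, different draws
  cs3 <- fit_fcs(mk$table, ps$specs, imputation_config(m = 3, burn_in = 2, seed = 12))
  expect_false(identical(cs$imputations[[1]]$phq9, cs3$imputations[[1]]$phq9))
})

test_that("random assignment matches its Bernoulli contract", {
  expect_identical(ran_assign(50, 0, seed = 1), rep(0L, 50))
  expect_identical(ran_assign(50, 1, seed = 1), rep(1L, 50))
  expect_error(ran_assign(10, 1.5), "\\[0, 1\\]")
  x <- ran_assign(63028, 0.0405, seed = 99)
  # expected positives 2553, binomial sd ~49.5
  expect_lt(abs(sum(x) - 2553), 3 * sqrt(63028 * 0.0405 * 0.9595))
})

test_that("Rubin pooling reproduces hand arithmetic and degenerate cases", {
  pe <- pool_rubin(c(0, 1), c(1, 1))
  expect_equal(pe$point, 0.5)
  expect_equal(pe$within, 1)
  expect_equal(pe$between, 0.5)
  expect_equal(pe$total, 1.75)

  same <- pool_rubin(rep(2.2, 5), rep(0.3, 5))
  expect_equal(same$point, 2.2)
  expect_equal(same$between, 0)
  expect_equal(same$total, same$within)
  expect_equal(same$df, Inf)
  expect_equal(same$ci95, 2.2 + c(-1, 1) * qnorm(0.975) * sqrt(0.3))

  expect_error(pool_rubin(1, 1), "m >= 2")
  expect_error(pool_rubin(c(1, NA), c(1, 1)), "finite")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "nonnegative")
})

test_that("Rubin-pooled intervals achieve nominal coverage on a normal-mean problem", {
  # proper MI for the mean of y (y = 1 + 0.8 x + e, 40% MCAR in y),
  # Bayesian-linear imputer, m = 15; 500 replicates
  specs <- rbind(variable_spec("y", "continuous", role = "target"),
                 variable_spec("x", "continuous", role = "predictor"))
  mu <- 1
  set.seed(2024)
  rep_seeds <- sample.int(1e7, 500)
  covered <- vapply(rep_seeds, function(s) {
    set.seed(s)
    n <- 80
    x <- rnorm(n)
    y <- mu + 0.8 * x + rnorm(n) * sqrt(1 - 0.8^2)
    d <- data.frame(x = x, y = y)
    d$y[sample.int(n, 32)] <- NA
    cs <- fit_fcs(d, specs, imputation_config(m = 15, burn_in = 2, seed = s))
    est <- vapply(cs$imputations, function(di) mean(di$y), numeric(1))
    vr <- vapply(cs$imputations, function(di) var(di$y) / n, numeric(1))
    pe <- pool_rubin(est, vr)
    pe$ci95[1] <= mu && mu <= pe$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
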
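test_that("confidence-interval overlap follows the shared-endpoint convention", {
  expect_true(ci_overlap(c(1.12, 1.36), c(1.05, 1.44)))
  expect_false(ci_overlap(c(4.87, 6.07), c(6.30, 7.71)))
  expect_true(ci_overlap(c(0, 1), c(1, 2)))      # touching endpoints overlap
  # symmetric in its arguments
  expect_equal(ci_overlap(c(0.5, 2), c(1.8, 3)), ci_overlap(c(1.8, 3), c(0.5, 2)))
  expect_equal(ci_overlap(c(1, 2), c(3, 4)), ci_overlap(c(3, 4), c(1, 2)))
  expect_error(ci_overlap(c(2, 1), c(0, 1)), "inverted")
})

test_that("pooled AORs collapse to the single fit when datasets are identical, and ignore dataset order", {
  co <- generate_cohort(small_params(n = 500, seed = 41, prev = 0.3))
  ps <- apply_preset("PHQ-BIN")
  tbl <- co; tbl$phq9 <- dichotomize_ideation(tbl$phq9)
  mk <- mask_wave_item(tbl, "phq9", "W2")
  cs <- fit_fcs(mk$table, ps$specs, imputation_config(m = 4, burn_in = 2, seed = 5))
  spec <- association_spec("smoking")

  res <- pooled_aor(cs, "phq9", spec)
  cs_rev <- cs
  cs_rev$imputations <- rev(cs$imputations)
  res_rev <- pooled_aor(cs_rev, "phq9", spec)
  expect_equal(res$aor, res_rev$aor, tolerance = 1e-12)
  expect_equal(res$lo, res_rev$lo, tolerance = 1e-12)

  # all m datasets identical: pooled point equals the single fit, B = 0,
  # CI driven by W only
  cs_same <- cs
  cs_same$imputations <- rep(cs$imputations[1], 3)
  res_same <- pooled_aor(cs_same, "phq9", spec)
  d1 <- cs$imputations[[1]]
  single <- aor_from_fit(wavegap:::fit_association(
    d1, dichotomize_ideation(d1$phq9[d1$wave == "W2"]), spec))
  expect_equal(res_same$aor, single$aor, tolerance = 1e-10)
  expect_equal(res_same$lo, single$lo, tolerance = 1e-10)
  pooled <- attr(res_same, "pooled")
  expect_true(all(vapply(pooled, function(p) p$between == 0, logical(1))))
  # with between-variance, the pooled CI is wider than the W-only CI
  expect_true(all(vapply(attr(res, "pooled"),
                         function(p) p$total >= p$within, logical(1))))
})

test_that("pooled intervals for a configured log-odds ratio are valid and the point estimate unbiased", {
  # Imputed-exposure association with the outcome inside the imputation
  # model: the pooled point recovers the configured effect, and the Rubin
  # interval is confidence-valid. Coverage runs above nominal here (the
  # imputer conditions on more than the analysis model, which makes Rubin's
  # total variance conservative), so the check is a lower bound plus an
  # unbiasedness bound, not a two-sided calibration band; see the vignette.
  res <- t(vapply(1:200, function(s) {
    p <- generator_params(n_participants = 1500, seed = s,
                          target_ideation_prevalence = 0.30)
    co <- generate_cohort(p)
    ps <- apply_preset("ALL-BIN")
    tbl <- co; tbl$phq9 <- dichotomize_ideation(tbl$phq9)
    mk <- mask_wave_item(tbl, "phq9", "W2")
    cs <- fit_fcs(mk$table, ps$specs,
                  imputation_config(m = 8, burn_in = 2, seed = s + 5000))
    r <- pooled_aor(cs, "phq9", association_spec("smoking"))
    k <- r$level == "current"
    c(cover = as.numeric(r$lo[k] <= 1.87 && 1.87 <= r$hi[k]),
      est = log(r$aor[k]))
  }, numeric(2)))
  expect_gte(mean(res[, "cover"]), 0.91)
  mc_se <- sd(res[, "est"]) / sqrt(nrow(res))
  expect_lt(abs(mean(res[, "est"]) - log(1.87)), 3 * mc_se + 0.02)
})

test_that("imputed-exposure associations are directionally concordant with the configured effects", {
  # configured sleep AORs are all > 1; the PHQ-BIN-imputed exposure should
  # estimate all three > 1 in >= 90% of seeds
  # n = 20,000 per seed: large enough that Monte-Carlo noise does not swamp
  # the (attenuated) imputed-exposure effect at the rarer outcome levels
  seeds <- 1:20
  ok <- vapply(seeds, function(s) {
    p <- generator_params(n_participants = 20000, seed = s)
    co <- generate_cohort(p)
    ps <- apply_preset("PHQ-BIN")
    tbl <- co; tbl$phq9 <- dichotomize_ideation(tbl$phq9)
    mk <- mask_wave_item(tbl, "phq9", "W2")
    cs <- fit_fcs(mk$table, ps$specs,
                  imputation_config(m = 4, burn_in = 2, seed = s + 1000))
    res <- pooled_aor(cs, "phq9", association_spec("sleep_cat"))
    all(res$aor > 1)   # every configured AOR exceeds 1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
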
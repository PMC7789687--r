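test_that("generation is deterministic and respects the table contract", {
  p <- small_params(n = 300, seed = 7)
  co1 <- generate_cohort(p)
  co2 <- generate_cohort(p)
  expect_identical(co1, co2)

  expect_equal(nrow(co1), 600)
  expect_false(anyDuplicated(co1[c("participant_id", "wave")]) > 0)
  expect_true(all(table(co1$participant_id) == 2))
  for (it in paste0("phq", 1:9)) expect_true(all(co1[[it]] %in% 0:3))
  for (it in paste0("pcl", 1:17)) expect_true(all(co1[[it]] %in% 0:4))
  for (it in paste0("pf", 1:10)) expect_true(all(co1[[it]] %in% 0:2))
  expect_true(all(co1$ptsd_screen %in% 0:1))
  expect_true(all(co1$sleep_hours >= 0))
  expect_identical(co1$sleep_cat, categorize_sleep(co1$sleep_hours))
  expect_false(anyNA(co1))

  co3 <- generate_cohort(small_params(n = 300, seed = 8))
  expect_false(identical(co1$phq1, co3$phq1))
})

test_that("empirical covariate and outcome marginals match the configuration", {
  p <- generator_params(n_participants = 12000, seed = 21)
  co <- generate_cohort(p)
  w1 <- co[co$wave == "W1", ]
  for (v in names(p$covariate_marginals)) {
    emp <- as.vector(table(w1[[v]]) / nrow(w1))
    tgt <- as.vector(p$covariate_marginals[[v]])
    # binomial Monte-Carlo bound: 4 sd of a proportion at n = 12,000
    expect_true(all(abs(emp - tgt) < 4 * sqrt(tgt * (1 - tgt) / 12000)),
                info = v)
  }
  emp_smk <- as.vector(table(w1$smoking) / nrow(w1))
  expect_true(all(abs(emp_smk - as.vector(p$smoking_marginals)) < 0.02))
  emp_slp <- as.vector(table(w1$sleep_cat) / nrow(w1))
  expect_true(all(abs(emp_slp - as.vector(p$sleep_marginals)) < 0.02))
})

test_that("zero loadings give uncorrelated items; cross-wave correlation is monotone in rho", {
  p0 <- generator_params(n_participants = 4000, seed = 3,
                         item_loadings = rep(0, 9))
  co <- generate_cohort(p0)
  w1 <- co[co$wave == "W1", ]
  cors <- cor(as.matrix(w1[paste0("phq", 1:8)]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.06)

  cross_cor <- sapply(c(0, 0.4, 0.8), function(r) {
    co <- generate_cohort(generator_params(n_participants = 4000, seed = 11,
                                           cross_wave_rho = r))
    s1 <- rowSums(co[co$wave == "W1", paste0("phq", 1:8)])
    s2 <- rowSums(co[co$wave == "W2", paste0("phq", 1:8)])
    cor(s1, s2)
  })
  expect_true(all(diff(cross_cor) > 0.05))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(generator_params(cross_wave_rho = 1), "\\[0, 1\\)")
  expect_error(generator_params(target_ideation_prevalence = 0), "\\(0, 1\\)")
  p <- generator_params()
  p$item_thresholds[[3]] <- c(1, 1, 2)          # not strictly increasing
  expect_error(validate_generator_params <- generate_cohort(p), "strictly increasing")
  expect_error(generator_params(smoking_marginals = c(never = 0.8, former = 0.5,
                                                      current = 0.1)),
               "sum to 1")
})

test_that("threshold calibration hits requested prevalences on fresh seeds", {
  # symmetric case: target 0.5 puts the cutpoint at the latent median (zero)
  p <- generator_params(n_participants = 1000, seed = 5,
                        target_ideation_prevalence = 0.5)
  p50 <- calibrate_ideation_threshold(p, seed = 101)
  expect_lt(abs(p50$item_thresholds[[9]][1]), 0.02)

  check_fresh <- function(target, lo, hi) {
    p <- generator_params(n_participants = 30000, seed = 5,
                          target_ideation_prevalence = target)
    p <- calibrate_ideation_threshold(p, seed = 303)
    p$seed <- 909L                               # fresh generation seed
    co <- generate_cohort(p)
    prev <- mean(dichotomize_ideation(co$phq9[co$wave == "W2"]))
    expect_gt(prev, lo); expect_lt(prev, hi)
  }
  check_fresh(0.0405, 0.037, 0.044)   # +-3 binomial sd around 4.05% at n=30,000
  check_fresh(0.10, 0.094, 0.106)
})

test_that("null configured smoking effect yields null estimated AORs", {
  # smoking_aors = (1, 1): the ideation CI should cover 1 in >= 90% of seeds
  covered <- sapply(1:50, function(s) {
    p <- generator_params(n_participants = 2500, seed = s,
                          target_ideation_prevalence = 0.15,
                          smoking_aors = c(former = 1, current = 1))
    co <- generate_cohort(p)
    w2 <- co[co$wave == "W2", ]
    w2$ideation <- dichotomize_ideation(w2$phq9)
    fit <- fit_multinomial(smoking ~ ideation, w2, ref = "never")
    cs <- wavegap:::coef_se_for(fit, "ideation")
    ci_lo <- cs$est - 1.96 * sqrt(cs$var)
    ci_hi <- cs$est + 1.96 * sqrt(cs$var)
    all(ci_lo <= 0 & ci_hi >= 0)
  })
  expect_gte(mean(covered), 0.9)
})

test_that("PTSD screen implements the DSM-IV sensitive rule", {
  expect_equal(screen_ptsd(rep(0, 17)), 0L)
  # exactly 1 intrusion, 3 avoidance, 2 hyperarousal at "moderate" (code 2)
  v <- rep(0, 17)
  v[c(1, 6, 7, 8, 13, 14)] <- 2
  expect_equal(screen_ptsd(v), 1L)
  # avoidance minimum unmet (only 2 of 3)
  v2 <- rep(0, 17)
  v2[c(1, 6, 7, 13, 14)] <- 2
  expect_equal(screen_ptsd(v2), 0L)
  # code 1 ("a little") does not count as moderate
  v3 <- rep(1, 17)
  expect_equal(screen_ptsd(v3), 0L)
  expect_equal(screen_ptsd(rep(4, 17)), 1L)
  expect_error(screen_ptsd(rep(0, 16)), "17")
  # vectorised over rows
  expect_equal(screen_ptsd(rbind(rep(0, 17), v)), c(0L, 1L))
})

test_that("ideation dichotomization is 'several days' or more", {
  expect_equal(dichotomize_ideation(0), 0L)
  expect_equal(dichotomize_ideation(1), 1L)
  expect_equal(dichotomize_ideation(3), 1L)
  expect_equal(dichotomize_ideation(c(0, 2, NA)), c(0L, 1L, NA))
  expect_error(dichotomize_ideation(4), "0-3")
  expect_error(dichotomize_ideation(-1), "0-3")
})
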
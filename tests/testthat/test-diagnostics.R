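test_that("confusion tabulates against truth and validates its inputs", {
  truth <- rep(c(1, 0), c(5, 15))
  cc <- confusion(truth, truth)
  expect_equal(cc[c("tp", "tn", "fp", "fn")],
               list(tp = 5L, tn = 15L, fp = 0L, fn = 0L))
  cc2 <- confusion(1 - truth, truth)
  expect_equal(cc2$tp, 0L)
  expect_equal(cc2$tn, 0L)
  set.seed(1)
  a <- rbinom(63028, 1, 0.04); b <- rbinom(63028, 1, 0.04)
  cc3 <- confusion(a, b)
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 63028L)
  expect_error(confusion(1:3, 1:2), "lengths differ")
  expect_error(confusion(c(1, NA), c(1, 0)), "missing")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("diagnostic statistics follow their defining ratios", {
  s <- diag_stats(list(tp = 1689, fn = 865, tn = 58137, fp = 2338))
  expect_equal(unname(s["sensitivity"]), 100 * 1689 / 2554, tolerance = 1e-12)
  expect_equal(round_half_up(s[["sensitivity"]]), 66)
  expect_equal(round_half_up(s[["ppv"]]), 42)
  expect_equal(round_half_up(s[["prevalence"]], 2), 6.39)
  s2 <- diag_stats(list(tp = 861, fn = 1692, tn = 1, fp = 1))
  expect_equal(round_half_up(s2[["sensitivity"]]), 34)
  expect_equal(unname(diag_stats(list(tp = 7, fn = 0, tn = 5, fp = 3))["sensitivity"]), 100)
})

test_that("diagnostics are scale-free and satisfy complement identities", {
  base <- list(tp = 13, fp = 29, tn = 411, fn = 17)
  s1 <- diag_stats(base)
  s2 <- diag_stats(lapply(base, `*`, 7L))
  expect_equal(s1, s2)
  expect_equal(unname(s1["sensitivity"] + 100 * 17 / (13 + 17)), 100)
  expect_equal(unname(s1["specificity"] + 100 * 29 / (411 + 29)), 100)
  expect_equal(unname(s1["ppv"] + 100 * 29 / (13 + 29)), 100)
  expect_equal(unname(s1["npv"] + 100 * 17 / (411 + 17)), 100)
})

test_that("zero denominators are flagged undefined, never silent zeros", {
  expect_warning(s <- diag_stats(list(tp = 0, fp = 0, tn = 10, fn = 2)),
                 "PPV undefined")
  expect_true(is.na(s[["ppv"]]))
  expect_equal(unname(s[["specificity"]]), 100)
})

test_that("pooling averages across imputations with percentile intervals", {
  rec <- function(tp, fp, tn, fn) {
    cc <- confusion(rep(c(1, 1, 0, 0), c(tp, fp, tn, fn)),
                    rep(c(1, 0, 0, 1), c(tp, fp, tn, fn)))
    list(counts = cc, stats = diag_stats(cc))
  }
  # identical tuples: interval degenerate at the value
  same <- pool_diagnostics(list(rec(5, 3, 40, 2), rec(5, 3, 40, 2)))
  expect_equal(same$stats["q2.5", "sensitivity"],
               same$stats["q97.5", "sensitivity"])
  # m = 2, sensitivities 60% and 70% pool to 65%
  two <- pool_diagnostics(list(rec(6, 5, 35, 4), rec(7, 5, 35, 3)))
  expect_equal(unname(two$stats["mean", "sensitivity"]), 65)
  expect_equal(unname(two$stats["min", "sensitivity"]), 60)
  expect_equal(unname(two$stats["max", "sensitivity"]), 70)
  expect_error(pool_diagnostics(list(rec(1, 1, 1, 1))), "m >= 2")
})

test_that("random assignment has its analytic operating characteristics", {
  # under independence E[sens] = 100p, E[spec] = 100(1-p),
  # E[PPV] = truth prevalence, E[NPV] = 1 - truth prevalence
  set.seed(5150)
  n <- 20000; m <- 50
  truth <- rbinom(n, 1, 0.10)
  per <- evaluate_ran(truth, p = 0.25, m = m, seed = 60601)
  pool <- pool_diagnostics(per)
  mce <- function(p, cnt) 100 * 3 * sqrt(p * (1 - p) / cnt) / sqrt(m)
  expect_lt(abs(pool$stats["mean", "sensitivity"] - 25), mce(0.25, sum(truth)))
  expect_lt(abs(pool$stats["mean", "specificity"] - 75), mce(0.75, n - sum(truth)))
  expect_lt(abs(pool$stats["mean", "ppv"] - 100 * mean(truth)),
            mce(mean(truth), 0.25 * n) + 0.2)
  expect_lt(abs(pool$stats["mean", "npv"] - 100 * (1 - mean(truth))),
            mce(mean(truth), 0.75 * n) + 0.2)
})

test_that("the report table formats pooled diagnostics at printed precision", {
  set.seed(9)
  truth <- rbinom(2000, 1, 0.2)
  per <- evaluate_ran(truth, m = 20, seed = 4)
  rep1 <- diagnostics_report(list(RAN = pool_diagnostics(per)), truth)
  expect_equal(rep1$statistic[5], "Prevalence")
  expect_match(rep1$RAN[5], "^\\d+\\.\\d{2} \\(")
  expect_match(rep1$RAN[6], "^\\d+ \\(\\d+-\\d+\\)$")
  expect_equal(rep1[["Self-reported"]][3], "-")
})
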
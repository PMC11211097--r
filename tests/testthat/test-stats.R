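# Reference p-values for the hand-implemented normality tests were computed
# with an independent implementation (scipy.stats.normaltest,
# statsmodels normal_ad / lilliefors) on the identical frozen samples.
test_that("normality tests match independent reference implementations", {
  set.seed(11)
  x_norm <- round(rnorm(50, 10, 2), 6)
  x_lnorm <- round(exp(rnorm(60)), 6)

  expect_equal(dagostino_pearson_test(x_norm)$p.value, 0.80407695,
               tolerance = 1e-6)
  expect_equal(anderson_darling_test(x_norm)$p.value, 0.7175498,
               tolerance = 1e-6)
  # the Lilliefors upper tail uses the Stephens polynomial; the reference
  # (statsmodels, Dallal-Wilkinson table interpolation) differs slightly
  expect_equal(lilliefors_test(x_norm)$p.value, 0.65879271, tolerance = 0.02)

  expect_equal(dagostino_pearson_test(x_lnorm)$p.value, 2.0222902e-13,
               tolerance = 1e-4)
  expect_equal(anderson_darling_test(x_lnorm)$p.value, 5.7833972e-14,
               tolerance = 1e-4)
  expect_lt(lilliefors_test(x_lnorm)$p.value, 1e-6)
})

test_that("normality battery verdicts on known distributions", {
  set.seed(21)
  v <- assess_normality(rnorm(1000))
  expect_true(v$gaussian)
  expect_length(v$per_test_p, 4L)
  expect_true(all(v$per_test_p > 0.05))

  v2 <- assess_normality(exp(rnorm(1000)))
  expect_false(v2$gaussian)
  expect_true(all(v2$per_test_p < 1e-6))

  expect_warning(v3 <- assess_normality(rep(5, 20)), "degenerate")
  expect_false(v3$gaussian)
  expect_warning(v4 <- assess_normality(rnorm(6)), "n < 8")
  expect_false(v4$gaussian)
  expect_error(assess_normality(c(1, 2, 3)), "sample-size")

  # combination rules: a sample that only one test would reject
  set.seed(22)
  x <- c(rnorm(80), 3.4) # borderline outlier
  pa <- assess_normality(x, rule = "all")
  pm <- assess_normality(x, rule = "majority")
  expect_true(sum(pa$per_test_p > 0.05) >= 3 || !pa$gaussian)
  expect_true(pm$gaussian == (sum(pm$per_test_p > 0.05) >= 3))
})

test_that("star grading applies the inclusive thresholds", {
  expect_identical(grade_stars(c(0.049, 0.5, 1e-5)), c("*", "ns", "****"))
  expect_identical(grade_stars(c(0.05, 0.01, 0.001, 1e-4, 0.051)),
                   c("*", "**", "***", "****", "ns"))
  expect_error(grade_stars(1.2), "domain")
  expect_error(grade_stars(-0.1), "domain")
})

test_that("Holm-Sidak adjustment is monotone and never below raw", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  # m = 1 reduces to the raw p-value
  expect_equal(holm_sidak_adjust(0.03), 0.03)
})

test_that("test selection follows the normality gate and group count", {
  set.seed(41)
  ctrl <- rnorm(1000, 100, 30)
  trt <- rnorm(1000, 150, 30)
  r <- select_and_run(list(control = ctrl, treated = trt),
                      control = "control")
  expect_identical(r$chosen_test, "t_one_tailed")
  expect_identical(r$comparisons$stars, "****")

  # identical samples: never significant
  same <- rnorm(500, 10, 2)
  r0 <- select_and_run(list(control = same, treated = same),
                       control = "control")
  expect_identical(r0$comparisons$stars, "ns")

  # a non-Gaussian group sends two groups to Mann-Whitney
  rmw <- select_and_run(list(control = exp(rnorm(400)),
                             treated = exp(rnorm(400, 0.3))),
                        control = "control")
  expect_identical(rmw$chosen_test, "mann_whitney_one_tailed")

  # three Gaussian groups: ANOVA + Holm-Sidak; three lognormal: Kruskal-Wallis
  g3 <- list(control = rnorm(300, 10), a = rnorm(300, 11), b = rnorm(300, 12))
  ra <- select_and_run(g3, control = "control")
  expect_identical(ra$chosen_test, "anova_holm_sidak")
  expect_identical(nrow(ra$comparisons), 2L)
  expect_false(is.na(ra$overall_p))
  rk <- select_and_run(list(control = exp(rnorm(300)), a = exp(rnorm(300)),
                            b = exp(rnorm(300, 0.5))), control = "control")
  expect_identical(rk$chosen_test, "kruskal_wallis")

  expect_error(select_and_run(list(a = 1:10)), "at least two")
  expect_error(select_and_run(list(a = 1:10, b = numeric())), "empty group")
})

test_that("selection is invariant under group order; no control means two-sided", {
  set.seed(51)
  g <- list(control = rnorm(200, 10), t1 = rnorm(200, 11), t2 = rnorm(200, 12))
  r1 <- select_and_run(g, control = "control")
  r2 <- select_and_run(g[c(3, 1, 2)], control = "control")
  expect_identical(r1$chosen_test, r2$chosen_test)
  expect_equal(r1$comparisons, r2$comparisons)

  expect_warning(rn <- select_and_run(g[1:2]), "two-sided")
  expect_identical(rn$tail, "two_sided")
})

test_that("rank branch is invariant under strictly monotone transforms", {
  set.seed(61)
  a <- exp(rnorm(150)); b <- exp(rnorm(150, 0.4))
  r1 <- select_and_run(list(control = a, treated = b), control = "control")
  r2 <- select_and_run(list(control = log(a), treated = log(b)),
                       control = "control")
  # log-transformed lognormal is Gaussian, so force the comparison at the
  # test level instead: Mann-Whitney p must match under the transform
  p1 <- wilcox.test(b, a, alternative = "greater", exact = FALSE)$p.value
  p2 <- wilcox.test(log(b), log(a), alternative = "greater",
                    exact = FALSE)$p.value
  expect_equal(p1, p2)
  expect_identical(r1$chosen_test, "mann_whitney_one_tailed")
  expect_identical(r2$chosen_test, "t_one_tailed")
})

test_that("one-tailed direction is treated > control", {
  set.seed(71)
  hi <- rnorm(300, 12); lo <- rnorm(300, 10)
  up <- select_and_run(list(control = lo, treated = hi), control = "control")
  down <- select_and_run(list(control = hi, treated = lo), control = "control")
  expect_lt(up$comparisons$p_raw, 0.001)
  expect_gt(down$comparisons$p_raw, 0.5)
})
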
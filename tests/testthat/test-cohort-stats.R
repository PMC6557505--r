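test_that("chi-square matches the direct-summation oracle", {
  set.seed(91)
  for (rep in 1:20) {
    counts <- matrix(rpois(4, 30) + 1, 2, 2)
    got <- chi_square_test(counts)
    want <- oracle_chisq(counts)
    expect_equal(got$statistic, unname(want["statistic"]), tolerance = 1e-12)
    expect_equal(got$df, unname(want["df"]))
    expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-12)
  }
})

test_that("chi-square degenerate and invariance properties hold", {
  # identical row proportions: statistic 0, p 1
  t0 <- chi_square_test(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1)
  # permutation invariance
  tab <- rbind(c(22, 39, 5), c(10, 21, 3))
  expect_equal(chi_square_test(tab)$statistic,
               chi_square_test(tab[, c(3, 1, 2)])$statistic, tolerance = 1e-12)
  expect_equal(chi_square_test(tab)$statistic,
               chi_square_test(tab[2:1, ])$statistic, tolerance = 1e-12)
  # zero marginal is an error; small expected counts warn in-object
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "zero marginal")
  expect_match(chi_square_test(rbind(c(2, 30), c(3, 40)))$warnings, "below 5")
  expect_error(chi_square_test(matrix(5, 1, 2)), "at least 2 x 2")
})

test_that("pooled t from summaries matches the closed-form oracle", {
  set.seed(92)
  for (rep in 1:20) {
    m1 <- rnorm(1, 60, 10); m2 <- rnorm(1, 60, 10)
    s1 <- runif(1, 2, 9); s2 <- runif(1, 2, 9)
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    got <- two_sample_t(mean1 = m1, sd1 = s1, n1 = n1,
                        mean2 = m2, sd2 = s2, n2 = n2)
    want <- oracle_pooled_t(m1, s1, n1, m2, s2, n2)
    expect_equal(got$statistic, unname(want["t"]), tolerance = 1e-12)
    expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-12)
    expect_equal(got$conf_low, unname(want["lo"]), tolerance = 1e-12)
    expect_equal(got$conf_high, unname(want["hi"]), tolerance = 1e-12)
  }
})

test_that("t-test edge cases and symmetry behave", {
  # identical groups: t = 0, p = 1
  t0 <- two_sample_t(mean1 = 5, sd1 = 1, n1 = 10, mean2 = 5, sd2 = 1, n2 = 10)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # antisymmetric under swapping groups
  ta <- two_sample_t(mean1 = 6, sd1 = 1, n1 = 12, mean2 = 5, sd2 = 2, n2 = 8)
  tb <- two_sample_t(mean1 = 5, sd1 = 2, n1 = 8, mean2 = 6, sd2 = 1, n2 = 12)
  expect_equal(ta$p_value, tb$p_value, tolerance = 1e-12)
  expect_equal(ta$estimate, -tb$estimate, tolerance = 1e-12)
  # zero pooled variance with unequal means: p = 0 with warning
  tz <- two_sample_t(mean1 = 6, sd1 = 0, n1 = 10, mean2 = 5, sd2 = 0, n2 = 10)
  expect_equal(tz$p_value, 0)
  expect_match(tz$warnings, "zero pooled variance")
  expect_error(two_sample_t(mean1 = 5, sd1 = 1, n1 = 1,
                            mean2 = 5, sd2 = 1, n2 = 10), "n >= 2")
})

test_that("raw-sample interface agrees with stats::t.test", {
  set.seed(93)
  x <- rnorm(30, 10, 2)
  y <- rnorm(20, 11, 3)
  got <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(c(got$conf_low, got$conf_high), as.numeric(ref$conf.int),
               tolerance = 1e-12)
  gotw <- two_sample_t(x, y, var_equal = FALSE)
  refw <- t.test(x, y)
  expect_equal(gotw$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(gotw$p_value, refw$p.value, tolerance = 1e-12)
  expect_equal(gotw$df, unname(refw$parameter), tolerance = 1e-12)
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(94)
  x <- rnorm(15, 0, 1)
  y <- rnorm(25, 0.7, 1.3)
  an <- anova_posthoc(list(a = x, b = y), posthoc = FALSE)
  tt <- two_sample_t(x, y)
  expect_equal(an$anova$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$anova$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("Tukey-Kramer post-hoc comparisons match the studentized-range law", {
  set.seed(95)
  g <- list(a = rnorm(12, 0, 1), b = rnorm(18, 0.5, 1), c = rnorm(9, 1.5, 1))
  res <- anova_posthoc(g)
  expect_equal(nrow(res$posthoc), 3)
  # oracle: recompute one adjusted p from the studentized range distribution
  ns <- lengths(g)
  means <- vapply(g, mean, numeric(1))
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) /
    (sum(ns) - 3)
  se <- sqrt(mse / 2 * (1 / ns["a"] + 1 / ns["b"]))
  q <- abs(means["a"] - means["b"]) / se
  p_ab <- stats::ptukey(q, 3, sum(ns) - 3, lower.tail = FALSE)
  row <- res$posthoc[res$posthoc$comparison == "b-a", ]
  expect_equal(row$p_adj, unname(p_ab), tolerance = 1e-9)
  # widely separated means with tiny variance: extreme pair p < 0.001
  far <- list(a = rnorm(10, 0, 0.01), b = rnorm(10, 0, 0.01),
              c = rnorm(10, 10, 0.01))
  resf <- anova_posthoc(far)
  expect_lt(resf$posthoc$p_adj[resf$posthoc$comparison == "c-a"], 1e-3)
  # zero-variance group is handled with a warning entry
  zv <- anova_posthoc(list(a = rep(1, 10), b = rnorm(10)))
  expect_match(zv$warnings, "zero variance")
  expect_error(anova_posthoc(list(a = rnorm(5))), "at least 2 groups")
})

test_that("anova_posthoc accepts tidy data frames with bare column names", {
  set.seed(96)
  df <- data.frame(sev = rnorm(30), grade = rep(c("1", "2", "3"), 10))
  a1 <- anova_posthoc(df, sev, grade)
  a2 <- anova_posthoc(split(df$sev, df$grade))
  expect_equal(a1$anova, a2$anova, tolerance = 1e-12)
})

test_that("interobserver comparison flags real marginal disagreement", {
  # identical graders: degenerate-to-null, p = 1
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:20),
                        grade_obs1 = rep(1:2, 10), grade_obs2 = rep(1:2, 10))
  same <- interobserver_comparison(rec)
  expect_equal(same$test$p_value, 1)
  expect_false(same$significant)
  # grade distributions 39/55/6 vs 64/36/0 disagree strongly
  rec2 <- tibble::tibble(
    grade_obs1 = rep(1:3, c(39, 55, 6)),
    grade_obs2 = rep(1:3, c(64, 36, 0)))
  dis <- interobserver_comparison(rec2)
  expect_lt(dis$test$p_value, 0.001)
  expect_true(dis$significant)
  expect_equal(unname(dis$marginal_table[1, ]), c(39, 55, 6))
  expect_equal(unname(dis$marginal_table[2, ]), c(64, 36, 0))
  # missing grades are reported by patient
  rec3 <- rec
  rec3$grade_obs2[c(3, 7)] <- NA
  expect_error(interobserver_comparison(rec3), "P03, P07")
})

test_that("interobserver p decreases as simulated disagreement grows", {
  meds <- vapply(c(50, 150, 300), function(off) {
    ps <- vapply(1:8, function(s) {
      co <- generate_cohort(cohort_spec(seed = s, observer_offsets = c(0, off)))
      interobserver_comparison(co)$test$p_value
    }, numeric(1))
    stats::median(ps)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
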
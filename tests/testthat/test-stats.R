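test_that("two-sample t agrees with brute force and base R", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- t_test(a, b)
  expect_equal(got$statistic, oracle_student_t(a, b), tolerance = 1e-12)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  w <- t_test(a, c(4, 6, 11), variant = "welch")
  refw <- stats::t.test(a, c(4, 6, 11))
  expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    expect_equal(t_test(x, y)$statistic, oracle_student_t(x, y),
                 tolerance = 1e-10)
    expect_equal(t_test(x, y, "welch")$statistic, oracle_welch_t(x, y),
                 tolerance = 1e-10)
  }
})

test_that("summary-statistic and raw t tests are bit-consistent", {
  set.seed(62)
  x <- rnorm(9, 2, 1.4); y <- rnorm(14, 1.1, 2.2)
  for (v in c("student", "welch")) {
    raw <- t_test(x, y, v)
    summ <- t_test(group_summary(n = 9, mean = mean(x), sd = sd(x)),
                   group_summary(n = 14, mean = mean(y), sd = sd(y)), v)
    expect_identical(raw$statistic, summ$statistic)
    expect_identical(raw$p_value, summ$p_value)
    expect_identical(raw$df, summ$df)
  }
})

test_that("degenerate t-test inputs follow the stated conventions", {
  same <- c(2, 2, 2)
  r <- t_test(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- t_test(c(2, 2, 2), c(3, 3, 3))
  expect_equal(r2$p_value, 0)
  expect_identical(r2$status, "degenerate")
  expect_equal(t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1) # identical samples
})

test_that("one-way ANOVA matches brute-force sums of squares and aov", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  got <- one_way_anova(g)
  expect_equal(got$statistic, oracle_anova_f(g), tolerance = 1e-12)
  df <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 2)))
  ref <- summary(stats::aov(y ~ f, df))[[1]]
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  eq <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  inf <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_identical(inf$statistic, Inf)
  expect_equal(inf$p_value, 0)
})

test_that("Friedman statistic handles perfect agreement, constancy and ties", {
  # every block ranks the k = 3 treatments identically: statistic 2b
  m <- matrix(rep(c(1, 5, 9), each = 10), nrow = 10)
  got <- friedman_test(m)
  expect_equal(got$statistic, 20)
  expect_equal(got$p_value, stats::pchisq(20, 2, lower.tail = FALSE))

  const <- matrix(3, nrow = 5, ncol = 4)
  expect_equal(friedman_test(const)$statistic, 0)
  expect_equal(friedman_test(const)$p_value, 1)

  set.seed(63)
  r <- matrix(rnorm(15 * 4), 15, 4) # tie-free: matches base R exactly
  ref <- stats::friedman.test(r)
  expect_equal(friedman_test(r)$statistic, unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(friedman_test(r)$p_value, ref$p.value, tolerance = 1e-12)

  # midrank tie handling shrinks the denominator, never yields NaN
  tied <- rbind(c(1, 1, 2), c(2, 2, 1), c(1, 2, 2), c(3, 1, 1))
  expect_true(is.finite(friedman_test(tied)$statistic))
})

test_that("Pearson correlation matches brute force, base R and closed forms", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  got <- pearson_correlation(x, y)
  expect_equal(got$r, 0.6, tolerance = 1e-12)
  expect_equal(got$r, oracle_pearson_r(x, y), tolerance = 1e-12)
  ref <- stats::cor.test(x, y)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 4)),
               class = "undefined_correlation")

  set.seed(64)
  for (i in 1:50) {
    u <- rnorm(sample(4:15, 1)); v <- rnorm(length(u))
    expect_equal(pearson_correlation(u, v)$r, oracle_pearson_r(u, v),
                 tolerance = 1e-10)
  }
})

test_that("published summary comparison: total cholesterol group 1 vs control", {
  # mean +/- SD 18.948 +/- 4.633 vs 2.901 +/- 2.788, n = 10 each
  r <- t_test(group_summary(label = "group1", n = 10, mean = 18.948, sd = 4.633),
              group_summary(label = "control", n = 10, mean = 2.901, sd = 2.788))
  expect_lt(r$p_value, 0.001)
  expect_gt(r$statistic, 0)
})
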
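# Group-comparison statistics implemented from their defining formulas.
# Each statistic here is cross-checked in the test suite against an
# independent route (base R's t.test/aov/friedman.test/cor.test and
# brute-force sum-of-squares evaluation); the summary-statistic t test has
# no base-R counterpart and is the form needed to reanalyse published
# mean +/- SD tables.

#' Group summary statistics
#'
#' A group reduced to its sufficient summary for two-sample t tests:
#' size, mean and sample standard deviation (n - 1 denominator). Construct
#' either from a raw sample or from published summary values.
#'
#' @param x Numeric sample, or `NULL` when giving summaries directly.
#' @param label Group label.
#' @param n,mean,sd Summary values (used when `x` is `NULL`).
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3), label = "a")
#' group_summary(label = "TC grp 1", n = 10, mean = 18.948, sd = 4.633)
group_summary <- function(x = NULL, label = NA_character_,
                          n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)))
      ceus_stop("sample must be numeric with n >= 2", "invalid_input")
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  } else {
    if (!is_count(n) || n < 2 || !is_number(mean) || !is_number(sd) || sd < 0)
      ceus_stop("need n >= 2, finite mean, sd >= 0", "invalid_input")
  }
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(x, label = NA_character_) {
  if (inherits(x, "group_summary")) x else group_summary(x, label = label)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group %s: n = %d, mean %.4g, SD %.4g\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

test_result <- function(test_name, statistic, df, p_value, comparison = NA,
                        extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, comparison = comparison), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic %.6g, df %s, p = %.4g\n",
              x$test_name, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Two-sample t test from raw samples or summary statistics
#'
#' Student's pooled-variance t test (default) or Welch's unequal-variance
#' test, two-sided. Inputs may be raw numeric samples or [group_summary()]
#' objects; both routes go through the same summary-statistic formulas, so
#' a raw sample and its matching (n, mean, sd) summary give identical
#' results. Degenerate data are handled by convention: zero variance with
#' equal means gives t = 0, p = 1; zero variance with unequal means gives
#' the p = 0 limit and a `"degenerate"` status.
#'
#' @param a,b Numeric samples (n >= 2) or [group_summary()] objects.
#' @param variant `"student"` or `"welch"`.
#' @return A `test_result` with fields `statistic` (t), `df`, `p_value`.
#' @export
#' @examples
#' t_test(c(1, 2, 3), c(4, 5, 6))
#' t_test(group_summary(n = 10, mean = 18.948, sd = 4.633),
#'        group_summary(n = 10, mean = 2.901, sd = 2.788))
t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(a, "a"); b <- as_group_summary(b, "b")
  diff <- a$mean - b$mean
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  status <- "ok"
  if (se == 0) {
    if (diff == 0) { t <- 0; p <- 1 }
    else { t <- sign(diff) * Inf; p <- 0; status <- "degenerate" }
    if (variant == "welch") df <- a$n + b$n - 2 # WS df is 0/0; report pooled
  } else {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  test_result(paste0(variant, "_t_test"), t, df, p,
              comparison = c(a$label, b$label), extra = list(status = status))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA for independent groups:
#' F = MS_between / MS_within on (k - 1, N - k) degrees of freedom.
#'
#' @param groups List of numeric samples, each n >= 2, at least 2 groups.
#' @return A `test_result` with the F statistic, both df and the p value.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    ceus_stop("need a list of >= 2 groups", "invalid_input")
  if (any(vapply(groups, length, 1L) < 2L))
    ceus_stop("every group needs n >= 2", "invalid_input")
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  means <- vapply(groups, mean, 1)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  if (msw == 0) {
    if (msb == 0) return(test_result("one_way_anova", 0, c(k - 1, N - k), 1))
    return(test_result("one_way_anova", Inf, c(k - 1, N - k), 0,
                       extra = list(status = "infinite_F")))
  }
  f <- msb / msw
  test_result("one_way_anova", f, c(k - 1, N - k),
              stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Friedman rank test for block designs
#'
#' Ranks treatments within each block (midranks for ties), then forms the
#' tie-corrected Friedman chi-square
#' \deqn{Q = (k-1) \sum_j (R_j - b(k+1)/2)^2 / (\sum_{ij} r_{ij}^2 - b k (k+1)^2 / 4)}
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' Blocks in which all treatments are tied contribute nothing; if every
#' block is constant the statistic is 0 and p = 1 by convention.
#'
#' @param block_matrix Numeric matrix, blocks in rows, treatments in
#'   columns; >= 2 of each.
#' @return A `test_result` with the chi-square statistic, df and p value.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L)
    ceus_stop("need a numeric blocks x treatments matrix, >= 2 of each",
              "invalid_input")
  b <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank)) # midranks within blocks
  Rj <- colSums(r)
  denom <- sum(r^2) - b * k * (k + 1)^2 / 4
  if (denom == 0) # all blocks completely tied
    return(test_result("friedman_test", 0, k - 1, 1))
  q <- (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / denom
  test_result("friedman_test", q, k - 1,
              stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' Pearson product-moment correlation with t-based significance
#'
#' r between two samples and the two-sided p value from
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. Also
#' reports the Fisher-z 95% confidence interval for r.
#'
#' @param x,y Equal-length numeric samples, n >= 3, neither constant.
#' @return An object of class `correlation_result` with fields `r`, `n`,
#'   `t_statistic`, `p_value`, `conf_int`.
#' @export
pearson_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) || length(x) < 3L)
    ceus_stop("need equal-length numeric samples with n >= 3", "invalid_input")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) ceus_stop("fewer than 3 complete pairs", "invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ceus_stop("correlation undefined for a constant variable",
              "undefined_correlation")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) < 1) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  } else {
    t <- sign(r) * Inf; p <- 0
  }
  ci <- c(NA_real_, NA_real_)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r); hw <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  structure(list(r = r, n = n, t_statistic = t, p_value = p, conf_int = ci),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4g (n = %d), t = %.4g, p = %.4g\n",
              x$r, x$n, x$t_statistic, x$p_value))
  if (!anyNA(x$conf_int))
    cat(sprintf("  95%% CI (Fisher z): [%.4g, %.4g]\n",
                x$conf_int[1], x$conf_int[2]))
  invisible(x)
}
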
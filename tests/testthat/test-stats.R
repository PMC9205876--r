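test_that("anova components recover trivial structure", {
  X <- cbind(c(1, 3, 6), c(1, 3, 6))          # identical columns
  comp <- anova_components(X)
  expect_equal(comp$MS_C, 0)
  expect_equal(comp$MS_E, 0)
  expect_gt(comp$MS_R, 0)
  Y <- rbind(c(1, 2, 5), c(1, 2, 5))          # identical rows
  expect_equal(anova_components(Y)$MS_R, 0)
})

test_that("anova components match the direct sum-of-squares oracle", {
  X <- rbind(c(1, 2), c(3, 4), c(6, 8))
  comp <- anova_components(X)
  g <- mean(X)
  expect_equal(comp$MS_R, 2 * sum((rowMeans(X) - g)^2) / 2)
  expect_equal(comp$MS_C, 3 * sum((colMeans(X) - g)^2) / 1)
  res <- X - outer(rowMeans(X), c(1, 1)) - rbind(colMeans(X), colMeans(X),
                                                 colMeans(X)) + g
  expect_equal(comp$MS_E, sum(res^2) / 2)
})

test_that("anova rejects missing cells and degenerate layouts", {
  X <- matrix(c(1, NA, 3, 4), 2)
  expect_error(anova_components(X), "missing")
  expect_error(anova_components(matrix(1:3, 1)), "n >= 2")
})

test_that("identical raters with varying subjects give ICC = 1", {
  X <- cbind(c(900, 1000, 1100, 1250), c(900, 1000, 1100, 1250),
             c(900, 1000, 1100, 1250))
  est <- icc(X)
  expect_equal(est$value, 1)
  expect_false(est$degenerate)
  expect_equal(est$band, "low")
})

test_that("identical subjects with rater effects give ICC <= 0", {
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  est <- icc(X)
  expect_lte(est$value, 0)
  expect_equal(est$band, "high")
})

test_that("an all-identical matrix is flagged degenerate with ICC 1", {
  est <- icc(matrix(5, 4, 3))
  expect_equal(est$value, 1)
  expect_true(est$degenerate)
})

test_that("ICC agrees with the aov-based oracle on random matrices", {
  set.seed(40)
  for (rep in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:9, 1)
    X <- matrix(rnorm(n * k, 100, 10), n, k) +
      rnorm(n, 0, 5)                            # subject effects
    expect_equal(icc(X)$value, oracle_icc(X), tolerance = 1e-9)
  }
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(41)
  X <- matrix(rnorm(24, 50, 8), 6, 4)
  v <- icc(X)$value
  expect_equal(icc(X + 13.7)$value, v, tolerance = 1e-12)
  expect_equal(icc(X * 3.2)$value, v, tolerance = 1e-12)
})

test_that("stratification uses half-open bands with boundaries in the lower band", {
  expect_equal(stratify_icc(0.93), "low")
  expect_equal(stratify_icc(0.9), "moderate")
  expect_equal(stratify_icc(0.75), "considerable")
  expect_equal(stratify_icc(0.5), "high")
  expect_equal(stratify_icc(-0.2), "high")
  expect_equal(stratify_icc(c(0.2, 0.8)), c("high", "moderate"))
})

test_that("tidy() exposes the ICC components", {
  td <- tidy(icc(matrix(rnorm(12, 10), 4, 3)))
  expect_named(td, c("icc", "band", "degenerate", "MS_R", "MS_C", "MS_E",
                     "n", "k"))
})

test_that("cv follows the sample-SD-over-absolute-mean definition", {
  expect_equal(cv_percent(c(3, 3, 3, 3)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  expect_true(is.na(cv_percent(c(-1, 1))))       # zero mean
  expect_error(cv_percent(5), "at least 2")
})

test_that("cv is scale invariant and zero iff constant", {
  set.seed(42)
  x <- runif(9, 10, 20)
  expect_equal(cv_percent(3.7 * x), cv_percent(x), tolerance = 1e-12)
  expect_gt(cv_percent(x), 0)
})

test_that("cv_summary takes the median of defined records", {
  expect_equal(cv_summary(12), 12)
  expect_equal(cv_summary(c(0, 10, 20)), 10)
  expect_equal(cv_summary(c(5, NA, 15)), 10)
  expect_true(is.na(cv_summary(c(NA_real_, NA_real_))))
})

test_that("a perfect common slope gives r_rm = 1", {
  d <- data.frame(subject_id = rep(1:3, each = 4), x = rep(1:4, 3))
  d$y <- 2 * d$x + rep(c(0, 5, 9), each = 4)
  fit <- rmcorr(d, x = "x", y = "y")
  expect_equal(fit$r_rm, 1)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$df, 3 * (4 - 1) - 1)         # N(k-1)-1
})

test_that("no within-subject association means r_rm near 0", {
  set.seed(44)
  d <- data.frame(subject_id = rep(1:8, each = 6), x = rep(1:6, 8))
  d$y <- rep(c(2, 7, 11, 4, 9, 5, 8, 3), each = 6) + rnorm(48, 0, 0.5)
  expect_lt(abs(rmcorr(d, x = "x", y = "y")$r_rm), 0.3)
})

test_that("rmcorr agrees with the normal-equations oracle", {
  set.seed(43)
  for (rep in 1:10) {
    d <- data.frame(subject_id = rep(1:3, each = 4), x = rep(1:4, 3))
    d$y <- 0.5 * d$x + rep(rnorm(3, 0, 4), each = 4) + rnorm(12)
    fit <- rmcorr(d, x = "x", y = "y")
    expect_equal(fit$r_rm, oracle_rmcorr(d$subject_id, d$x, d$y),
                 tolerance = 1e-9)
  }
})

test_that("rmcorr refuses unusable designs", {
  one <- data.frame(subject_id = rep(1, 4), x = 1:4, y = rnorm(4))
  expect_error(rmcorr(one, x = "x", y = "y"), "2 subjects")
  flat <- data.frame(subject_id = rep(1:3, each = 3), x = 1,
                     y = rnorm(9))
  expect_error(rmcorr(flat, x = "x", y = "y"), "variance")
  thin <- data.frame(subject_id = c(1, 2, 2, 3, 3), x = c(1, 1, 2, 1, 2),
                     y = rnorm(5))
  expect_error(rmcorr(thin, x = "x", y = "y"), "2 observations")
})

test_that("bonferroni flags follow alpha / m", {
  expect_true(bonferroni(0.04, m = 1)$significant)
  expect_false(bonferroni(0.04, m = 98)$significant)
  expect_true(bonferroni(0.0001, m = 98)$significant)
  tab <- bonferroni(c(0.001, 0.2))
  expect_equal(tab$p_bonferroni, c(0.002, 0.4))
  expect_error(bonferroni(1.2), "0, 1")
})
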
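test_that("exact binomial tails match hand-derived values", {
  expect_equal(binom_tail(2, 26, 0.5), 352 / 2^26)
  expect_equal(binom_tail(2, 10, 0.5), 56 / 1024)
  expect_equal(binom_tail(10, 10, 0.5), 1)
  expect_equal(binom_tail(0, 8, 0.3, side = "ge"), 1)
  expect_error(binom_tail(2, 10, 0), "theta")
  expect_error(binom_tail(11, 10, 0.5), "0..n")
})

test_that("binomial tails agree with explicit enumeration", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(1:20, 1)
    k <- sample(0:n, 1)
    theta <- runif(1, 0.05, 0.95)
    side <- sample(c("le", "ge"), 1)
    expect_equal(binom_tail(k, n, theta, side),
                 oracle_binom_tail(k, n, theta, side), tolerance = 1e-12)
  }
  # full 2^n outcome enumeration at theta = 0.5
  for (n in c(5L, 9L, 12L)) {
    k <- sample(0:n, 1)
    expect_equal(binom_tail(k, n, 0.5), oracle_binom_tail_2n(k, n),
                 tolerance = 1e-12)
    expect_equal(binom_tail(k, n, 0.5, "ge"), oracle_binom_tail_2n(k, n, "ge"),
                 tolerance = 1e-12)
  }
})

test_that("lower and upper tails are complementary at theta 0.5", {
  for (n in c(7L, 26L, 330L)) {
    for (a in c(0L, n %/% 3, n - 1L)) {
      expect_equal(binom_tail(a, n, 0.5) + binom_tail(a + 1L, n, 0.5, "ge"), 1)
    }
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(5.64e-4, 330), 0.18612)
  expect_equal(round(bonferroni(5.654e-4, 330), 2), 0.19)
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_error(bonferroni(0.01, 0), "m")
})

test_that("directional bias tests reproduce the published marker-table cells", {
  # (186, 144): raw tail below 0.05, correction caps at 1
  t1 <- direction_bias_test(count_split("atherogenesis", 186, 144), 0.5,
                            m = 330)
  expect_lt(t1$p_raw, 0.05)
  expect_equal(t1$p_adj, 1)
  # (195, 135): raw tail of order 1e-3, adjusted 0.19
  t2 <- direction_bias_test(count_split("atherosclerosis", 195, 135), 0.5,
                            m = 330)
  expect_lt(t2$p_raw, 1e-3)
  expect_equal(round(t2$p_adj, 2), 0.19)
  # (91, 239): the excess side is b, tail taken there
  t3 <- direction_bias_test(count_split("atheroprotection", 91, 239), 0.5,
                            m = 330)
  expect_identical(t3$side, "le")
  expect_lt(t3$p_raw, 1e-6)
  expect_lt(t3$p_adj, 1e-4)
  # symmetric splits are never extreme
  expect_gt(direction_bias_test(count_split("x", 12, 12), 0.5)$p_raw, 0.5)
  expect_error(direction_bias_test(count_split("x", 0, 0), 0.5), "empty")
})

test_that("DEG concordance tests reproduce the published verification row", {
  expect_equal(deg_concordance_test(count_split("p", 2, 24))$p_raw,
               352 / 2^26)
  expect_equal(deg_concordance_test(count_split("g", 10, 16))$p_raw,
               oracle_binom_tail(10, 26, 0.5), tolerance = 1e-12)
  expect_equal(round(deg_concordance_test(count_split("g", 10, 16))$p_raw, 2),
               0.16)
  expect_equal(round(deg_concordance_test(count_split("s", 14, 12))$p_raw, 2),
               0.42)
  expect_gt(deg_concordance_test(count_split("t", 13, 13))$p_raw, 0.5)
})

test_that("the lowest-bar sign test follows its closed form", {
  vals <- list(a = c(3, 4), b = c(6, 7), c = c(8, 9), d = c(5, 6),
               e = c(7, 8), f = c(9, 10))
  t6 <- lowest_bar_sign_test(vals, "a")
  expect_equal(t6$p_raw, 0.5^5)
  expect_lt(t6$p_raw, 0.05)
  expect_true(t6$lowest)
  expect_equal(lowest_bar_sign_test(vals, "b")$p_raw, 1)
  expect_equal(lowest_bar_sign_test(vals[1:2], "a")$p_raw, 0.5)
  tie <- lowest_bar_sign_test(list(a = 1, b = 1, c = 2), "a")
  expect_equal(tie$p_raw, 1)
  expect_true(tie$tie)
  expect_error(lowest_bar_sign_test(vals[1], "a"), "at least 2")
})

test_that("Mann-Whitney exact path matches full labeling enumeration", {
  t <- mannwhitney_u(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(unname(t$statistic), 0)
  expect_equal(t$p_raw, 1 / 6)
  expect_true(t$exact)
  set.seed(29)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq(1, 100, by = 0.5), n1)
    y <- sample(setdiff(seq(1, 100, by = 0.5), x), n2)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mannwhitney_u(x, y, alt)$p_raw,
                   oracle_mannwhitney(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney falls back to a tie-corrected normal approximation", {
  x <- c(1, 2, 2, 5, 8, 9, 11, 12, 15)
  y <- c(2, 3, 4, 6, 6, 10, 13, 14, 18, 20)
  t <- mannwhitney_u(x, y)
  expect_false(t$exact)
  expect_match(t$method, "approximation")
  # tie-free samples above the exact-path cutoff: approximate p close to
  # the enumerated p
  x2 <- c(1.1, 2.3, 3.7, 5.2, 8.1, 9.4, 10.2, 13.5, 16.1)
  y2 <- c(0.5, 2.9, 4.4, 6.6, 7.7, 11.3, 12.8, 14.2, 17.9, 19.3)
  t2 <- mannwhitney_u(x2, y2)
  expect_false(t2$exact)
  expect_equal(t2$p_raw, oracle_mannwhitney(x2, y2), tolerance = 0.02)
  expect_error(mannwhitney_u(numeric(0), 1), "non-empty")
})

test_that("a sample compared with itself is unremarkable", {
  x <- c(2, 5, 9, 14, 20)
  expect_gt(mannwhitney_u(x, x)$p_raw, 0.9)
  expect_equal(mean_z_test(x, x)$statistic, 0)
  expect_equal(mean_z_test(x, x)$p_raw, 1)
})

test_that("mean and SEM follow their definitions", {
  ms <- mean_sem(c(3, 5))
  expect_equal(ms$mean, 4)
  expect_equal(ms$sem, 1)
  const <- mean_sem(rep(7, 5))
  expect_equal(const$sem, 0)
  single <- mean_sem(42)
  expect_equal(single$mean, 42)
  expect_false(single$sem_defined)
  expect_error(mean_sem(numeric(0)), "empty")
})

test_that("adjusted p-values are monotone in multiplicity and bounded by 1", {
  p <- 0.004
  adj <- vapply(c(1, 10, 100, 400), function(m) bonferroni(p, m), numeric(1))
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj <= 1))
  t <- direction_bias_test(count_split("x", 20, 5), 0.5, m = 50)
  expect_gte(t$p_adj, t$p_raw)
})
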
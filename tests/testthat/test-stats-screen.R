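test_that("zero-spread samples are never screened", {
  r <- thompson_tau_screen(c(5, 5, 5, 5))
  expect_equal(r$retained, c(5, 5, 5, 5))
  expect_length(r$removed, 0)
})

test_that("a gross outlier is removed at the hand-computed cutoff", {
  x <- c(1, 2, 3, 4, 100)
  r <- thompson_tau_screen(x, alpha = 0.05)
  expect_equal(r$removed, 100)
  expect_equal(sort(r$retained), c(1, 2, 3, 4))
  # oracle: tau * s with the printed critical value t_{0.025,3} = 3.182
  # gives 1.5712 * 43.617 = 68.53, below |100 - 22| = 78
  expect_equal(r$tau_thresholds[1], tau_cutoff_hand(x), tolerance = 1e-3)
  expect_gt(max(abs(x - mean(x))), r$tau_thresholds[1])
  # idempotence: re-screening the retained values removes nothing
  r2 <- thompson_tau_screen(r$retained)
  expect_length(r2$removed, 0)
})

test_that("screening is idempotent on simulated group data", {
  for (s in 1:20) {
    set.seed(s)
    r <- thompson_tau_screen(rnorm(15, 10, 2))
    r2 <- thompson_tau_screen(r$retained)
    expect_length(r2$removed, 0)
    expect_equal(sort(c(r$retained, r$removed)), sort(rnorm_set <- {
      set.seed(s); rnorm(15, 10, 2)
    }))
  }
})

test_that("an injected 10-sigma outlier is always caught; clean samples lose few points", {
  caught <- 0; removed_clean <- 0
  for (s in 1:500) {
    set.seed(s)
    x <- rnorm(20)
    caught <- caught + (10 %in% thompson_tau_screen(c(x, 10))$removed)
    removed_clean <- removed_clean + length(thompson_tau_screen(x)$removed)
  }
  expect_equal(caught, 500)
  # the screen at alpha = 0.05 trims roughly a tenth of clean normal points
  expect_lt(removed_clean / (500 * 20), 0.12)
  expect_true(all(vapply(1:20, function(s) {
    set.seed(s); length(thompson_tau_screen(rnorm(20))$retained) >= 2
  }, logical(1))))
})

test_that("screen guards its preconditions", {
  expect_error(thompson_tau_screen(c(1, 2)), "at least 3")
  expect_error(thompson_tau_screen(1:10, alpha = 0.8), "alpha")
})

test_that("two-sample t-test matches the closed form", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  r <- t_test_two_tailed(a, b)
  # oracle by hand: pooled sd = 1, se = sqrt(2/3), t = -10 / 0.8165
  expect_equal(r$t_statistic, -10 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$degrees_of_freedom, 4)
  expect_lt(r$p_value, 0.001)
  # identical groups: the null case
  r0 <- t_test_two_tailed(a, a)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("pooled and Welch agree for equal sizes and variances", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  rp <- t_test_two_tailed(a, b, "pooled")
  rw <- t_test_two_tailed(a, b, "welch")
  expect_equal(rp$t_statistic, rw$t_statistic, tolerance = 1e-12)
  expect_equal(rp$degrees_of_freedom, rw$degrees_of_freedom,
               tolerance = 1e-12)
  expect_equal(rp$p_value, rw$p_value, tolerance = 1e-12)
})

test_that("swapping groups negates t and preserves p", {
  set.seed(4)
  a <- rnorm(8, 5); b <- rnorm(12, 6)
  for (v in c("pooled", "welch")) {
    r1 <- t_test_two_tailed(a, b, v)
    r2 <- t_test_two_tailed(b, a, v)
    expect_equal(r1$t_statistic, -r2$t_statistic, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("raw-data and summary-statistics routes agree to 1e-9", {
  set.seed(9)
  a <- rnorm(9, 5, 2); b <- rnorm(14, 6, 3)
  for (v in c("pooled", "welch")) {
    raw <- t_test_two_tailed(a, b, v)
    summ <- t_test_from_summary(length(a), mean(a), sd(a) / sqrt(length(a)),
                                length(b), mean(b), sd(b) / sqrt(length(b)),
                                v)
    expect_equal(raw$t_statistic, summ$t_statistic, tolerance = 1e-9)
    expect_equal(raw$degrees_of_freedom, summ$degrees_of_freedom,
                 tolerance = 1e-9)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-9)
  }
})

test_that("summary-route monotonicity: doubling SEMs halves t", {
  r1 <- t_test_from_summary(10, 5, 0.5, 10, 6, 0.5)
  r2 <- t_test_from_summary(10, 5, 1.0, 10, 6, 1.0)
  expect_equal(r2$t_statistic, r1$t_statistic / 2, tolerance = 1e-12)
  expect_gt(r2$p_value, r1$p_value)
})

test_that("degenerate inputs follow the stated conventions", {
  r <- t_test_two_tailed(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$p_value, 1)
  expect_equal(t_test_from_summary(5, 4, 0, 5, 4, 0)$p_value, 1)
  expect_equal(t_test_from_summary(5, 4, 0, 5, 9, 0)$p_value, 0)
  expect_error(t_test_two_tailed(1, c(1, 2)), "at least 2")
  expect_error(t_test_from_summary(1, 0, 1, 5, 0, 1), "n >= 2")
})

test_that("printed near-identical expression levels are non-significant", {
  r <- t_test_from_summary(15, 470.4, 66.1, 11, 465.6, 68.2,
                           variant = "welch")
  expect_gt(r$p_value, 0.9)
  expect_lt(abs(r$t_statistic), 0.1)
})
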
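# condition-level statistics

test_that("one-sample t: symmetric data, formula oracle, degenerate input", {
  r <- one_sample_t(c(0.9, 1.0, 1.1), 1.0)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # closed-form oracle for {1.2, 1.5, 1.4, 1.3} vs mu0 = 1
  x <- c(1.2, 1.5, 1.4, 1.3)
  t_oracle <- (mean(x) - 1) / (sd(x) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), 3)
  r2 <- one_sample_t(x, 1.0)
  expect_equal(r2$t, t_oracle)
  expect_equal(r2$df, 3)
  expect_equal(r2$p, p_oracle)
  expect_error(one_sample_t(c(1, 1, 1), 0), "zero variance")
  expect_error(one_sample_t(c(1), 0), "n >= 2")
})

test_that("two-sample t: identical groups, monotonicity, formula oracle", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # p decreases monotonically with the shift
  base <- c(0.1, -0.2, 0.3, 0, -0.1, 0.2)
  ps <- vapply(c(0.5, 1, 2, 4), function(d)
    two_sample_t(base, base + d)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  # Welch formula oracle on random small groups
  withr::with_seed(5, {
    a <- rnorm(7); b <- rnorm(9, 0.8)
  })
  va <- var(a) / 7; vb <- var(b) / 9
  t_oracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 / (va^2 / 6 + vb^2 / 8)
  r2 <- two_sample_t(a, b)
  expect_equal(r2$t, t_oracle)
  expect_equal(r2$df, df_oracle)
  expect_equal(r2$p, 2 * pt(-abs(t_oracle), df_oracle))
  # pooled variant matches the classical formula
  sp2 <- (6 * var(a) + 8 * var(b)) / 14
  t_pool <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 7 + 1 / 9))
  r3 <- two_sample_t(a, b, equal_var = TRUE)
  expect_equal(r3$t, t_pool)
  expect_equal(r3$df, 14)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  gs <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- one_way_anova(gs)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  # SS_between = 6, SS_within = 6 -> F = (6/2)/(6/6) = 3
  gs2 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  r2 <- one_way_anova(gs2)
  expect_equal(r2$F, 3)
  expect_equal(r2$df1, 2)
  expect_equal(r2$df2, 6)
  expect_equal(r2$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), "n >= 2")
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))),
               "zero within-group variance")
})

test_that("ANOVA control comparisons use pooled MS_within and Bonferroni", {
  withr::with_seed(8, {
    gs <- list(ctrl = rnorm(10), t1 = rnorm(10, 1), t2 = rnorm(10, 0.1))
  })
  r <- one_way_anova(gs, control = "ctrl")
  vc <- r$vs_control
  expect_equal(vc$group, c("t1", "t2"))
  msw <- (9 * var(gs$ctrl) + 9 * var(gs$t1) + 9 * var(gs$t2)) / 27
  t1_oracle <- (mean(gs$t1) - mean(gs$ctrl)) / sqrt(msw * (2 / 10))
  expect_equal(vc$t[1], t1_oracle)
  expect_equal(vc$df[1], 27)
  expect_equal(vc$p_adj, pmin(1, vc$p_raw * 2))
  expect_equal(vc$stars, p_to_stars(vc$p_adj))
})

test_that("bootstrap median CI is seeded, ordered and degenerate-safe", {
  expect_equal(unname(bootstrap_median_ci(rep(5, 5), 1000, seed = 3)),
               c(5, 5))
  x <- c(3.2, 1.1, 4.8, 2.2, 5.9, 3.3, 2.8, 4.1)
  ci1 <- bootstrap_median_ci(x, 2000, seed = 42)
  ci2 <- bootstrap_median_ci(x, 2000, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  expect_lte(ci1[1], median(x))
  expect_gte(ci1[2], median(x))
  expect_error(bootstrap_median_ci(c(1, 2), 1000), "n >= 3")
  expect_error(bootstrap_median_ci(x, 10), "n_boot")
  # the global RNG stream is not disturbed
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(bootstrap_median_ci(x, 1000, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("significance stars follow the threshold map", {
  expect_equal(p_to_stars(c(0.02, 0.00005, 0.2, 0.009, 0.0009)),
               c("*", "****", "ns", "**", "***"))
  # boundaries are strict inequalities
  expect_equal(p_to_stars(c(0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***"))
  expect_error(p_to_stars(1.2), "\\[0, 1\\]")
  expect_error(p_to_stars(-0.1), "\\[0, 1\\]")
})

test_that("compare_conditions builds the comparison table", {
  withr::with_seed(21, {
    metrics <- data.frame(
      field_id = sprintf("f%02d", 1:30),
      condition = rep(c("ctrl", "treat"), each = 15),
      neurite_length_per_cell_um = c(rnorm(15, 20, 3), rnorm(15, 40, 3)),
      excluded = FALSE)
  })
  cmp <- compare_conditions(metrics, control = "ctrl", n_boot = 2000,
                            seed = 7)
  expect_equal(cmp$group, c("ctrl", "treat"))
  expect_equal(cmp$test[2], "two_sample_t")
  expect_lt(cmp$p[2], 0.001)
  expect_equal(cmp$stars[2], p_to_stars(cmp$p[2]))
  expect_true(all(cmp$ci_lo <= cmp$median & cmp$median <= cmp$ci_hi))
  # excluded fields are dropped
  metrics2 <- metrics
  metrics2$excluded[metrics2$condition == "treat"] <- TRUE
  expect_error(compare_conditions(metrics2, control = "ctrl"),
               ">= 2 conditions")
  # three groups go through ANOVA with control comparisons
  withr::with_seed(22, {
    m3 <- data.frame(
      field_id = sprintf("g%02d", 1:30),
      condition = rep(c("ctrl", "a", "b"), each = 10),
      neurite_length_per_cell_um = c(rnorm(10, 20), rnorm(10, 30),
                                     rnorm(10, 21)),
      excluded = FALSE)
  })
  cmp3 <- compare_conditions(m3, control = "ctrl", n_boot = 2000, seed = 7)
  expect_equal(cmp3$group[1], "ctrl")
  expect_equal(cmp3$test[1], "one_way_anova_F")
  expect_true(all(cmp3$test[-1] == "one_way_anova"))
  expect_true(all(!is.na(cmp3$p[-1])))
})
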
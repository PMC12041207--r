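test_that("paired t matches the textbook formulas", {
  a <- c(5, 7, 9, 11); b <- c(4, 5, 8, 9)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  out <- paired_t(a, b)
  expect_equal(out$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(out$p_two_sided, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_equal(out$cohen_d, mean(d) / sd(d), tolerance = 1e-12)
  hw <- qt(0.975, 3) * sd(d) / sqrt(4)
  expect_equal(c(out$ci_low, out$ci_high), mean(d) + c(-hw, hw),
               tolerance = 1e-12)
  expect_true(out$ci_low <= out$estimate && out$estimate <= out$ci_high)
})

test_that("degenerate paired comparisons are flagged", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)
  expect_equal(same$cohen_d, 0)
  expect_match(same$flag, "degenerate")

  shift <- paired_t(c(1, 2, 3), c(0, 1, 2))
  expect_equal(shift$estimate, 1)
  expect_equal(shift$p_two_sided, 0)
  expect_match(shift$flag, "degenerate")

  expect_error(paired_t(1:3, 1:4), "mismatch")
})

test_that("paired t is antisymmetric and shift invariant", {
  set.seed(11)
  a <- rnorm(20, 10); b <- rnorm(20, 9)
  ab <- paired_t(a, b); ba <- paired_t(b, a)
  expect_equal(ab$t_stat, -ba$t_stat)
  expect_equal(ab$p_two_sided, ba$p_two_sided)
  shifted <- paired_t(a + 100, b + 100)
  expect_equal(shifted$t_stat, ab$t_stat, tolerance = 1e-9)
})

test_that("independent t agrees with the Welch and pooled oracles", {
  set.seed(2)
  a <- rnorm(12, 10, 2); b <- rnorm(9, 8, 3)
  w <- independent_t(a, b)
  se_w <- sqrt(var(a) / 12 + var(b) / 9)
  t_w <- (mean(a) - mean(b)) / se_w
  df_w <- se_w^4 / ((var(a) / 12)^2 / 11 + (var(b) / 9)^2 / 8)
  expect_equal(w$t_stat, t_w, tolerance = 1e-9)
  expect_equal(w$df, df_w, tolerance = 1e-9)
  expect_equal(w$p_two_sided, 2 * pt(-abs(t_w), df_w), tolerance = 1e-9)
  sp <- sqrt((11 * var(a) + 8 * var(b)) / 19)
  expect_equal(w$cohen_d, (mean(a) - mean(b)) / sp, tolerance = 1e-9)

  p <- independent_t(a, b, welch = FALSE)
  t_p <- (mean(a) - mean(b)) / (sp * sqrt(1 / 12 + 1 / 9))
  expect_equal(p$t_stat, t_p, tolerance = 1e-9)
  expect_equal(p$df, 19)

  ident <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$p_two_sided, 1)
  expect_equal(ident$cohen_d, 0)
  expect_error(independent_t(1, 1:3), "at least 2")
})

test_that("extreme separation yields an extreme verdict", {
  set.seed(5)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 10, 1)
  out <- independent_t(b, a)
  expect_lt(out$p_two_sided, 1e-10)
  expect_gt(out$cohen_d, 7)
  expect_true(out$significant)
})

test_that("two-sample power is exact at the null and matches Monte Carlo", {
  expect_equal(power_two_sample(0, 20, 25, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  expect_gt(power_two_sample(5, 30, 30), 0.999)
  expect_error(power_two_sample(0.5, 10, 10, alpha = 1.2), "alpha")

  # monotone in effect size, sample sizes and alpha
  expect_true(all(diff(sapply(c(0.2, 0.5, 0.8, 1.2),
                              power_two_sample, n1 = 30, n2 = 30)) > 0))
  expect_true(all(diff(sapply(c(10, 30, 80),
                              function(n) power_two_sample(0.5, n, n))) > 0))
  expect_lt(power_two_sample(0.5, 30, 30, alpha = 0.01),
            power_two_sample(0.5, 30, 30, alpha = 0.10))

  # Monte-Carlo oracle at the study's global-comparison sample sizes
  set.seed(123)
  nsim <- 20000; n1 <- 30; n2 <- 83; d <- 0.8
  x1 <- matrix(rnorm(nsim * n1, d, 1), nrow = n1)
  x2 <- matrix(rnorm(nsim * n2, 0, 1), nrow = n2)
  v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (colMeans(x1) - colMeans(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  mc <- mean(abs(tstat) > qt(0.975, n1 + n2 - 2))
  expect_equal(power_two_sample(d, n1, n2), mc, tolerance = 0.02)
})

test_that("assumption checks report Levene and Shapiro without gating", {
  set.seed(42)
  g1 <- rnorm(30); g2 <- rnorm(30)
  rep_equal <- check_assumptions(list(a = g1, b = g1))
  expect_equal(rep_equal$levene$p, 1)

  rep_ok <- check_assumptions(list(a = g1, b = g2))
  expect_gt(rep_ok$levene$p, 0.05)
  expect_equal(nrow(rep_ok$normality), 2L)
  expect_true(all(rep_ok$normality$shapiro_p > 0.001))

  rep_het <- check_assumptions(list(const = rep(1, 30), var = g2))
  expect_lt(rep_het$levene$p, 0.05)
  expect_true(is.na(rep_het$normality$shapiro_w[1]))

  expect_error(check_assumptions(list(1:2, 1:5)), "at least 3")
})

test_that("the joint rule gates significance on both p and effect size", {
  expect_true(joint_significance(0.01, 1.8))
  expect_false(joint_significance(0.01, 0.1))
  expect_false(joint_significance(0.2, 2.0))
  expect_true(joint_significance(0.01, -0.5))   # magnitude, not sign
  expect_false(joint_significance(0.049, 0.2))  # strict d threshold
})
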
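test_that("noiseless lines are fitted exactly", {
  x <- seq(2, 20, length.out = 10)
  f <- fit_loglog(x, x)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  g <- fit_loglog(x, 2 * x^1.5)
  expect_equal(g$slope, 1.5, tolerance = 1e-9)
  expect_equal(g$intercept, log10(2), tolerance = 1e-9)
  expect_equal(g$df, 8L)
})

test_that("fits agree with the textbook least-squares oracle under noise", {
  set.seed(3)
  x <- 10^runif(25, 0, 1.2)
  y <- 0.5 * x^1.2 * 10^rnorm(25, 0, 0.1)
  f <- fit_loglog(x, y)
  o <- ols_oracle(log10(x), log10(y))
  expect_equal(f$slope, o$slope, tolerance = 1e-12)
  expect_equal(f$slope_se, o$se, tolerance = 1e-12)
  expect_equal(f$r2, o$r2, tolerance = 1e-12)
  expect_equal(f$p_slope_zero, 2 * pt(-abs(o$slope / o$se), o$df),
               tolerance = 1e-12)
})

test_that("domain and degeneracy violations are rejected with context", {
  expect_error(fit_loglog(c(1, 2, -1, 3), c(1, 2, 3, 4)), "index 3")
  expect_error(fit_loglog(c(1, 2, 3), c(1, 0, 3)), "index 2")
  expect_error(fit_loglog(rep(2, 5), 1:5), "constant")
  expect_error(fit_loglog(1:2, 1:2), "at least 3")
})

test_that("slope test against a null matches direct t evaluation", {
  fit <- structure(list(slope = 0.79, slope_se = 0.05, df = 28),
                   class = "powerlaw_fit")
  out <- test_slope_against(fit, 1)
  expect_equal(out$t_vs_null, -4.2, tolerance = 1e-12)
  expect_equal(out$p_slope_vs_null, 2 * pt(-4.2, 28), tolerance = 1e-12)
  expect_lt(abs(out$p_slope_vs_null - 2.4e-4), 5e-5)

  same <- test_slope_against(structure(list(slope = 1, slope_se = 0.1, df = 10),
                                       class = "powerlaw_fit"), 1)
  expect_equal(same$t_vs_null, 0)
  expect_equal(same$p_slope_vs_null, 1)

  degen <- structure(list(slope = 1.2, slope_se = 0, df = 10),
                     class = "powerlaw_fit")
  expect_error(test_slope_against(degen, 1), "degenerate")
})

test_that("near-noiseless power laws drive the slope-vs-null p toward zero", {
  x <- seq(2, 20, length.out = 15)
  p <- vapply(c(1e-2, 1e-4, 1e-6), function(sd) {
    set.seed(1)
    f <- fit_loglog(x, x^1.4 * 10^rnorm(15, 0, sd))
    test_slope_against(f, 1)$p_slope_vs_null
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_lt(p[3], 1e-12)
})

test_that("mixed mode equals site-mean OLS with one observation per site", {
  set.seed(8)
  x <- 10^runif(12, 0.2, 1.2)
  y <- 0.6 * x^1.3 * 10^rnorm(12, 0, 0.05)
  site <- sprintf("S%02d", 1:12)
  a <- fit_loglog(x, y, mode = "site_means")
  b <- fit_loglog(x, y, mode = "mixed", site = site)
  expect_identical(b$mode, "site_means")
  expect_equal(b$slope, a$slope)
  expect_equal(b$slope_se, a$slope_se)
})

test_that("mixed mode with replicates recovers the generating exponent", {
  sim <- simulate_transect(pure_config(seed = 21, b_p = 1.3))
  pairs <- pair_site_periods(sim$leaf)
  reps <- pairs$replicates
  f <- fit_loglog(reps$mat_p, reps$sen_p, mode = "mixed", site = reps$site_id)
  expect_identical(f$mode, "mixed")
  expect_equal(f$df, 28L)
  expect_lt(abs(f$slope - 1.3), 0.2)
  expect_error(fit_loglog(reps$mat_p, reps$sen_p, mode = "mixed"), "site")
})

test_that("seed-averaged recovery of a 1.3 exponent lands in [1.2, 1.4]", {
  slopes <- vapply(1:100, function(s) {
    sim <- simulate_transect(pure_config(seed = s, b_p = 1.3))
    pairs <- pair_site_periods(sim$leaf)
    fit_loglog(pairs$sites$mat_p, pairs$sites$sen_p)$slope
  }, numeric(1))
  expect_gt(mean(slopes), 1.2)
  expect_lt(mean(slopes), 1.4)
})

test_that("powerlaw_fit methods predict, invert and simulate on the data scale", {
  x <- seq(2, 20, length.out = 12)
  f <- fit_loglog(x, 2 * x^1.5)
  expect_equal(predict(f, newdata = 10), 2 * 10^1.5, tolerance = 1e-9)
  expect_equal(unname(coef(f)), c(log10(2), 1.5), tolerance = 1e-9)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-9)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(12L, 2L))
  expect_true(all(sims > 0))
})
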
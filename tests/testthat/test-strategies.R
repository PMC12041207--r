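test_that("concentration control is detected for a supra-linear power law only", {
  x <- seq(8, 30, length.out = 10)
  steep <- pair_site_periods(make_leaf_table(x, 0.05 * x^1.5))
  v <- concentration_control_test(steep, "N")
  expect_true(v$supported)
  expect_equal(v$evidence$fit$slope, 1.5, tolerance = 1e-9)

  linear <- pair_site_periods(make_leaf_table(x, 0.4 * x))
  expect_false(concentration_control_test(linear, "N")$supported)
})

test_that("independent mature and senesced concentrations rarely support concentration control", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    mat <- 10^rnorm(30, log10(20), 0.08)
    sen <- 10^rnorm(30, log10(8), 0.08)
    pairs <- pair_site_periods(make_leaf_table(mat, sen))
    concentration_control_test(pairs, "N")$supported
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 0.03)
})

test_that("stoichiometric resorption is recognised and destroyed by shuffling", {
  sim <- simulate_transect(synthetic_config(seed = 3, lambda_np = 1,
                                            sigma_log = 0.02))
  sites <- suppressMessages(site_resorption(pair_site_periods(sim$leaf)))
  expect_true(stoichiometry_control_test(sites)$supported)

  set.seed(99)
  hits <- vapply(1:100, function(i) {
    shuf <- sites
    k <- sample(nrow(shuf))
    shuf$pre <- shuf$pre[k]
    shuf$resorbed_p <- shuf$resorbed_p[k]
    shuf$resorbed_np <- shuf$resorbed_n / shuf$resorbed_p
    suppressMessages(stoichiometry_control_test(shuf)$supported)
  }, logical(1))
  expect_lte(mean(hits), 0.05)

  expect_error(suppressMessages(stoichiometry_control_test(sites[1:2, ])),
               "insufficiency")
})

test_that("limitation control recovers the generating exponent exactly without noise", {
  sim <- simulate_transect(pure_config(seed = 5, sigma_log = 0))
  sites <- site_resorption(pair_site_periods(sim$leaf))
  v <- limitation_control_test(sites)
  expect_equal(v$evidence$lambda, 0.79, tolerance = 1e-7)
  expect_true(v$supported)

  # the intensity effect preserves stoichiometric allocation, so the
  # exponent survives it even though concentrations shift per site
  sim2 <- simulate_transect(synthetic_config(seed = 5, sigma_log = 0,
                                             tradeoff_slope = 0,
                                             site_effect_sd = 0.1))
  sites2 <- site_resorption(pair_site_periods(sim2$leaf))
  expect_equal(limitation_control_test(sites2)$evidence$lambda, 0.79,
               tolerance = 0.05)

  flat <- simulate_transect(pure_config(seed = 6, sigma_log = 0,
                                        lambda_np = 1, epsilon_np = 1.7))
  sitesf <- site_resorption(pair_site_periods(flat$leaf))
  vf <- limitation_control_test(sitesf)
  expect_equal(vf$evidence$lambda, 1, tolerance = 1e-7)
  expect_false(vf$supported)
})

test_that("limitation control has high power at lambda 0.8 under replicate noise", {
  hits <- vapply(1:30, function(s) {
    sim <- simulate_transect(pure_config(seed = s, lambda_np = 0.8))
    sites <- site_resorption(pair_site_periods(sim$leaf))
    limitation_control_test(sites)$supported
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("efficiency-ratio and resorbed-ratio regressions agree on the exponent algebra", {
  # constructed exactly from the ratio power law: the resorbed-ratio fit
  # gives lambda and the ratio of efficiencies scaled by mature N:P gives
  # lambda - 1
  np <- seq(8, 22, length.out = 12)
  eps <- 1.33
  lambda <- 0.79
  resorbed_np <- eps * np^lambda
  f1 <- fit_loglog(np, resorbed_np)
  f2 <- fit_loglog(np, resorbed_np / np)
  expect_equal(f1$slope, lambda, tolerance = 1e-9)
  expect_equal(f2$slope, lambda - 1, tolerance = 1e-9)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-9)
})

test_that("verdicts are invariant to site relabelling and row order", {
  sim <- simulate_transect(synthetic_config(seed = 17))
  sites <- suppressMessages(site_resorption(pair_site_periods(sim$leaf)))
  v0 <- limitation_control_test(sites)

  set.seed(2)
  perm <- sample(nrow(sites))
  shuffled <- sites[perm, ]
  shuffled$site_id <- paste0("Z", seq_len(nrow(sites)))
  v1 <- limitation_control_test(shuffled)
  expect_equal(v1$supported, v0$supported)
  expect_equal(v1$evidence$lambda, v0$evidence$lambda, tolerance = 1e-12)

  leaf_perm <- sim$leaf[sample(nrow(sim$leaf)), ]
  s2 <- suppressMessages(site_resorption(pair_site_periods(leaf_perm)))
  v2 <- limitation_control_test(s2)
  expect_equal(v2$evidence$lambda, v0$evidence$lambda, tolerance = 1e-12)
})

test_that("sites with non-positive resorbed P are excluded with a message", {
  sim <- simulate_transect(synthetic_config(seed = 9, n_sites = 10))
  sites <- site_resorption(pair_site_periods(sim$leaf))
  sites$resorbed_p[1] <- -0.05
  sites$resorbed_np[1] <- NA_real_
  expect_message(v <- limitation_control_test(sites), "excluded 1")
  expect_equal(v$excluded, 1L)
  expect_equal(v$evidence$fit$n, 9L)
})
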
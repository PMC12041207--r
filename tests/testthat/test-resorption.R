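test_that("resorption efficiency follows the mature-senesced definition", {
  expect_equal(resorption_efficiency(10, 5), 50)
  expect_equal(resorption_efficiency(7.3, 7.3), 0)
  expect_equal(resorption_efficiency(8.2, 3.1), (8.2 - 3.1) / 8.2 * 100)
  expect_warning(out <- resorption_efficiency(5, 6), "negative")
  expect_lt(out, 0)
  expect_error(resorption_efficiency(0, 1), "nu_mat")
  expect_error(resorption_efficiency(10, -1), "nu_sen")
})

test_that("absolute resorption is consistent with efficiency for random pairs", {
  expect_equal(absolute_resorption(10, 4), 6)
  expect_equal(absolute_resorption(5.5, 5.5), 0)
  set.seed(1)
  mat <- runif(200, 0.5, 40)
  sen <- runif(200, 0, 1) * mat
  expect_equal(absolute_resorption(mat, sen) / mat * 100,
               resorption_efficiency(mat, sen), tolerance = 1e-12)
  # efficiency is always below 100 and zero only at equality
  expect_true(all(resorption_efficiency(mat, sen) < 100))
})

test_that("power-law generated senesced values reproduce the closed-form efficiency", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0.05, 1.5)
    b <- runif(1, 0.5, 2)
    mat <- runif(30, 0.5, 40)
    sen <- a * mat^b
    expect_equal(suppressWarnings(resorption_efficiency(mat, sen)),
                 (1 - a * mat^(b - 1)) * 100, tolerance = 1e-9)
  }
})

test_that("proficiency classification uses a strict boundary", {
  v <- proficiency_class("P", c(0.3, 0.4, 0.9))
  expect_equal(v$complete, c(TRUE, FALSE, FALSE))
  expect_equal(unique(v$boundary), 0.4)
  # invariant: complete iff strictly below the boundary
  expect_equal(v$complete, v$sen_conc < v$boundary)
  expect_error(proficiency_class("N", 5), "boundary")
  expect_equal(proficiency_class("N", 5, boundary = 7)$complete, TRUE)
})

test_that("MLCF table holds the five growth-form constants and validates overrides", {
  tab <- mlcf_table()
  expect_equal(unname(tab[c("evergreen_broadleaf", "deciduous_broadleaf",
                            "conifer", "forb", "graminoid")]),
               c(0.780, 0.784, 0.745, 0.640, 0.713))
  expect_equal(unname(mlcf_table(c(forb = 0.7))["forb"]), 0.7)
  expect_error(mlcf_table(c(shrub = 0.7)), "unknown growth form")
  expect_error(mlcf_table(c(forb = 1.2)), "\\(0, 1\\]")
})

test_that("mass-to-concentration conversion matches hand substitution and inverts", {
  expect_equal(mass_to_concentration_basis(0.5, "forb"), 68)
  expect_equal(mass_to_concentration_basis(0, "evergreen_broadleaf"), 22)
  # an MLCF of 1 (no mass loss) makes the conversion the identity
  expect_equal(mass_to_concentration_basis(0.42, "forb",
                                           mlcf_table(c(forb = 1))), 42)
  expect_error(mass_to_concentration_basis(0.5, "shrub"), "lookup")
  expect_error(mass_to_concentration_basis(1.2, "forb"), "\\[0, 1\\)")

  set.seed(7)
  m <- runif(100, 0, 0.99)
  forms <- sample(names(mlcf_table()), 100, replace = TRUE)
  conv <- mass_to_concentration_basis(m, forms)
  expect_equal(concentration_to_mass_basis(conv, forms), m, tolerance = 1e-9)
})

test_that("the conversion is monotone in efficiency and correction factor", {
  m <- seq(0.05, 0.95, by = 0.05)
  out <- mass_to_concentration_basis(m, rep("graminoid", length(m)))
  expect_true(all(diff(out) > 0))
  # for mlcf < 1 the concentration-based value exceeds the mass-based one
  expect_true(all(out > m * 100))
  one_m <- 0.4
  by_form <- vapply(names(mlcf_table()),
                    function(f) mass_to_concentration_basis(one_m, f),
                    numeric(1))
  expect_equal(order(by_form), order(-mlcf_table()))
})

test_that("site resorption summary flags undefined resorbed ratios", {
  tab <- make_leaf_table(mat_n = c(20, 18), sen_n = c(8, 9),
                         mat_p = c(1.5, 1.4), sen_p = c(0.4, 1.4))
  pairs <- pair_site_periods(tab)
  expect_message(sites <- site_resorption(pairs), "non-positive resorbed P")
  expect_true(is.na(sites$resorbed_np[2]))
  expect_equal(sites$resorbed_np[1], (20 - 8) / (1.5 - 0.4))
  expect_equal(sites$mature_np, c(20 / 1.5, 18 / 1.4))
})
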
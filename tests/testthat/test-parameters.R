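test_that("median/rate conversions follow the exponential assumption and invert", {
  expect_equal(median_to_rate(log(2)), 1)
  expect_equal(median_to_rate(0.77), 0.90021, tolerance = 1e-4)
  expect_equal(median_to_rate(2), 0.34657, tolerance = 1e-4)
  for (m in c(0.01, 0.77, 1.5, 12, 80))
    expect_equal(rate_to_median(median_to_rate(m)), m)
  expect_error(median_to_rate(0), "positive")
  expect_error(rate_to_median(-1), "positive")
})

test_that("rate_to_annual_prob is bounded, increasing, and linear for tiny rates", {
  expect_equal(rate_to_annual_prob(0), 0)
  expect_equal(rate_to_annual_prob(log(2)), 0.5)
  expect_equal(rate_to_annual_prob(0.904), 0.59504, tolerance = 1e-4)
  r <- seq(0, 10, by = 0.05)
  p <- rate_to_annual_prob(r)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  tiny <- c(1e-8, 1e-6, 5e-5)
  expect_equal(rate_to_annual_prob(tiny), tiny, tolerance = 1e-4)
  expect_error(rate_to_annual_prob(-0.1), "nonnegative")
})

test_that("gamma moment matching reproduces frozen shape/scale pairs", {
  expect_equal(gamma_from_mean_se(1, 1), list(shape = 1, scale = 1))
  g <- gamma_from_mean_se(0.351, 0.103)
  expect_equal(g$shape, 11.612, tolerance = 1e-3)
  expect_equal(g$scale, 0.030225, tolerance = 1e-3)
  g2 <- gamma_from_mean_se(1.053e-5, 1.39e-6)
  expect_equal(g2$shape, 57.386, tolerance = 1e-3)
  expect_equal(g2$scale, 1.8348e-7, tolerance = 1e-3)
  expect_error(gamma_from_mean_se(0, 1), "positive")
  expect_error(gamma_from_mean_se(1, 0), "positive")
})

test_that("beta moment matching reproduces frozen alpha/beta pairs", {
  b <- beta_from_mean_se(0.5, 0.25)
  expect_equal(b$alpha, 1.5)
  expect_equal(b$beta, 1.5)
  b2 <- beta_from_mean_se(0.8, 0.05)
  expect_equal(b2$alpha, 50.4)
  expect_equal(b2$beta, 12.6)
  expect_error(beta_from_mean_se(0.5, 0.5), "se too large")
  expect_error(beta_from_mean_se(1.2, 0.1), "between 0 and 1")
})

test_that("moment-matched samplers recover mean and SD within 3 MC standard errors", {
  n <- 1e5
  set.seed(101)
  for (spec in list(c(0.351, 0.103), c(1.053e-5, 1.39e-6), c(0.904, 0.10))) {
    g <- gamma_from_mean_se(spec[1], spec[2])
    x <- rgamma(n, shape = g$shape, scale = g$scale)
    expect_lt(abs(mean(x) - spec[1]), 3 * spec[2] / sqrt(n))
    expect_lt(abs(sd(x) - spec[2]), 3 * spec[2] / sqrt(n))
  }
  b <- beta_from_mean_se(0.8, 0.05)
  x <- rbeta(n, b$alpha, b$beta)
  expect_lt(abs(mean(x) - 0.8), 3 * 0.05 / sqrt(n))
  expect_lt(abs(sd(x) - 0.05), 3 * 0.05 / sqrt(n))
})

test_that("direct standardization handles crude, equal-weight and split-stratum cases", {
  one <- data.frame(age_band = "40-49", sex = "F", cases = 10,
                    person_years = 1e6, reference_population = 123)
  expect_equal(standardize_incidence(one), 1e-5)
  two <- data.frame(cases = c(10, 30), person_years = c(1e6, 1e6),
                    reference_population = c(500, 500))
  expect_equal(standardize_incidence(two), 2e-5)
  # invariant: splitting a stratum into identical halves changes nothing
  split2 <- data.frame(cases = c(10, 15, 15), person_years = c(1e6, 5e5, 5e5),
                       reference_population = c(500, 250, 250))
  expect_equal(standardize_incidence(split2),
               standardize_incidence(two))
  expect_error(standardize_incidence(two[0, ]), "non-empty")
  bad <- two; bad$person_years[1] <- 0
  expect_error(standardize_incidence(bad), "positive")
})

test_that("life-table weighting averages on the rate scale", {
  single <- data.frame(annual_mortality = -expm1(-0.0314), patient_weight = 1)
  expect_equal(weighted_background_mortality(single), 0.0314)
  two <- data.frame(annual_mortality = -expm1(-c(0.01, 0.05)),
                    patient_weight = c(0.5, 0.5))
  expect_equal(weighted_background_mortality(two), 0.03)
  expect_error(weighted_background_mortality(
    data.frame(annual_mortality = 1, patient_weight = 1)), "infinite rate")
})

test_that("parameter table ships the default configuration and validates rows", {
  tab <- default_parameter_table()
  expect_equal(nrow(tab), 7)
  expect_setequal(tab$family, c("gamma", "beta"))
  expect_true(all(tab$min <= tab$base & tab$base <= tab$max))
  p <- parameter_set_from_table(tab)
  expect_equal(unclass(p), unclass(gist_parameters()), tolerance = 1e-12)
  expect_error(parameter_set_from_table(tab, overrides = list(nope = 1)),
               "unknown parameter")
  bad <- tab; bad$base[1] <- bad$max[1] * 2
  expect_error(validate_parameter_row(bad[1, ]), "min <= base <= max")
  bad2 <- tab[tab$name == "p_resectable", ]; bad2$se <- 0.9
  expect_error(validate_parameter_row(bad2), "beta family")
})

test_that("parameter tables round-trip through CSV", {
  tab <- default_parameter_table()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tab, tmp)
  expect_equal(read_parameter_table(tmp), tab, tolerance = 1e-12)
})

test_that("parameter-set invariants are enforced", {
  expect_error(gist_parameters(incidence = 0), "strictly positive")
  expect_error(gist_parameters(p_resectable = 1), "strictly between")
  expect_error(gist_parameters(population = -1), "positive")
  expect_error(gist_parameters(thirdline_exit_rate = Inf), "finite")
})
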
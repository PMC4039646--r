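test_that("tornado analysis ranks incidence and third-line survival first", {
  tor <- one_way_sa(base_params())
  expect_s3_class(tor, "gist_tornado")
  expect_equal(nrow(tor), 7)
  expect_true(all(diff(tor$swing) <= 0))
  expect_setequal(tor$parameter[1:2], c("incidence", "thirdline_exit_rate"))
  # imatinib and sunitinib transition rates are least influential
  expect_setequal(tor$parameter[6:7],
                  c("imatinib_failure_rate", "sunitinib_failure_rate"))
})

test_that("degenerate min = max = base ranges give zero swings", {
  tab <- default_parameter_table()
  tab$min <- tab$max <- tab$base
  tor <- one_way_sa(base_params(), tab)
  expect_equal(tor$swing, rep(0, 7))
  bad <- default_parameter_table()
  bad$min[1] <- bad$max[1] + 1
  expect_error(one_way_sa(base_params(), bad), "min > max")
})

test_that("parameter sampling honours families, fixing, and the RNG contract", {
  tab <- default_parameter_table()
  # all fixed: input returned exactly
  tabf <- tab; tabf$family <- "fixed"
  d <- sample_parameter_sets(tabf, 5)
  for (nm in tab$name) expect_equal(d[[nm]], rep(tab$base[tab$name == nm], 5))
  # moment recovery at 1e5 draws
  set.seed(77)
  d <- sample_parameter_sets(tab, 1e5)
  for (i in seq_len(nrow(tab))) {
    x <- d[[tab$name[i]]]
    mc <- 3 * tab$se[i] / sqrt(1e5)
    expect_lt(abs(mean(x) - tab$base[i]), mc)
    expect_lt(abs(sd(x) - tab$se[i]), mc)
  }
  expect_true(all(d$p_resectable > 0 & d$p_resectable < 1))
  expect_true(all(as.matrix(d) > 0))
  # same seed, same draws
  set.seed(123); a <- sample_parameter_sets(tab, 50)
  set.seed(123); b <- sample_parameter_sets(tab, 50)
  expect_identical(a, b)
  # single-draw interface returns a valid parameter set
  set.seed(5)
  expect_s3_class(sample_parameter_set(tab), "gist_parameters")
})

test_that("recentring shifts the sampling means to the scenario values", {
  tab <- default_parameter_table()
  sc <- gist_parameters(incidence = 1.5e-5)
  set.seed(9)
  d <- sample_parameter_sets(tab, 2e4, params = sc)
  expect_equal(mean(d$incidence), 1.5e-5, tolerance = 3 * 0.139e-5 / sqrt(2e4) / 1.5e-5)
  expect_equal(mean(d$thirdline_exit_rate), 0.904, tolerance = 0.01)
})

test_that("PSA is reproducible, nested, and collapses in the zero-variance limit", {
  a <- run_psa(n_draws = 400, seed = 2024)
  b <- run_psa(n_draws = 400, seed = 2024)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ci, b$ci)
  expect_gte(a$prob_below_orphan, a$prob_below_ultra_orphan)
  expect_true(all(a$ci[, 1] <= a$ci[, 3]))
  # deterministic base outcome lies inside the credibility intervals
  o <- gist_model()$outcomes
  expect_gt(o$thirdline_prev_per_100k, a$ci["thirdline_prev_per_100k", 1])
  expect_lt(o$thirdline_prev_per_100k, a$ci["thirdline_prev_per_100k", 3])
  # all-fixed table: intervals collapse onto the deterministic outcome
  tabf <- default_parameter_table(); tabf$family <- "fixed"
  z <- run_psa(table = tabf, n_draws = 10, seed = 1)
  expect_equal(unname(z$ci["thirdline_prev_per_100k", ]),
               rep(o$thirdline_prev_per_100k, 3))
  expect_true(z$prob_below_ultra_orphan %in% c(0, 1))
})

test_that("credibility intervals tighten as standard errors shrink", {
  tab <- default_parameter_table()
  widths <- vapply(c(1, 0.5, 0.1), function(f) {
    t2 <- tab; t2$se <- t2$se * f
    ci <- run_psa(table = t2, n_draws = 1500, seed = 31)$ci
    unname(ci["thirdline_prev_per_100k", 3] - ci["thirdline_prev_per_100k", 1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("simulate() on a fitted model delegates to the PSA", {
  fit <- gist_model()
  s <- simulate(fit, nsim = 300, seed = 11)
  expect_s3_class(s, "gist_psa")
  expect_equal(s$n_draws, 300)
  expect_identical(s$draws, run_psa(n_draws = 300, seed = 11)$draws)
})
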
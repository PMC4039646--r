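test_that("one annual cycle from the empty population admits the incident cohort", {
  p <- base_params()
  s0 <- empty_state()
  # empty system with no inflow is a fixed point
  p0 <- gist_parameters(incidence = 1e-300)
  expect_equal(unname(annual_step(s0, p0)[occ]), rep(0, 4), tolerance = 1e-250)
  s1 <- annual_step(s0, p)
  n_new <- p$incidence * p$population
  expect_equal(unname(s1["z2"]), 0.8 * n_new)   # 524.50 resectable
  expect_equal(unname(s1["z3"]), 0.2 * n_new)   # 131.12 direct to imatinib
  expect_equal(unname(s1[c("z4", "z5")]), c(0, 0))
  expect_equal(unname(s1["cumulative_incident"]), n_new)
})

test_that("mass is conserved at every step for random parameter sets", {
  for (k in 1:25) {
    p <- random_parameter_set(seed = 500 + k)
    s <- empty_state()
    for (t in 1:30) s <- annual_step(s, p)
    inflow <- s["cumulative_incident"]
    balance <- sum(s[occ]) + s["cumulative_deaths"]
    expect_equal(unname(balance), unname(inflow), tolerance = 1e-12)
  }
})

test_that("the closed form is a fixed point of the annual step", {
  for (seed in c(11, 12, 13)) {
    p <- random_parameter_set(seed = seed)
    z <- closed_form_equilibrium(p)
    s <- c(z, cumulative_deaths = 0, cumulative_incident = 0)
    s1 <- annual_step(s, p)
    expect_equal(unname(s1[occ]), unname(z), tolerance = 1e-9)
  }
})

test_that("iterated and closed-form equilibria agree over the valid parameter space", {
  for (k in 1:50) {
    p <- random_parameter_set(seed = 9000 + k)
    eq <- solve_equilibrium(p, tolerance = 1e-8)
    expect_true(eq$converged)
    expect_equal(unname(eq$state[occ]), unname(closed_form_equilibrium(p)),
                 tolerance = 1e-6)
  }
})

test_that("equilibrium counts are linear in incidence and population, monotone in the right directions", {
  p <- base_params()
  z <- closed_form_equilibrium(p)
  z2x <- closed_form_equilibrium(
    gist_parameters(incidence = 2 * p$incidence))
  expect_equal(unname(z2x), unname(2 * z))
  zpop <- closed_form_equilibrium(gist_parameters(population = 2 * p$population))
  expect_equal(unname(zpop), unname(2 * z))
  # z5 decreases as the third-line exit rate grows (shorter survival)
  g5_grid <- seq(0.2, 2, length.out = 12)
  z5s <- vapply(g5_grid, function(g)
    closed_form_equilibrium(gist_parameters(thirdline_exit_rate = g))["z5"],
    numeric(1))
  expect_true(all(diff(z5s) < 0))
  # z2 increases with the resectable proportion
  p_grid <- seq(0.1, 0.9, length.out = 9)
  z2s <- vapply(p_grid, function(pp)
    closed_form_equilibrium(gist_parameters(p_resectable = pp))["z2"],
    numeric(1))
  expect_true(all(diff(z2s) > 0))
})

test_that("occupancies stay nonnegative along trajectories", {
  for (k in 1:10) {
    p <- random_parameter_set(seed = 40 + k)
    traj <- run_transient(p, 60)
    expect_true(all(as.matrix(traj[occ]) >= 0))
  }
})

test_that("outcome mapping and threshold indicator arithmetic are exact", {
  p <- base_params()
  s <- c(z2 = 100, z3 = 50, z4 = 25, z5 = 1245.242, cumulative_deaths = 0,
         cumulative_incident = 0)
  o <- state_outcomes(s, p)
  expect_equal(o$thirdline_prev_per_100k, 2.0, tolerance = 1e-6)
  expect_false(o$below_ultra_orphan)   # boundary is strict
  expect_equal(o$total_count, 1420.242)
  expect_equal(o$imatinib_count, 50)
  expect_equal(o$sunitinib_count, 25)
  o0 <- state_outcomes(empty_state(), p)
  expect_equal(o0$total_count, 0)
  expect_true(o0$below_ultra_orphan)
})

test_that("apportioned exit variant stays close to the additive default", {
  p <- base_params()
  za <- closed_form_equilibrium(p, exits = "additive")
  zb <- closed_form_equilibrium(p, exits = "apportioned")
  expect_equal(unname(zb), unname(za), tolerance = 0.1)
  eq <- solve_equilibrium(p, exits = "apportioned")
  expect_equal(unname(eq$state[occ]), unname(zb), tolerance = 1e-5)
})

test_that("gist_model wraps the solution with coherent methods", {
  fit <- gist_model()
  expect_s3_class(fit, "gist_model")
  expect_equal(unname(fit$state), unname(closed_form_equilibrium(fit$params)))
  expect_equal(fit$outcomes$total_count, sum(fit$state))
  it <- gist_model(method = "iterate")
  expect_true(it$converged)
  expect_equal(unname(it$state), unname(fit$state), tolerance = 1e-6)
  cf <- coef(fit)
  expect_equal(unname(cf["incidence"]), 1.053e-5)
  traj <- predict(fit, years = 200)
  expect_equal(unname(unlist(traj[201, occ])), unname(fit$state),
               tolerance = 1e-3)
  expect_output(print(fit), "Third-line eligible")
  expect_output(print(summary(fit)), "State occupancies")
})
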
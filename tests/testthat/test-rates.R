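test_that("observed division rate is the exponential growth constant", {
  expect_equal(observed_division_rate(1000, 1000, 46), 0)
  expect_equal(observed_division_rate(1e5, 2e5, 24), log(2))
  expect_equal(observed_division_rate(100, 100 * exp(1), 46), 24 / 46,
    tolerance = 1e-12
  )
  expect_error(observed_division_rate(0, 10, 24), "positive")
})

test_that("toy full-division day doubles the population: mu = log 2", {
  g <- toy_grid3()
  spec <- model_spec("bmb", dt = 1)
  th <- mpm_theta(spec, g,
    delta_max = 24, delta_incr = 1, gamma_max = 0, e_k = 300,
    rho_max = 0, omega0 = c(0, 0, 1), sigma = 10
  ) # per-step delta_3 = 1
  light <- light_series(seq(0, 24, 1), rep(0, 25))
  expect_equal(model_daily_division_rate(th, spec, g, light, c(0, 24)), log(2),
    tolerance = 1e-12
  )
})

test_that("model estimator equals the totals-based estimator exactly", {
  g <- ref_grid()
  set.seed(17)
  light <- diel_par(14, 600, 1 / 3, 46)
  times <- seq(0, 46, 2)
  for (nm in c("bmx", "bmb", "pmb", "fmf", "ftf")) {
    spec <- model_spec(nm)
    th <- random_theta(spec, g)
    tr <- simulate_trajectory(th, spec, g, light, times)
    mu_hat <- model_daily_division_rate(th, spec, g, light, times)
    K <- length(times)
    mu_obs <- observed_division_rate(1, tr$totals[K], 46)
    expect_equal(mu_hat, mu_obs, tolerance = 1e-10, label = nm)
    # delta == 0 model gives exactly zero
    th0 <- th
    th0$delta_max <- 0
    expect_equal(model_daily_division_rate(th0, spec, g, light, times), 0,
      tolerance = 1e-12
    )
  }
})

test_that("hourly division series telescopes to the daily rate", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(23)
  th <- random_theta(spec, g)
  light <- diel_par(14, 600, 1 / 3, 46)
  times <- seq(0, 46, 2)
  tr <- simulate_trajectory(th, spec, g, light, times)
  h <- hourly_division_series(tr)
  mu_hat <- model_daily_division_rate(th, spec, g, light, times)
  expect_equal(sum(h$rate) / 24, mu_hat * 46 / 24, tolerance = 1e-10)
  # constant growth factor g per step at dt = 1/3: every hourly value 72 log g
  fake <- list(
    step_growth = rep(1.01, 18), dt = 1 / 3,
    lattice_times = seq(0, 6, 1 / 3)
  )
  expect_equal(hourly_division_series(fake)$rate, rep(72 * log(1.01), 6),
    tolerance = 1e-12
  )
  # zero-division trajectory: all-zero series
  th0 <- th
  th0$delta_max <- 0
  tr0 <- simulate_trajectory(th0, spec, g, light, times)
  expect_equal(hourly_division_series(tr0)$rate, rep(0, 46), tolerance = 1e-10)
})

test_that("carbon fluxes convert transitions to midpoint carbon differences", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  light <- light_series(seq(0, 2, 1 / 3), rep(500, 7))
  times <- c(0, 2)
  th <- random_theta(spec, g)
  th$gamma_max <- 0
  expect_equal(carbon_flux_series(th, spec, g, light, times)$hourly$flux,
    c(0, 0),
    tolerance = 1e-14
  )
  # single occupied class, first step: increment is P(grow) * (vbar_{i+1} - vbar_i)
  i <- 5L
  th2 <- random_theta(spec, g)
  th2$omega0 <- replace(rep(0, 27), i, 1)
  tr <- simulate_trajectory(th2, spec, g, light, times, keep_steps = TRUE)
  fl <- sizempm:::step_carbon_fluxes(tr, g)
  gam <- growth_fractions(th2, g, 500, spec$dt)
  rho <- loss_fractions(th2, g, spec$dt, "basic")
  expect_equal(
    fl$fixation[1],
    (1 - rho[i]) * gam[i] * (g$midpoints[i + 1] - g$midpoints[i]),
    tolerance = 1e-12
  )
  expect_equal(
    fl$loss[1],
    rho[i] * (g$midpoints[i] - g$midpoints[i - 1]),
    tolerance = 1e-12
  )
})

test_that("fixation increases with light and is capped by P_max", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(3)
  th <- random_theta(spec, g)
  times <- seq(0, 24, 2)
  dim_light <- diel_par(14, 200, 1 / 3, 24)
  bright <- diel_par(14, 1200, 1 / 3, 24)
  f_dim <- carbon_flux_series(th, spec, g, dim_light, times)$daily
  f_bright <- carbon_flux_series(th, spec, g, bright, times)$daily
  expect_gte(f_bright, f_dim)
  expect_gte(pmax_estimate(th, spec, g, bright, times), f_bright)
  # saturating light everywhere: P_max coincides with realized fixation
  sat <- light_series(seq(0, 24, 1 / 3), rep(1e7 * th$e_k, 73))
  f_sat <- carbon_flux_series(th, spec, g, sat, times)$daily
  expect_equal(pmax_estimate(th, spec, g, sat, times) / f_sat, 1,
    tolerance = 1e-4
  )
})

test_that("fixation minus loss balances mean-size change without division", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(29)
  th <- random_theta(spec, g)
  th$delta_max <- 0
  light <- diel_par(14, 600, 1 / 3, 24)
  times <- seq(0, 24, 2)
  tr <- simulate_trajectory(th, spec, g, light, times, keep_steps = TRUE)
  fl <- sizempm:::step_carbon_fluxes(tr, g)
  s0 <- sum(th$omega0 * g$midpoints)
  sK <- sum(tr$omegas[length(times), ] * g$midpoints)
  expect_equal(sum(fl$fixation - fl$loss), sK - s0, tolerance = 1e-8)
})

test_that("size-distribution MSE matches direct evaluation", {
  tr <- list(times = c(0, 2), omegas = rbind(c(0.6, 0.4), c(1, 0)))
  obs <- obs_set(c(0, 2), rbind(c(50, 50), c(100, 1)))
  obs$proportions <- rbind(c(0.5, 0.5), c(1, 0))
  expect_equal(psd_mse(tr, obs), mean(c(0.01, 0.01, 0, 0)))
  tr2 <- list(times = c(0, 2), omegas = obs$proportions)
  expect_equal(psd_mse(tr2, obs), 0)
  tr3 <- list(times = c(0, 1), omegas = obs$proportions)
  expect_error(psd_mse(tr3, obs), "do not match")
  expect_equal(
    psd_mse(
      list(times = 0, omegas = rbind(c(1, 0))),
      list(times = 0, proportions = rbind(c(0, 1)))
    ),
    1
  )
})

test_that("lagged size-division correlation finds the imposed phase", {
  ts <- 0:99
  size <- sin(2 * pi * ts / 24)
  div_t <- 6:99
  division <- sin(2 * pi * (div_t - 6) / 24)
  expect_equal(
    lagged_size_division_correlation(ts, size, div_t, division, lag = 6), 1,
    tolerance = 1e-10
  )
  expect_equal(
    lagged_size_division_correlation(ts, size, div_t, division, lag = 18), -1,
    tolerance = 1e-10
  )
  # independent noise: near-zero correlation
  set.seed(5)
  n <- 1e4
  expect_lt(
    abs(lagged_size_division_correlation(
      seq_len(n + 10), rnorm(n + 10), seq_len(n), rnorm(n),
      lag = 0
    )),
    0.05
  )
  expect_error(
    lagged_size_division_correlation(1:3, 1:3, 1:3, 1:3, lag = 2),
    "fewer than 3"
  )
})
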
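test_that("diel light is a half-sine with the stated peak and integral", {
  lt <- diel_par(14, 600, dt = 1 / 3, T_end = 46)
  # midnight is dark, mid-photoperiod hits the peak exactly
  expect_equal(light_at(lt, 0), 0)
  expect_equal(light_at(lt, 12), 600)
  expect_equal(light_at(lt, 36), 600)
  # one-day integral of a half-sine: peak * 2 * photoperiod / pi
  day <- lt$values[lt$times < 24]
  expect_equal(sum(day) * (1 / 3), 600 * 2 * 14 / pi, tolerance = 0.01 * 600 * 2 * 14 / pi)
  expect_error(diel_par(0, 600), "photoperiod")
})

test_that("generated counts are reproducible multinomials with the right totals", {
  sc <- quick_scenario(seed = 31)
  d1 <- generate_dataset(sc)
  expect_equal(unname(rowSums(d1$obs$counts)), rep(2e4, 13))
  d2 <- generate_dataset(sc)
  expect_identical(d1$obs$counts, d2$obs$counts)
  sc3 <- quick_scenario(seed = 32)
  d3 <- generate_dataset(sc3)
  expect_false(identical(d1$obs$counts, d3$obs$counts))
  # byte-identical file output under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_size_distribution(d1$obs, p1)
  write_size_distribution(d2$obs, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
})

test_that("with huge concentration the counts concentrate on the mean field", {
  g <- small_grid()
  sc <- mpm_scenario("bmb",
    grid = g, T_end = 8, obs_spacing = 4,
    N_per_time = 1e6, sigma = 1e8, seed = 12, dt = 1 / 2,
    theta = default_theta(model_spec("bmb", dt = 1 / 2), g, sigma = 1e8)
  )
  dat <- generate_dataset(sc)
  for (k in seq_along(dat$obs$times)) {
    p_hat <- dat$obs$proportions[k, ]
    p <- dat$trajectory$omegas[k, ]
    se <- sqrt(pmax(p * (1 - p) / 1e6, 1e-12))
    expect_true(all(abs(p_hat - p) <= 3 * se + 1e-5))
  }
})

test_that("count overdispersion follows the Dirichlet factor (N+sigma)/(1+sigma)", {
  g <- size_grid(16, 1 / 2, 5)
  spec <- model_spec("bmb", dt = 1)
  omega <- c(0.1, 0.25, 0.3, 0.25, 0.1)
  N <- 500
  sig <- 5
  set.seed(44)
  reps <- 400
  counts <- t(vapply(seq_len(reps), function(r) {
    eta <- rgamma(5, shape = sig * omega)
    eta <- eta / sum(eta)
    drop(rmultinom(1, N, eta))
  }, numeric(5)))
  v_obs <- apply(counts, 2, var)
  v_mult <- N * omega * (1 - omega)
  factor_expected <- (N + sig) / (1 + sig)
  ratio <- mean(v_obs / v_mult)
  expect_gt(ratio, 0.75 * factor_expected)
  expect_lt(ratio, 1.25 * factor_expected)
})

test_that("bulk measurements close the carbon balance", {
  # zero-rate model: constant abundance and size, zero fluxes
  g <- small_grid()
  spec <- model_spec("bmb", dt = 1 / 2)
  th <- default_theta(spec, g)
  th$delta_max <- 0
  th$gamma_max <- 0
  th$rho_max <- 0
  sc <- mpm_scenario(spec, grid = g, theta = th, T_end = 8, obs_spacing = 2)
  dat <- generate_dataset(sc)
  bulk <- generate_bulk(sc, dat$trajectory)
  expect_equal(diff(bulk$abundance), rep(0, 4), tolerance = 1e-9)
  expect_equal(diff(bulk$mean_size), rep(0, 4), tolerance = 1e-9)
  expect_equal(bulk$fixation, rep(0, 5))
  expect_equal(empirical_carbon_loss(bulk)$loss, rep(0, 4), tolerance = 1e-12)

  # division- and loss-free model: s_{t+1} - s_t = dt * f_t exactly
  th2 <- default_theta(spec, g)
  th2$delta_max <- 0
  th2$rho_max <- 0
  sc2 <- mpm_scenario(spec, grid = g, theta = th2, T_end = 8, obs_spacing = 2)
  dat2 <- generate_dataset(sc2)
  bulk2 <- generate_bulk(sc2, dat2$trajectory)
  i <- 1:4
  expect_equal(bulk2$mean_size[i + 1] - bulk2$mean_size[i],
    2 * bulk2$fixation[i],
    tolerance = 1e-10
  )

  # full default model: the balance inversion recovers the generating loss
  sc3 <- mpm_scenario("bmb", grid = size_grid(), seed = 3)
  dat3 <- generate_dataset(sc3)
  bulk3 <- generate_bulk(sc3, dat3$trajectory)
  l_hat <- empirical_carbon_loss(bulk3)$loss
  expect_equal(l_hat, attr(bulk3, "generating_loss"), tolerance = 1e-10)
})
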
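test_that("time modulation is a convex, periodic spline of its control points", {
  # constant control polygon gives a constant spline
  expect_equal(time_modulation(rep(0.5, 6), seq(0, 30, by = 0.7)),
    rep(0.5, length(seq(0, 30, by = 0.7))),
    tolerance = 1e-12
  )
  # 24-h periodicity
  set.seed(11)
  tau <- runif(6)
  expect_equal(time_modulation(tau, 3.7), time_modulation(tau, 27.7),
    tolerance = 1e-12
  )
  ts <- seq(0, 24, by = 0.1)
  q <- time_modulation(tau, ts)
  expect_true(all(q >= min(tau) - 1e-12 & q <= max(tau) + 1e-12))
  expect_error(time_modulation(c(1.2, rep(0.5, 5)), 1), "\\[0, 1\\]")
  expect_error(time_modulation(rep(0.5, 5), 1), "6 values")
})

test_that("spline evaluation matches an independent de Boor basis", {
  skip_if_not_installed("splines")
  ts <- seq(0, 23.9, by = 0.37)
  # periodic cardinal cubic B-splines on knots 4*Z, wrapped mod 6 control pts
  knots <- 4 * (-3:9)
  D <- splines::splineDesign(knots, ts, ord = 4)
  for (tau in list(c(1, 0, 0, 0, 0, 0), runif(6))) {
    ref <- drop(D %*% tau[((seq_len(ncol(D)) - 4) %% 6) + 1])
    expect_equal(time_modulation(tau, ts), ref, tolerance = 1e-10)
  }
})

test_that("division fractions follow the cumulative-increment form", {
  g <- ref_grid()
  # zero maximum rate kills division everywhere
  th <- list(delta_max = 0, delta_incr = rep(1 / 19, 19))
  expect_equal(division_fractions(th, g, 5, 1 / 3), rep(0, 27))
  # classes below j never divide
  set.seed(2)
  incr <- rgamma(19, 1)
  incr <- incr / sum(incr)
  d <- division_fractions(list(delta_max = 30, delta_incr = incr), g, 5, 1 / 3)
  expect_equal(d[1:8], rep(0, 8))
  # full cumulative sum at the top class: (dt/24) * delta_max
  expect_equal(d[27], (1 / 3) / 24 * 30, tolerance = 1e-12)
  d36 <- division_fractions(list(delta_max = 36, delta_incr = incr), g, 0, 1 / 3)
  expect_equal(d36[27], 0.5, tolerance = 1e-12)
  # nondecreasing over the dividing classes, for any increment simplex
  for (rep in 1:20) {
    incr <- rgamma(19, 0.5)
    incr <- incr / sum(incr)
    d <- division_fractions(list(delta_max = runif(1, 0, 72), delta_incr = incr),
      g, runif(1, 0, 48), 1 / 3
    )
    expect_true(all(diff(d[9:27]) >= -1e-15))
    expect_true(all(d >= 0 & d <= 1))
  }
  expect_error(
    division_fractions(list(delta_max = 1, delta_incr = rep(0.5, 2)), g, 0, 1 / 3),
    "length"
  )
})

test_that("growth fractions saturate with light and vanish in the dark", {
  g <- ref_grid()
  th <- list(gamma_max = 2, e_k = 300)
  expect_equal(growth_fractions(th, g, 0, 1 / 3), rep(0, 27))
  gr <- growth_fractions(th, g, 1e9 * 300, 1 / 3)
  # top class cannot grow at any light
  expect_identical(gr[27], 0)
  # saturated per-step fraction: dt / (24 (2^dv - 1)) * gamma_max
  expect_equal(gr[1], (1 / 3) / (24 * (2^(1 / 8) - 1)) * 2, tolerance = 1e-6)
  expect_equal(gr[1], 0.30691, tolerance = 1e-4)
  # light-saturated limit bounds growth at every finite PAR
  gstar <- light_saturated_growth(th, g, 1 / 3)
  for (E in c(1, 50, 700)) {
    expect_true(all(growth_fractions(th, g, E, 1 / 3) <= gstar + 1e-15))
  }
  expect_equal(growth_fractions(th, g, 1e9 * 300, 1 / 3), gstar, tolerance = 1e-6)
  # e_k = 0 is the saturated limit: full at any light, zero in the dark
  th0 <- list(gamma_max = 2, e_k = 0)
  expect_equal(growth_fractions(th0, g, 10, 1 / 3), gstar, tolerance = 1e-12)
  expect_equal(growth_fractions(th0, g, 0, 1 / 3), rep(0, 27))
  expect_equal(light_saturated_growth(list(gamma_max = 0, e_k = 1), g, 1 / 3), rep(0, 27))
})

test_that("size scaling of fixation is anchored at 1", {
  g <- ref_grid()
  expect_equal(size_scaling_fixation(list(), g, "basic"), rep(1, 27))
  s0 <- size_scaling_fixation(list(beta_gamma = 0), g, "power")
  expect_equal(s0, rep(1, 27))
  s1 <- size_scaling_fixation(list(beta_gamma = 1), g, "power")
  expect_equal(s1[27], 1)
  expect_equal(s1[1], g$midpoints[1] / g$midpoints[27], tolerance = 1e-14)
  sn <- size_scaling_fixation(list(beta_gamma = -0.5), g, "power")
  expect_equal(sn[1], 1)
  expect_true(all(s1 > 0 & s1 <= 1) && all(sn > 0 & sn <= 1))
  sf <- size_scaling_fixation(list(gamma_max = seq(0.2, 2, length.out = 26)), g, "free")
  expect_equal(max(sf), 1)
  expect_length(sf, 27)
})

test_that("loss fractions spare the smallest class", {
  g <- ref_grid()
  expect_equal(loss_fractions(list(), g, 1 / 3, "none"), rep(0, 27))
  r <- loss_fractions(list(rho_max = 1), g, 1 / 3, "basic")
  expect_identical(r[1], 0)
  expect_equal(r[2:27], rep((1 / 3) / (24 * (2^(1 / 8) - 1)), 26), tolerance = 1e-12)
  expect_equal(r[2], 0.15346, tolerance = 1e-4)
  expect_error(
    loss_fractions(list(rho_max = rep(1, 5)), g, 1 / 3, "free"),
    "length"
  )
})

test_that("every fraction stays in [0,1] across randomized valid parameters", {
  g <- ref_grid()
  set.seed(99)
  for (nm in all_model_names()) {
    spec <- model_spec(nm)
    for (rep in 1:5) {
      th <- random_theta(spec, g)
      d <- division_fractions(th, g, runif(1, 0, 48), spec$dt,
        timedep = spec$division == "timedep"
      )
      gr <- growth_fractions(th, g, runif(1, 0, 3000), spec$dt, mode = spec$fixation)
      rh <- loss_fractions(th, g, spec$dt, mode = spec$loss)
      expect_true(all(c(d, gr, rh) >= 0 & c(d, gr, rh) <= 1))
    }
  }
})
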
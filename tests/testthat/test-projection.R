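test_that("zero rates give the identity step matrix", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  th <- random_theta(spec, g)
  th$delta_max <- 0
  th$gamma_max <- 0
  th$rho_max <- 0
  A <- step_matrix(th, spec, g, 500, 0)
  expect_equal(unclass(A), diag(27), ignore_attr = TRUE)
})

test_that("hand-enumerated toy column: division halves into class i - j + 1", {
  g <- toy_grid3() # m = 3, j = 3: halving shifts 2 classes down
  spec <- model_spec("bmb", dt = 1)
  d <- 0.3
  th <- mpm_theta(spec, g,
    delta_max = 24 * d, delta_incr = 1, gamma_max = 0, e_k = 300,
    rho_max = 0, omega0 = c(0.2, 0.3, 0.5), sigma = 10
  )
  A <- unclass(step_matrix(th, spec, g, 0, 0))
  expect_equal(A[1, 3], 2 * d)
  expect_equal(A[3, 3], 1 - d)
  expect_equal(A[, 1], c(1, 0, 0))
  expect_equal(A[, 2], c(0, 1, 0))
  expect_equal(A[2, 3], 0)
})

test_that("column sums are 1 for non-dividing and 1 + delta for dividing classes", {
  g <- ref_grid()
  set.seed(31)
  for (nm in c("bmx", "bmb", "pmb", "fmf", "ftf", "ptb")) {
    spec <- model_spec(nm)
    for (rep in 1:8) {
      th <- random_theta(spec, g)
      t_s <- runif(1, 0, 46)
      A <- unclass(step_matrix(th, spec, g, runif(1, 0, 2000), t_s))
      d <- division_fractions(th, g, t_s, spec$dt,
        timedep = spec$division == "timedep"
      )
      expect_equal(colSums(A), 1 + d, tolerance = 1e-12)
      expect_true(all(A >= 0))
    }
  }
})

test_that("mass moves only one class up, one down, or j-1 down per step", {
  g <- ref_grid()
  spec <- model_spec("ftf")
  set.seed(5)
  th <- random_theta(spec, g)
  A <- unclass(step_matrix(th, spec, g, 800, 21))
  m <- g$m
  allowed <- matrix(FALSE, m, m)
  diag(allowed) <- TRUE
  allowed[cbind(2:m, 1:(m - 1))] <- TRUE # growth
  allowed[cbind(1:(m - 1), 2:m)] <- TRUE # loss
  allowed[cbind((g$j:m) - g$j + 1L, g$j:m)] <- TRUE # division
  expect_true(all(A[!allowed] == 0))
})

test_that("block composition equals ordered stepwise application", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(7)
  th <- random_theta(spec, g)
  A0 <- step_matrix(th, spec, g, 100, 0)
  A1 <- step_matrix(th, spec, g, 900, 1 / 3)
  B <- compose_block(list(A0, A1))
  expect_identical(attr(B, "r"), 2L)
  x <- rgamma(27, 1)
  expect_equal(drop(unclass(B) %*% x),
    drop(unclass(A1) %*% (unclass(A0) %*% x)),
    tolerance = 1e-12
  )
  expect_equal(unclass(compose_block(list(A0))), unclass(A0), ignore_attr = TRUE)
  expect_error(compose_block(list()), "empty")
})

test_that("projection renormalizes and reports the division growth factor", {
  g <- toy_grid3()
  spec <- model_spec("bmb", dt = 1)
  th <- mpm_theta(spec, g,
    delta_max = 12, delta_incr = 1, gamma_max = 0, e_k = 300,
    rho_max = 0, omega0 = c(0, 0, 1), sigma = 10
  ) # per-step delta_3 = 0.5
  A <- step_matrix(th, spec, g, 0, 0)
  out <- project_step(A, c(0, 0, 1))
  expect_equal(as.numeric(out), c(2 / 3, 0, 1 / 3))
  expect_equal(attr(out, "growth_factor"), 1.5)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("without division the projection conserves total mass exactly", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(13)
  th <- random_theta(spec, g)
  th$delta_max <- 0
  A <- step_matrix(th, spec, g, 650, 12)
  om <- rgamma(27, 1)
  om <- om / sum(om)
  out <- project_step(A, om)
  expect_equal(attr(out, "growth_factor"), 1, tolerance = 1e-12)
  # 1'Ax = 1'x + sum_{i>=j} delta_i x_i for any nonnegative x
  th2 <- random_theta(spec, g)
  A2 <- unclass(step_matrix(th2, spec, g, 650, 12))
  d2 <- division_fractions(th2, g, 12, spec$dt)
  x <- rgamma(27, 1)
  expect_equal(sum(A2 %*% x), sum(x) + sum(d2 * x), tolerance = 1e-12)
})

test_that("trajectories: zero rates stay put; totals track division only", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  th <- random_theta(spec, g)
  th$delta_max <- 0
  th$gamma_max <- 0
  th$rho_max <- 0
  light <- diel_par(14, 600, spec$dt, 24)
  tr <- simulate_trajectory(th, spec, g, light, seq(0, 24, 4))
  expect_equal(tr$omegas, matrix(th$omega0, 7, 27, byrow = TRUE), tolerance = 1e-14)
  expect_equal(tr$totals, rep(1, 7), tolerance = 1e-14)
  # division-free model: totals identically 1 even with growth and loss
  th2 <- random_theta(spec, g)
  th2$delta_max <- 0
  tr2 <- simulate_trajectory(th2, spec, g, light, seq(0, 24, 4))
  expect_equal(tr2$totals, rep(1, 7), tolerance = 1e-10)
  expect_error(
    simulate_trajectory(th2, spec, g, light, c(0, 0.5)),
    "multiples of dt"
  )
})

test_that("matrix projection matches the agent-based Monte Carlo process", {
  g <- ref_grid()
  spec <- model_spec("bmb")
  set.seed(77)
  th <- random_theta(spec, g)
  light <- diel_par(14, 600, spec$dt, 24)
  N0 <- 2e5
  x0 <- drop(rmultinom(1, N0, th$omega0))
  n_steps <- 6L # 2 h
  mc <- simulate_agents(th, spec, g, light, n_steps, x0)
  ex <- expected_counts(th, spec, g, light, n_steps, x0)
  tot <- sum(ex)
  se <- sqrt(pmax(tot * (ex / tot) * (1 - ex / tot), 1))
  expect_true(all(abs(mc - ex) <= 4 * se + 2))
})

test_that("trajectories export as tidy data frames", {
  g <- small_grid()
  spec <- model_spec("bmb", dt = 1 / 2)
  th <- default_theta(spec, g)
  light <- diel_par(14, 600, spec$dt, 12)
  tr <- simulate_trajectory(th, spec, g, light, seq(0, 12, 4))
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "class_index", "proportion", "total"))
  expect_equal(nrow(df), 4 * g$m)
  expect_equal(sum(df$proportion), 4, tolerance = 1e-10)
})
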
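# Shared fixtures: small grids, random interior parameter draws, a fast
# synthetic scenario, and an agent-based Monte Carlo simulator used as the
# independent oracle for the matrix projection.

ref_grid <- function() size_grid(16, 1 / 8, 27)

toy_grid3 <- function() size_grid(1, 1 / 2, 3)

small_grid <- function() size_grid(16, 1 / 4, 13)

# Random parameter vector strictly inside all bounds for any model variant.
random_theta <- function(spec, grid, sigma = 200) {
  m <- grid$m
  j <- grid$j
  md <- m - j + 1L
  ub_div <- division_rate_bound(spec$dt)
  ub_gr <- growth_rate_bound(grid$delta_v, spec$dt)
  rsimplex <- function(n) {
    x <- stats::rgamma(n, 1)
    x / sum(x)
  }
  gmax <- if (spec$fixation == "free") {
    runif(m - 1L, 0.05, 0.9) * ub_gr
  } else {
    runif(1, 0.05, 0.9) * ub_gr
  }
  rho <- switch(spec$loss,
    none = NULL,
    basic = runif(1, 0.02, 0.5) * ub_gr,
    free = runif(m - 1L, 0.02, 0.5) * ub_gr
  )
  mpm_theta(
    spec, grid,
    delta_max = runif(1, 0.05, 0.9) * ub_div,
    delta_incr = rsimplex(md),
    tau_control = if (spec$division == "timedep") runif(6, 0.05, 0.95) else NULL,
    gamma_max = gmax,
    e_k = runif(1, 50, 2000),
    beta_gamma = if (spec$fixation == "power") runif(1, -2, 2) else NULL,
    mu_gamma = if (spec$fixation == "free") runif(1, 0.1, 0.9) * ub_gr else NULL,
    sigma_gamma = if (spec$fixation == "free") runif(1, 0.2, 2) else NULL,
    rho_max = rho,
    mu_rho = if (spec$loss == "free") runif(1, 0.1, 0.9) * ub_gr else NULL,
    sigma_rho = if (spec$loss == "free") runif(1, 0.2, 2) else NULL,
    omega0 = rsimplex(m),
    sigma = sigma
  )
}

# Small, fast scenario for fit-based tests: 13 classes, dt = 1/2 h, one day.
quick_scenario <- function(model = "bmb", seed = 1, N = 2e4, sigma = 300) {
  grid <- small_grid()
  spec <- model_spec(model, dt = 1 / 2)
  th <- default_theta(spec, grid, sigma = sigma)
  mpm_scenario(spec,
    grid = grid, theta = th, T_end = 24, obs_spacing = 2,
    N_per_time = N, sigma = sigma, seed = seed
  )
}

# Agent-based Monte Carlo oracle: N0 cells per class followed individually
# (in aggregate, via per-class multinomial draws over the four fates) through
# the divide/shrink/grow/stay process. Returns final class counts.
simulate_agents <- function(theta, spec, grid, light, n_steps, x0) {
  m <- grid$m
  j <- grid$j
  dt <- spec$dt
  x <- x0
  for (s in seq_len(n_steps)) {
    t_s <- (s - 1L) * dt
    E_s <- light_at(light, t_s)
    delta <- division_fractions(theta, grid, t_s, dt,
      timedep = spec$division == "timedep"
    )
    gamma <- growth_fractions(theta, grid, E_s, dt, mode = spec$fixation)
    rho <- loss_fractions(theta, grid, dt, mode = spec$loss)
    xn <- numeric(m)
    for (i in seq_len(m)) {
      if (x[i] == 0) next
      p_div <- delta[i]
      p_shr <- (1 - delta[i]) * rho[i]
      p_gro <- (1 - delta[i]) * (1 - rho[i]) * gamma[i]
      p_sty <- 1 - p_div - p_shr - p_gro
      fates <- drop(stats::rmultinom(1, x[i], c(p_div, p_shr, p_gro, p_sty)))
      if (fates[1] > 0) xn[i - j + 1L] <- xn[i - j + 1L] + 2L * fates[1]
      if (fates[2] > 0) xn[i - 1L] <- xn[i - 1L] + fates[2]
      if (fates[3] > 0) xn[i + 1L] <- xn[i + 1L] + fates[3]
      xn[i] <- xn[i] + fates[4]
    }
    x <- xn
  }
  x
}

# Expected class counts from the matrix projection for the same setup.
expected_counts <- function(theta, spec, grid, light, n_steps, x0) {
  m <- grid$m
  x <- x0
  for (s in seq_len(n_steps)) {
    t_s <- (s - 1L) * spec$dt
    A <- step_matrix(theta, spec, grid, light_at(light, t_s), t_s)
    x <- drop(unclass(A) %*% x)
  }
  x
}
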
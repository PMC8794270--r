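# Synthetic diel experiments with the statistical structure the inference
# assumes: a half-sine diel light cycle, a deterministic mean trajectory from
# a generating parameter vector, and Dirichlet-multinomial count noise. The
# default scenario mirrors the reference laboratory design: 27 logarithmic
# size classes from 16 fg C, dt = 1/3 h, a 46-h record observed every 2 h,
# and generating rates in the plausible range for an exponentially growing
# Prochlorococcus culture (daily division near 0.6 d^-1).

#' Diel light curve on the dt lattice
#'
#' Half-sine of the stated peak over each photoperiod window, zero in
#' darkness, repeated daily. Midnight (t = 0) is dark by convention; the
#' photoperiod is centered on t = 12 h.
#'
#' @param photoperiod light hours per 24 (0 < photoperiod <= 24).
#' @param peak peak PAR (umol photons m^-2 s^-1).
#' @param dt lattice spacing (hours).
#' @param T_end last lattice time (hours).
#' @return A \code{\link{light_series}}.
#' @export
diel_par <- function(photoperiod = 14, peak = 600, dt = 1 / 3, T_end = 46) {
  if (photoperiod <= 0 || photoperiod > 24) {
    stop("photoperiod must be in (0, 24] hours", call. = FALSE)
  }
  times <- seq(0, T_end, by = dt)
  tod <- times %% 24
  dawn <- (24 - photoperiod) / 2
  inside <- tod > dawn & tod < dawn + photoperiod
  values <- numeric(length(times))
  values[inside] <- peak * sin(pi * (tod[inside] - dawn) / photoperiod)
  light_series(times, values)
}

# Deterministic sub-seeds for the independent random streams of a scenario.
split_seed <- function(master, idx) {
  as.integer((as.double(master) * 48271 + idx * 104729) %% 2147483647)
}

#' Generating parameter vector for the default diel scenario
#'
#' A biologically plausible parameter vector for any model variant on the
#' reference grid: division ramping up over the largest ~8 size classes at a
#' level producing a daily division rate near 0.6 d^-1 for the monotone
#' variants, carbon fixation sized for roughly 60-65 fg C cell^-1 d^-1 at a
#' saturation parameter of 300 umol photons m^-2 s^-1, modest carbon loss
#' (~18 fg C cell^-1 d^-1), and an initial size distribution centered near
#' 45 fg C. Time-dependent variants gate division towards the hours after
#' dusk (yielding a slower culture); free variants get smooth size
#' dependence.
#'
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param sigma Dirichlet concentration of the observation model.
#' @return An \code{\link{mpm_theta}}.
#' @export
default_theta <- function(spec, grid, sigma = 200) {
  m <- grid$m
  j <- grid$j
  vb <- grid$midpoints
  # division ramps up over the largest ~8 classes
  md <- m - j + 1L
  ramp <- stats::plogis((seq_len(md) - (md - 5)) / 1.2)
  incr <- diff(c(0, ramp)) / max(ramp)
  incr <- incr / sum(incr)
  tau <- if (spec$division == "timedep") {
    # basis l peaks near t = 4 (l + 2) h mod 24: gate division into the
    # hours around and after dusk (~19-28 h)
    c(0.05, 0.05, 0.20, 0.95, 0.70, 0.10)
  } else {
    NULL
  }
  gb <- growth_rate_bound(grid$delta_v, spec$dt)
  gmax_scalar <- min(2.8, 0.95 * gb)
  gamma_max <- switch(spec$fixation,
    basic = gmax_scalar,
    power = gmax_scalar,
    free = gmax_scalar * (vb[-m] / vb[1])^(-0.12)
  )
  beta_gamma <- if (spec$fixation == "power") -0.12 else NULL
  rho_scalar <- 0.35
  rho_max <- switch(spec$loss,
    none = NULL,
    basic = rho_scalar,
    free = pmin(rho_scalar * (vb[-1L] / vb[1])^(0.25), 0.95 * gb)
  )
  omega0 <- stats::dnorm(log(vb), log(45), 0.35)
  omega0 <- omega0 / sum(omega0)
  mpm_theta(
    spec, grid,
    delta_max = if (spec$division == "timedep") 36 else 12,
    delta_incr = incr, tau_control = tau,
    gamma_max = gamma_max, e_k = 300, beta_gamma = beta_gamma,
    mu_gamma = if (spec$fixation == "free") gmax_scalar else NULL,
    sigma_gamma = if (spec$fixation == "free") 0.5 else NULL,
    rho_max = rho_max,
    mu_rho = if (spec$loss == "free") rho_scalar else NULL,
    sigma_rho = if (spec$loss == "free") 0.3 else NULL,
    omega0 = omega0, sigma = sigma
  )
}

#' Scenario configuration for a synthetic diel experiment
#'
#' @param model model name or \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param theta generating parameters; defaults to
#'   \code{\link{default_theta}}.
#' @param T_end record length (hours).
#' @param obs_spacing observation spacing (hours, multiple of dt).
#' @param N_per_time cells counted per observation time (scalar or length-K).
#' @param sigma Dirichlet concentration of the count noise.
#' @param photoperiod light hours per 24.
#' @param peak_par peak PAR (umol photons m^-2 s^-1).
#' @param seed master seed; split deterministically into substreams.
#' @param dt projection step (hours) when \code{model} is a name.
#' @return list of class \code{"mpm_scenario"}.
#' @export
mpm_scenario <- function(model = "bmb", grid = size_grid(), theta = NULL,
                         T_end = 46, obs_spacing = 2, N_per_time = 1e5,
                         sigma = 200, photoperiod = 14, peak_par = 600,
                         seed = 1L, dt = 1 / 3) {
  spec <- if (inherits(model, "mpm_spec")) model else model_spec(model, dt = dt)
  if (abs(obs_spacing / spec$dt - round(obs_spacing / spec$dt)) > 1e-8) {
    stop("observation spacing must be a multiple of dt", call. = FALSE)
  }
  if (is.null(theta)) theta <- default_theta(spec, grid, sigma = sigma)
  theta$sigma <- sigma
  validate_theta(theta, spec, grid)
  structure(
    list(
      spec = spec, grid = grid, theta = theta, T_end = T_end,
      obs_spacing = obs_spacing, N_per_time = N_per_time, sigma = sigma,
      photoperiod = photoperiod, peak_par = peak_par, seed = seed
    ),
    class = "mpm_scenario"
  )
}

#' Generate a synthetic dataset from a scenario
#'
#' Simulates the deterministic mean trajectory under the scenario's diel
#' light, then draws per-time compositions
#' \eqn{\eta_k \sim Dirichlet(\sigma \omega_k)} and counts
#' \eqn{n_k \sim Multinomial(N_k, \eta_k)}. Fixed seeds give identical
#' output.
#'
#' @param scenario an \code{\link{mpm_scenario}}.
#' @return list with \code{obs} (an \code{\link{obs_set}}), \code{light}
#'   (a \code{\link{light_series}}), \code{trajectory} (the generating
#'   \code{"mpm_trajectory"}), \code{theta} (generating parameters) and
#'   \code{rates} (the generating daily rates from
#'   \code{\link{derived_rates}}).
#' @export
generate_dataset <- function(scenario) {
  sc <- scenario
  light <- diel_par(sc$photoperiod, sc$peak_par, sc$spec$dt, sc$T_end)
  obs_times <- seq(0, sc$T_end, by = sc$obs_spacing)
  traj <- simulate_trajectory(sc$theta, sc$spec, sc$grid, light, obs_times,
    keep_steps = TRUE
  )
  K <- length(obs_times)
  N <- rep(sc$N_per_time, length.out = K)
  set.seed(split_seed(sc$seed, 3L))
  counts <- t(vapply(seq_len(K), function(k) {
    eta <- stats::rgamma(sc$grid$m, shape = sc$sigma * traj$omegas[k, ])
    eta <- eta / sum(eta)
    drop(stats::rmultinom(1, N[k], eta))
  }, numeric(sc$grid$m)))
  list(
    obs = obs_set(obs_times, counts),
    light = light,
    trajectory = traj,
    theta = sc$theta,
    rates = derived_rates(sc$theta, sc$spec, sc$grid, light, obs_times)
  )
}

#' Generate bulk measurements consistent with a scenario trajectory
#'
#' Produces the abundance / mean-size / fixation table that the empirical
#' carbon-loss inversion consumes: abundance proportional to the
#' unnormalized totals, mean size \eqn{s_t = \sum_i \omega_t^{(i)} \bar
#' v_i}, and per-cell fixation rates in which each dt-step increment is
#' divided by the growth factors of the remaining steps of its measurement
#' interval — i.e. fluxes are expressed per cell counted at the end of the
#' interval, which is the convention the carbon-balance identity itself
#' uses (its flux term is not corrected by the abundance ratio).
#'
#' @param scenario an \code{\link{mpm_scenario}}.
#' @param trajectory the scenario's kept-steps trajectory (from
#'   \code{\link{generate_dataset}}).
#' @param base_abundance abundance at t = 0 (cells per volume).
#' @return A \code{\link{bulk_measurements}}; attribute
#'   \code{"generating_loss"} holds the matching per-interval loss series
#'   (fg C cell^-1 h^-1) under the same convention.
#' @export
generate_bulk <- function(scenario, trajectory, base_abundance = 1e5) {
  traj <- trajectory
  grid <- scenario$grid
  if (is.null(traj$step_omegas)) {
    stop("trajectory must be simulated with keep_steps = TRUE", call. = FALSE)
  }
  fl <- step_carbon_fluxes(traj, grid)
  dtm <- scenario$obs_spacing
  r <- round(dtm / traj$dt) # steps per measurement interval
  K <- length(traj$times)
  fix <- numeric(K)
  loss <- numeric(K)
  for (k in seq_len(K - 1L)) {
    sidx <- (k - 1L) * r + seq_len(r)
    g <- traj$step_growth[sidx]
    # divide each step's per-cell increment by all growth factors from its
    # own step to the end of the interval (division dilutes per-cell carbon)
    kappa <- rev(cumprod(rev(g)))
    fix[k] <- sum(fl$fixation[sidx] / kappa) / dtm
    loss[k] <- sum(fl$loss[sidx] / kappa) / dtm
  }
  s_t <- drop(traj$omegas %*% grid$midpoints)
  bulk <- bulk_measurements(
    times = traj$times,
    abundance = base_abundance * traj$totals,
    mean_size = s_t,
    fixation = fix
  )
  attr(bulk, "generating_loss") <- loss[seq_len(K - 1L)]
  bulk
}
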
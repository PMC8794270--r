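# Rate estimators: the quantities a fitted model reports. Division rates are
# read off the renormalization factors (growth, loss and stasis conserve cell
# number, so the normalizer isolates division); carbon fluxes convert
# per-step class-transition probabilities into carbon using midpoint
# differences (a cell moving up one class gains vbar_{i+1} - vbar_i fg C).

#' Observed daily division rate from cell totals
#'
#' The exponential growth constant \eqn{\mu = (24/T) \log(N_K / N_0)} in
#' d^-1, valid when cell mortality is negligible.
#'
#' @param N0,NK positive cell totals at the first and last observation.
#' @param T_h elapsed time in hours.
#' @return division rate (d^-1).
#' @examples
#' observed_division_rate(1e5, 2e5, 24) # log(2)
#' @export
observed_division_rate <- function(N0, NK, T_h) {
  if (N0 <= 0 || NK <= 0) stop("cell totals must be positive", call. = FALSE)
  if (T_h <= 0) stop("elapsed time must be positive", call. = FALSE)
  (24 / T_h) * log(NK / N0)
}

#' Model-implied daily division rate
#'
#' Simulates the mean trajectory and applies the division-rate estimator to
#' the unnormalized relative totals:
#' \eqn{\hat\mu = (24/T)\log(\mathbf{1}^T[\prod_k B_k]\omega_0)}, equal to
#' \eqn{(24/T)} times the summed log step growth factors.
#'
#' @inheritParams simulate_trajectory
#' @param obs_times observation times (hours) spanning the record.
#' @return division rate (d^-1).
#' @export
model_daily_division_rate <- function(theta, spec, grid, light, obs_times) {
  traj <- simulate_trajectory(theta, spec, grid, light, obs_times)
  T_h <- max(obs_times) - min(obs_times)
  (24 / T_h) * sum(log(traj$step_growth))
}

#' Hourly division-rate series from a trajectory
#'
#' For each one-hour bin, 24 times the log of the product of that bin's step
#' growth factors, in d^-1, so that the mean over bins times \eqn{T/24}
#' telescopes back to the daily rate.
#'
#' @param traj an \code{"mpm_trajectory"} (carries per-step growth factors).
#' @return data frame with \code{hour} (bin start, hours) and \code{rate}
#'   (d^-1).
#' @export
hourly_division_series <- function(traj) {
  dt <- traj$dt
  per_h <- round(1 / dt)
  S <- length(traj$step_growth)
  if (S %% per_h != 0L) {
    stop("trajectory does not tile whole hours (bin boundaries off the dt lattice)",
      call. = FALSE
    )
  }
  bins <- rep(seq_len(S %/% per_h), each = per_h)
  rate <- 24 * tapply(log(traj$step_growth), bins, sum)
  data.frame(
    hour = traj$lattice_times[1] + (seq_len(S %/% per_h) - 1L),
    rate = as.numeric(rate)
  )
}

# Per-step carbon fluxes (fg C per current cell per step) from a kept-steps
# trajectory: expected increments using the actual one-process-per-step
# transition probabilities.
step_carbon_fluxes <- function(traj, grid, gamma_override = NULL) {
  m <- grid$m
  vb <- grid$midpoints
  dup <- c(vb[-1L] - vb[-m], 0) # carbon gained moving up from class i
  ddn <- c(0, vb[-1L] - vb[-m]) # carbon lost moving down from class i
  S <- length(traj$step_growth)
  fix <- numeric(S)
  loss <- numeric(S)
  for (s in seq_len(S)) {
    fr <- traj$step_fractions[[s]]
    gamma <- if (is.null(gamma_override)) fr$gamma else gamma_override
    w_up <- (1 - fr$delta) * (1 - fr$rho) * gamma
    w_dn <- (1 - fr$delta) * fr$rho
    om <- traj$step_omegas[, s]
    fix[s] <- sum(om * w_up * dup)
    loss[s] <- sum(om * w_dn * ddn)
  }
  list(fixation = fix, loss = loss)
}

#' Carbon fixation / loss flux series
#'
#' Per dt step, the expected per-cell carbon increment
#' \eqn{\sum_i \omega_i P(\mathrm{grow}_i) (\bar v_{i+1} - \bar v_i)} for
#' fixation and \eqn{\sum_i \omega_i P(\mathrm{shrink}_i)(\bar v_i - \bar
#' v_{i-1})} for loss, with the one-process-per-step transition
#' probabilities \eqn{P(\mathrm{grow}_i) = (1-\delta_i)(1-\rho_i)\gamma_i}
#' and \eqn{P(\mathrm{shrink}_i) = (1-\delta_i)\rho_i}. Hourly bins sum
#' steps; the daily total sums the record and divides by its length in days.
#'
#' @inheritParams model_daily_division_rate
#' @param which \code{"fixation"} or \code{"loss"}.
#' @return list with \code{hourly} (data frame \code{hour},
#'   \code{flux} in fg C cell^-1 h^-1), \code{daily}
#'   (fg C cell^-1 d^-1) and \code{per_step} (fg C cell^-1 per dt step).
#' @export
carbon_flux_series <- function(theta, spec, grid, light, obs_times,
                               which = c("fixation", "loss")) {
  which <- match.arg(which)
  traj <- simulate_trajectory(theta, spec, grid, light, obs_times,
    keep_steps = TRUE
  )
  flux <- step_carbon_fluxes(traj, grid)[[which]]
  bin_flux_series(flux, traj, obs_times)
}

bin_flux_series <- function(flux, traj, obs_times) {
  dt <- traj$dt
  per_h <- round(1 / dt)
  S <- length(flux)
  bins <- rep(seq_len(S %/% per_h), each = per_h)
  hourly <- as.numeric(tapply(flux, bins, sum))
  T_h <- max(obs_times) - min(obs_times)
  list(
    hourly = data.frame(
      hour = traj$lattice_times[1] + (seq_len(S %/% per_h) - 1L),
      flux = hourly
    ),
    daily = sum(flux) / (T_h / 24),
    per_step = flux
  )
}

#' Maximum photosynthetic rate P_max implied by a parameter vector
#'
#' Daily carbon fixation recomputed with the light-saturated growth
#' fractions \eqn{\gamma^\star_i} in place of \eqn{\gamma_i(t)} at every
#' step, along the actual (theta-implied) trajectory; in
#' fg C cell^-1 d^-1.
#'
#' @inheritParams model_daily_division_rate
#' @return P_max (fg C cell^-1 d^-1); always at least the daily fixation.
#' @export
pmax_estimate <- function(theta, spec, grid, light, obs_times) {
  traj <- simulate_trajectory(theta, spec, grid, light, obs_times,
    keep_steps = TRUE
  )
  gstar <- light_saturated_growth(theta, grid, spec$dt, mode = spec$fixation)
  flux <- step_carbon_fluxes(traj, grid, gamma_override = gstar)$fixation
  T_h <- max(obs_times) - min(obs_times)
  sum(flux) / (T_h / 24)
}

#' Mean squared error of the fitted size distribution
#'
#' Mean over observation times and size classes of the squared difference
#' between the model proportions and the observed proportions.
#'
#' @param traj an \code{"mpm_trajectory"} at the observation times.
#' @param obs an \code{\link{obs_set}} at the same times.
#' @return mean squared error (dimensionless).
#' @export
psd_mse <- function(traj, obs) {
  if (length(traj$times) != length(obs$times) ||
    max(abs(traj$times - obs$times)) > 1e-8) {
    stop("trajectory and observation times do not match", call. = FALSE)
  }
  mean((traj$omegas - obs$proportions)^2)
}

#' Lagged correlation between cell size and division rate
#'
#' Pearson correlation of the division series at time \eqn{t} with the size
#' series at time \eqn{t - lag}, over the overlapping support; used to
#' diagnose the delay between the cell-size peak and the division peak.
#' Works for the mean-size series or any percentile-size series.
#'
#' @param size_times,sizes times (hours) and values of the size series.
#' @param div_times,division times (hours) and values of the division series.
#' @param lag lag in hours (division at \code{t} vs size at \code{t - lag}).
#' @param tol time-matching tolerance (hours).
#' @return Pearson correlation coefficient.
#' @export
lagged_size_division_correlation <- function(size_times, sizes, div_times,
                                             division, lag, tol = 1e-6) {
  want <- div_times - lag
  idx <- vapply(want, function(t) {
    hit <- which(abs(size_times - t) <= tol)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  if (sum(ok) < 3L) {
    stop("fewer than 3 overlapping points after lagging", call. = FALSE)
  }
  stats::cor(division[ok], sizes[idx[ok]])
}

# All derived daily quantities for one parameter vector, sharing one
# trajectory simulation (used per posterior draw).
derived_rates <- function(theta, spec, grid, light, obs_times) {
  traj <- simulate_trajectory(theta, spec, grid, light, obs_times,
    keep_steps = TRUE
  )
  T_h <- max(obs_times) - min(obs_times)
  fl <- step_carbon_fluxes(traj, grid)
  gstar <- light_saturated_growth(theta, grid, spec$dt, mode = spec$fixation)
  pfl <- step_carbon_fluxes(traj, grid, gamma_override = gstar)$fixation
  # step growth factors are >= 1 in exact arithmetic; clamp rounding residue
  mu <- (24 / T_h) * sum(log(traj$step_growth))
  c(
    mu_daily = if (mu < 0 && mu > -1e-9) 0 else mu,
    daily_fixation = sum(fl$fixation) / (T_h / 24),
    daily_loss = sum(fl$loss) / (T_h / 24),
    p_max = sum(pfl) / (T_h / 24),
    e_k = unname(theta$e_k)
  )
}
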
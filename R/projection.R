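# Step projection matrices and trajectory propagation. A cell either divides
# (moving down j-1 classes, i.e. halving, and producing two daughters),
# shrinks one class, grows one class, or stays, in any one dt step; the
# conditional factorization is divide-first, then shrink, then grow. Columns
# index the source class, rows the destination class.

# Per-class transition weights for one step, given the per-step fractions.
# Using delta_i = 0 for i < j, rho_1 = 0 and gamma_m = 0, the general forms
#   division  2 delta_i
#   growth    (1 - delta_i)(1 - rho_i) gamma_i
#   loss      (1 - delta_i) rho_i
#   stasis    (1 - delta_i)(1 - gamma_i)(1 - rho_i)
# reproduce every boundary case of the piecewise definitions.
step_weights <- function(delta, gamma, rho) {
  list(
    division = 2 * delta,
    growth = (1 - delta) * (1 - rho) * gamma,
    loss = (1 - delta) * rho,
    stasis = (1 - delta) * (1 - gamma) * (1 - rho)
  )
}

# All per-step fractions for a model at one time.
step_fractions <- function(theta, spec, grid, E_t, t) {
  delta <- division_fractions(theta, grid, t, spec$dt,
    timedep = spec$division == "timedep"
  )
  gamma <- growth_fractions(theta, grid, E_t, spec$dt, mode = spec$fixation)
  rho <- loss_fractions(theta, grid, spec$dt, mode = spec$loss)
  bad <- c(delta, gamma, rho)
  if (anyNA(bad) || any(bad < 0) || any(bad > 1)) {
    stop("internal consistency failure: a transition fraction fell outside [0, 1]",
      call. = FALSE
    )
  }
  list(delta = delta, gamma = gamma, rho = rho)
}

#' Assemble one dt-step projection matrix
#'
#' Builds the m x m matrix whose column i distributes cells of size class i
#' over their possible fates in one dt step: division to class
#' \eqn{i - j + 1} (a halving, weight \eqn{2\delta_i(t)} for the two
#' daughters), growth to class \eqn{i + 1}, shrinkage to class \eqn{i - 1},
#' and stasis. Column sums are 1 for non-dividing classes and
#' \eqn{1 + \delta_i(t)} for dividing classes.
#'
#' @param theta an \code{\link{mpm_theta}}.
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param E_t PAR at the step start time.
#' @param t step start time (hours).
#' @return m x m numeric matrix of class \code{"step_matrix"} with
#'   attribute \code{t}.
#' @export
step_matrix <- function(theta, spec, grid, E_t, t) {
  m <- grid$m
  j <- grid$j
  fr <- step_fractions(theta, spec, grid, E_t, t)
  w <- step_weights(fr$delta, fr$gamma, fr$rho)
  if (any(unlist(w) < 0) || any(unlist(w) > 2)) {
    stop("internal consistency failure: step-matrix entry outside [0, 2]",
      call. = FALSE
    )
  }
  A <- matrix(0, m, m)
  A[cbind(seq_len(m), seq_len(m))] <- w$stasis
  if (m > 1L) {
    up <- seq_len(m - 1L)
    A[cbind(up + 1L, up)] <- w$growth[up]
    A[cbind(up, up + 1L)] <- w$loss[up + 1L]
  }
  div_src <- j:m
  A[cbind(div_src - j + 1L, div_src)] <-
    A[cbind(div_src - j + 1L, div_src)] + w$division[div_src]
  structure(A, class = c("step_matrix", "matrix", "array"), t = t)
}

#' Compose step matrices into a projection block
#'
#' The block projecting over one observation interval is the ordered product
#' of its step matrices, later steps applied on the left:
#' \eqn{B = A^{(r-1)} \cdots A^{(1)} A^{(0)}}.
#'
#' @param steps nonempty list of conforming step matrices, in time order.
#' @return m x m numeric matrix of class \code{"projection_block"} with
#'   attribute \code{r} (number of composed steps).
#' @export
compose_block <- function(steps) {
  if (length(steps) == 0L) {
    stop("cannot compose an empty sequence of step matrices", call. = FALSE)
  }
  B <- unclass(steps[[1L]])
  for (s in seq_along(steps)[-1L]) {
    B <- unclass(steps[[s]]) %*% B
  }
  structure(B, class = c("projection_block", "matrix", "array"), r = length(steps))
}

#' Project and renormalize the mean size distribution
#'
#' Applies a projection block to a simplex and renormalizes:
#' \eqn{\omega' = B\omega / \mathbf{1}^T B \omega}. The normalizer is the
#' interval's total growth factor; since growth, loss and stasis conserve
#' cell number, it isolates the relative increase in cell number caused by
#' division.
#'
#' @param B projection block (or any m x m nonnegative matrix).
#' @param omega length-m simplex.
#' @return the projected simplex, with attribute \code{"growth_factor"}
#'   holding \eqn{\mathbf{1}^T B \omega}.
#' @export
project_step <- function(B, omega) {
  u <- drop(unclass(B) %*% omega)
  g <- sum(u)
  if (!is.finite(g) || g <= 0) {
    stop("internal error: nonpositive normalizer in projection", call. = FALSE)
  }
  structure(u / g, growth_factor = g)
}

#' Simulate the deterministic mean trajectory of a model
#'
#' Propagates the mean relative size distribution from \code{theta$omega0}
#' across the dt lattice, renormalizing at each step, and records the
#' distribution at each observation time together with the running product of
#' step growth factors (the relative total cell number).
#'
#' @param theta an \code{\link{mpm_theta}}.
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param light a \code{\link{light_series}} covering the dt lattice up to the
#'   last observation time.
#' @param obs_times observation times (hours), each a multiple of dt,
#'   starting at the lattice origin.
#' @param keep_steps if \code{TRUE}, also return the per-step distributions
#'   and fractions (needed by the carbon-flux estimators).
#' @return An object of class \code{"mpm_trajectory"}: list with
#'   \code{times}, \code{omegas} (K x m matrix of simplexes), \code{totals}
#'   (relative cell number at observation times), \code{step_growth}
#'   (per-step growth factors), and optionally \code{step_omegas}
#'   (m x (S+1)), \code{step_fractions}.
#' @export
simulate_trajectory <- function(theta, spec, grid, light, obs_times,
                                keep_steps = FALSE) {
  dt <- spec$dt
  rel <- (obs_times - obs_times[1]) / dt
  if (any(abs(rel - round(rel)) > 1e-8) || obs_times[1] / dt - round(obs_times[1] / dt) > 1e-8) {
    stop("observation times must be multiples of dt", call. = FALSE)
  }
  obs_steps <- as.integer(round(rel))
  S <- max(obs_steps)
  lat_times <- seq(obs_times[1], by = dt, length.out = S + 1L)
  E <- light_at(light, lat_times)
  m <- grid$m
  omega <- theta$omega0
  K <- length(obs_times)
  omegas <- matrix(NA_real_, K, m)
  totals <- numeric(K)
  step_growth <- numeric(S)
  step_omegas <- if (keep_steps) matrix(NA_real_, m, S + 1L) else NULL
  frac_list <- if (keep_steps) vector("list", S) else NULL
  total <- 1
  k <- 1L
  if (obs_steps[1L] == 0L) {
    omegas[1L, ] <- omega
    totals[1L] <- total
    k <- 2L
  }
  if (keep_steps) step_omegas[, 1L] <- omega
  for (s in seq_len(S)) {
    t_s <- lat_times[s]
    fr <- step_fractions(theta, spec, grid, E[s], t_s)
    w <- step_weights(fr$delta, fr$gamma, fr$rho)
    u <- w$stasis * omega
    if (m > 1L) {
      up <- seq_len(m - 1L)
      u[up + 1L] <- u[up + 1L] + w$growth[up] * omega[up]
      u[up] <- u[up] + w$loss[up + 1L] * omega[up + 1L]
    }
    dsrc <- grid$j:m
    ddst <- dsrc - grid$j + 1L
    u[ddst] <- u[ddst] + w$division[dsrc] * omega[dsrc]
    g <- sum(u)
    omega <- u / g
    total <- total * g
    step_growth[s] <- g
    if (keep_steps) {
      step_omegas[, s + 1L] <- omega
      frac_list[[s]] <- fr
    }
    if (k <= K && s == obs_steps[k]) {
      omegas[k, ] <- omega
      totals[k] <- total
      k <- k + 1L
    }
  }
  structure(
    list(
      times = obs_times, omegas = omegas, totals = totals,
      step_growth = step_growth, lattice_times = lat_times,
      step_omegas = step_omegas, step_fractions = frac_list,
      dt = dt
    ),
    class = "mpm_trajectory"
  )
}

#' Export a trajectory as a tidy data frame
#' @param x an \code{"mpm_trajectory"}.
#' @param ... unused.
#' @return data frame with columns \code{time_h}, \code{class_index},
#'   \code{proportion}, \code{total}.
#' @export
as.data.frame.mpm_trajectory <- function(x, ...) {
  K <- length(x$times)
  m <- ncol(x$omegas)
  data.frame(
    time_h = rep(x$times, each = m),
    class_index = rep(seq_len(m), K),
    proportion = as.vector(t(x$omegas)),
    total = rep(x$totals, each = m)
  )
}
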
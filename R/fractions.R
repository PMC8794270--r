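# Per-class, per-step transition fractions: division, carbon fixation (growth),
# and carbon loss (shrinkage). All *_max rate parameters are stored in d^-1;
# the dt/24 and (2^delta_v - 1) normalizations are applied only here, when
# converting to per-step fractions, so rates are comparable across
# discretization choices.

#' Upper bound for the maximum division rate (d^-1)
#' @param dt step length in hours.
#' @return \code{24/dt}, so that the per-step fraction \code{(dt/24) delta_max}
#'   cannot exceed 1.
#' @export
division_rate_bound <- function(dt) 24 / dt

#' Upper bound for maximum fixation/loss rates (d^-1)
#' @param delta_v log2 size-class width.
#' @param dt step length in hours.
#' @return \code{24 (2^delta_v - 1) / dt}, so that per-step growth and
#'   shrinkage fractions cannot exceed 1.
#' @export
growth_rate_bound <- function(delta_v, dt) 24 * (2^delta_v - 1) / dt

# Cardinal cubic B-spline on [0, 4), zero elsewhere. Integer shifts form a
# partition of unity, which is what keeps the periodic spline inside the
# convex hull of its control points.
cubic_bspline_cardinal <- function(x) {
  y <- numeric(length(x))
  i1 <- x >= 0 & x < 1
  i2 <- x >= 1 & x < 2
  i3 <- x >= 2 & x < 3
  i4 <- x >= 3 & x < 4
  u <- x[i1]
  y[i1] <- u^3 / 6
  u <- x[i2] - 1
  y[i2] <- (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6
  u <- x[i3] - 2
  y[i3] <- (3 * u^3 - 6 * u^2 + 4) / 6
  u <- x[i4] - 3
  y[i4] <- (1 - u)^3 / 6
  y
}

#' Periodic cubic B-spline basis for time-of-day modulation
#'
#' Evaluates the 6 periodic (24 h) cardinal cubic B-spline basis functions at
#' the given times. Rows sum to 1, so any control polygon in \eqn{[0,1]^6}
#' yields a modulation in \eqn{[0,1]}.
#'
#' @param t times in hours.
#' @param n_knots number of knots over one period (default 6, evenly spaced).
#' @param period period in hours (default 24).
#' @return matrix \code{length(t) x n_knots} of basis weights.
#' @export
time_spline_basis <- function(t, n_knots = 6L, period = 24) {
  h <- period / n_knots
  u <- (t / h) %% n_knots
  B <- vapply(
    seq_len(n_knots) - 1L,
    function(l) cubic_bspline_cardinal((u - l) %% n_knots),
    numeric(length(t))
  )
  matrix(B, nrow = length(t), ncol = n_knots)
}

#' Time-of-day division modulation q(t)
#'
#' A periodic (24 h) cubic B-spline with 6 evenly spaced knots whose control
#' points live in \eqn{[0,1]}; the value is a convex combination of the
#' control points, so \eqn{q(t) \in [0,1]} and \eqn{q(t) = q(t + 24)}.
#'
#' @param tau_control numeric vector of 6 control points in \eqn{[0,1]}.
#' @param t times in hours (nonnegative).
#' @return numeric vector of modulation values in \eqn{[0,1]}.
#' @examples
#' time_modulation(rep(0.5, 6), c(0, 3.7, 12)) # constant 0.5
#' @export
time_modulation <- function(tau_control, t) {
  if (length(tau_control) != 6L || anyNA(tau_control) ||
    any(tau_control < 0 | tau_control > 1)) {
    stop("tau_control must be 6 values in [0, 1]", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be nonnegative (hours)", call. = FALSE)
  drop(time_spline_basis(t) %*% tau_control)
}

#' Per-class division fractions delta_i(t)
#'
#' For classes below the smallest dividing class \eqn{j} the fraction is 0;
#' for \eqn{i \ge j} it is
#' \eqn{(dt/24)\,\delta_{max}\, q(t) \sum_{k=j}^i \delta_{incr}^{(k)}},
#' a nondecreasing function of size because the increments are a simplex.
#'
#' @param params list with \code{delta_max} (d^-1), \code{delta_incr} (simplex
#'   of length \code{m - j + 1}) and, for time-dependent models,
#'   \code{tau_control} (6 values in \eqn{[0,1]}).
#' @param grid a \code{\link{size_grid}}.
#' @param t time in hours.
#' @param dt step length in hours.
#' @param timedep logical; if \code{FALSE}, \eqn{q(t) = 1}.
#' @return numeric vector of m per-step division fractions in \eqn{[0,1]}.
#' @export
division_fractions <- function(params, grid, t, dt, timedep = FALSE) {
  m <- grid$m
  j <- grid$j
  incr <- params$delta_incr
  if (length(incr) != m - j + 1L) {
    stop(sprintf(
      "delta_incr has length %d but the grid needs m - j + 1 = %d increments",
      length(incr), m - j + 1L
    ), call. = FALSE)
  }
  q <- if (timedep) time_modulation(params$tau_control, t) else 1
  out <- numeric(m)
  out[j:m] <- (dt / 24) * params$delta_max * q * cumsum(incr)
  out
}

#' Size scaling of carbon fixation s_gamma(i)
#'
#' \code{basic}: no size dependence (all ones). \code{power}: power law in the
#' class midpoint, anchored so the largest scaling is 1 — for
#' \eqn{\beta_\gamma \ge 0} scalings are \eqn{(\bar v_i/\bar v_m)^{\beta}},
#' for \eqn{\beta_\gamma < 0} they are \eqn{(\bar v_i/\bar v_1)^{\beta}}.
#' \code{free}: per-class maximum rates normalized by their maximum. The
#' class-m entry is never used by the growth fractions (the top class cannot
#' grow) and is filled with the last defined value.
#'
#' @param params list with \code{beta_gamma} (power mode) or per-class
#'   \code{gamma_max} (free mode, length m - 1 for classes 1..m-1).
#' @param grid a \code{\link{size_grid}}.
#' @param mode one of \code{"basic"}, \code{"power"}, \code{"free"}.
#' @return numeric vector of m scalings in \eqn{(0, 1]}.
#' @export
size_scaling_fixation <- function(params, grid, mode = c("basic", "power", "free")) {
  mode <- match.arg(mode)
  m <- grid$m
  switch(mode,
    basic = rep(1, m),
    power = {
      beta <- params$beta_gamma
      vb <- grid$midpoints
      ref <- if (beta >= 0) vb[m] else vb[1]
      (vb / ref)^beta
    },
    free = {
      g <- params$gamma_max
      if (length(g) != m - 1L) {
        stop(sprintf(
          "free-mode gamma_max must have one rate per growing class (length %d)",
          m - 1L
        ), call. = FALSE)
      }
      s <- g / max(g)
      c(s, s[m - 1L])
    }
  )
}

# Per-class maximum fixation rate vector (d^-1), length m; entry m is a
# placeholder (class m cannot grow).
gamma_rate_vector <- function(params, grid, mode) {
  if (mode == "free") {
    c(params$gamma_max, 0)
  } else {
    params$gamma_max * size_scaling_fixation(params, grid, mode)
  }
}

#' Per-class growth (carbon fixation) fractions gamma_i(t)
#'
#' \eqn{\gamma_i(t) = \frac{dt}{24(2^{\Delta v}-1)}\gamma_{max} s_\gamma(i)
#' (1 - e^{-E(t)/E_k})} for \eqn{i < m}, and 0 for the top class, which has no
#' larger class to grow into. \code{e_k = 0} is treated as the fully
#' saturated limit (factor 1 whenever there is any light).
#'
#' @param params list with \code{gamma_max} (scalar, or per-class vector of
#'   length m - 1 in free mode), \code{e_k} (umol photons m^-2 s^-1) and, for
#'   power mode, \code{beta_gamma}.
#' @param grid a \code{\link{size_grid}}.
#' @param E_t photosynthetically active radiation at time t (nonnegative).
#' @param dt step length in hours.
#' @param mode fixation mode, as in \code{\link{size_scaling_fixation}}.
#' @return numeric vector of m per-step growth fractions in \eqn{[0,1]}.
#' @export
growth_fractions <- function(params, grid, E_t, dt, mode = "basic") {
  if (E_t < 0) stop("PAR must be nonnegative", call. = FALSE)
  gstar <- light_saturated_growth(params, grid, dt, mode)
  light <- if (params$e_k > 0) 1 - exp(-E_t / params$e_k) else as.numeric(E_t > 0)
  gstar * light
}

#' Light-saturated growth fractions gamma*_i
#'
#' The limit of \code{\link{growth_fractions}} as PAR grows without bound;
#' used to define the maximum photosynthetic rate P_max.
#'
#' @inheritParams growth_fractions
#' @return numeric vector of m fractions, with the top class 0.
#' @export
light_saturated_growth <- function(params, grid, dt, mode = "basic") {
  m <- grid$m
  cg <- dt / (24 * (2^grid$delta_v - 1))
  gvec <- gamma_rate_vector(params, grid, mode)
  out <- cg * gvec
  out[m] <- 0
  out
}

#' Per-class loss (carbon shrinkage) fractions rho_i
#'
#' \eqn{\rho_1 = 0} (nothing below the smallest class);
#' \eqn{\rho_i = \frac{dt}{24(2^{\Delta v}-1)}\rho_{max} s_\rho(i)} for
#' \eqn{i > 1}. \code{mode = "none"} returns all zeros.
#'
#' @param params list with \code{rho_max}: a scalar (basic) or a per-class
#'   vector of length m - 1 for classes 2..m (free); ignored for
#'   \code{mode = "none"}.
#' @param grid a \code{\link{size_grid}}.
#' @param dt step length in hours.
#' @param mode one of \code{"none"}, \code{"basic"}, \code{"free"}.
#' @return numeric vector of m per-step shrinkage fractions in \eqn{[0,1]}.
#' @export
loss_fractions <- function(params, grid, dt, mode = c("none", "basic", "free")) {
  mode <- match.arg(mode)
  m <- grid$m
  if (mode == "none") {
    return(numeric(m))
  }
  cr <- dt / (24 * (2^grid$delta_v - 1))
  if (mode == "basic") {
    rvec <- rep(params$rho_max, m - 1L)
  } else {
    rvec <- params$rho_max
    if (length(rvec) != m - 1L) {
      stop(sprintf(
        "free-mode rho_max must have one rate per shrinking class (length %d)",
        m - 1L
      ), call. = FALSE)
    }
  }
  c(0, cr * rvec)
}
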
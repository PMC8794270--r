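# Parameter vector handling: construction, validation, flattening, and the
# bijection between the constrained parameter space and the unconstrained
# space the sampler works on (scaled logit for bounded scalars, log for
# positives, stick-breaking for simplexes), with log-Jacobians and their
# analytic gradients.

#' Construct a model parameter vector
#'
#' Bundles all parameters of a size-structured MPM: division
#' (\code{delta_max}, \code{delta_incr}, optionally \code{tau_control}),
#' carbon fixation (\code{gamma_max}, \code{e_k}, optionally
#' \code{beta_gamma} or hierarchical \code{mu_gamma}/\code{sigma_gamma}),
#' carbon loss (\code{rho_max}, optionally \code{mu_rho}/\code{sigma_rho}),
#' the initial mean size distribution \code{omega0}, and the
#' Dirichlet-multinomial concentration \code{sigma}.
#'
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param delta_max maximum division rate (d^-1).
#' @param delta_incr simplex of per-class division increments
#'   (length \code{m - j + 1}).
#' @param tau_control 6 spline control points in \eqn{[0,1]}
#'   (time-dependent division only).
#' @param gamma_max maximum carbon fixation rate (d^-1); scalar, or length
#'   \code{m - 1} in free mode.
#' @param e_k photosynthetic saturation parameter (umol photons m^-2 s^-1).
#' @param beta_gamma power-law exponent (power mode only).
#' @param mu_gamma,sigma_gamma hierarchical location/scale for free-mode
#'   fixation rates.
#' @param rho_max maximum carbon loss rate (d^-1); scalar (basic), or length
#'   \code{m - 1} for classes 2..m (free); omitted when the model has no loss.
#' @param mu_rho,sigma_rho hierarchical location/scale for free-mode loss.
#' @param omega0 simplex of length m: initial mean size distribution.
#' @param sigma Dirichlet concentration parameter (> 0).
#' @return A list of class \code{"mpm_theta"}.
#' @export
mpm_theta <- function(spec, grid, delta_max, delta_incr, tau_control = NULL,
                      gamma_max, e_k, beta_gamma = NULL,
                      mu_gamma = NULL, sigma_gamma = NULL,
                      rho_max = NULL, mu_rho = NULL, sigma_rho = NULL,
                      omega0, sigma) {
  theta <- structure(
    list(
      delta_max = delta_max, delta_incr = delta_incr, tau_control = tau_control,
      gamma_max = gamma_max, e_k = e_k, beta_gamma = beta_gamma,
      mu_gamma = mu_gamma, sigma_gamma = sigma_gamma,
      rho_max = rho_max, mu_rho = mu_rho, sigma_rho = sigma_rho,
      omega0 = omega0, sigma = sigma
    ),
    class = "mpm_theta", model = format(spec)
  )
  validate_theta(theta, spec, grid)
  theta
}

#' Validate a parameter vector against a model specification and grid
#'
#' Checks dimensions, simplex constraints and the declared rate bounds
#' (division in \eqn{[0, 24/dt]}, fixation/loss in
#' \eqn{[0, 24(2^{\Delta v}-1)/dt]}).
#'
#' @param theta an \code{\link{mpm_theta}} (or plain list with its fields).
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param tol tolerance for simplex sum checks.
#' @return \code{theta}, invisibly; errors describe the violated constraint.
#' @export
validate_theta <- function(theta, spec, grid, tol = 1e-8) {
  m <- grid$m
  j <- grid$j
  ub_div <- division_rate_bound(spec$dt)
  ub_gr <- growth_rate_bound(grid$delta_v, spec$dt)
  chk_range <- function(x, lo, hi, what) {
    if (is.null(x) || anyNA(x) || any(x < lo - tol) || any(x > hi + tol)) {
      stop(sprintf("%s must lie in [%g, %g]", what, lo, hi), call. = FALSE)
    }
  }
  chk_simplex <- function(x, len, what) {
    if (is.null(x) || length(x) != len) {
      stop(sprintf("%s must have length %d", what, len), call. = FALSE)
    }
    if (any(x < -tol) || abs(sum(x) - 1) > max(tol, 1e-6)) {
      stop(sprintf("%s must be a simplex (nonnegative, summing to 1)", what),
        call. = FALSE
      )
    }
  }
  chk_range(theta$delta_max, 0, ub_div, "delta_max")
  chk_simplex(theta$delta_incr, m - j + 1L, "delta_incr")
  if (spec$division == "timedep") {
    chk_range(theta$tau_control, 0, 1, "tau_control")
    if (length(theta$tau_control) != 6L) {
      stop("tau_control must have 6 control points", call. = FALSE)
    }
  }
  if (spec$fixation == "free") {
    if (length(theta$gamma_max) != m - 1L) {
      stop(sprintf("free-mode gamma_max must have length m - 1 = %d", m - 1L),
        call. = FALSE
      )
    }
    chk_range(theta$mu_gamma, 0, ub_gr, "mu_gamma")
    if (is.null(theta$sigma_gamma) || theta$sigma_gamma <= 0) {
      stop("sigma_gamma must be positive", call. = FALSE)
    }
  } else if (spec$fixation == "power") {
    chk_range(theta$beta_gamma, -10, 10, "beta_gamma")
    if (length(theta$gamma_max) != 1L) stop("gamma_max must be scalar", call. = FALSE)
  } else if (length(theta$gamma_max) != 1L) {
    stop("gamma_max must be scalar", call. = FALSE)
  }
  chk_range(theta$gamma_max, 0, ub_gr, "gamma_max")
  chk_range(theta$e_k, 0, 5000, "e_k")
  if (spec$loss == "basic") {
    if (length(theta$rho_max) != 1L) stop("rho_max must be scalar", call. = FALSE)
    chk_range(theta$rho_max, 0, ub_gr, "rho_max")
  } else if (spec$loss == "free") {
    if (length(theta$rho_max) != m - 1L) {
      stop(sprintf("free-mode rho_max must have length m - 1 = %d", m - 1L),
        call. = FALSE
      )
    }
    chk_range(theta$rho_max, 0, ub_gr, "rho_max")
    chk_range(theta$mu_rho, 0, ub_gr, "mu_rho")
    if (is.null(theta$sigma_rho) || theta$sigma_rho <= 0) {
      stop("sigma_rho must be positive", call. = FALSE)
    }
  } else if (!is.null(theta$rho_max) && any(theta$rho_max != 0)) {
    stop("a model without loss cannot carry nonzero rho_max", call. = FALSE)
  }
  chk_simplex(theta$omega0, m, "omega0")
  if (is.null(theta$sigma) || theta$sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  invisible(theta)
}

# ---------------------------------------------------------------------------
# Flat layout of the constrained parameter space for a given model variant.
# Each block carries a transform type:
#   "lub"     scaled logit with bounds (lo, hi), one unconstrained dim per entry
#   "simplex" stick-breaking, K entries -> K-1 unconstrained dims
#   "pos"     log transform, (0, Inf)
theta_layout <- function(spec, grid, sigma_guard = 1e4) {
  m <- grid$m
  j <- grid$j
  ub_div <- division_rate_bound(spec$dt)
  ub_gr <- growth_rate_bound(grid$delta_v, spec$dt)
  blocks <- list()
  add <- function(blocks, name, type, n, lo = NA, hi = NA) {
    blocks[[name]] <- list(name = name, type = type, n = n, lo = lo, hi = hi)
    blocks
  }
  blocks <- add(blocks, "delta_max", "lub", 1L, 0, ub_div)
  blocks <- add(blocks, "delta_incr", "simplex", m - j + 1L)
  if (spec$division == "timedep") {
    blocks <- add(blocks, "tau_control", "lub", 6L, 0, 1)
  }
  if (spec$fixation == "free") {
    blocks <- add(blocks, "gamma_max", "lub", m - 1L, 0, ub_gr)
    blocks <- add(blocks, "mu_gamma", "lub", 1L, 0, ub_gr)
    blocks <- add(blocks, "sigma_gamma", "pos", 1L)
  } else {
    blocks <- add(blocks, "gamma_max", "lub", 1L, 0, ub_gr)
  }
  blocks <- add(blocks, "e_k", "lub", 1L, 0, 5000)
  if (spec$fixation == "power") {
    blocks <- add(blocks, "beta_gamma", "lub", 1L, -10, 10)
  }
  if (spec$loss == "basic") {
    blocks <- add(blocks, "rho_max", "lub", 1L, 0, ub_gr)
  } else if (spec$loss == "free") {
    blocks <- add(blocks, "rho_max", "lub", m - 1L, 0, ub_gr)
    blocks <- add(blocks, "mu_rho", "lub", 1L, 0, ub_gr)
    blocks <- add(blocks, "sigma_rho", "pos", 1L)
  }
  blocks <- add(blocks, "omega0", "simplex", m)
  blocks <- add(blocks, "sigma", "lub", 1L, 0, sigma_guard)
  n_un <- sum(vapply(blocks, function(b) {
    if (b$type == "simplex") b$n - 1L else b$n
  }, integer(1)))
  structure(list(blocks = blocks, n_unconstrained = n_un, spec = spec, grid = grid),
    class = "theta_layout"
  )
}

# Names of the constrained scalars, in layout order (used to label draws).
layout_par_names <- function(layout) {
  unlist(lapply(layout$blocks, function(b) {
    if (b$n == 1L) b$name else sprintf("%s[%d]", b$name, seq_len(b$n))
  }), use.names = FALSE)
}

theta_to_list <- function(values, layout) {
  theta <- list()
  pos <- 0L
  for (b in layout$blocks) {
    theta[[b$name]] <- values[pos + seq_len(b$n)]
    pos <- pos + b$n
  }
  structure(theta, class = "mpm_theta", model = format(layout$spec))
}

theta_to_values <- function(theta, layout) {
  unlist(lapply(layout$blocks, function(b) {
    v <- theta[[b$name]]
    if (is.null(v)) stop(sprintf("theta lacks block '%s'", b$name), call. = FALSE)
    v
  }), use.names = FALSE)
}

# --- scalar transforms ------------------------------------------------------

logistic <- function(y) 1 / (1 + exp(-y))

constrain_lub <- function(y, lo, hi) {
  s <- logistic(y)
  x <- lo + (hi - lo) * s
  # log|dx/dy| = log(hi-lo) + log s + log(1-s)
  logJ <- sum(log(hi - lo) + log(s) + log1p(-s))
  list(x = x, s = s, logJ = logJ)
}

unconstrain_lub <- function(x, lo, hi) {
  p <- (x - lo) / (hi - lo)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p) - log1p(-p)
}

# --- simplex stick-breaking -------------------------------------------------

constrain_simplex <- function(y) {
  K <- length(y) + 1L
  z <- logistic(y - log(K - seq_len(K - 1L)))
  x <- numeric(K)
  sticks <- numeric(K) # stick_k = remaining mass before break k
  stick <- 1
  logJ <- 0
  for (k in seq_len(K - 1L)) {
    sticks[k] <- stick
    x[k] <- stick * z[k]
    logJ <- logJ + log(z[k]) + log1p(-z[k]) + log(stick)
    stick <- stick * (1 - z[k])
  }
  sticks[K] <- stick
  x[K] <- stick
  list(x = x, z = z, sticks = sticks, logJ = logJ)
}

unconstrain_simplex <- function(x) {
  K <- length(x)
  z <- numeric(K - 1L)
  stick <- 1
  for (k in seq_len(K - 1L)) {
    z[k] <- x[k] / stick
    stick <- stick - x[k]
  }
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  log(z) - log1p(-z) + log(K - seq_len(K - 1L))
}

# Reverse-mode through the simplex transform: given xbar (dloglik/dx, length K)
# return ybar (length K-1), EXCLUDING the log-Jacobian's own gradient.
simplex_pullback <- function(xbar, cache) {
  z <- cache$z
  sticks <- cache$sticks
  K <- length(xbar)
  ybar <- numeric(K - 1L)
  sbar <- xbar[K]
  for (k in seq(K - 1L, 1L)) {
    zbar <- sticks[k] * (xbar[k] - sbar)
    sbar <- z[k] * xbar[k] + (1 - z[k]) * sbar
    ybar[k] <- zbar * z[k] * (1 - z[k])
  }
  ybar
}

# d logJ / dy for the simplex transform.
simplex_logJ_grad <- function(cache) {
  z <- cache$z
  K <- length(z) + 1L
  1 - z * (K - seq_len(K - 1L) + 1)
}

# --- whole-vector transform -------------------------------------------------

#' Map an unconstrained vector to a constrained parameter list
#'
#' The sampler works on an unconstrained space: bounded scalars via scaled
#' logit, positive scalars via log, simplexes via stick-breaking. Returns the
#' constrained parameters, the log-Jacobian of the map (added to the target
#' density), and a cache used to pull gradients back.
#'
#' @param y unconstrained numeric vector.
#' @param layout a layout from \code{theta_layout()} (internal).
#' @return list with \code{theta}, \code{logJ}, \code{cache}.
#' @keywords internal
constrain_theta <- function(y, layout) {
  theta <- list()
  cache <- list()
  logJ <- 0
  pos <- 0L
  for (b in layout$blocks) {
    if (b$type == "lub") {
      yb <- y[pos + seq_len(b$n)]
      cc <- constrain_lub(yb, b$lo, b$hi)
      theta[[b$name]] <- cc$x
      cache[[b$name]] <- cc
      logJ <- logJ + cc$logJ
      pos <- pos + b$n
    } else if (b$type == "pos") {
      yb <- y[pos + 1L]
      theta[[b$name]] <- exp(yb)
      cache[[b$name]] <- list(x = exp(yb))
      logJ <- logJ + yb
      pos <- pos + 1L
    } else { # simplex
      yb <- y[pos + seq_len(b$n - 1L)]
      cc <- constrain_simplex(yb)
      theta[[b$name]] <- cc$x
      cache[[b$name]] <- cc
      logJ <- logJ + cc$logJ
      pos <- pos + b$n - 1L
    }
  }
  list(
    theta = structure(theta, class = "mpm_theta", model = format(layout$spec)),
    logJ = logJ, cache = cache
  )
}

#' Map a constrained parameter list to the unconstrained vector
#' @param theta an \code{\link{mpm_theta}}.
#' @param layout a layout from \code{theta_layout()} (internal).
#' @return unconstrained numeric vector.
#' @keywords internal
unconstrain_theta <- function(theta, layout) {
  out <- numeric(layout$n_unconstrained)
  pos <- 0L
  for (b in layout$blocks) {
    x <- theta[[b$name]]
    if (b$type == "lub") {
      out[pos + seq_len(b$n)] <- unconstrain_lub(x, b$lo, b$hi)
      pos <- pos + b$n
    } else if (b$type == "pos") {
      out[pos + 1L] <- log(x)
      pos <- pos + 1L
    } else {
      out[pos + seq_len(b$n - 1L)] <- unconstrain_simplex(x)
      pos <- pos + b$n - 1L
    }
  }
  out
}

# Pull a gradient on the constrained scale (named list gbar, one entry per
# block, same shapes as theta) back to the unconstrained scale, adding the
# gradient of the log-Jacobian when the target includes it (sampling does;
# mode finding does not).
pullback_grad <- function(gbar, cache, layout, jacobian = TRUE) {
  gy <- numeric(layout$n_unconstrained)
  pos <- 0L
  for (b in layout$blocks) {
    g <- gbar[[b$name]]
    if (is.null(g)) g <- 0
    if (b$type == "lub") {
      cc <- cache[[b$name]]
      s <- cc$s
      gy[pos + seq_len(b$n)] <- g * (b$hi - b$lo) * s * (1 - s) +
        if (jacobian) (1 - 2 * s) else 0
      pos <- pos + b$n
    } else if (b$type == "pos") {
      gy[pos + 1L] <- g * cache[[b$name]]$x + if (jacobian) 1 else 0
      pos <- pos + 1L
    } else {
      cc <- cache[[b$name]]
      if (length(g) == 1L && g[1] == 0) g <- numeric(b$n)
      gy[pos + seq_len(b$n - 1L)] <- simplex_pullback(g, cc) +
        if (jacobian) simplex_logJ_grad(cc) else 0
      pos <- pos + b$n - 1L
    }
  }
  gy
}
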
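# Prior configuration and evaluation. Default informative priors: truncated
# normals for rate maxima and the photosynthetic saturation parameter,
# Beta(9, 1) for spline control points, Exponential(0.1) for hierarchical
# scales; everything else is uniform over its declared support ("flat"),
# including the simplexes and the concentration parameter (which carries a
# configurable upper guard so the posterior stays proper).

#' Default prior configuration for a model variant
#'
#' One entry per parameter block with \code{family} (\code{"normal"},
#' \code{"beta"}, \code{"exponential"}, \code{"flat"}), \code{location},
#' \code{scale} and \code{bounds}. Normal priors are truncated to their
#' bounds. Free-mode per-class rates get \code{family = "hierarchical"},
#' meaning Normal(\code{mu_gamma}, \code{sigma_gamma}) (resp.
#' \code{mu_rho}, \code{sigma_rho}) truncated to the rate bounds.
#'
#' @param spec an \code{\link{model_spec}}.
#' @param grid a \code{\link{size_grid}}.
#' @param sigma_guard upper bound of the uniform guard on the concentration
#'   parameter (default 1e4).
#' @param overrides named list of partial entries merged over the defaults,
#'   e.g. \code{list(e_k = list(location = 500))}.
#' @return A list of class \code{"prior_config"}.
#' @export
prior_config <- function(spec, grid, sigma_guard = 1e4, overrides = list()) {
  ub_gr <- growth_rate_bound(grid$delta_v, spec$dt)
  ub_div <- division_rate_bound(spec$dt)
  ent <- function(family, location = NA, scale = NA, bounds) {
    list(family = family, location = location, scale = scale, bounds = bounds)
  }
  pr <- list(
    delta_max = ent("flat", bounds = c(0, ub_div)),
    delta_incr = ent("flat", bounds = c(0, 1)),
    e_k = ent("normal", 1000, 1000, c(0, 5000)),
    omega0 = ent("flat", bounds = c(0, 1)),
    sigma = ent("flat", bounds = c(0, sigma_guard))
  )
  if (spec$division == "timedep") {
    pr$tau_control <- ent("beta", 9, 1, c(0, 1))
  }
  if (spec$fixation == "free") {
    pr$gamma_max <- ent("hierarchical", "mu_gamma", "sigma_gamma", c(0, ub_gr))
    pr$mu_gamma <- ent("normal", 10, 10, c(0, ub_gr))
    pr$sigma_gamma <- ent("exponential", scale = 0.1, bounds = c(0, Inf))
  } else {
    pr$gamma_max <- ent("normal", 10, 10, c(0, ub_gr))
    if (spec$fixation == "power") {
      pr$beta_gamma <- ent("normal", 0, 0.1, c(-10, 10))
    }
  }
  if (spec$loss == "basic") {
    pr$rho_max <- ent("normal", 3, 10, c(0, ub_gr))
  } else if (spec$loss == "free") {
    pr$rho_max <- ent("hierarchical", "mu_rho", "sigma_rho", c(0, ub_gr))
    pr$mu_rho <- ent("normal", 10, 10, c(0, ub_gr))
    pr$sigma_rho <- ent("exponential", scale = 0.1, bounds = c(0, Inf))
  }
  for (nm in names(overrides)) {
    if (is.null(pr[[nm]])) {
      pr[[nm]] <- overrides[[nm]]
    } else {
      pr[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    }
  }
  structure(pr, class = "prior_config", sigma_guard = sigma_guard)
}

#' Flat priors over the declared supports
#'
#' Replaces every informative prior with a uniform over the same bounds, so
#' the posterior is proportional to the likelihood (used to probe prior
#' sensitivity and for maximum-likelihood benchmarks).
#'
#' @inheritParams prior_config
#' @return A \code{"prior_config"}.
#' @export
flat_priors <- function(spec, grid, sigma_guard = 1e4) {
  pr <- prior_config(spec, grid, sigma_guard = sigma_guard)
  for (nm in names(pr)) {
    pr[[nm]]$family <- "flat"
  }
  structure(pr, class = "prior_config", sigma_guard = sigma_guard)
}

# log density of Normal(mu, sd) truncated to [lo, hi], elementwise; also the
# partial derivatives needed when mu/sd are themselves sampled.
trunc_normal_lpdf <- function(x, mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  logZ <- log(stats::pnorm(b) - stats::pnorm(a))
  sum(stats::dnorm(x, mu, sd, log = TRUE) - logZ)
}

trunc_normal_grads <- function(x, mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  phia <- stats::dnorm(a)
  phib <- stats::dnorm(b)
  n <- length(x)
  list(
    dx = -(x - mu) / sd^2,
    dmu = sum((x - mu) / sd^2) - n * (phia - phib) / (sd * Z),
    dsd = sum(-1 / sd + (x - mu)^2 / sd^3) -
      n * (a * phia - b * phib) / (sd * Z)
  )
}

#' Log prior density of a parameter vector
#'
#' Sum of the per-block log prior densities under a \code{\link{prior_config}}.
#' Flat blocks contribute 0 inside their bounds; any parameter at or outside a
#' bound makes the result \code{-Inf}. Hierarchical free-mode rates contribute
#' truncated Normal(mu, sigma) terms whose location and scale are themselves
#' parameters with their own priors.
#'
#' @param theta an \code{\link{mpm_theta}}.
#' @param spec an \code{\link{model_spec}}.
#' @param priors a \code{\link{prior_config}}.
#' @return log prior density (finite, or \code{-Inf} outside the support).
#' @export
log_prior <- function(theta, spec, priors) {
  lp <- 0
  for (nm in names(priors)) {
    p <- priors[[nm]]
    x <- theta[[nm]]
    if (is.null(x)) {
      stop(sprintf("theta lacks parameter '%s' required by the priors", nm),
        call. = FALSE
      )
    }
    lo <- p$bounds[1]
    hi <- p$bounds[2]
    if (nm %in% c("delta_incr", "omega0")) {
      # simplex support: entries in [0,1] summing to one
      if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-6) {
        return(-Inf)
      }
      next
    }
    # bounds are open: mass at the boundary itself is zero
    if (any(x <= lo & is.finite(lo)) || any(x >= hi & is.finite(hi))) {
      return(-Inf)
    }
    lp <- lp + switch(p$family,
      flat = 0,
      normal = trunc_normal_lpdf(x, p$location, p$scale, lo, hi),
      beta = sum(stats::dbeta(x, p$location, p$scale, log = TRUE)),
      exponential = sum(stats::dexp(x, rate = p$scale, log = TRUE)),
      hierarchical = trunc_normal_lpdf(
        x, theta[[p$location]], theta[[p$scale]], lo, hi
      ),
      stop(sprintf("unknown prior family '%s'", p$family), call. = FALSE)
    )
    if (!is.finite(lp)) {
      return(-Inf)
    }
  }
  lp
}

# Gradient of log_prior w.r.t. the constrained parameters, as a named list
# (used on the sampler's main path; assumes theta strictly inside its bounds).
log_prior_grad <- function(theta, spec, priors) {
  g <- list()
  add <- function(g, nm, val) {
    g[[nm]] <- (if (is.null(g[[nm]])) 0 else g[[nm]]) + val
    g
  }
  for (nm in names(priors)) {
    p <- priors[[nm]]
    x <- theta[[nm]]
    if (nm %in% c("delta_incr", "omega0") || p$family == "flat") next
    lo <- p$bounds[1]
    hi <- p$bounds[2]
    if (p$family == "normal") {
      g <- add(g, nm, -(x - p$location) / p$scale^2)
    } else if (p$family == "beta") {
      g <- add(g, nm, (p$location - 1) / x - (p$scale - 1) / (1 - x))
    } else if (p$family == "exponential") {
      g <- add(g, nm, rep(-p$scale, length(x)))
    } else if (p$family == "hierarchical") {
      gr <- trunc_normal_grads(x, theta[[p$location]], theta[[p$scale]], lo, hi)
      g <- add(g, nm, gr$dx)
      g <- add(g, p$location, gr$dmu)
      g <- add(g, p$scale, gr$dsd)
    }
  }
  g
}

#' Read a prior configuration from a YAML or JSON file
#'
#' The file holds partial entries keyed by parameter name
#' (\code{family}, \code{location}, \code{scale}, \code{bounds}); anything not
#' given keeps its default from \code{\link{prior_config}}.
#'
#' @param path file path (extension .yaml/.yml or .json).
#' @inheritParams prior_config
#' @return A \code{"prior_config"}.
#' @export
read_prior_config <- function(path, spec, grid, sigma_guard = 1e4) {
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- lapply(overrides, function(e) {
    if (!is.null(e$bounds)) e$bounds <- as.numeric(e$bounds)
    e
  })
  prior_config(spec, grid, sigma_guard = sigma_guard, overrides = overrides)
}
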
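# Main model-fitting interface. fit_mpm() runs NUTS chains over the
# unconstrained posterior and returns an "mpm_fit" object carrying
# constrained draws, convergence diagnostics and per-draw derived rates;
# fit_map() computes the posterior mode (the MLE under flat priors) by
# gradient-based optimization with restarts.

r_trunc_norm <- function(n, mu, sd, lo, hi) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

# Draw an initial unconstrained point: informative priors are sampled on the
# constrained scale and mapped over; flat blocks start uniform(-2, 2) on the
# unconstrained scale.
draw_init <- function(layout, priors) {
  theta <- list()
  draw_block <- function(b) {
    p <- priors[[b$name]]
    switch(p$family,
      normal = r_trunc_norm(b$n, p$location, p$scale, b$lo, b$hi),
      beta = stats::rbeta(b$n, p$location, p$scale),
      exponential = stats::rexp(b$n, rate = p$scale),
      hierarchical = {
        mu <- theta[[p$location]]
        sd <- theta[[p$scale]]
        r_trunc_norm(b$n, mu, sd, p$bounds[1], p$bounds[2])
      },
      NULL # flat
    )
  }
  # hyperparameters first, then hierarchical children
  ord <- order(vapply(
    layout$blocks,
    function(b) priors[[b$name]]$family == "hierarchical", logical(1)
  ))
  for (b in layout$blocks[ord]) {
    theta[[b$name]] <- draw_block(b)
  }
  y <- numeric(layout$n_unconstrained)
  pos <- 0L
  for (b in layout$blocks) {
    n_un <- if (b$type == "simplex") b$n - 1L else b$n
    x <- theta[[b$name]]
    y[pos + seq_len(n_un)] <- if (is.null(x)) {
      stats::runif(n_un, -2, 2)
    } else if (b$type == "lub") {
      unconstrain_lub(x, b$lo, b$hi)
    } else if (b$type == "pos") {
      log(x)
    } else {
      unconstrain_simplex(x)
    }
    pos <- pos + n_un
  }
  y
}

#' Fit a size-structured MPM by Hamiltonian Monte Carlo
#'
#' Samples the posterior of a size-structured matrix population model given
#' size-distribution counts and a PAR series, using a No-U-Turn sampler with
#' adaptive step size and diagonal mass matrix over the unconstrained
#' parameter space (analytic adjoint gradients). The default run
#' configuration is 6 chains of 2000 iterations with the first 1000
#' discarded as warmup; a fit with any split-\eqn{\hat R \ge 1.05} is
#' flagged divergent.
#'
#' @param obs an \code{\link{obs_set}} of size-class counts.
#' @param light a \code{\link{light_series}} covering the dt lattice over
#'   the observation record.
#' @param model three-letter model name (see \code{\link{model_spec}}) or an
#'   \code{mpm_spec}.
#' @param grid a \code{\link{size_grid}}.
#' @param priors a \code{\link{prior_config}}; defaults to
#'   \code{prior_config(spec, grid)}.
#' @param chains number of chains (at least 2 for \eqn{\hat R}).
#' @param iterations iterations per chain, including warmup.
#' @param warmup warmup iterations discarded per chain.
#' @param seed integer seed driving initialization and sampling.
#' @param target_accept dual-averaging target acceptance statistic
#'   (default 0.9: the simplex-heavy geometry of these posteriors rewards a
#'   smaller step size than the common 0.8).
#' @param max_treedepth maximum trajectory doublings.
#' @param include_k0 include the first observation in the likelihood.
#' @param dt projection step (hours) when \code{model} is given as a name.
#' @param init_retries attempts per chain to find a finite starting point.
#' @param derived_max_draws cap on the number of draws used for per-draw
#'   derived rates (evenly thinned).
#' @param verbose print progress.
#' @return An object of class \code{"mpm_fit"}; see
#'   \code{\link{summary.mpm_fit}}.
#' @export
fit_mpm <- function(obs, light, model = "bmb", grid = size_grid(),
                    priors = NULL, chains = 6L, iterations = 2000L,
                    warmup = 1000L, seed = 1L, target_accept = 0.9,
                    max_treedepth = 10L, include_k0 = TRUE, dt = 1 / 3,
                    init_retries = 20L, derived_max_draws = 2000L,
                    verbose = FALSE) {
  spec <- if (inherits(model, "mpm_spec")) model else model_spec(model, dt = dt)
  if (is.null(priors)) priors <- prior_config(spec, grid)
  if (warmup >= iterations) stop("warmup must be smaller than iterations", call. = FALSE)
  if (chains < 2L) {
    warning("fewer than 2 chains: split-Rhat is not defined", call. = FALSE)
  }
  post <- make_posterior(spec, obs, light, grid, priors, include_k0 = include_k0)
  layout <- post$layout
  par_names <- layout_par_names(layout)
  P <- length(par_names)
  n_keep <- iterations - warmup

  set.seed(as.integer(seed) %% .Machine$integer.max)
  chain_seeds <- sample.int(2^30, chains)
  chain_res <- vector("list", chains)
  t_start <- Sys.time()
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    y0 <- NULL
    for (try in seq_len(init_retries)) {
      cand <- draw_init(layout, priors)
      if (is.finite(post$lp(cand)$value)) {
        y0 <- cand
        break
      }
    }
    if (is.null(y0)) {
      stop(sprintf(
        "chain %d: no finite starting point in %d attempts; check priors and data alignment",
        ch, init_retries
      ), call. = FALSE)
    }
    res <- nuts_chain(post$lp, y0,
      iterations = iterations, warmup = warmup,
      target_accept = target_accept, max_treedepth = max_treedepth
    )
    # constrained draws
    con <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, par_names))
    for (i in seq_len(n_keep)) {
      con[i, ] <- theta_to_values(
        constrain_theta(res$draws[i, ], layout)$theta, layout
      )
    }
    res$constrained <- con
    chain_res[[ch]] <- res
    if (verbose) {
      message(sprintf(
        "chain %d/%d: stepsize %.3g, %d divergences, mean accept %.2f",
        ch, chains, res$stepsize, res$divergences, res$accept_stat
      ))
    }
  }
  arr <- array(NA_real_, c(n_keep, chains, P), dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(chains)) arr[, ch, ] <- chain_res[[ch]]$constrained
  rhat <- if (chains >= 2L && n_keep >= 4L) {
    vapply(seq_len(P), function(p) compute_rhat(arr[, , p]), numeric(1))
  } else {
    rep(NA_real_, P)
  }
  names(rhat) <- par_names
  draws <- do.call(rbind, lapply(chain_res, `[[`, "constrained"))
  chain_id <- rep(seq_len(chains), each = n_keep)

  # per-draw derived daily rates (evenly thinned)
  total <- nrow(draws)
  keep_idx <- if (total > derived_max_draws) {
    unique(round(seq(1, total, length.out = derived_max_draws)))
  } else {
    seq_len(total)
  }
  derived <- t(vapply(keep_idx, function(i) {
    th <- theta_to_list(draws[i, ], layout)
    derived_rates(th, spec, grid, light, obs$times)
  }, numeric(5)))
  derived <- as.data.frame(derived)
  derived$sigma <- draws[keep_idx, "sigma"]
  derived$draw <- keep_idx

  fit <- structure(
    list(
      spec = spec, grid = grid, obs = obs, light = light, priors = priors,
      layout = layout, draws = draws, chain_id = chain_id, chain_array = arr,
      rhat = rhat, divergences = vapply(chain_res, `[[`, 0L, "divergences"),
      stepsize = vapply(chain_res, `[[`, 0, "stepsize"),
      accept_stat = vapply(chain_res, `[[`, 0, "accept_stat"),
      logp = unlist(lapply(chain_res, `[[`, "logp")),
      derived = derived,
      config = list(
        chains = chains, iterations = iterations, warmup = warmup,
        seed = seed, target_accept = target_accept,
        max_treedepth = max_treedepth, include_k0 = include_k0
      ),
      elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    ),
    class = "mpm_fit"
  )
  fit
}

#' Was the sampling flagged divergent?
#' @param fit an \code{"mpm_fit"}.
#' @param rhat_limit flag threshold (default 1.05).
#' @return \code{TRUE} when any parameter's split-\eqn{\hat R} is at or
#'   above the limit.
#' @export
is_divergent_fit <- function(fit, rhat_limit = 1.05) {
  any(fit$rhat >= rhat_limit, na.rm = TRUE)
}

# Posterior-median parameter vector, with simplexes renormalized.
median_theta <- function(fit) {
  med <- apply(fit$draws, 2, stats::median)
  th <- theta_to_list(med, fit$layout)
  th$omega0 <- th$omega0 / sum(th$omega0)
  th$delta_incr <- th$delta_incr / sum(th$delta_incr)
  th
}

#' @export
print.mpm_fit <- function(x, ...) {
  d <- x$derived
  qd <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75))
  cat(sprintf(
    "Size-structured MPM fit, model m_%s (%d classes, dt = %s h)\n",
    format(x$spec), x$grid$m, format(x$spec$dt)
  ))
  cat(sprintf(
    "  %d chains x %d iterations (%d warmup); max split-Rhat %.3f; %d divergent transitions%s\n",
    x$config$chains, x$config$iterations, x$config$warmup,
    max(x$rhat, na.rm = TRUE), sum(x$divergences),
    if (is_divergent_fit(x)) " [FLAGGED DIVERGENT: Rhat >= 1.05]" else ""
  ))
  mu <- qd(d$mu_daily)
  fx <- qd(d$daily_fixation)
  lo <- qd(d$daily_loss)
  cat(sprintf(
    "  daily division   %.3f d^-1      (IQR %.3f-%.3f)\n", mu[2], mu[1], mu[3]
  ))
  cat(sprintf(
    "  daily C fixation %.2f fg C/cell (IQR %.2f-%.2f)\n", fx[2], fx[1], fx[3]
  ))
  cat(sprintf(
    "  daily C loss     %.2f fg C/cell (IQR %.2f-%.2f)\n", lo[2], lo[1], lo[3]
  ))
  invisible(x)
}

#' Posterior summary of a fitted MPM
#'
#' @param object an \code{"mpm_fit"}.
#' @param pars optional character vector restricting the parameter table.
#' @param ... unused.
#' @return list of class \code{"summary.mpm_fit"} with \code{parameters}
#'   (mean, median, quartiles, 95\% interval, \eqn{\hat R} per scalar) and
#'   \code{rates} (the same for the derived daily quantities).
#' @export
summary.mpm_fit <- function(object, pars = NULL, ...) {
  tab <- function(mat, rhat = NULL) {
    qs <- t(apply(mat, 2, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
    out <- data.frame(
      mean = colMeans(mat), q2.5 = qs[, 1], q25 = qs[, 2],
      median = qs[, 3], q75 = qs[, 4], q97.5 = qs[, 5]
    )
    if (!is.null(rhat)) out$rhat <- rhat
    out
  }
  p <- tab(object$draws, object$rhat)
  if (!is.null(pars)) p <- p[rownames(p) %in% pars | grepl(paste(pars, collapse = "|"), rownames(p)), ]
  rates <- tab(as.matrix(object$derived[, c(
    "mu_daily", "daily_fixation", "daily_loss", "p_max", "e_k", "sigma"
  )]))
  structure(
    list(
      parameters = p, rates = rates, model = format(object$spec),
      divergent = is_divergent_fit(object), config = object$config
    ),
    class = "summary.mpm_fit"
  )
}

#' @export
print.summary.mpm_fit <- function(x, ...) {
  cat(sprintf("Model m_%s posterior summary\n\nDerived daily rates:\n", x$model))
  print(round(x$rates, 4))
  cat("\nParameters (head):\n")
  print(round(utils::head(x$parameters, 12), 4))
  if (x$divergent) cat("\nWARNING: fit flagged divergent (split-Rhat >= 1.05)\n")
  invisible(x)
}

#' @export
coef.mpm_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' Predicted mean size distributions from a fitted model
#'
#' Simulates the trajectory at the requested times from the
#' posterior-median parameters (simplexes renormalized after the
#' componentwise median).
#'
#' @param object an \code{"mpm_fit"}.
#' @param times observation times (hours, on the dt lattice); defaults to
#'   the fitted observation times.
#' @param ... unused.
#' @return an \code{"mpm_trajectory"}.
#' @export
predict.mpm_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$obs$times
  simulate_trajectory(
    median_theta(object), object$spec, object$grid, object$light, times,
    keep_steps = TRUE
  )
}

#' @export
fitted.mpm_fit <- function(object, ...) {
  predict(object)$omegas
}

#' Residual size-distribution proportions
#' @param object an \code{"mpm_fit"}.
#' @param ... unused.
#' @return K x m matrix of observed minus fitted proportions.
#' @export
residuals.mpm_fit <- function(object, ...) {
  object$obs$proportions - fitted(object)
}

#' Posterior-predictive count datasets from a fitted model
#'
#' For each replicate, draws a posterior parameter vector, simulates its
#' mean trajectory, then draws per-time compositions from
#' Dirichlet(\eqn{\sigma\omega_k}) and counts from the multinomial with the
#' observed totals.
#'
#' @param object an \code{"mpm_fit"}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of \code{\link{obs_set}} objects.
#' @export
simulate.mpm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    th <- theta_to_list(object$draws[i, ], object$layout)
    th$omega0 <- th$omega0 / sum(th$omega0)
    th$delta_incr <- th$delta_incr / sum(th$delta_incr)
    traj <- simulate_trajectory(
      th, object$spec, object$grid, object$light, object$obs$times
    )
    counts <- t(vapply(seq_along(object$obs$times), function(k) {
      eta <- stats::rgamma(object$grid$m, shape = th$sigma * traj$omegas[k, ])
      eta <- eta / sum(eta)
      drop(stats::rmultinom(1, object$obs$totals[k], eta))
    }, numeric(object$grid$m)))
    obs_set(object$obs$times, counts)
  })
}

#' Diagnostic plot of a fitted MPM
#'
#' Two panels: observed (points) vs fitted (lines) size-class proportions at
#' a few observation times, and the posterior-median hourly division-rate
#' series with its interquartile band.
#'
#' @param x an \code{"mpm_fit"}.
#' @param n_draws number of posterior draws for the hourly-rate band.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.mpm_fit <- function(x, n_draws = 100L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  traj <- predict(x)
  K <- length(x$obs$times)
  show <- unique(round(seq(1, K, length.out = 4)))
  cols <- grDevices::hcl.colors(length(show), "Dark 2")
  graphics::matplot(x$grid$midpoints, t(x$obs$proportions[show, , drop = FALSE]),
    pch = 1, col = cols, log = "x", xlab = "cell size (fg C)",
    ylab = "proportion", main = "observed vs fitted PSD"
  )
  graphics::matlines(x$grid$midpoints, t(traj$omegas[show, , drop = FALSE]),
    lty = 1, col = cols
  )
  idx <- sample.int(nrow(x$draws), min(n_draws, nrow(x$draws)))
  hr <- vapply(idx, function(i) {
    th <- theta_to_list(x$draws[i, ], x$layout)
    th$omega0 <- th$omega0 / sum(th$omega0)
    th$delta_incr <- th$delta_incr / sum(th$delta_incr)
    tr <- simulate_trajectory(th, x$spec, x$grid, x$light, x$obs$times)
    hourly_division_series(tr)$rate
  }, numeric(floor((max(x$obs$times) - min(x$obs$times)))))
  qs <- apply(hr, 1, stats::quantile, c(0.25, 0.5, 0.75))
  hours <- min(x$obs$times) + seq_len(ncol(qs)) - 1
  graphics::plot(hours, qs[2, ],
    type = "l", lwd = 2, ylim = range(qs),
    xlab = "time (h)", ylab = "division rate (d^-1)",
    main = "hourly division (median, IQR)"
  )
  graphics::polygon(c(hours, rev(hours)), c(qs[1, ], rev(qs[3, ])),
    col = grDevices::adjustcolor("steelblue", 0.3), border = NA
  )
  graphics::lines(hours, qs[2, ], lwd = 2)
  invisible(x)
}

#' Maximum a posteriori / maximum likelihood fit
#'
#' Gradient-based optimization (L-BFGS-B on the unconstrained scale, with
#' the change-of-variables Jacobian excluded, so the optimum is the mode of
#' the posterior density over the constrained parameters); under
#' \code{\link{flat_priors}} this is the maximum likelihood estimator.
#' Multiple random restarts are kept
#' and reported, since the likelihood surface is multimodal enough that
#' single-start optimization is unreliable — per-restart objective values
#' are part of the result, so instability is observable.
#'
#' @inheritParams fit_mpm
#' @param restarts number of random restarts (>= 1).
#' @param maxit iteration cap per restart.
#' @return list of class \code{"mpm_map"} with \code{theta} (best
#'   constrained parameters), \code{value} (its log posterior),
#'   \code{restart_values}, \code{convergence}, \code{spec}.
#' @export
fit_map <- function(obs, light, model = "bmb", grid = size_grid(),
                    priors = NULL, restarts = 5L, seed = 1L,
                    include_k0 = TRUE, dt = 1 / 3, maxit = 500L) {
  if (restarts < 1L) stop("restarts must be at least 1", call. = FALSE)
  spec <- if (inherits(model, "mpm_spec")) model else model_spec(model, dt = dt)
  if (is.null(priors)) priors <- prior_config(spec, grid)
  # mode finding excludes the transform Jacobian: the optimum is the MAP (or
  # MLE under flat priors) on the constrained scale, not of the sampling
  # density on the unconstrained scale
  post <- make_posterior(spec, obs, light, grid, priors,
    include_k0 = include_k0, jacobian = FALSE
  )
  layout <- post$layout
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fn <- function(y) {
    v <- post$lp(y)$value
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(y) {
    ev <- post$lp(y)
    if (!is.finite(ev$value)) rep(0, length(y)) else -ev$grad
  }
  vals <- numeric(restarts)
  best <- NULL
  conv <- integer(restarts)
  inits <- numeric(0)
  for (r in seq_len(restarts)) {
    y0 <- NULL
    for (try in seq_len(20L)) {
      cand <- draw_init(layout, priors)
      if (is.finite(post$lp(cand)$value)) {
        y0 <- cand
        break
      }
    }
    if (is.null(y0)) stop("no finite starting point found", call. = FALSE)
    opt <- stats::optim(y0, fn, gr,
      method = "L-BFGS-B",
      control = list(maxit = maxit)
    )
    vals[r] <- -opt$value
    conv[r] <- opt$convergence
    if (is.null(best) || -opt$value > best$value) {
      best <- list(y = opt$par, value = -opt$value, init_value = post$lp(y0)$value)
    }
  }
  theta <- constrain_theta(best$y, layout)$theta
  structure(
    list(
      theta = theta, value = best$value, init_value = best$init_value,
      restart_values = vals, convergence = conv, spec = spec, grid = grid,
      layout = layout
    ),
    class = "mpm_map"
  )
}

#' @export
print.mpm_map <- function(x, ...) {
  cat(sprintf(
    "MAP fit, model m_%s: best log posterior %.2f over %d restart(s)\n",
    format(x$spec), x$value, length(x$restart_values)
  ))
  cat(
    "  per-restart values:",
    paste(sprintf("%.2f", x$restart_values), collapse = ", "), "\n"
  )
  if (length(x$restart_values) > 1L && stats::sd(x$restart_values) > 1) {
    cat("  note: restart values disagree; the optimum is initialization-sensitive\n")
  }
  invisible(x)
}

#' Export posterior draws as tidy CSV
#' @param fit an \code{"mpm_fit"}.
#' @param path output CSV path (columns chain, iteration, parameter, value).
#' @return \code{path}, invisibly.
#' @export
write_draws <- function(fit, path) {
  n_keep <- nrow(fit$draws) / fit$config$chains
  df <- data.frame(
    chain = rep(fit$chain_id, ncol(fit$draws)),
    iteration = rep(rep(seq_len(n_keep), fit$config$chains), ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a JSON fit summary
#'
#' Per-parameter posterior mean, median, quantiles and \eqn{\hat R},
#' divergence counts, derived daily-rate summaries, and the run
#' configuration (seed included).
#'
#' @param fit an \code{"mpm_fit"}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(fit, path) {
  s <- summary(fit)
  jsonlite::write_json(
    list(
      model = s$model,
      config = fit$config,
      divergent = s$divergent,
      divergences = fit$divergences,
      parameters = cbind(parameter = rownames(s$parameters), s$parameters),
      rates = cbind(quantity = rownames(s$rates), s$rates)
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
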
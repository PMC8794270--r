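# Builds the differentiable unconstrained log-posterior for a model variant:
# constrain -> per-step fraction matrices -> compiled forward/adjoint kernel
# -> chain rule back to parameters -> priors and transform Jacobians. This is
# the sampler's main path; the plain-R log_posterior() is the independent
# reference evaluation it is tested against.

make_posterior <- function(spec, obs, light, grid, priors, include_k0 = TRUE,
                           jacobian = TRUE) {
  layout <- theta_layout(spec, grid,
    sigma_guard = attr(priors, "sigma_guard") %||% 1e4
  )
  m <- grid$m
  j <- grid$j
  dt <- spec$dt
  t0 <- obs$times[1]
  rel <- (obs$times - t0) / dt
  if (any(abs(rel - round(rel)) > 1e-8)) {
    stop("observation times must be multiples of dt", call. = FALSE)
  }
  obs_steps <- as.integer(round(rel))
  S <- max(obs_steps)
  step_times <- t0 + seq_len(S) * dt - dt # step start times
  E <- light_at(light, step_times)
  counts_t <- t(obs$counts) # m x K
  timedep <- spec$division == "timedep"
  Bq <- if (timedep) time_spline_basis(step_times %% 24) else NULL
  cdelta <- dt / 24
  cgrow <- dt / (24 * (2^grid$delta_v - 1))
  vb <- grid$midpoints
  md <- m - j + 1L
  dividing <- j:m

  eval_lp <- function(y, need_grad = TRUE) {
    cc <- constrain_theta(y, layout)
    theta <- cc$theta
    # per-step division fractions
    Cinc <- cumsum(theta$delta_incr)
    q <- if (timedep) drop(Bq %*% theta$tau_control) else rep(1, S)
    dmat <- matrix(0, m, S)
    dmat[dividing, ] <- cdelta * theta$delta_max * outer(Cinc, q)
    # per-step growth fractions
    if (spec$fixation == "free") {
      gvec <- c(theta$gamma_max, 0)
      svec <- NULL
    } else {
      svec <- size_scaling_fixation(theta, grid, spec$fixation)
      gvec <- theta$gamma_max * svec
    }
    L <- if (theta$e_k > 0) 1 - exp(-E / theta$e_k) else as.numeric(E > 0)
    gmat <- cgrow * outer(gvec, L)
    gmat[m, ] <- 0
    # loss fractions (time-invariant)
    rho <- loss_fractions(theta, grid, dt, mode = spec$loss)

    kern <- mpm_loglik_grad_cpp(
      dmat, gmat, rho, theta$omega0, theta$sigma,
      counts_t, obs_steps, j, include_k0, need_grad
    )
    ll <- kern$loglik
    if (!is.finite(ll)) {
      return(list(value = -Inf, grad = rep(NA_real_, layout$n_unconstrained)))
    }
    lpri <- log_prior(theta, spec, priors)
    value <- ll + lpri + if (jacobian) cc$logJ else 0
    if (!need_grad) {
      return(list(value = value, grad = NULL, theta = theta, kernel = kern))
    }

    gbar <- log_prior_grad(theta, spec, priors)
    acc <- function(nm, v) {
      gbar[[nm]] <<- (gbar[[nm]] %||% 0) + v
    }
    # division chain
    Dd <- kern$d_delta[dividing, , drop = FALSE]
    acc("delta_max", cdelta * sum(Dd * outer(Cinc, q)))
    Cbar <- cdelta * theta$delta_max * drop(Dd %*% q)
    acc("delta_incr", rev(cumsum(rev(Cbar))))
    if (timedep) {
      qbar <- cdelta * theta$delta_max * drop(crossprod(Dd, Cinc))
      acc("tau_control", drop(crossprod(Bq, qbar)))
    }
    # growth chain
    Dg <- kern$d_gamma
    gvec_bar <- cgrow * drop(Dg %*% L)
    Lbar <- cgrow * drop(crossprod(Dg, gvec))
    if (theta$e_k > 0) {
      acc("e_k", sum(Lbar * (-exp(-E / theta$e_k) * E / theta$e_k^2)))
    }
    if (spec$fixation == "free") {
      acc("gamma_max", gvec_bar[seq_len(m - 1L)])
    } else {
      acc("gamma_max", sum(gvec_bar * svec))
      if (spec$fixation == "power") {
        ref <- if (theta$beta_gamma >= 0) vb[m] else vb[1]
        acc("beta_gamma", theta$gamma_max * sum(gvec_bar * svec * log(vb / ref)))
      }
    }
    # loss chain
    if (spec$loss == "basic") {
      acc("rho_max", cgrow * sum(kern$d_rho[-1L]))
    } else if (spec$loss == "free") {
      acc("rho_max", cgrow * kern$d_rho[-1L])
    }
    acc("omega0", kern$d_omega0)
    acc("sigma", kern$d_sigma)

    list(
      value = value,
      grad = pullback_grad(gbar, cc$cache, layout, jacobian = jacobian),
      theta = theta
    )
  }

  list(
    lp = function(y) eval_lp(y, need_grad = TRUE),
    lp_value = function(y) eval_lp(y, need_grad = FALSE)$value,
    layout = layout, obs_steps = obs_steps, S = S, E = E
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
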
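# No-U-Turn sampler over a differentiable log density on R^d, with
# dual-averaging step-size adaptation and diagonal mass-matrix estimation
# during warmup (windowed, Stan-style). The target function returns
# list(value, grad); non-finite values are treated as zero-probability
# regions (the proposal is rejected and the transition flagged divergent
# when the energy error explodes).

# One leapfrog step in the diagonal metric (momentum ~ N(0, M)).
leapfrog <- function(lp, q, p, grad, eps, inv_mass) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * inv_mass * p
  ev <- lp(q)
  if (!is.finite(ev$value)) {
    return(list(q = q, p = p, value = -Inf, grad = grad, ok = FALSE))
  }
  p <- p + 0.5 * eps * ev$grad
  list(q = q, p = p, value = ev$value, grad = ev$grad, ok = TRUE)
}

joint_logp <- function(value, p, inv_mass) {
  value - 0.5 * sum(p^2 * inv_mass)
}

# Recursive doubling of the trajectory (slice-sampling variant).
build_tree <- function(lp, q, p, grad, value, logu, dir, depth, eps, inv_mass,
                       H0) {
  if (depth == 0L) {
    st <- leapfrog(lp, q, p, grad, dir * eps, inv_mass)
    H <- joint_logp(st$value, st$p, inv_mass)
    n_ok <- as.integer(is.finite(H) && logu <= H)
    divergent <- !is.finite(H) || (H0 - H) > 1000
    alpha <- if (is.finite(H)) min(1, exp(H - H0)) else 0
    return(list(
      q_minus = st$q, p_minus = st$p, grad_minus = st$grad, val_minus = st$value,
      q_plus = st$q, p_plus = st$p, grad_plus = st$grad, val_plus = st$value,
      q_prop = st$q, val_prop = st$value, grad_prop = st$grad,
      n = n_ok, stop = divergent, alpha = alpha, n_alpha = 1L,
      divergent = divergent
    ))
  }
  t1 <- build_tree(lp, q, p, grad, value, logu, dir, depth - 1L, eps, inv_mass, H0)
  if (t1$stop) {
    return(t1)
  }
  if (dir == -1) {
    t2 <- build_tree(
      lp, t1$q_minus, t1$p_minus, t1$grad_minus, t1$val_minus,
      logu, dir, depth - 1L, eps, inv_mass, H0
    )
    t1$q_minus <- t2$q_minus
    t1$p_minus <- t2$p_minus
    t1$grad_minus <- t2$grad_minus
    t1$val_minus <- t2$val_minus
  } else {
    t2 <- build_tree(
      lp, t1$q_plus, t1$p_plus, t1$grad_plus, t1$val_plus,
      logu, dir, depth - 1L, eps, inv_mass, H0
    )
    t1$q_plus <- t2$q_plus
    t1$p_plus <- t2$p_plus
    t1$grad_plus <- t2$grad_plus
    t1$val_plus <- t2$val_plus
  }
  ntot <- t1$n + t2$n
  if (t2$n > 0L && stats::runif(1) < t2$n / max(ntot, 1L)) {
    t1$q_prop <- t2$q_prop
    t1$val_prop <- t2$val_prop
    t1$grad_prop <- t2$grad_prop
  }
  dq <- t1$q_plus - t1$q_minus
  uturn <- sum(dq * (inv_mass * t1$p_minus)) < 0 ||
    sum(dq * (inv_mass * t1$p_plus)) < 0
  t1$n <- ntot
  t1$stop <- t2$stop || uturn
  t1$divergent <- t1$divergent || t2$divergent
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1
}

# Heuristic initial step size: double/halve until the one-step acceptance
# probability crosses 1/2.
find_initial_stepsize <- function(lp, q, grad, value, inv_mass) {
  d <- length(q)
  eps <- 0.1
  p <- stats::rnorm(d) / sqrt(inv_mass)
  H0 <- joint_logp(value, p, inv_mass)
  st <- leapfrog(lp, q, p, grad, eps, inv_mass)
  H1 <- joint_logp(st$value, st$p, inv_mass)
  a <- if (is.finite(H1) && (H1 - H0) > log(0.5)) 1 else -1
  for (it in seq_len(50L)) {
    eps <- eps * 2^a
    st <- leapfrog(lp, q, p, grad, eps, inv_mass)
    H1 <- joint_logp(st$value, st$p, inv_mass)
    ok <- is.finite(H1) && a * (H1 - H0) > -a * log(2)
    if (!ok) break
  }
  eps
}

# Warmup schedule: step-size-only buffers at both ends, doubling
# variance-estimation windows in between (collapsed for short warmups).
warmup_windows <- function(warmup) {
  if (warmup < 60L) {
    return(list(init = warmup, ends = integer(0), term = 0L))
  }
  init <- max(15L, round(0.15 * warmup))
  term <- max(20L, round(0.10 * warmup))
  middle <- warmup - init - term
  ends <- integer(0)
  w <- max(15L, round(middle / 7))
  pos <- init
  while (middle > 0L) {
    if (middle < 2L * w) w <- middle
    pos <- pos + w
    ends <- c(ends, pos)
    middle <- middle - w
    w <- 2L * w
  }
  list(init = init, ends = ends, term = term)
}

#' One NUTS chain over a differentiable log density
#'
#' Low-level sampler used by \code{\link{fit_mpm}}; exposed so that the
#' sampler can be validated against analytically known targets.
#'
#' @param lp function of a numeric vector returning
#'   \code{list(value, grad)} (unnormalized log density and its gradient).
#' @param init initial position.
#' @param iterations total iterations (including warmup).
#' @param warmup number of adaptation iterations to discard.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth maximum trajectory doublings per iteration.
#' @return list with \code{draws} (post-warmup positions, one row per
#'   iteration), \code{logp}, \code{divergences}, \code{treedepths},
#'   \code{stepsize}, \code{inv_mass}, \code{accept_stat}.
#' @export
nuts_chain <- function(lp, init, iterations = 1000L, warmup = 500L,
                       target_accept = 0.8, max_treedepth = 10L) {
  d <- length(init)
  q <- init
  ev <- lp(q)
  if (!is.finite(ev$value)) {
    stop("log density is not finite at the initial point", call. = FALSE)
  }
  inv_mass <- rep(1, d)
  eps <- find_initial_stepsize(lp, q, ev$grad, ev$value, inv_mass)
  # dual averaging state
  mu <- log(10 * eps)
  log_eps_bar <- 0
  H_bar <- 0
  da_count <- 0L
  gamma_da <- 0.05
  t0 <- 10
  kappa <- 0.75
  sched <- warmup_windows(warmup)
  win_draws <- NULL
  win_ends <- sched$ends

  n_keep <- iterations - warmup
  draws <- matrix(NA_real_, max(n_keep, 0L), d)
  logp <- numeric(max(n_keep, 0L))
  divergences <- 0L
  treedepths <- integer(max(n_keep, 0L))
  accept_sum <- 0
  accept_n <- 0L

  value <- ev$value
  grad <- ev$grad
  for (it in seq_len(iterations)) {
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    H0 <- joint_logp(value, p0, inv_mass)
    logu <- H0 + log(stats::runif(1))
    q_minus <- q
    q_plus <- q
    p_minus <- p0
    p_plus <- p0
    grad_minus <- grad
    grad_plus <- grad
    val_minus <- value
    val_plus <- value
    q_prop <- q
    val_prop <- value
    grad_prop <- grad
    n <- 1L
    depth <- 0L
    stop_flag <- FALSE
    divergent <- FALSE
    alpha <- 0
    n_alpha <- 0L
    while (!stop_flag && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        tr <- build_tree(
          lp, q_minus, p_minus, grad_minus, val_minus, logu, dir,
          depth, eps, inv_mass, H0
        )
        q_minus <- tr$q_minus
        p_minus <- tr$p_minus
        grad_minus <- tr$grad_minus
        val_minus <- tr$val_minus
      } else {
        tr <- build_tree(
          lp, q_plus, p_plus, grad_plus, val_plus, logu, dir,
          depth, eps, inv_mass, H0
        )
        q_plus <- tr$q_plus
        p_plus <- tr$p_plus
        grad_plus <- tr$grad_plus
        val_plus <- tr$val_plus
      }
      alpha <- alpha + tr$alpha
      n_alpha <- n_alpha + tr$n_alpha
      if (!tr$stop && tr$n > 0L && stats::runif(1) < min(1, tr$n / n)) {
        q_prop <- tr$q_prop
        val_prop <- tr$val_prop
        grad_prop <- tr$grad_prop
      }
      n <- n + tr$n
      divergent <- divergent || tr$divergent
      dq <- q_plus - q_minus
      stop_flag <- tr$stop ||
        sum(dq * (inv_mass * p_minus)) < 0 ||
        sum(dq * (inv_mass * p_plus)) < 0
      depth <- depth + 1L
    }
    q <- q_prop
    value <- val_prop
    grad <- grad_prop
    accept_stat <- if (n_alpha > 0L) alpha / n_alpha else 0

    if (it <= warmup) {
      # dual averaging
      da_count <- da_count + 1L
      H_bar <- (1 - 1 / (da_count + t0)) * H_bar +
        (target_accept - accept_stat) / (da_count + t0)
      log_eps <- mu - sqrt(da_count) / gamma_da * H_bar
      w_da <- da_count^(-kappa)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      # mass-matrix windows
      if (length(win_ends)) {
        win_draws <- rbind(win_draws, q)
        if (it == win_ends[1L]) {
          nw <- nrow(win_draws)
          if (nw >= 10L) {
            v <- apply(win_draws, 2, stats::var)
            v <- v * nw / (nw + 5) + 1e-3 * (5 / (nw + 5))
            inv_mass <- v
            eps <- find_initial_stepsize(lp, q, grad, value, inv_mass)
            mu <- log(10 * eps)
            H_bar <- 0
            log_eps_bar <- log(eps)
            da_count <- 0L
          }
          win_draws <- NULL
          win_ends <- win_ends[-1L]
        }
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      idx <- it - warmup
      draws[idx, ] <- q
      logp[idx] <- value
      treedepths[idx] <- depth
      if (divergent) divergences <- divergences + 1L
      accept_sum <- accept_sum + accept_stat
      accept_n <- accept_n + 1L
    }
  }
  list(
    draws = draws, logp = logp, divergences = divergences,
    treedepths = treedepths, stepsize = eps, inv_mass = inv_mass,
    accept_stat = if (accept_n) accept_sum / accept_n else NA_real_
  )
}

#' Split-Rhat convergence diagnostic
#'
#' Plain (non-rank-normalized) split-\eqn{\hat R}: each chain is split in
#' half, and the usual between/within variance ratio is computed over the
#' resulting half-chains. Chains with zero total variance return 1 by
#' convention.
#'
#' @param chains matrix of draws, one column per chain (equal lengths, at
#'   least 4), or a list of equal-length numeric vectors.
#' @return \eqn{\hat R \ge 1} (or 1 for degenerate zero-variance input).
#' @export
compute_rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  if (ncol(chains) < 2L || n < 4L) {
    stop("need at least 2 chains of length >= 4", call. = FALSE)
  }
  half <- floor(n / 2)
  splits <- cbind(
    chains[seq_len(half), , drop = FALSE],
    chains[half + seq_len(half), , drop = FALSE]
  )
  if (max(splits) - min(splits) == 0) {
    return(1)
  }
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) {
    return(Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
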
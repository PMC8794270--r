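test_that("Dirichlet-multinomial pmf matches direct evaluation", {
  # two classes, one cell: P = omega_1 when sigma-weighting is symmetric
  expect_equal(dirichlet_multinomial_loglik(c(1, 0), c(0.5, 0.5), 2), log(0.5),
    tolerance = 1e-12
  )
  # exchangeability: common permutation leaves the value unchanged
  set.seed(4)
  n <- c(5, 0, 2, 7)
  om <- c(0.1, 0.4, 0.3, 0.2)
  p <- sample(4)
  expect_equal(
    dirichlet_multinomial_loglik(n, om, 3.7),
    dirichlet_multinomial_loglik(n[p], om[p], 3.7)
  )
  # zero mean proportion with observed counts is impossible, signaled as -Inf
  expect_identical(dirichlet_multinomial_loglik(c(1, 1), c(1, 0), 2), -Inf)
  expect_error(dirichlet_multinomial_loglik(c(1, 0), c(0.5, 0.5), 0), "positive")
})

test_that("large concentration recovers the multinomial", {
  set.seed(9)
  om <- c(0.2, 0.5, 0.3)
  n <- c(4, 11, 5)
  expect_equal(
    dirichlet_multinomial_loglik(n, om, 1e8),
    dmultinom(n, prob = om, log = TRUE),
    tolerance = 1e-5
  )
})

test_that("pmf sums to one over all outcomes (exhaustive enumeration)", {
  enumerate_counts <- function(m, N) {
    if (m == 1L) {
      return(matrix(N, 1, 1))
    }
    do.call(rbind, lapply(0:N, function(k) {
      cbind(k, enumerate_counts(m - 1L, N - k))
    }))
  }
  set.seed(21)
  for (rep in 1:4) {
    m <- sample(2:3, 1)
    N <- sample(1:5, 1)
    om <- rgamma(m, 1)
    om <- om / sum(om)
    sg <- runif(1, 0.5, 50)
    cnts <- enumerate_counts(m, N)
    total <- sum(apply(cnts, 1, function(n) {
      exp(dirichlet_multinomial_loglik(n, om, sg))
    }))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("single-observation likelihood peaks at the empirical proportions", {
  n <- c(12, 5, 3)
  grid_w <- seq(0.05, 0.9, by = 0.01)
  best <- -Inf
  best_w <- NULL
  for (w1 in grid_w) {
    for (w2 in grid_w) {
      if (w1 + w2 >= 0.999) next
      om <- c(w1, w2, 1 - w1 - w2)
      # sigma-free composition: use the multinomial limit
      ll <- dmultinom(n, prob = om, log = TRUE)
      if (ll > best) {
        best <- ll
        best_w <- om
      }
    }
  }
  expect_equal(best_w[1:2], (n / sum(n))[1:2], tolerance = 0.011)
})

test_that("doubling counts shifts the likelihood but not its maximizer", {
  om_grid <- seq(0.1, 0.9, by = 0.02)
  n1 <- c(6, 4)
  n2 <- 2L * n1
  prof <- function(n) {
    vapply(om_grid, function(w) {
      dirichlet_multinomial_loglik(n, c(w, 1 - w), 50)
    }, 0)
  }
  p1 <- prof(n1)
  p2 <- prof(n2)
  expect_identical(which.max(p1), which.max(p2))
  expect_false(isTRUE(all.equal(max(p1), max(p2))))
})

test_that("priors truncate at their bounds and match stats densities", {
  g <- ref_grid()
  spec <- model_spec("ftf")
  priors <- prior_config(spec, g)
  set.seed(15)
  th <- random_theta(spec, g)
  # at/outside a bound: -Inf
  th_bad <- th
  th_bad$e_k <- 5001
  expect_identical(log_prior(th_bad, spec, priors), -Inf)
  th_bad$e_k <- 5000
  expect_identical(log_prior(th_bad, spec, priors), -Inf)
  # manual reconstruction of every informative block
  ub <- growth_rate_bound(g$delta_v, spec$dt)
  tn <- function(x, mu, sd, lo, hi) {
    sum(dnorm(x, mu, sd, log = TRUE) -
      log(pnorm((hi - mu) / sd) - pnorm((lo - mu) / sd)))
  }
  manual <- tn(th$e_k, 1000, 1000, 0, 5000) +
    sum(dbeta(th$tau_control, 9, 1, log = TRUE)) +
    tn(th$gamma_max, th$mu_gamma, th$sigma_gamma, 0, ub) +
    tn(th$mu_gamma, 10, 10, 0, ub) +
    dexp(th$sigma_gamma, 0.1, log = TRUE) +
    tn(th$rho_max, th$mu_rho, th$sigma_rho, 0, ub) +
    tn(th$mu_rho, 10, 10, 0, ub) +
    dexp(th$sigma_rho, 0.1, log = TRUE)
  expect_equal(log_prior(th, spec, priors), manual, tolerance = 1e-10)
})

test_that("flat priors make the posterior equal the likelihood inside bounds", {
  g <- small_grid()
  spec <- model_spec("bmb", dt = 1 / 2)
  sc <- quick_scenario(seed = 3)
  dat <- generate_dataset(sc)
  th <- dat$theta
  fp <- flat_priors(spec, g)
  expect_identical(log_prior(th, spec, fp), 0)
  expect_equal(
    log_posterior(th, spec, dat$obs, dat$light, g, fp),
    log_likelihood(th, spec, dat$obs, dat$light, g)
  )
  # excluding the k = 0 term removes exactly that observation's contribution
  expect_equal(
    log_likelihood(th, spec, dat$obs, dat$light, g) -
      log_likelihood(th, spec, dat$obs, dat$light, g, include_k0 = FALSE),
    dirichlet_multinomial_loglik(dat$obs$counts[1, ], th$omega0, th$sigma)
  )
})

test_that("log posterior is finite on the interior for every model variant", {
  g <- small_grid()
  set.seed(42)
  light <- diel_par(14, 600, 1 / 2, 12)
  times <- seq(0, 12, 4)
  counts <- t(rmultinom(length(times), 5000, rep(1 / 13, 13)))
  obs <- obs_set(times, counts)
  for (nm in all_model_names()) {
    spec <- model_spec(nm, dt = 1 / 2)
    priors <- prior_config(spec, g)
    th <- random_theta(spec, g)
    lp <- log_posterior(th, spec, obs, light, g, priors)
    expect_true(is.finite(lp), label = paste("finite log posterior for", nm))
  }
})
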
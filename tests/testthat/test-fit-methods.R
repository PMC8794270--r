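# One small end-to-end fit shared by the S3-method checks: 13 size classes,
# one simulated day observed every 2 h, short two-chain run.
local({
  sc <- quick_scenario(seed = 71)
  dat <- generate_dataset(sc)
  fit <- fit_mpm(dat$obs, dat$light, sc$spec,
    grid = small_grid(),
    chains = 2, iterations = 240, warmup = 120, seed = 8
  )

  test_that("fit object carries draws, diagnostics and derived rates", {
    n_keep <- 120 * 2
    expect_equal(nrow(fit$draws), n_keep)
    expect_identical(colnames(fit$draws)[1], "delta_max")
    expect_true(all(is.finite(fit$rhat)))
    expect_true(all(fit$rhat >= 1 - 1e-8))
    expect_named(
      fit$derived,
      c(
        "mu_daily", "daily_fixation", "daily_loss", "p_max", "e_k",
        "sigma", "draw"
      )
    )
    expect_true(all(fit$derived$mu_daily >= 0))
    expect_true(all(fit$derived$daily_fixation >= 0))
    expect_true(all(fit$derived$p_max >= fit$derived$daily_fixation - 1e-9))
    # every stored draw satisfies the parameter invariants
    i <- sample(nrow(fit$draws), 5)
    for (k in i) {
      th <- sizempm:::theta_to_list(fit$draws[k, ], fit$layout)
      expect_silent(validate_theta(th, fit$spec, fit$grid, tol = 1e-6))
    }
  })

  test_that("print, summary and coef expose the posterior surface", {
    expect_output(print(fit), "m_bmb")
    expect_output(print(fit), "daily division")
    s <- summary(fit)
    expect_s3_class(s, "summary.mpm_fit")
    expect_true(all(c("median", "rhat") %in% names(s$parameters)))
    expect_identical(rownames(s$rates)[1], "mu_daily")
    expect_output(print(s), "posterior summary")
    cf <- coef(fit)
    expect_named(cf)
    expect_equal(unname(cf["sigma"]), median(fit$draws[, "sigma"]))
  })

  test_that("predict, fitted and residuals work on the observation lattice", {
    tr <- predict(fit)
    expect_s3_class(tr, "mpm_trajectory")
    expect_equal(tr$times, fit$obs$times)
    expect_equal(rowSums(tr$omegas), rep(1, length(fit$obs$times)),
      tolerance = 1e-10
    )
    r <- residuals(fit)
    expect_equal(dim(r), dim(fit$obs$proportions))
    expect_equal(r, fit$obs$proportions - fitted(fit))
    tr2 <- predict(fit, times = seq(0, 12, 2))
    expect_equal(tr2$times, seq(0, 12, 2))
  })

  test_that("posterior-predictive simulation returns matching count sets", {
    sims <- simulate(fit, nsim = 2, seed = 123)
    expect_length(sims, 2)
    for (s in sims) {
      expect_s3_class(s, "obs_set")
      expect_equal(s$times, fit$obs$times)
      expect_equal(s$totals, fit$obs$totals)
    }
    sims2 <- simulate(fit, nsim = 2, seed = 123)
    expect_identical(sims[[1]]$counts, sims2[[1]]$counts)
  })

  test_that("plot method renders without error", {
    pdf(NULL)
    on.exit(dev.off())
    expect_silent(plot(fit, n_draws = 10))
  })

  test_that("draws and summaries export to CSV and JSON", {
    csv <- withr::local_tempfile(fileext = ".csv")
    write_draws(fit, csv)
    df <- read.csv(csv)
    expect_named(df, c("chain", "iteration", "parameter", "value"))
    expect_equal(nrow(df), nrow(fit$draws) * ncol(fit$draws))
    js <- withr::local_tempfile(fileext = ".json")
    write_summary_json(fit, js)
    j <- jsonlite::read_json(js)
    expect_identical(j$model, "bmb")
    expect_equal(j$config$seed, 8)
    expect_true(length(j$parameters) == ncol(fit$draws))
  })
})
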
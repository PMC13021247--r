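# Wiener first-passage density, absorption probabilities, trial simulator
# and contaminant-mixture likelihood.

test_that("parameter validation rejects out-of-domain values", {
  expect_error(ddm_params(v = 1, a = -1, z = 0.5, t0 = 0.3), "boundary")
  expect_error(ddm_params(v = 1, a = 2, z = 1.2, t0 = 0.3), "starting point")
  expect_error(ddm_params(v = 1, a = 2, z = 0, t0 = 0.3), "starting point")
  expect_error(ddm_params(v = 1, a = 2, z = 0.5, t0 = -0.1), "nondecision")
  expect_error(ddm_params(v = 1, a = 2, z = 0.5, t0 = 0.3, p_out = 1),
               "contaminant")
})

test_that("density is zero before the nondecision time", {
  p <- ddm_params(v = 0, a = 2, z = 0.5, t0 = 0.3)
  rts <- c(0.05, 0.1, 0.2, 0.29999, 0.3)
  expect_equal(wfpt_density(rts, 1, p), rep(0, 5))
  expect_equal(wfpt_density(rts, 0, p), rep(0, 5))
})

test_that("upper and lower defective densities integrate to one", {
  grid <- expand.grid(a = c(0.5, 1.5, 4), v = c(-4, -1, 0, 1, 4),
                      z = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    p <- ddm_params(v = grid$v[i], a = grid$a[i], z = grid$z[i], t0 = 0.2)
    iu <- integrate(function(t) wfpt_density(t, 1, p), 0.2, Inf,
                    rel.tol = 1e-8)$value
    il <- integrate(function(t) wfpt_density(t, 0, p), 0.2, Inf,
                    rel.tol = 1e-8)$value
    expect_lt(abs(iu + il - 1), 1e-4)
    # and the upper mass equals the closed-form absorption probability
    expect_lt(abs(iu - choice_probability(p, "upper")), 1e-4)
  }
})

test_that("lower-boundary density is the reflected upper-boundary density", {
  tt <- seq(0.31, 5, by = 0.07)
  for (v in c(-2, 0.3, 1.5)) for (z in c(0.3, 0.52, 0.7)) {
    p1 <- ddm_params(v = v, a = 1.8, z = z, t0 = 0.3)
    p2 <- ddm_params(v = -v, a = 1.8, z = 1 - z, t0 = 0.3)
    expect_identical(wfpt_density(tt, 1, p1), wfpt_density(tt, 0, p2))
  }
})

test_that("small-time and large-time series agree in the overlap region", {
  tt <- seq(0.35, 4, by = 0.05)
  for (v in c(-1.5, 0, 2)) for (z in c(0.2, 0.5, 0.65)) {
    p <- ddm_params(v = v, a = 2, z = z, t0 = 0.3)
    d_small <- wfpt_density(tt, 1, p, regime = "small")
    d_large <- wfpt_density(tt, 1, p, regime = "large")
    expect_lt(max(abs(d_small - d_large)), 1e-6)
  }
})

test_that("density and absorption probability match a brute-force Euler simulation", {
  # independent oracle: explicit Euler time stepping at a fine step
  p <- ddm_params(v = 1, a = 1.5, z = 0.5, t0 = 0.3)
  n <- 4e4
  sim <- ddmpse:::simulate_ddm_euler(p, n, seed = 101, dt = 1e-5)
  # absorption probability within 4 binomial SEs
  p_up <- choice_probability(p, "upper")
  se <- sqrt(p_up * (1 - p_up) / n)
  expect_lt(abs(mean(sim$choice) - p_up), 4 * se)
  # density at a few response times: simulated bin mass vs integrated density
  for (tc in c(0.5, 0.8, 1.5)) {
    lo <- tc - 0.05; hi <- tc + 0.05
    p_bin <- integrate(function(t) wfpt_density(t, 1, p), lo, hi,
                       rel.tol = 1e-8)$value
    obs <- mean(sim$rt >= lo & sim$rt < hi & sim$choice == 1)
    se_bin <- sqrt(p_bin * (1 - p_bin) / n)
    expect_lt(abs(obs - p_bin), 4 * se_bin + 0.02 * p_bin)
  }
})

test_that("zero-drift absorption probability equals the relative starting point", {
  expect_equal(choice_probability(ddm_params(0, 2, 0.5, 0.3)), 0.5)
  expect_equal(choice_probability(ddm_params(0, 1.6, 0.52, 0.3)), 0.52)
  p <- ddm_params(0.8, 1.7, 0.4, 0.3)
  expect_equal(choice_probability(p, "upper") + choice_probability(p, "lower"), 1)
})

test_that("simulated trials respect drift strength and the nondecision floor", {
  s <- simulate_ddm_trials(ddm_params(5, 1.5, 0.5, 0.3), 1e4, seed = 2)
  expect_gt(mean(s$choice), 0.95)
  expect_gte(min(s$rt), 0.3)
  expect_error(simulate_ddm_trials(ddm_params(1, 1, 0.5, 0.3), 0), "count")
  # reproducible given seed
  s2 <- simulate_ddm_trials(ddm_params(5, 1.5, 0.5, 0.3), 1e4, seed = 2)
  expect_identical(s, s2)
})

test_that("simulator choice fractions are consistent with choice_probability", {
  for (pars in list(c(1, 2, 0.5), c(-0.8, 1.4, 0.6), c(0, 1.6, 0.52))) {
    p <- ddm_params(pars[1], pars[2], pars[3], 0.3)
    s <- simulate_ddm_trials(p, 1e5, seed = 7)
    p_up <- choice_probability(p, "upper")
    se <- sqrt(p_up * (1 - p_up) / 1e5)
    expect_lt(abs(mean(s$choice) - p_up), 3 * se + 1e-4)
  }
})

test_that("simulated RTs match the density-implied distribution (KS < 0.01)", {
  sets <- list(c(1, 2, 0.5, 0.3), c(-1.5, 1.2, 0.4, 0.2),
               c(0.5, 3, 0.6, 0.4), c(0, 1.6, 0.52, 0.35),
               c(2.5, 0.8, 0.3, 0.25))
  for (pars in sets) {
    p <- ddm_params(pars[1], pars[2], pars[3], pars[4])
    s <- simulate_ddm_trials(p, 1e5, seed = 11)
    # density-implied CDF of the upper-boundary decision time, computed on an
    # independent uniform grid by trapezoid integration
    x <- sort(s$rt[s$choice == 1] - p$t0)
    hi <- max(x) * 1.05
    tg <- seq(0, hi, length.out = 20001)
    d <- wfpt_density(tg + p$t0, 1, p)
    cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2) * (tg[2] - tg[1]))
    cdf <- cdf / choice_probability(p, "upper")
    theo <- approx(tg, cdf, xout = x, rule = 2)$y
    ks <- max(abs(theo - seq_along(x) / length(x)),
              abs(theo - (seq_along(x) - 1) / length(x)))
    expect_lt(ks, 0.01)
  }
})

test_that("mixture likelihood reduces to the density and floors contaminants", {
  p0 <- ddm_params(1, 2, 0.5, 0.3, p_out = 0)
  tr <- data.frame(choice = 1L, rt = 0.8)
  expect_equal(ddm_loglik(tr, p0, t_max = 3), log(wfpt_density(0.8, 1, p0)))
  # rt before t0 with p_out = 0: reported as -Inf
  expect_identical(ddm_loglik(data.frame(choice = 1L, rt = 0.2), p0,
                              t_max = 3), -Inf)
  # with the contaminant floor: exactly the uniform component
  p5 <- ddm_params(1, 2, 0.5, 0.3, p_out = 0.05)
  expect_equal(ddm_loglik(data.frame(choice = 1L, rt = 0.2), p5, t_max = 3),
               log(0.05 * (1 / 3) / 2))
  expect_error(ddm_loglik(data.frame(choice = integer(0), rt = numeric(0)), p0),
               "non-empty")
})

test_that("likelihood concentrates at the generating parameters", {
  p_true <- ddm_params(1, 1.8, 0.55, 0.3, p_out = 0)
  p_hi <- ddm_params(2, 1.8, 0.55, 0.3, p_out = 0)
  p_lo <- ddm_params(0, 1.8, 0.55, 0.3, p_out = 0)
  wins <- 0L
  for (r in 1:20) {
    tr <- simulate_ddm_trials(p_true, 100, seed = 300 + r)
    ll <- ddm_loglik(tr, p_true, t_max = 5)
    if (ll > ddm_loglik(tr, p_hi, t_max = 5) &&
        ll > ddm_loglik(tr, p_lo, t_max = 5)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
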
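# Synthetic experiment generator: morph-to-drift map, design balance,
# determinism and contaminant injection.

test_that("morph-to-drift map is antisymmetric and anchored", {
  expect_equal(morph_to_drift(50, 3), 0)
  expect_equal(morph_to_drift(100, 2), 2)
  expect_equal(morph_to_drift(0, 2), -2)
  grid <- c(0, 20, 35, 45, 55, 65, 80, 100)
  v <- morph_to_drift(grid, 2)
  expect_true(all(diff(v) > 0))
  expect_equal(v + rev(v), rep(0, 8))   # pairs (45,55), (35,65), (20,80), (0,100)
})

test_that("generated experiments have balanced design and counterbalancing", {
  cfg <- experiment_config(1, n_per_cell = 3, seed = 4, fast_frac = 0,
                           outlier_frac = 0)
  ex <- generate_experiment(cfg)
  expect_equal(nrow(ex$trials), 6 * 560)
  expect_equal(length(unique(ex$trials$participant)), 6)
  # every morph level exactly 70 times per participant, 10 per block
  m <- table(ex$trials$participant, ex$trials$morph_pct_self)
  expect_true(all(m == 70))
  mb <- table(ex$trials$participant, ex$trials$block,
              ex$trials$morph_pct_self)
  expect_true(all(mb == 10))
  # balanced condition assignment and counterbalancing factors recorded
  expect_equal(as.integer(table(ex$trials$condition)), c(1680L, 1680L))
  expect_setequal(unique(ex$trials$pencil_is_self), c(TRUE, FALSE))
  expect_setequal(unique(ex$trials$key_self), c("C", "M"))
  # ground truth emitted per participant
  expect_equal(nrow(ex$truth), 6)
  expect_true(all(c("z", "a", "t0", "v_max") %in% names(ex$truth)))
})

test_that("identical config and seed give byte-identical tables", {
  cfg <- experiment_config(2, n_per_cell = 2, blocks = 2, seed = 99)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$truth, e2$truth)
})

test_that("config validation rejects unbalanced grids and bad fractions", {
  expect_error(experiment_config(1, trials_per_block = 81), "equally often")
  expect_error(experiment_config(1, fast_frac = 0.5), "fractions")
  expect_error(experiment_config(3), "experiment")
})

test_that("contaminant injection produces material for the filter", {
  cfg <- experiment_config(1, n_per_cell = 3, blocks = 3, seed = 14,
                           fast_frac = 0, outlier_frac = 0)
  ex <- generate_experiment(cfg)
  # without fast guesses nothing falls below the 200 ms threshold
  expect_gt(min(ex$trials$rt_s), 0.2)
  con <- inject_contaminants(ex$trials, fast_frac = 0.04,
                             outlier_frac = 0.04, seed = 1)
  expect_equal(sum(con$rt_s < 0.2), round(0.04 * nrow(con)))
  expect_equal(nrow(con), nrow(ex$trials))
  expect_error(inject_contaminants(ex$trials, fast_frac = 0.2), "fractions")
})

test_that("an unbiased generator is symmetric around the midpoint", {
  coh <- simulate_cohort(6, "own", list(z = 0.5, v_max = 1.9, a = 1.6,
                                        t0 = 0.35),
                         trials_per_morph = 60, sd_frac = 0, seed = 3)
  d <- coh$trials
  # pooled P(self) at the innermost pair (45/55) averages to ~0.5
  sel <- d$morph_pct_self %in% c(45, 55)
  p_mid <- mean(d$response[sel])
  expect_lt(abs(p_mid - 0.5), 3 * sqrt(0.25 / sum(sel)) + 0.005)
  # and the full pooled self rate is ~0.5 by antisymmetry
  expect_lt(abs(mean(d$response) - 0.5), 0.02)
})

test_that("a self-ward starting-point bias shifts the fitted PSE leftward", {
  shifts <- vapply(1:3, function(r) {
    coh <- simulate_cohort(6, "own", list(z = 0.56, v_max = 1.74, a = 1.6,
                                          t0 = 0.35),
                           trials_per_morph = 40, sd_frac = 0,
                           seed = 800 + r)
    fits <- fit_participants(coh$trials)
    mean(fits$pse)
  }, numeric(1))
  expect_true(all(shifts < 50))
})

test_that("per-parameter SD control fixes chosen parameters across subjects", {
  coh <- simulate_cohort(4, "own", list(z = 0.5, v_max = 1.9, a = 1.6,
                                        t0 = 0.35),
                         trials_per_morph = 2,
                         sd_frac = c(z = 0, a = 0.1, t0 = 0.1, v_max = 0.1),
                         seed = 2)
  expect_equal(coh$truth$z, rep(0.5, 4))
  expect_gt(sd(coh$truth$a), 0)
})
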
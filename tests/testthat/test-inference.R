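# Design construction, hierarchical sampling, DIC, directional
# probabilities and Bayes-factor arithmetic.

test_that("design maps trials to the model's parameter cells", {
  cfg <- experiment_config(1, n_per_cell = 2, blocks = 1, seed = 6,
                           fast_frac = 0, outlier_frac = 0)
  ex <- generate_experiment(cfg)
  des <- build_design(ex$trials, "M2")
  expect_equal(length(des$v_labels), 16)    # 2 judgments x 8 morphs
  expect_equal(des$n_z_cells, 2L)
  expect_equal(des$n_a_cells, 1L)
  des3 <- build_design(ex$trials, "M3")
  expect_equal(des3$n_a_cells, 2L)
  des1 <- build_design(ex$trials, "M1")
  expect_equal(des1$n_z_cells, 0L)
  expect_false(des1$model$z_free)
  # single-condition data: z map collapses to one free cell
  one <- ex$trials[ex$trials$condition == "ownership", ]
  expect_equal(build_design(one, "M2")$n_z_cells, 1L)
  # between-subject violation is caught
  bad <- ex$trials
  bad$condition[bad$participant == bad$participant[1]][1:5] <- "identity"
  expect_error(build_design(bad, "M2"), "between-subject")
})

test_that("model family is nested with identical likelihoods at shared values", {
  coh <- shared_cohort()
  d1 <- build_design(coh$trials, "M1")
  d2 <- build_design(coh$trials, "M2")
  v <- matrix(rnorm(d1$S * d1$C), d1$S, d1$C)
  zt <- rep(0, d1$S)  # z = 0.5: the value M1 pins
  la <- rep(log(1.6), d1$S); lt0 <- rep(log(0.3), d1$S)
  ll1 <- ddmpse:::loglik_cells_cpp(d1$rt, d1$choice, d1$off, v, zt, la, lt0,
                                   0.05, 3)
  ll2 <- ddmpse:::loglik_cells_cpp(d2$rt, d2$choice, d2$off, v, zt, la, lt0,
                                   0.05, 3)
  expect_identical(sum(ll1), sum(ll2))
})

test_that("relabeling the boundaries maps the likelihood to (-v, 1-z)", {
  p <- ddm_params(v = 0.8, a = 1.7, z = 0.6, t0 = 0.3, p_out = 0.05)
  p_flip <- ddm_params(v = -0.8, a = 1.7, z = 0.4, t0 = 0.3, p_out = 0.05)
  tr <- simulate_ddm_trials(p, 500, seed = 17)
  tr_flip <- data.frame(choice = 1L - tr$choice, rt = tr$rt)
  expect_identical(ddm_loglik(tr, p, t_max = 4),
                   ddm_loglik(tr_flip, p_flip, t_max = 4))
})

test_that("the hierarchical fit recovers group-level generative values", {
  coh <- shared_cohort()           # group z = 0.55, v_max = 1.74, a = 1.6
  fit <- shared_fit()
  z_hat <- mean(ddmpse:::group_draws(fit, "z", "ownership"))
  expect_lt(abs(z_hat - mean(coh$truth$z)), 0.03)
  a_hat <- mean(ddmpse:::group_draws(fit, "a"))
  expect_lt(abs(a_hat - mean(coh$truth$a)), 0.15)
  t0_hat <- mean(ddmpse:::group_draws(fit, "t0"))
  expect_lt(abs(t0_hat - mean(coh$truth$t0)), 0.05)
  # morph-resolved drift recovered up to pooled noise
  v_hat <- colMeans(fit$group$v[ddmpse:::post_idx(fit), ])
  v_true <- morph_to_drift(fit$design$morphs, mean(coh$truth$v_max))
  expect_gt(cor(v_hat, v_true), 0.98)
  expect_lt(sqrt(mean((v_hat - v_true)^2)), 0.3)
})

test_that("fits are deterministic given the seed and DIC follows", {
  coh <- simulate_cohort(3, "own", list(z = 0.52, v_max = 1.74, a = 1.6,
                                        t0 = 0.35),
                         trials_per_morph = 10, seed = 2)
  f1 <- fit_hddm(coh$trials, "M2", 200, 50, seed = 33, check_rhat = FALSE)
  f2 <- fit_hddm(coh$trials, "M2", 200, 50, seed = 33, check_rhat = FALSE)
  expect_identical(f1$deviance, f2$deviance)
  expect_identical(compute_dic(f1)$dic, compute_dic(f2)$dic)
  expect_error(fit_hddm(coh$trials, "M2", 200, 200), "n_burn")
})

test_that("directional probabilities follow the draw geometry", {
  # total separation: all ownership draws above identity draws
  f <- fake_z_fit(list(ownership = seq(0.54, 0.56, length.out = 100),
                       identity = seq(0.48, 0.50, length.out = 100)))
  expect_equal(directional_prob(f, "z", "ownership", "identity"), 0)
  # identical marginals: equipoise up to draw pairing
  g <- fake_z_fit(list(a = rep(c(0.5, 0.52), 50), b = rep(c(0.52, 0.5), 50)))
  expect_equal(directional_prob(g, "z", "a", "b"), 0.5)
  # threshold form
  expect_equal(directional_prob(f, "z", "identity", threshold = 0.5), 1)
  expect_error(directional_prob(f, "z", "nope", threshold = 0.5), "unknown")
  expect_error(directional_prob(f, "z", "ownership"), "supply")
})

test_that("a strong generating bias yields a small p_Bayes for z > 0.5", {
  fit <- shared_fit()   # generated at group z = 0.55
  p <- directional_prob(fit, "z", "ownership", threshold = 0.5)
  expect_lt(p, 0.05)
})

test_that("Bayes-factor arithmetic reproduces the reported pairs", {
  pairs <- list(c(0.045, 21), c(0.002, 499), c(0.019, 52), c(0.081, 11),
                c(0.110, 8))
  for (pr in pairs)
    expect_equal(round(bayes_factor(pr[1])), pr[2])
  expect_equal(bayes_factor(0.5), 1)
  expect_identical(format_bf10(0), "> 999")
  expect_identical(format_bf10(0.0005), "> 999")
  expect_identical(format_bf10(0.045), "21")
  expect_error(bayes_factor(-0.1), "0, 1")
})

test_that("split-R-hat flags trending chains and passes stationary ones", {
  set.seed(9)
  expect_lt(split_rhat(rnorm(1000)), 1.02)
  expect_gt(split_rhat(seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1)),
            1.2)
})

test_that("condition-mean drift summaries fold the morph cells", {
  fit <- shared_fit()
  dm <- drift_condition_means(fit)
  expect_equal(nrow(dm), 1)
  # generating folded mean = v_max / 2 under the linear map
  expect_lt(abs(dm$mean - mean(shared_cohort()$truth$v_max) / 2), 0.15)
})
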
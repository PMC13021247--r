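# Fast-guess filtering, cumulative-logistic fitting, PSE extraction,
# random-responder exclusion and group-level tests.

test_that("fast-guess filter removes rt < 200 ms and reports fractions", {
  tr <- data.frame(participant = c("a", "a", "b"), condition = "c",
                   morph_pct_self = 45, response = 1,
                   rt_s = c(0.150, 0.250, 0.500))
  out <- filter_trials(tr)
  expect_equal(out$trials$rt_s, c(0.250, 0.500))
  expect_equal(out$report$n_removed[out$report$participant == "a"], 1)
  # all-kept input is an identity mapping
  tr2 <- tr[tr$rt_s >= 0.2, ]
  expect_identical(filter_trials(tr2)$trials, tr2)
})

test_that("about 1% of trials are removed when 1% fast guesses are injected", {
  cfg <- experiment_config(1, n_per_cell = 4, blocks = 2, seed = 8,
                           fast_frac = 0.01, outlier_frac = 0)
  ex <- generate_experiment(cfg)
  out <- filter_trials(ex$trials)
  frac <- sum(out$report$n_removed) / sum(out$report$n_total)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.016)
})

test_that("logistic fit recovers a symmetric step at the midpoint", {
  m <- rep(c(0, 20, 35, 45, 55, 65, 80, 100), each = 10)
  y <- as.integer(m > 50)
  cv <- suppressWarnings(fit_logistic(m, y))
  expect_equal(cv$alpha, 50, tolerance = 1e-4)
  expect_equal(pse(cv), cv$alpha)
})

test_that("logistic fit recovers generative locations without material bias", {
  errs <- vapply(1:20, function(r) {
    set.seed(400 + r)
    m <- rep(c(0, 20, 35, 45, 55, 65, 80, 100), each = 70)
    y <- rbinom(length(m), 1, plogis(0.15 * (m - 45)))
    fit_logistic(m, y)$alpha - 45
  }, numeric(1))
  expect_true(all(abs(errs) < 2))
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("PSE is invariant to relabeling the response axis", {
  set.seed(21)
  m <- rep(c(0, 20, 35, 45, 55, 65, 80, 100), each = 40)
  y <- rbinom(length(m), 1, plogis(0.12 * (m - 47)))
  cv <- fit_logistic(m, y)
  cv_flip <- fit_logistic(m, 1L - y)
  expect_equal(cv_flip$alpha, cv$alpha, tolerance = 1e-6)
  expect_equal(cv_flip$beta_raw, -cv$beta_raw, tolerance = 1e-6)
  expect_gt(cv$beta, 0)
  expect_gt(cv_flip$beta, 0)  # orientation normalized
})

test_that("symmetric responses give a PSE at the grid midpoint", {
  grid <- c(0, 20, 35, 45, 55, 65, 80, 100)
  # exact symmetry: response counts mirrored around 50
  m <- rep(grid, each = 10)
  k <- c(1, 2, 3, 4, 6, 7, 8, 9)           # successes of 10, antisymmetric
  y <- unlist(lapply(seq_along(grid), function(i)
    rep(c(1L, 0L), c(k[i], 10 - k[i]))))
  cv <- fit_logistic(m, y)
  expect_equal(cv$alpha, 50, tolerance = 1e-6)
})

test_that("random responders are excluded, steep observers kept", {
  grid <- c(0, 20, 35, 45, 55, 65, 80, 100)
  m <- rep(grid, each = 70)
  set.seed(31)
  flat <- data.frame(participant = "flat", condition = "c",
                     morph_pct_self = m, response = rbinom(560, 1, 0.5),
                     rt_s = 0.5)
  steep <- data.frame(participant = "steep", condition = "c",
                      morph_pct_self = m,
                      response = rbinom(560, 1, plogis(0.2 * (m - 50))),
                      rt_s = 0.5)
  fits <- fit_participants(rbind(flat, steep))
  exc <- exclude_random_responders(fits)
  expect_identical(exc$excluded$participant, "flat")
  expect_identical(exc$kept$participant, "steep")
})

test_that("coin-flip responders are flagged in nearly all replicates", {
  grid <- c(0, 20, 35, 45, 55, 65, 80, 100)
  m <- rep(grid, each = 70)
  flagged <- vapply(1:40, function(r) {
    set.seed(500 + r)
    tr <- data.frame(participant = "p", condition = "c", morph_pct_self = m,
                     response = rbinom(560, 1, 0.5), rt_s = 0.5)
    fits <- fit_participants(tr)
    nrow(exclude_random_responders(fits)$excluded) == 1
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("group tests report shifts against the midpoint and between conditions", {
  f1 <- data.frame(participant = letters[1:4], condition = "own",
                   pse = c(45, 45, 45, 45))
  f2 <- data.frame(participant = letters[5:8], condition = "id",
                   pse = c(45, 45, 45, 45))
  g <- group_pse_tests(rbind(f1, f2))
  expect_true(all(g$by_condition$t < 0 | !is.finite(g$by_condition$t)))
  expect_equal(g$between$delta_m, 0)
  expect_equal(g$between$t, 0)
  # uniform shift: large standardized effect
  f3 <- data.frame(participant = letters[1:5], condition = "own",
                   pse = c(44, 45, 46, 45, 45))
  g3 <- group_pse_tests(f3)
  expect_lt(g3$by_condition$t, 0)
  expect_lt(g3$by_condition$d, -3)
  expect_error(group_pse_tests(data.frame(participant = "a",
                                          condition = "x", pse = 45)),
               "participants")
  # pooled-variance df bookkeeping: n1 + n2 - 2
  expect_equal(g$between$df, 4 + 4 - 2)
})

test_that("cohorts at reported condition summaries reproduce the group shift", {
  # sampling simulation at reported means/SDs: ownership 45 (SD 12, n 35)
  # vs identity 52 (SD 12, n 39) should show the ~7-point separation and a
  # significant shift in most replicates
  deltas <- numeric(6); sig <- logical(6)
  for (r in 1:6) {
    own <- simulate_logistic_cohort(35, 45, 12, trials_per_morph = 30,
                                    condition = "ownership", seed = 600 + r)
    ident <- simulate_logistic_cohort(39, 52, 12, trials_per_morph = 30,
                                      condition = "identity", seed = 700 + r)
    fits <- fit_participants(rbind(own$trials, ident$trials))
    g <- group_pse_tests(fits)
    m <- setNames(g$by_condition$mean_pse, g$by_condition$condition)
    deltas[r] <- m["identity"] - m["ownership"]
    sig[r] <- g$between$p < 0.05
  }
  expect_lt(abs(mean(deltas) - 7), 2)
  expect_gte(sum(sig), 4)
})
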
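# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# one biased-ownership cohort: 8 subjects x 240 trials, group z = 0.55
shared_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- simulate_cohort(
      8, "ownership", list(z = 0.55, v_max = 1.74, a = 1.6, t0 = 0.35),
      trials_per_morph = 30, seed = 5)
  .fixtures$cohort
}

# fast M2 fit of the shared cohort, reused by inference and evaluation tests
shared_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- fit_hddm(shared_cohort()$trials, "M2", n_samples = 800,
                              n_burn = 200, seed = 1, check_rhat = FALSE)
  .fixtures$fit
}

# minimal stand-in fit object for directional-probability arithmetic
fake_z_fit <- function(z_draws_by_cond, conditions = names(z_draws_by_cond)) {
  n <- length(z_draws_by_cond[[1]])
  structure(list(
    model = hddm_model("M2"),
    design = list(conditions = conditions, n_a_cells = 1L,
                  morphs = c(0, 100), C = 2L,
                  v_labels = sprintf("v[%s,%g]", rep(conditions, each = 2),
                                     c(0, 100))),
    group = list(z = qlogis(do.call(cbind, z_draws_by_cond))),
    meta = list(n_samples = n, n_burn = 0L)
  ), class = "hddm_fit")
}
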
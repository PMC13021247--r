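# Synthetic replicates of the two morph-continuum classification
# experiments: factorial design, counterbalancing, and diffusion-generated
# choices and response times, with ground truth for recovery studies.

MORPH_GRID <- c(0, 20, 35, 45, 55, 65, 80, 100)

#' Linear morph-to-drift map
#'
#' `v = v_max * (2 * morph/100 - 1)`: antisymmetric about the 50% midpoint,
#' positive toward the self boundary, magnitude growing as ambiguity
#' decreases. This is the generative convenience used by the simulator; the
#' inference models still fit one free drift per morph cell.
#'
#' @param morph Morph level(s) in % self.
#' @param v_max Drift magnitude at the continuum anchors.
#' @return Drift rate(s).
#' @export
morph_to_drift <- function(morph, v_max) {
  v_max * (2 * morph / 100 - 1)
}

#' Configuration of a synthetic experiment
#'
#' Encodes the factorial designs of the two experiments: two between-subject
#' conditions (Experiment 1: ownership vs identity judgment; Experiment 2:
#' short vs long exposure), 8 morph levels, 7 blocks of 80 trials with every
#' stimulus shown 10 times per block (560 trials, 70 per morph level per
#' participant), and roughly 40 participants per condition.
#'
#' Default generative group means encode the fitted signatures of the
#' manipulations: an unbiased starting point for the identity judgment
#' (z = 0.50) versus a self-ward bias for ownership (z = 0.52), and drift
#' scales chosen so the sign-folded condition-mean drifts reproduce the
#' reported condition means (0.95/0.87 for Experiment 1, 1.05/0.99 for
#' Experiment 2) under the linear morph map. Boundary separation (1.6) and
#' nondecision time (0.35 s) are realistic values for speeded two-choice
#' classification; between-subject SDs are 10% of each mean.
#'
#' @param experiment 1 or 2.
#' @param n_per_cell Participants per between-subject condition.
#' @param blocks,trials_per_block Block structure; `blocks *
#'   trials_per_block / length(morph_grid)` must be an integer.
#' @param morph_grid Morph levels in % self.
#' @param group_params Named list per condition with elements `z`, `v_max`,
#'   `a`, `t0` (group means); `NULL` uses the defaults above.
#' @param sd_frac Between-subject SD as a fraction of each group mean.
#' @param fast_frac Fraction of trials replaced by fast guesses
#'   (rt ~ U(0.05, 0.2), random choice).
#' @param outlier_frac Fraction replaced by slow uniform outliers
#'   (rt ~ U(0.2, 5), random choice).
#' @param seed Top-level seed governing all randomness.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = 1, n_per_cell = 40, blocks = 7,
                              trials_per_block = 80, morph_grid = MORPH_GRID,
                              group_params = NULL, sd_frac = 0.1,
                              fast_frac = 0.01, outlier_frac = 0.02,
                              seed = 1) {
  stopifnot(experiment %in% c(1, 2), n_per_cell >= 1, blocks >= 1)
  if (trials_per_block %% length(morph_grid) != 0)
    stop("each morph level must appear equally often within a block",
         call. = FALSE)
  if (is.null(group_params)) {
    group_params <- if (experiment == 1) {
      list(ownership = list(z = 0.52, v_max = 1.74, a = 1.6, t0 = 0.35),
           identity  = list(z = 0.50, v_max = 1.90, a = 1.6, t0 = 0.35))
    } else {
      list(short = list(z = 0.53, v_max = 2.10, a = 1.6, t0 = 0.35),
           long  = list(z = 0.52, v_max = 1.98, a = 1.6, t0 = 0.35))
    }
  }
  stopifnot(length(group_params) >= 1, !is.null(names(group_params)))
  if (fast_frac < 0 || fast_frac > 0.1 || outlier_frac < 0 || outlier_frac > 0.1)
    stop("contaminant fractions must lie in [0, 0.1]", call. = FALSE)
  structure(list(experiment = experiment, n_per_cell = n_per_cell,
                 blocks = blocks, trials_per_block = trials_per_block,
                 morph_grid = sort(morph_grid), group_params = group_params,
                 sd_frac = sd_frac, fast_frac = fast_frac,
                 outlier_frac = outlier_frac, seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment %d config: %d participants/condition (%s), %d blocks x %d trials, seed %d\n",
              x$experiment, x$n_per_cell,
              paste(names(x$group_params), collapse = "/"),
              x$blocks, x$trials_per_block, x$seed))
  invisible(x)
}

# truncated-normal subject draw (simple rejection; bounds generous)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a cohort of diffusion-model participants
#'
#' Draws subject-level parameters from the group distributions and simulates
#' balanced morph-level trials per subject through [simulate_ddm_trials()]
#' with the linear morph-to-drift map. This is the core used by
#' [generate_experiment()]; it is also useful directly for recovery studies
#' of a single condition.
#'
#' @param n_subjects Number of participants.
#' @param condition Condition label attached to all trials.
#' @param group List with group means `z`, `v_max`, `a`, `t0`.
#' @param trials_per_morph Trials per morph level per participant.
#' @param morph_grid Morph levels.
#' @param sd_frac Between-subject SD as a fraction of each mean: a scalar,
#'   or a named vector with any of `z`, `a`, `t0`, `v_max` to control each
#'   parameter separately (0 gives identical subjects on that parameter).
#' @param seed Integer seed.
#' @param id_prefix Prefix for participant identifiers.
#' @return A list with `trials` (participant, condition, morph_pct_self,
#'   response, rt_s) and `truth` (subject-level generative parameters).
#' @export
simulate_cohort <- function(n_subjects, condition, group,
                            trials_per_morph = 70, morph_grid = MORPH_GRID,
                            sd_frac = 0.1, seed = 1, id_prefix = "s") {
  set.seed(as.integer(seed))
  sf <- function(p) {
    if (length(sd_frac) == 1L && is.null(names(sd_frac))) return(sd_frac)
    if (p %in% names(sd_frac)) unname(sd_frac[p]) else 0.1
  }
  draw <- function(p, lo, hi) {
    s <- sf(p) * group[[p]]
    if (s == 0) rep(group[[p]], n_subjects)
    else rtrunc_norm(n_subjects, group[[p]], s, lo, hi)
  }
  z <- draw("z", 0.02, 0.98)
  a <- draw("a", 0.2, 10)
  t0 <- draw("t0", 0.05, 2)
  v_max <- draw("v_max", 0.05, 20)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    per_m <- lapply(morph_grid, function(m) {
      p <- ddm_params(v = morph_to_drift(m, v_max[s]), a = a[s], z = z[s],
                      t0 = t0[s])
      tr <- simulate_ddm_trials(p, trials_per_morph)
      data.frame(morph_pct_self = m, response = tr$choice, rt_s = tr$rt)
    })
    dd <- do.call(rbind, per_m)
    rows[[s]] <- data.frame(participant = sprintf("%s%02d", id_prefix, s),
                            condition = condition, dd,
                            stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, rows),
       truth = data.frame(participant = sprintf("%s%02d", id_prefix,
                                                seq_len(n_subjects)),
                          condition = condition, z = z, a = a, t0 = t0,
                          v_max = v_max, stringsAsFactors = FALSE))
}

#' Generate a full synthetic experiment
#'
#' Builds the complete two-condition data set: balanced morph presentation
#' within blocks (every level equally often per block), randomized trial
#' order, object-owner and key-response counterbalancing flags, diffusion
#' choices/response times from subject-level parameters drawn around the
#' condition group means, and injected contaminant trials to exercise the
#' exclusion rules. Responses are emitted response coded (`"self"` /
#' `"friend"`, i.e. the self-related vs other-related response), and the
#' morph axis is % self-owned object regardless of counterbalancing.
#'
#' @param config An [experiment_config()].
#' @return A list with `trials` (one row per trial: participant, condition,
#'   block, trial, morph_pct_self, pencil_is_self, key_self, response,
#'   rt_s) and `truth` (subject-level generative parameters).
#' @export
generate_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(as.integer(config$seed))
  conds <- names(config$group_params)
  per_block <- config$trials_per_block / length(config$morph_grid)
  n_total <- length(conds) * config$n_per_cell
  # balanced condition assignment and counterbalancing across the sample
  cond_of <- rep(conds, each = config$n_per_cell)
  pencil_self <- rep_len(c(TRUE, FALSE), n_total)
  key_self <- rep_len(c("C", "M"), n_total)

  all_tr <- vector("list", n_total)
  all_truth <- vector("list", n_total)
  p_id <- sprintf("p%03d", seq_len(n_total))
  for (i in seq_len(n_total)) {
    g <- config$group_params[[cond_of[i]]]
    z <- rtrunc_norm(1, g$z, config$sd_frac * g$z, 0.02, 0.98)
    a <- rtrunc_norm(1, g$a, config$sd_frac * g$a, 0.2, 10)
    t0 <- rtrunc_norm(1, g$t0, config$sd_frac * g$t0, 0.05, 2)
    v_max <- rtrunc_norm(1, g$v_max, config$sd_frac * g$v_max, 0.05, 20)
    blocks <- lapply(seq_len(config$blocks), function(b) {
      m <- sample(rep(config$morph_grid, per_block))
      data.frame(block = b, trial = seq_along(m), morph_pct_self = m)
    })
    dd <- do.call(rbind, blocks)
    dd$response <- NA_integer_; dd$rt_s <- NA_real_
    for (m in config$morph_grid) {
      idx <- which(dd$morph_pct_self == m)
      p <- ddm_params(v = morph_to_drift(m, v_max), a = a, z = z, t0 = t0)
      tr <- simulate_ddm_trials(p, length(idx))
      dd$response[idx] <- tr$choice
      dd$rt_s[idx] <- tr$rt
    }
    all_tr[[i]] <- data.frame(participant = p_id[i], condition = cond_of[i],
                              dd[, c("block", "trial", "morph_pct_self")],
                              pencil_is_self = pencil_self[i],
                              key_self = key_self[i],
                              response = ifelse(dd$response == 1L, "self",
                                                "friend"),
                              rt_s = dd$rt_s, stringsAsFactors = FALSE)
    all_truth[[i]] <- data.frame(participant = p_id[i],
                                 condition = cond_of[i], z = z, a = a,
                                 t0 = t0, v_max = v_max,
                                 stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, all_tr)
  trials <- inject_contaminants(trials, config$fast_frac,
                                config$outlier_frac)
  list(trials = trials, truth = do.call(rbind, all_truth), config = config)
}

#' Inject contaminant trials
#'
#' Replaces a random `fast_frac` of trials with fast guesses
#' (rt ~ U(0.05, 0.2) s, coin-flip response) and a disjoint `outlier_frac`
#' with slow uniform outliers (rt ~ U(0.2, 5) s, coin-flip response),
#' providing material for the fast-guess filter and the contaminant-mixture
#' likelihood.
#'
#' @param trials Trial table with `response` and `rt_s` columns.
#' @param fast_frac,outlier_frac Fractions in \[0, 0.1\].
#' @param seed Optional seed (when `NULL` the current RNG stream is used,
#'   as inside [generate_experiment()]).
#' @return The trial table with contaminated rows replaced.
#' @export
inject_contaminants <- function(trials, fast_frac = 0.01, outlier_frac = 0,
                                seed = NULL) {
  if (fast_frac < 0 || fast_frac > 0.1 || outlier_frac < 0 ||
      outlier_frac > 0.1)
    stop("contaminant fractions must lie in [0, 0.1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(trials)
  n_fast <- round(fast_frac * n); n_out <- round(outlier_frac * n)
  if (n_fast + n_out == 0) return(trials)
  pick <- sample.int(n, n_fast + n_out)
  is_char <- is.character(trials$response)
  coin <- function(k) if (is_char) sample(c("self", "friend"), k, TRUE)
                      else rbinom(k, 1L, 0.5)
  if (n_fast) {
    f <- pick[seq_len(n_fast)]
    trials$rt_s[f] <- runif(n_fast, 0.05, 0.2)
    trials$response[f] <- coin(n_fast)
  }
  if (n_out) {
    o <- pick[n_fast + seq_len(n_out)]
    trials$rt_s[o] <- runif(n_out, 0.2, 5)
    trials$response[o] <- coin(n_out)
  }
  trials
}

#' Simulate a cohort of logistic observers
#'
#' Draws participant-level generative PSEs from a normal distribution and
#' simulates Bernoulli classifications from cumulative logistic curves with
#' those locations — the sampling model used to check the PSE estimator
#' against reported condition means and SDs.
#'
#' @param n Number of participants.
#' @param mean_pse,sd_pse Population mean and SD of the generative PSEs
#'   (% self).
#' @param slope Logistic slope per % self.
#' @param trials_per_morph Trials per morph level per participant.
#' @param morph_grid Morph levels.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @param id_prefix Prefix for participant identifiers (keep distinct when
#'   combining cohorts).
#' @return A list with `trials` and `truth` (participant, true_pse).
#' @export
simulate_logistic_cohort <- function(n, mean_pse, sd_pse, slope = 0.15,
                                     trials_per_morph = 70,
                                     morph_grid = MORPH_GRID,
                                     condition = "cond", seed = 1,
                                     id_prefix = condition) {
  set.seed(as.integer(seed))
  alphas <- rnorm(n, mean_pse, sd_pse)
  ids <- sprintf("%s_%02d", id_prefix, seq_len(n))
  rows <- lapply(seq_len(n), function(s) {
    m <- rep(morph_grid, each = trials_per_morph)
    y <- rbinom(length(m), 1, plogis(slope * (m - alphas[s])))
    data.frame(participant = ids[s], condition = condition,
               morph_pct_self = m, response = y,
               rt_s = 0.5, stringsAsFactors = FALSE)
  })
  list(trials = do.call(rbind, rows),
       truth = data.frame(participant = ids, true_pse = alphas))
}
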
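# Hierarchical Bayesian estimation of the nested DDM model family.
#
# Subject-level parameters live on unconstrained scales (v raw, logit z,
# log a, log t0) with group-level normal distributions per cell; group means
# and variances get conjugate normal / inverse-gamma updates, subject-level
# parameters single-site random-walk Metropolis updates with proposal scales
# adapted during burn-in (frozen afterwards).

#' Default group-level hyperpriors
#'
#' Weakly informative priors on the unconstrained scales: normal priors on
#' the group means (`m0`, `s0`) and inverse-gamma priors on the group
#' variances (`shape`, `rate`). Drift means are centred at 0, starting point
#' at logit(0.5) = 0, boundary separation at log(1.5) and nondecision time at
#' log(0.3 s).
#'
#' @return A nested list of hyperparameters, one block per parameter type.
#' @export
hddm_priors <- function() {
  list(
    v  = list(m0 = 0,         s0 = 5,   shape = 2.5, rate = 0.5),
    z  = list(m0 = 0,         s0 = 1.5, shape = 2.5, rate = 0.1),
    a  = list(m0 = log(1.5),  s0 = 1,   shape = 2.5, rate = 0.05),
    t0 = list(m0 = log(0.3),  s0 = 1,   shape = 2.5, rate = 0.05)
  )
}

# conjugate update of a group (mean, sd) given subject values x
update_group <- function(x, sigma2, pr) {
  n <- length(x)
  prec <- 1 / pr$s0^2 + n / sigma2
  mu <- rnorm(1, (pr$m0 / pr$s0^2 + sum(x) / sigma2) / prec, sqrt(1 / prec))
  s2 <- 1 / rgamma(1, pr$shape + n / 2, rate = pr$rate + sum((x - mu)^2) / 2)
  c(mu, sqrt(s2))
}

#' Fit a hierarchical drift-diffusion model
#'
#' Samples the posterior of one model variant by Markov chain Monte Carlo.
#' Each iteration sweeps random-walk Metropolis updates over all
#' subject-level parameters (drift per morph cell, starting point, boundary,
#' nondecision time, on unconstrained scales) and conjugate Gibbs updates
#' over the group-level means and spreads. Trials are response coded: the
#' upper boundary is the self-related response. Outlier handling follows the
#' fixed-probability contaminant mixture: each trial density is
#' `(1 - p_out) * wfpt + p_out * unif(0, t_max)/2` with `t_max` the 99th
#' percentile of the observed response times.
#'
#' The deviance `-2 log L` is recorded at every iteration for
#' [compute_dic()]. Convergence can be checked with [split_rhat()] on any
#' stored draw vector; a warning is emitted when the worst group-level
#' split-R-hat exceeds 1.05.
#'
#' @param trials Trial table (columns `participant`, `condition`,
#'   `morph_pct_self`, `response`, `rt_s`; see [read_trials()]).
#' @param model Model variant: `"M1"`, `"M2"`, `"M3"` or an [hddm_model()].
#' @param n_samples Total MCMC iterations (the analysis default is 10000;
#'   the documented fast mode uses 2000).
#' @param n_burn Burn-in iterations discarded by all summaries (default
#'   1000; fast mode 500).
#' @param seed Integer seed; the fit is reproducible given the seed.
#' @param priors Hyperpriors, see [hddm_priors()].
#' @param p_out Contaminant fraction of the outlier mixture.
#' @param check_rhat Compute split-R-hat on group-level draws and warn above
#'   1.05.
#' @return An object of class `hddm_fit` with group- and subject-level draw
#'   arrays, the deviance trace, and sampler metadata.
#' @export
fit_hddm <- function(trials, model = "M2", n_samples = 2000, n_burn = 500,
                     seed = 1, priors = hddm_priors(), p_out = 0.05,
                     check_rhat = TRUE) {
  if (n_burn >= n_samples) stop("`n_burn` must be smaller than `n_samples`",
                                call. = FALSE)
  des <- if (inherits(trials, "hddm_design")) trials else
    build_design(trials, model)
  mod <- des$model
  set.seed(as.integer(seed))
  S <- des$S; C <- des$C; K <- des$K
  tmax <- as.numeric(quantile(des$rt, 0.99))

  # init: subject-level
  v <- matrix(0, S, C)
  zt <- rep(0, S)                                    # logit(0.5)
  la <- rep(log(1.5), S)
  min_rt <- vapply(seq_len(S), function(s)
    min(des$rt[(des$off[s, 1] + 1):des$off[s, C + 1]]), numeric(1))
  lt0 <- log(pmax(0.05, 0.7 * min_rt))
  # group-level: mean/sd per v cell (condition x morph), z cell, a cell, t0
  g_v <- matrix(0, 2, K * C); g_v[2, ] <- 0.7        # row 1 mean, row 2 sd
  g_z <- matrix(c(0, 0.2), 2, max(1L, des$n_z_cells))
  g_a <- matrix(c(log(1.5), 0.2), 2, des$n_a_cells)
  g_t <- matrix(c(log(0.3), 0.2), 2, 1)
  if (!mod$z_free) zt[] <- 0                          # z pinned at 0.5

  # proposal scales
  sc_v <- matrix(0.4, S, C); sc_z <- rep(0.15, S)
  sc_a <- rep(0.1, S); sc_t <- rep(0.08, S)

  cll <- loglik_cells_cpp(des$rt, des$choice, des$off, v, zt, la, lt0,
                          p_out, tmax)

  # storage
  draws_gv <- matrix(NA_real_, n_samples, K * C,
                     dimnames = list(NULL, des$v_labels))
  draws_gv_sd <- matrix(NA_real_, n_samples, K * C)
  draws_gz <- matrix(NA_real_, n_samples, max(1L, des$n_z_cells))
  draws_gz_sd <- draws_gz
  draws_ga <- matrix(NA_real_, n_samples, des$n_a_cells)
  draws_ga_sd <- draws_ga
  draws_gt <- matrix(NA_real_, n_samples, 1)
  draws_gt_sd <- draws_gt
  sub_v <- array(NA_real_, c(n_samples, S, C))
  sub_zt <- matrix(NA_real_, n_samples, S)
  sub_la <- matrix(NA_real_, n_samples, S)
  sub_lt0 <- matrix(NA_real_, n_samples, S)
  deviance <- numeric(n_samples)

  # per-subject expanded prior means/sds
  vcell <- function(s, c) (des$subj_cond[s] - 1L) * C + c
  vmap <- outer(seq_len(S), seq_len(C), vcell)        # S x C group cell index
  zmap <- if (des$n_z_cells > 0) des$subj_cond else rep(1L, S)
  amap <- if (des$n_a_cells > 1) des$subj_cond else rep(1L, S)

  acc <- list(v = matrix(0, S, C), z = rep(0, S), a = rep(0, S), t = rep(0, S))
  batch <- 0L; adapt_every <- 25L

  for (it in seq_len(n_samples)) {
    mu_v <- matrix(g_v[1, vmap], S, C); sd_v <- matrix(g_v[2, vmap], S, C)
    sw <- mh_sweep_cpp(des$rt, des$choice, des$off, v, zt, la, lt0, cll,
                       mu_v, sd_v, g_z[1, zmap], g_z[2, zmap],
                       g_a[1, amap], g_a[2, amap],
                       rep(g_t[1, 1], S), rep(g_t[2, 1], S),
                       sc_v, sc_z, sc_a, sc_t, mod$z_free, p_out, tmax)
    v <- sw$v; zt <- sw$zt; la <- sw$la; lt0 <- sw$lt0; cll <- sw$cll
    acc$v <- acc$v + sw$acc_v; acc$z <- acc$z + sw$acc_z
    acc$a <- acc$a + sw$acc_a; acc$t <- acc$t + sw$acc_t
    batch <- batch + 1L

    # group conjugate updates
    for (k in seq_len(K)) {
      idx <- which(des$subj_cond == k)
      for (c in seq_len(C)) {
        j <- (k - 1L) * C + c
        g_v[, j] <- update_group(v[idx, c], g_v[2, j]^2, priors$v)
      }
    }
    if (mod$z_free) for (j in seq_len(des$n_z_cells)) {
      idx <- which(zmap == j)
      g_z[, j] <- update_group(zt[idx], g_z[2, j]^2, priors$z)
    }
    for (j in seq_len(des$n_a_cells)) {
      idx <- which(amap == j)
      g_a[, j] <- update_group(la[idx], g_a[2, j]^2, priors$a)
    }
    g_t[, 1] <- update_group(lt0, g_t[2, 1]^2, priors$t0)

    # adapt proposal scales during burn-in
    if (it <= n_burn && batch == adapt_every) {
      tune <- function(sc, rate) pmin(pmax(sc * exp(rate - 0.44), 0.005), 5)
      sc_v <- tune(sc_v, acc$v / batch)
      if (mod$z_free) sc_z <- tune(sc_z, acc$z / batch)
      sc_a <- tune(sc_a, acc$a / batch)
      sc_t <- tune(sc_t, acc$t / batch)
      acc <- list(v = matrix(0, S, C), z = rep(0, S), a = rep(0, S),
                  t = rep(0, S))
      batch <- 0L
    }

    draws_gv[it, ] <- g_v[1, ]; draws_gv_sd[it, ] <- g_v[2, ]
    draws_gz[it, ] <- g_z[1, ]; draws_gz_sd[it, ] <- g_z[2, ]
    draws_ga[it, ] <- g_a[1, ]; draws_ga_sd[it, ] <- g_a[2, ]
    draws_gt[it, ] <- g_t[1, ]; draws_gt_sd[it, ] <- g_t[2, ]
    sub_v[it, , ] <- v; sub_zt[it, ] <- zt; sub_la[it, ] <- la
    sub_lt0[it, ] <- lt0
    deviance[it] <- -2 * sum(cll)
  }

  fit <- structure(list(
    design = des, model = mod,
    group = list(v = draws_gv, v_sd = draws_gv_sd,
                 z = draws_gz, z_sd = draws_gz_sd,
                 a = draws_ga, a_sd = draws_ga_sd,
                 t0 = draws_gt, t0_sd = draws_gt_sd),
    subject = list(v = sub_v, zt = sub_zt, la = sub_la, lt0 = sub_lt0),
    deviance = deviance,
    meta = list(n_samples = n_samples, n_burn = n_burn, seed = seed,
                p_out = p_out, t_max = tmax, n_chains = 1L)
  ), class = "hddm_fit")

  if (check_rhat) {
    rh <- max(vapply(seq_len(ncol(draws_gv)), function(j)
      split_rhat(draws_gv[-seq_len(n_burn), j]), numeric(1)))
    if (mod$z_free)
      rh <- max(rh, split_rhat(draws_gz[-seq_len(n_burn), 1]))
    fit$meta$max_rhat <- rh
    if (is.finite(rh) && rh > 1.05)
      warning(sprintf("possible non-convergence: max split-R-hat = %.3f (threshold 1.05); consider more samples", rh),
              call. = FALSE)
  }
  fit
}

post_idx <- function(fit) (fit$meta$n_burn + 1L):fit$meta$n_samples

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed by splitting a single chain (or
#' each of several chains) in half and comparing within- to between-half
#' variance.
#'
#' @param x Numeric vector of post-burn draws, or a matrix with one chain
#'   per column.
#' @return The split-R-hat value.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])))
  m <- ncol(halves)
  means <- colMeans(halves); vars <- apply(halves, 2, stats::var)
  W <- mean(vars); B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = D(theta_bar) + 2 * p_D` with effective parameter count
#' `p_D = mean posterior deviance - deviance at the posterior mean` (means
#' taken on the unconstrained parameter scales). Lower values indicate
#' better fit after penalizing complexity.
#'
#' @param fit An [fit_hddm()] result.
#' @return A list with elements `dic`, `p_d`, `d_bar` and `d_hat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (is.null(fit$deviance)) stop("fit has no deviance trace", call. = FALSE)
  keep <- post_idx(fit)
  d_bar <- mean(fit$deviance[keep])
  des <- fit$design
  v_bar <- apply(fit$subject$v[keep, , , drop = FALSE], c(2, 3), mean)
  zt_bar <- colMeans(fit$subject$zt[keep, , drop = FALSE])
  la_bar <- colMeans(fit$subject$la[keep, , drop = FALSE])
  lt_bar <- colMeans(fit$subject$lt0[keep, , drop = FALSE])
  d_hat <- -2 * sum(loglik_cells_cpp(des$rt, des$choice, des$off,
                                     matrix(v_bar, des$S, des$C), zt_bar,
                                     la_bar, lt_bar, fit$meta$p_out,
                                     fit$meta$t_max))
  p_d <- d_bar - d_hat
  list(dic = d_hat + 2 * p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' Compare fitted models by DIC
#'
#' @param ... Named or unnamed [fit_hddm()] results.
#' @return A data frame with one row per model (model, dic, p_d), ordered as
#'   given.
#' @export
compare_dic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "hddm_fit"))
    fits <- fits[[1]]
  nm <- names(fits)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(fits, function(f) f$model$variant, character(1))
  res <- lapply(fits, compute_dic)
  data.frame(model = nm,
             dic = vapply(res, `[[`, numeric(1), "dic"),
             p_d = vapply(res, `[[`, numeric(1), "p_d"),
             row.names = NULL)
}

# natural-scale draws of a group-level quantity, post-burn
group_draws <- function(fit, param, level = NULL) {
  keep <- post_idx(fit)
  des <- fit$design
  switch(param,
    z = {
      if (!fit$model$z_free) return(rep(0.5, length(keep)))
      j <- if (is.null(level)) 1L else match(level, des$conditions)
      if (is.na(j)) stop("unknown condition: ", level, call. = FALSE)
      plogis(fit$group$z[keep, j])
    },
    a = {
      j <- if (is.null(level) || fit$design$n_a_cells == 1L) 1L
           else match(level, des$conditions)
      if (is.na(j)) stop("unknown condition: ", level, call. = FALSE)
      exp(fit$group$a[keep, j])
    },
    t0 = exp(fit$group$t0[keep, 1]),
    v = {
      j <- match(level, des$v_labels)
      if (is.na(j)) stop("unknown drift cell: ", level, call. = FALSE)
      fit$group$v[keep, j]
    },
    v_mean = drift_condition_draws(fit, level),
    stop("unknown parameter: ", param, call. = FALSE)
  )
}

# sign-folded condition-mean drift draws: mean over morph cells of
# v * sign(morph - 50)
drift_condition_draws <- function(fit, condition) {
  des <- fit$design
  k <- match(condition, des$conditions)
  if (is.na(k)) stop("unknown condition: ", condition, call. = FALSE)
  keep <- post_idx(fit)
  cols <- (k - 1L) * des$C + seq_len(des$C)
  sgn <- sign(des$morphs - 50)
  sgn[sgn == 0] <- 1
  as.numeric(fit$group$v[keep, cols, drop = FALSE] %*% (sgn / des$C))
}

#' Condition-mean drift summaries
#'
#' Posterior mean and 95% interval of the sign-folded condition-mean drift:
#' for each condition, the mean over the morph cells of `v * sign(morph-50)`,
#' a scalar index of information-uptake speed comparable across conditions.
#'
#' @param fit An [fit_hddm()] result.
#' @return A data frame, one row per condition.
#' @export
drift_condition_means <- function(fit) {
  des <- fit$design
  rows <- lapply(des$conditions, function(k) {
    x <- drift_condition_draws(fit, k)
    data.frame(condition = k, mean = mean(x),
               q2.5 = quantile(x, 0.025), q97.5 = quantile(x, 0.975),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Directional posterior probability
#'
#' Fraction of post-burn draws that violate a stated direction — the
#' reporting convention in which small values indicate strong directional
#' evidence. Either compares two condition levels of a parameter
#' (hypothesis: `level > level2`) or one level against a constant
#' (hypothesis: `level > threshold`).
#'
#' @param fit An [fit_hddm()] result.
#' @param param `"z"`, `"a"`, `"t0"`, `"v"` (a drift-cell label) or
#'   `"v_mean"` (sign-folded condition-mean drift).
#' @param level Condition level (or drift-cell label) asserted to be larger.
#' @param level2 Condition level asserted to be smaller (omit when testing
#'   against `threshold`).
#' @param threshold Constant to test against (e.g. 0.5 for an unbiased
#'   starting point).
#' @return The posterior probability that the stated direction is violated.
#' @export
directional_prob <- function(fit, param, level = NULL, level2 = NULL,
                             threshold = NULL) {
  x <- group_draws(fit, param, level)
  if (!is.null(level2)) {
    y <- group_draws(fit, param, level2)
    mean(x <= y)
  } else if (!is.null(threshold)) {
    mean(x <= threshold)
  } else {
    stop("supply either `level2` or `threshold`", call. = FALSE)
  }
}

#' Directional Bayes factor from a posterior probability
#'
#' `BF10 = (1 - p) / p`, the posterior odds of the stated direction against
#' its complement (under equal prior odds, the convention used alongside
#' directional posterior probabilities). `p = 0` returns `Inf` and `p = 1`
#' returns 0; use [format_bf10()] to render these as the reporting bounds
#' `"> 999"` / `"< 0.001"` rather than infinities.
#'
#' @param p_bayes Directional posterior probability in \[0, 1\].
#' @return The Bayes factor (numeric).
#' @examples
#' round(bayes_factor(0.045))  # 21
#' round(bayes_factor(0.002))  # 499
#' @export
bayes_factor <- function(p_bayes) {
  if (!is.numeric(p_bayes) || any(p_bayes < 0 | p_bayes > 1))
    stop("`p_bayes` must lie in [0, 1]", call. = FALSE)
  ifelse(p_bayes == 0, Inf, (1 - p_bayes) / p_bayes)
}

#' Format a directional Bayes factor for reporting
#'
#' Rounds to the nearest integer as conventionally reported; values beyond
#' 999 (including `p_bayes` of exactly 0 or 1) are reported as bounds.
#'
#' @inheritParams bayes_factor
#' @return A character scalar, e.g. `"21"`, `"> 999"`.
#' @export
format_bf10 <- function(p_bayes) {
  bf <- bayes_factor(p_bayes)
  if (!is.finite(bf) || bf > 999) return("> 999")
  if (bf < 0.001) return("< 0.001")
  as.character(round(bf))
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM fit (Model %s): %d subjects, %d trials\n",
              x$model$variant, x$design$S, length(x$design$rt)))
  cat(sprintf("  %d MCMC samples (%d burn), seed %s, p_out = %.2f\n",
              x$meta$n_samples, x$meta$n_burn, x$meta$seed, x$meta$p_out))
  if (!is.null(x$meta$max_rhat))
    cat(sprintf("  max split-R-hat (group level): %.3f\n", x$meta$max_rhat))
  invisible(x)
}

#' Posterior summary table of group-level parameters
#'
#' @param object An [fit_hddm()] result.
#' @param ... Unused.
#' @return A data frame with one row per group-level parameter (natural
#'   scale): posterior mean, SD and central 95% interval.
#' @export
summary.hddm_fit <- function(object, ...) {
  fit <- object; des <- fit$design; keep <- post_idx(fit)
  blocks <- list()
  blocks$v <- lapply(des$v_labels, function(l) group_draws(fit, "v", l))
  names(blocks$v) <- des$v_labels
  if (fit$model$z_free) {
    blocks$z <- lapply(des$conditions, function(k) group_draws(fit, "z", k))
    names(blocks$z) <- sprintf("z[%s]", des$conditions)
  }
  if (des$n_a_cells > 1) {
    blocks$a <- lapply(des$conditions, function(k) group_draws(fit, "a", k))
    names(blocks$a) <- sprintf("a[%s]", des$conditions)
  } else {
    blocks$a <- list(a = group_draws(fit, "a"))
  }
  blocks$t0 <- list(t0 = group_draws(fit, "t0"))
  all <- unlist(blocks, recursive = FALSE)
  names(all) <- sub("^[vazt0]+\\.", "", names(all))
  out <- data.frame(
    parameter = names(all),
    mean = vapply(all, mean, numeric(1)),
    sd = vapply(all, sd, numeric(1)),
    q2.5 = vapply(all, quantile, numeric(1), 0.025),
    q97.5 = vapply(all, quantile, numeric(1), 0.975),
    row.names = NULL)
  out
}
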
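# Regression of the starting point on the point of subjective equality:
# subject-level z is expressed through an inverse-logit link of
# intercept + slope * standardized PSE, estimated jointly with the
# remaining hierarchical DDM parameters.

#' Regress the starting point on the PSE
#'
#' Fits a drift-diffusion model in which each subject's relative starting
#' point is `z_s = plogis(b0 + b1 * PSE_std_s)` with the PSE standardized
#' before entry; drift (per morph cell), boundary and nondecision time keep
#' their hierarchical structure. A negative slope means reductions in the
#' PSE go with increases in the starting point — the signature of a
#' response-selection origin of the behavioral bias. The intercept prior is
#' normal(0, 1.5) and the slope prior normal(0, 1) on the logit scale.
#'
#' @param trials Trial table (see [read_trials()]).
#' @param pse Named numeric vector (or data frame with `participant` and
#'   `pse` columns): one PSE per participant in `trials`.
#' @inheritParams fit_hddm
#' @return An object of class `hddm_regression` with post-burn draws of
#'   `b0` (intercept) and `b1` (slope, per PSE SD), the deviance trace, and
#'   the posterior probability that the slope is negative.
#' @export
regress_z_on_pse <- function(trials, pse, n_samples = 2000, n_burn = 500,
                             seed = 1, priors = hddm_priors(),
                             p_out = 0.05) {
  if (is.data.frame(pse)) pse <- setNames(pse$pse, pse$participant)
  des <- build_design(trials, hddm_model("M2"))
  if (is.null(names(pse))) {
    if (length(pse) != des$S)
      stop("`pse` must carry one value per participant", call. = FALSE)
    names(pse) <- des$subjects
  }
  miss <- setdiff(des$subjects, names(pse))
  if (length(miss)) stop("missing PSE for participant(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- pse[des$subjects]
  if (sd(x) == 0)
    stop("degenerate predictor: PSE values are constant", call. = FALSE)
  x <- as.numeric(scale(x))
  set.seed(as.integer(seed))
  S <- des$S; C <- des$C; K <- des$K
  tmax <- as.numeric(quantile(des$rt, 0.99))

  b0 <- 0; b1 <- 0
  zt <- b0 + b1 * x
  v <- matrix(0, S, C)
  la <- rep(log(1.5), S)
  min_rt <- vapply(seq_len(S), function(s)
    min(des$rt[(des$off[s, 1] + 1):des$off[s, C + 1]]), numeric(1))
  lt0 <- log(pmax(0.05, 0.7 * min_rt))
  g_v <- matrix(0, 2, K * C); g_v[2, ] <- 0.7
  g_a <- matrix(c(log(1.5), 0.2), 2, 1)
  g_t <- matrix(c(log(0.3), 0.2), 2, 1)
  sc_v <- matrix(0.4, S, C); sc_a <- rep(0.1, S); sc_t <- rep(0.08, S)
  sc_b <- c(0.1, 0.1)
  cll <- loglik_cells_cpp(des$rt, des$choice, des$off, v, zt, la, lt0,
                          p_out, tmax)
  vmap <- outer(seq_len(S), seq_len(C),
                function(s, c) (des$subj_cond[s] - 1L) * C + c)

  draws_b <- matrix(NA_real_, n_samples, 2,
                    dimnames = list(NULL, c("b0", "b1")))
  draws_gv <- matrix(NA_real_, n_samples, K * C,
                     dimnames = list(NULL, des$v_labels))
  deviance <- numeric(n_samples)
  acc <- list(v = matrix(0, S, C), a = rep(0, S), t = rep(0, S), b = c(0, 0))
  batch <- 0L

  for (it in seq_len(n_samples)) {
    mu_v <- matrix(g_v[1, vmap], S, C); sd_v <- matrix(g_v[2, vmap], S, C)
    sw <- mh_sweep_cpp(des$rt, des$choice, des$off, v, zt, la, lt0, cll,
                       mu_v, sd_v, rep(0, S), rep(1, S),
                       rep(g_a[1, 1], S), rep(g_a[2, 1], S),
                       rep(g_t[1, 1], S), rep(g_t[2, 1], S),
                       sc_v, rep(0.1, S), sc_a, sc_t, FALSE, p_out, tmax)
    v <- sw$v; la <- sw$la; lt0 <- sw$lt0; cll <- sw$cll
    acc$v <- acc$v + sw$acc_v; acc$a <- acc$a + sw$acc_a
    acc$t <- acc$t + sw$acc_t

    # regression coefficients: random-walk MH, full-data likelihood
    for (j in 1:2) {
      prop <- c(b0, b1)
      prop[j] <- prop[j] + rnorm(1, 0, sc_b[j])
      zt_p <- prop[1] + prop[2] * x
      cll_p <- loglik_cells_cpp(des$rt, des$choice, des$off, v, zt_p, la,
                                lt0, p_out, tmax)
      pr_sd <- if (j == 1) 1.5 else 1
      lr <- sum(cll_p) - sum(cll) +
        dnorm(prop[j], 0, pr_sd, log = TRUE) -
        dnorm(c(b0, b1)[j], 0, pr_sd, log = TRUE)
      if (is.finite(lr) && (lr >= 0 || runif(1) < exp(lr))) {
        b0 <- prop[1]; b1 <- prop[2]; zt <- zt_p; cll <- cll_p
        acc$b[j] <- acc$b[j] + 1
      }
    }

    for (k in seq_len(K)) {
      idx <- which(des$subj_cond == k)
      for (c in seq_len(C)) {
        j <- (k - 1L) * C + c
        g_v[, j] <- update_group(v[idx, c], g_v[2, j]^2, priors$v)
      }
    }
    g_a[, 1] <- update_group(la, g_a[2, 1]^2, priors$a)
    g_t[, 1] <- update_group(lt0, g_t[2, 1]^2, priors$t0)

    batch <- batch + 1L
    if (it <= n_burn && batch == 25L) {
      tune <- function(sc, rate) pmin(pmax(sc * exp(rate - 0.44), 0.005), 5)
      sc_v <- tune(sc_v, acc$v / batch)
      sc_a <- tune(sc_a, acc$a / batch)
      sc_t <- tune(sc_t, acc$t / batch)
      sc_b <- tune(sc_b, acc$b / batch)
      acc <- list(v = matrix(0, S, C), a = rep(0, S), t = rep(0, S),
                  b = c(0, 0))
      batch <- 0L
    }

    draws_b[it, ] <- c(b0, b1)
    draws_gv[it, ] <- g_v[1, ]
    deviance[it] <- -2 * sum(cll)
  }

  keep <- (n_burn + 1L):n_samples
  structure(list(
    design = des, pse_std = x,
    draws = list(b0 = draws_b[, 1], b1 = draws_b[, 2], v = draws_gv),
    deviance = deviance,
    p_slope_negative = mean(draws_b[keep, 2] < 0),
    meta = list(n_samples = n_samples, n_burn = n_burn, seed = seed,
                p_out = p_out, t_max = tmax)
  ), class = "hddm_regression")
}

#' @export
print.hddm_regression <- function(x, ...) {
  keep <- (x$meta$n_burn + 1L):x$meta$n_samples
  b1 <- x$draws$b1[keep]
  cat(sprintf("Starting-point-on-PSE regression (%d subjects)\n", x$design$S))
  cat(sprintf("  slope (logit z per PSE SD): mean %.3f, 95%% CI [%.3f, %.3f]\n",
              mean(b1), quantile(b1, 0.025), quantile(b1, 0.975)))
  cat(sprintf("  P(slope < 0) = %.3f\n", x$p_slope_negative))
  invisible(x)
}
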
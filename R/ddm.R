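#' Drift-diffusion parameter set
#'
#' Bundles the four parameters of the two-boundary diffusion process plus the
#' contaminant fraction of the outlier mixture. The diffusion coefficient is
#' fixed at 1, so `v` and `a` are on the scale conventional in hierarchical
#' DDM software: drift `v` in evidence units per second (positive values push
#' toward the upper boundary, here the self-related response), boundary
#' separation `a` in evidence units, relative starting point `z` as a
#' fraction of `a`, and nondecision time `t0` in seconds.
#'
#' @param v Drift rate (signed; positive toward the upper boundary).
#' @param a Boundary separation, must be > 0.
#' @param z Relative starting point, in (0, 1); 0.5 is unbiased.
#' @param t0 Nondecision time in seconds, >= 0.
#' @param p_out Contaminant fraction in \[0, 1): probability that a trial is
#'   an outlier drawn uniformly on (0, `t_max`\] with a coin-flip response.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1, a = 1.6, z = 0.52, t0 = 0.35)
#' choice_probability(p)
#' @export
ddm_params <- function(v, a, z, t0, p_out = 0) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("boundary separation `a` must be a single value > 0", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0 || z >= 1)
    stop("relative starting point `z` must lie strictly in (0, 1)",
         call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("nondecision time `t0` must be >= 0", call. = FALSE)
  if (!is.numeric(p_out) || length(p_out) != 1L || p_out < 0 || p_out >= 1)
    stop("contaminant fraction `p_out` must lie in [0, 1)", call. = FALSE)
  structure(list(v = v, a = a, z = z, t0 = t0, p_out = p_out),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.3f, a = %.3f, z = %.3f, t0 = %.3f, p_out = %.3f\n",
              x$v, x$a, x$z, x$t0, x$p_out))
  invisible(x)
}

as_ddm_params <- function(params) {
  if (inherits(params, "ddm_params")) return(params)
  do.call(ddm_params, as.list(params))
}

# map a choice argument to integer upper-boundary indicators
choice_to_upper <- function(choice) {
  if (is.character(choice)) {
    bad <- !choice %in% c("upper", "lower", "self", "friend")
    if (any(bad)) stop("unknown boundary label(s): ",
                       paste(unique(choice[bad]), collapse = ", "),
                       call. = FALSE)
    as.integer(choice %in% c("upper", "self"))
  } else if (is.logical(choice)) {
    as.integer(choice)
  } else {
    ch <- as.integer(choice)
    if (any(!ch %in% c(0L, 1L))) stop("numeric choices must be 0/1",
                                      call. = FALSE)
    ch
  }
}

#' Wiener first-passage-time density
#'
#' Defective density of absorption at one boundary of the drift-diffusion
#' process at clock time `rt`. Evaluated by a truncated-series expansion with
#' small-time/large-time regime switching (term count adaptive, standardized
#' truncation error below 1e-10). The lower-boundary density is obtained from
#' the upper-boundary formula through the reflection `v -> -v`, `z -> 1 - z`.
#' Returns 0 for `rt <= t0`.
#'
#' @param rt Response times in seconds (vectorized).
#' @param choice Boundary: `"upper"`/`"lower"` (or `"self"`/`"friend"`,
#'   or 1/0), recycled if scalar.
#' @param params A [ddm_params()] object (its `p_out` is ignored here; see
#'   [ddm_loglik()] for the contaminant mixture).
#' @param regime Series regime: `"auto"` picks the cheaper expansion;
#'   `"small"`/`"large"` force one (used for cross-checking the two
#'   expansions).
#' @return Density values (1/seconds), >= 0.
#' @export
wfpt_density <- function(rt, choice, params, regime = c("auto", "small", "large")) {
  params <- as_ddm_params(params)
  regime <- match.arg(regime)
  reg <- match(regime, c("auto", "small", "large")) - 1L
  up <- choice_to_upper(choice)
  stopifnot(length(up) == 1L || length(up) == length(rt))
  dwfpt_cpp(as.numeric(rt), up, params$v, params$a, params$z, params$t0, reg)
}

#' Boundary absorption probability
#'
#' Closed-form probability that the diffusion is absorbed at the given
#' boundary: `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))`, reducing
#' to `z` as `v -> 0`. The two boundary probabilities sum to 1.
#'
#' @inheritParams wfpt_density
#' @param boundary `"upper"` or `"lower"`.
#' @return A probability.
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  va <- params$v * params$a
  p_up <- if (abs(va) < 1e-9) params$z else
    expm1(-2 * va * params$z) / expm1(-2 * va)
  p_up <- min(max(p_up, 0), 1)
  if (boundary == "upper") p_up else 1 - p_up
}

#' Simulate drift-diffusion trials
#'
#' Draws choices from the closed-form absorption probability and response
#' times by numerical inversion of the conditional first-passage-time CDF
#' (trapezoid integration of the series density on a fine grid), so samples
#' follow the model's own distribution to grid accuracy. With `p_out > 0`, a
#' fraction of trials is replaced by contaminants: uniform response times on
#' (0, `t_max`\] with coin-flip choices.
#'
#' @inheritParams wfpt_density
#' @param n Number of trials (>= 1).
#' @param seed Optional integer seed; when supplied the output is
#'   reproducible.
#' @param t_max Upper end of the contaminant response-time distribution in
#'   seconds.
#' @param grid_n Number of grid points per boundary for the CDF inversion.
#' @return A data frame with columns `choice` (1 = upper boundary) and `rt`
#'   (seconds).
#' @export
simulate_ddm_trials <- function(params, n, seed = NULL, t_max = 5,
                                grid_n = 4096L) {
  params <- as_ddm_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  p_up <- choice_probability(params, "upper")
  choice <- rbinom(n, 1L, p_up)
  rt <- numeric(n)
  for (b in c(1L, 0L)) {
    idx <- which(choice == b)
    if (!length(idx)) next
    inv <- wfpt_cdf_grid(params, b, grid_n)
    u <- runif(length(idx), 0, inv$p_total)
    rt[idx] <- params$t0 + approx(inv$cdf, inv$t, xout = u, rule = 2)$y
  }
  if (params$p_out > 0) {
    out <- runif(n) < params$p_out
    n_out <- sum(out)
    if (n_out) {
      rt[out] <- runif(n_out, 0, t_max)
      choice[out] <- rbinom(n_out, 1L, 0.5)
    }
  }
  data.frame(choice = choice, rt = rt)
}

# defective CDF of decision time at one boundary on a fine grid, for
# inverse-CDF sampling; returns strictly increasing (cdf, t) pairs
wfpt_cdf_grid <- function(params, upper, grid_n = 4096L) {
  p_b <- choice_probability(params, if (upper == 1L) "upper" else "lower")
  # find a horizon capturing essentially all conditional mass
  t_hi <- max(1, params$a^2)
  repeat {
    tg <- seq(0, t_hi, length.out = 257L)
    d <- dwfpt_cpp(tg + params$t0, upper, params$v, params$a, params$z,
                   params$t0, 0L)
    mass <- sum((d[-1] + d[-length(d)]) / 2) * (tg[2] - tg[1])
    if (mass >= p_b * (1 - 1e-7) || t_hi > 2000) break
    t_hi <- t_hi * 2
  }
  tg <- seq(0, t_hi, length.out = as.integer(grid_n))
  d <- dwfpt_cpp(tg + params$t0, upper, params$v, params$a, params$z,
                 params$t0, 0L)
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2) * (tg[2] - tg[1]))
  keep <- c(TRUE, diff(cdf) > 0)
  list(t = tg[keep], cdf = cdf[keep], p_total = max(cdf))
}

#' Contaminant-mixture log-likelihood of a trial set
#'
#' Per-trial density is `(1 - p_out) * wfpt + p_out * unif(0, t_max) / 2`,
#' the uniform outlier mass split equally across the two boundaries; the
#' function returns the sum of log densities. With `p_out = 0` a trial with
#' `rt <= t0` yields `-Inf`.
#'
#' @param trials A data frame with columns `rt` (or `rt_s`) and `choice` (or
#'   `response`), choices coded as for [wfpt_density()].
#' @param params A [ddm_params()] object; its `p_out` sets the mixture
#'   weight.
#' @param t_max Upper end of the contaminant distribution; defaults to the
#'   99th percentile of the response times in `trials`.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
ddm_loglik <- function(trials, params, t_max = NULL) {
  params <- as_ddm_params(params)
  rt <- if (!is.null(trials$rt)) trials$rt else trials$rt_s
  ch <- if (!is.null(trials$choice)) trials$choice else trials$response
  if (is.null(rt) || is.null(ch) || !nrow(trials))
    stop("`trials` must be a non-empty data frame with rt/choice columns",
         call. = FALSE)
  if (is.null(t_max)) t_max <- as.numeric(quantile(rt, 0.99))
  ll <- loglik_mix_cpp(as.numeric(rt), choice_to_upper(ch), params$v,
                       params$a, params$z, params$t0, params$p_out, t_max)
  sum(ll)
}

#' Euler-Maruyama reference simulator
#'
#' Simulates the diffusion by explicit time stepping. This is a slow
#' brute-force reference used to validate the series density and the
#' inverse-CDF sampler; analysis code should use [simulate_ddm_trials()].
#'
#' @inheritParams simulate_ddm_trials
#' @param dt Euler step in seconds.
#' @param t_cap Decision-time cap in seconds (paths still running at the cap
#'   are assigned to the nearer boundary; with sensible parameters this is
#'   vanishingly rare).
#' @return A data frame with columns `choice` and `rt`.
#' @keywords internal
simulate_ddm_euler <- function(params, n, seed = NULL, dt = 1e-4, t_cap = 30) {
  params <- as_ddm_params(params)
  if (!is.null(seed)) set.seed(seed)
  out <- sim_ddm_euler_cpp(as.integer(n), params$v, params$a, params$z,
                           params$t0, dt, t_cap)
  data.frame(choice = out$choice, rt = out$rt)
}
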
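# Trial filtering, cumulative-logistic psychometric fitting, PSE extraction
# and group-level tests against the objective mid-point of the continuum.

#' Exclude anticipatory responses
#'
#' Removes trials with response times below the fast-guess threshold
#' (default 200 ms). The exclusion report tallies removals per participant.
#'
#' @param trials Trial table with an `rt_s` (or `rt`) column in seconds.
#' @param min_rt Threshold in seconds; trials with `rt < min_rt` are
#'   removed.
#' @return A list with `trials` (kept rows) and `report` (per-participant
#'   data frame: `n_total`, `n_removed`, `frac_removed`).
#' @export
filter_trials <- function(trials, min_rt = 0.2) {
  rt <- if (!is.null(trials$rt_s)) trials$rt_s else trials$rt
  if (is.null(rt)) stop("trials need an rt_s/rt column", call. = FALSE)
  pid <- if (!is.null(trials$participant)) as.character(trials$participant)
         else rep("p1", nrow(trials))
  keep <- rt >= min_rt
  rep_df <- do.call(rbind, lapply(split(keep, pid), function(k)
    data.frame(n_total = length(k), n_removed = sum(!k),
               frac_removed = mean(!k))))
  rep_df <- data.frame(participant = rownames(rep_df), rep_df,
                       row.names = NULL)
  if (!any(keep)) warning("all trials removed by the fast-guess filter",
                          call. = FALSE)
  list(trials = trials[keep, , drop = FALSE], report = rep_df)
}

#' Fit a cumulative logistic psychometric function
#'
#' Maximum-likelihood Bernoulli fit of
#' `P(self) = 1 / (1 + exp(-beta * (morph - alpha)))` to one participant's
#' responses, via logistic regression; `alpha` is the point of subjective
#' equality (PSE) on the 0-100% self axis and `beta` the slope per percent.
#' No lapse/guess asymptotes are fitted. Under complete separation the
#' unbounded estimate diverges, so the fit falls back to a bounded
#' optimisation (slope capped) with a warning.
#'
#' @param morph Morph levels (% self) per trial.
#' @param y Responses per trial: 1/TRUE = classified self-owned.
#' @return An object of class `psych_curve`: `alpha`, `beta` (orientation
#'   normalized to positive, with the raw sign in `beta_raw`), `n_trials`,
#'   log-likelihoods of the fit and of the constant-probability null, and
#'   the fit method used.
#' @examples
#' set.seed(1)
#' m <- rep(c(0, 20, 35, 45, 55, 65, 80, 100), each = 20)
#' y <- rbinom(length(m), 1, plogis(0.15 * (m - 45)))
#' fit_logistic(m, y)$alpha
#' @export
fit_logistic <- function(morph, y) {
  y <- choice_to_upper(y)
  stopifnot(length(morph) == length(y), length(y) > 0)
  if (length(unique(morph)) < 2)
    stop("need responses at >= 2 distinct morph levels", call. = FALSE)
  p_bar <- mean(y)
  ll_null <- if (p_bar %in% c(0, 1)) 0 else
    sum(y * log(p_bar) + (1 - y) * log(1 - p_bar))

  g <- suppressWarnings(glm(y ~ morph, family = binomial()))
  b <- coef(g)
  separated <- !g$converged || !is.finite(b[2]) || abs(b[2]) > 2 ||
    abs(b[1]) > 200
  if (!separated) {
    alpha <- -b[[1]] / b[[2]]
    beta <- b[[2]]
    ll <- as.numeric(logLik(g))
    method <- "glm"
  } else {
    warning("complete or quasi-complete separation; using bounded-parameter fit",
            call. = FALSE)
    nll <- function(par) {
      eta <- par[2] * (morph - par[1])
      -sum(y * plogis(eta, log.p = TRUE) +
             (1 - y) * plogis(-eta, log.p = TRUE))
    }
    o <- optim(c(50, if (mean(y[morph > 50]) >= mean(y[morph < 50])) 0.5 else -0.5),
               nll, method = "L-BFGS-B",
               lower = c(-100, -2), upper = c(200, 2))
    alpha <- o$par[1]; beta <- o$par[2]; ll <- -o$value
    method <- "bounded"
  }
  structure(list(alpha = as.numeric(alpha), beta = abs(as.numeric(beta)),
                 beta_raw = as.numeric(beta), n_trials = length(y),
                 loglik = ll, loglik_null = ll_null, method = method),
            class = "psych_curve")
}

#' @export
print.psych_curve <- function(x, ...) {
  cat(sprintf("Psychometric curve: PSE = %.2f%%, slope = %.4f per %% (%d trials, %s fit)\n",
              x$alpha, x$beta, x$n_trials, x$method))
  invisible(x)
}

#' Point of subjective equality
#'
#' The morph level at which the two classifications are equally likely: by
#' construction `P(self | morph = PSE) = 0.5`, i.e. the location `alpha` of
#' the fitted cumulative logistic.
#'
#' @param curve A [fit_logistic()] result.
#' @return The PSE in % self units.
#' @export
pse <- function(curve) {
  stopifnot(inherits(curve, "psych_curve"))
  curve$alpha
}

#' Fit psychometric curves for every participant
#'
#' @param trials Trial table (see [read_trials()]).
#' @return A data frame with one row per participant (participant,
#'   condition, pse, slope, n_trials, p_flat = likelihood-ratio p-value
#'   against a constant-probability model, anchor_acc = accuracy at the two
#'   continuum anchors, method). Curves themselves are attached as the
#'   `"curves"` attribute.
#' @export
fit_participants <- function(trials) {
  d <- normalize_trials(trials)
  anchors <- range(d$morph)
  # one curve per participant and condition (coincident for between-subject
  # designs, where each participant contributes a single condition)
  d$cell <- paste(d$participant, d$condition, sep = "\r")
  ids <- unique(d$cell)
  curves <- list()
  rows <- lapply(ids, function(p) {
    dp <- d[d$cell == p, ]
    cv <- fit_logistic(dp$morph, dp$y)
    curves[[dp$participant[1]]] <<- cv
    lrt <- 2 * (cv$loglik - cv$loglik_null)
    is_anchor <- dp$morph %in% anchors
    correct <- ifelse(dp$morph[is_anchor] == anchors[2], dp$y[is_anchor],
                      1 - dp$y[is_anchor])
    data.frame(participant = dp$participant[1], condition = dp$condition[1],
               pse = cv$alpha, slope = cv$beta, n_trials = cv$n_trials,
               p_flat = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
               anchor_acc = if (any(is_anchor)) mean(correct) else NA_real_,
               method = cv$method, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}

#' Exclude random responders
#'
#' Flags participants whose response probability is statistically flat
#' across morph levels: a likelihood-ratio test of the fitted logistic
#' against a constant-probability model that is non-significant at
#' `alpha_level`, or anchor-level accuracy (at the continuum endpoints)
#' below `anchor_min`. Either symptom triggers exclusion.
#'
#' @param fits A [fit_participants()] table.
#' @param alpha_level Significance level of the flatness test.
#' @param anchor_min Minimum accuracy at the 0%/100% anchors.
#' @return A list with `kept` and `excluded` participant fit tables and the
#'   reason per exclusion.
#' @export
exclude_random_responders <- function(fits, alpha_level = 0.01,
                                      anchor_min = 0.6) {
  flat <- fits$p_flat >= alpha_level
  poor <- !is.na(fits$anchor_acc) & fits$anchor_acc < anchor_min
  drop <- flat | poor
  reason <- ifelse(flat & poor, "flat+anchor", ifelse(flat, "flat", "anchor"))
  excluded <- fits[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[drop]
  list(kept = fits[!drop, , drop = FALSE], excluded = excluded)
}

#' Group-level PSE tests against the objective mid-point
#'
#' One-sample t-tests of each condition's PSEs against the reference
#' (the physical mid-point, 50%), with Cohen's d = mean shift / SD, and —
#' when exactly two conditions are present — a pooled-variance two-sample
#' t-test between conditions with Cohen's d on the pooled SD and a 95% CI
#' for the difference.
#'
#' @param fits A [fit_participants()] table (after exclusions), or any data
#'   frame with `pse` and `condition` columns.
#' @param reference The objective mid-point of the continuum.
#' @return A list with `by_condition` (data frame) and, for two conditions,
#'   `between` (data frame: difference, t, df, p, d, CI bounds).
#' @export
group_pse_tests <- function(fits, reference = 50) {
  sp <- split(fits$pse, fits$condition)
  if (any(lengths(sp) < 2))
    stop("need >= 2 participants per condition", call. = FALSE)
  by_cond <- do.call(rbind, lapply(names(sp), function(k) {
    x <- sp[[k]]
    shift <- mean(x) - reference
    if (sd(x) > 0) {
      tt <- t.test(x, mu = reference)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    } else {  # degenerate: identical PSEs
      tstat <- if (shift == 0) 0 else sign(shift) * Inf
      pval <- if (shift == 0) 1 else 0
    }
    data.frame(condition = k, n = length(x), mean_pse = mean(x),
               sd_pse = sd(x), t = tstat, df = length(x) - 1, p = pval,
               d = if (sd(x) > 0) shift / sd(x) else
                 if (shift == 0) 0 else sign(shift) * Inf,
               row.names = NULL)
  }))
  out <- list(by_condition = by_cond)
  if (length(sp) == 2) {
    x <- sp[[1]]; y <- sp[[2]]
    sd_pool <- sqrt(((length(x) - 1) * stats::var(x) +
                       (length(y) - 1) * stats::var(y)) /
                      (length(x) + length(y) - 2))
    delta <- mean(x) - mean(y)
    if (sd_pool > 0) {
      tt <- t.test(x, y, var.equal = TRUE)
      out$between <- data.frame(
        condition_a = names(sp)[1], condition_b = names(sp)[2],
        delta_m = delta, t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, d = delta / sd_pool,
        ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2], row.names = NULL)
    } else {
      out$between <- data.frame(
        condition_a = names(sp)[1], condition_b = names(sp)[2],
        delta_m = delta, t = if (delta == 0) 0 else sign(delta) * Inf,
        df = length(x) + length(y) - 2, p = if (delta == 0) 1 else 0,
        d = if (delta == 0) 0 else sign(delta) * Inf,
        ci_lo = delta, ci_hi = delta, row.names = NULL)
    }
  }
  out
}

#' Full psychometric analysis of a trial table
#'
#' Convenience wrapper chaining the fast-guess filter, per-participant
#' curve fits, random-responder exclusion and the group-level tests.
#'
#' @inheritParams fit_participants
#' @inheritParams group_pse_tests
#' @param min_rt Fast-guess threshold in seconds.
#' @return A list: `filter_report`, `fits` (kept), `excluded`, `group`.
#' @export
psychometric_analysis <- function(trials, min_rt = 0.2, reference = 50) {
  flt <- filter_trials(trials, min_rt)
  fits <- fit_participants(flt$trials)
  exc <- exclude_random_responders(fits)
  grp <- group_pse_tests(exc$kept, reference)
  list(filter_report = flt$report, fits = exc$kept,
       excluded = exc$excluded, group = grp)
}
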
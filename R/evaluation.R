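# Posterior predictive checks, drift-based psychometric functions, and
# quantitative comparison of empirical vs model-simulated curves.

#' Simulate datasets from the posterior
#'
#' Draws `n_datasets` post-burn iterations (one joint parameter draw per
#' dataset, so the simulated spread reflects parameter uncertainty) and
#' simulates a full dataset with the identical design — same participants,
#' morph-level trial counts and conditions — through the model's trial
#' simulator, including the contaminant mixture at the fitted `p_out`.
#'
#' @param fit An [fit_hddm()] result.
#' @param n_datasets Number of simulated datasets.
#' @param seed Integer seed.
#' @return A list of trial tables (participant, condition, morph_pct_self,
#'   response, rt_s).
#' @export
posterior_predict <- function(fit, n_datasets = 10, seed = 1) {
  stopifnot(inherits(fit, "hddm_fit"))
  set.seed(as.integer(seed))
  des <- fit$design
  iters <- sample(post_idx(fit), n_datasets, replace = TRUE)
  lapply(iters, function(it) {
    rows <- vector("list", des$S * des$C)
    r <- 0L
    for (s in seq_len(des$S)) {
      z <- plogis(fit$subject$zt[it, s])
      a <- exp(fit$subject$la[it, s])
      t0 <- exp(fit$subject$lt0[it, s])
      for (c in seq_len(des$C)) {
        n_sc <- des$counts[s, c]
        if (n_sc == 0) next
        p <- ddm_params(v = fit$subject$v[it, s, c], a = a, z = z, t0 = t0,
                        p_out = fit$meta$p_out)
        tr <- simulate_ddm_trials(p, n_sc, t_max = fit$meta$t_max)
        r <- r + 1L
        rows[[r]] <- data.frame(participant = des$subjects[s],
                                condition = des$conditions[des$subj_cond[s]],
                                morph_pct_self = des$morphs[c],
                                response = tr$choice, rt_s = tr$rt,
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(r)])
  })
}

#' Drift-based psychometric function
#'
#' Posterior mean and central 95% interval of the group-level drift rate in
#' every condition x morph cell — the process-level analogue of the
#' psychometric curve: drift grows in magnitude as stimulus ambiguity
#' decreases, positive for self-dominant and negative for other-dominant
#' images. A per-condition monotonicity diagnostic (is the posterior-mean
#' sequence increasing in morph level?) is attached.
#'
#' @param fit An [fit_hddm()] result.
#' @return A data frame (condition, morph, mean, q2.5, q97.5) with a
#'   `monotone` attribute naming each condition's diagnostic.
#' @export
drift_psychometric <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  des <- fit$design
  if (des$C < 2) stop("model has no morph-resolved drift cells", call. = FALSE)
  keep <- post_idx(fit)
  rows <- list(); mono <- logical(0)
  for (k in seq_along(des$conditions)) {
    cols <- (k - 1L) * des$C + seq_len(des$C)
    m <- fit$group$v[keep, cols, drop = FALSE]
    df <- data.frame(condition = des$conditions[k], morph = des$morphs,
                     mean = colMeans(m),
                     q2.5 = apply(m, 2, quantile, 0.025),
                     q97.5 = apply(m, 2, quantile, 0.975), row.names = NULL)
    mono[des$conditions[k]] <- all(diff(df$mean) > 0)
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  attr(out, "monotone") <- mono
  out
}

# group-mean PSE and per-morph P(self) for one trial table
curve_summaries <- function(trials, min_rt = 0.2) {
  flt <- filter_trials(trials, min_rt)
  d <- normalize_trials(flt$trials)
  fits <- fit_participants(flt$trials)
  by_cond <- split(fits$pse, fits$condition)
  pse_mean <- vapply(by_cond, mean, numeric(1))
  agg <- stats::aggregate(y ~ condition + morph, data = d, FUN = mean)
  list(pse = pse_mean, p_self = agg)
}

#' Compare empirical and model-simulated psychometric curves
#'
#' Makes the posterior predictive check quantitative: per condition it
#' reports the absolute difference between the empirical group-mean PSE and
#' the mean over simulated datasets, the simulated 95% band of group-mean
#' PSEs, a misfit flag when the empirical PSE falls outside that band, and
#' per-morph differences between empirical and mean simulated response
#' probabilities with their own 95% bands.
#'
#' @param trials The empirical (or synthetic input) trial table.
#' @param simulated A list of simulated trial tables from
#'   [posterior_predict()].
#' @param min_rt Fast-guess threshold applied to both sides.
#' @return An object of class `ppc_result` with elements `pse` (per
#'   condition) and `p_self` (per condition x morph).
#' @export
compare_curves <- function(trials, simulated, min_rt = 0.2) {
  emp <- curve_summaries(trials, min_rt)
  sims <- lapply(simulated, curve_summaries, min_rt = min_rt)
  conds <- names(emp$pse)
  sim_ok <- all(vapply(sims, function(s)
    setequal(names(s$pse), conds), logical(1)))
  if (!sim_ok) stop("simulated datasets have different conditions than the input",
                    call. = FALSE)
  pse_mat <- do.call(rbind, lapply(sims, function(s) s$pse[conds]))
  pse_df <- data.frame(
    condition = conds,
    pse_empirical = emp$pse[conds],
    pse_simulated = colMeans(pse_mat),
    band_lo = apply(pse_mat, 2, quantile, 0.025),
    band_hi = apply(pse_mat, 2, quantile, 0.975), row.names = NULL)
  pse_df$abs_diff <- abs(pse_df$pse_empirical - pse_df$pse_simulated)
  pse_df$misfit <- pse_df$pse_empirical < pse_df$band_lo |
    pse_df$pse_empirical > pse_df$band_hi

  key <- function(df) paste(df$condition, df$morph)
  base <- emp$p_self[order(key(emp$p_self)), ]
  sim_p <- vapply(sims, function(s) {
    v <- s$p_self[order(key(s$p_self)), "y"]
    v
  }, numeric(nrow(base)))
  p_df <- data.frame(condition = base$condition, morph = base$morph,
                     p_empirical = base$y,
                     p_simulated = rowMeans(sim_p),
                     band_lo = apply(sim_p, 1, quantile, 0.025),
                     band_hi = apply(sim_p, 1, quantile, 0.975),
                     row.names = NULL)
  p_df$inside_band <- p_df$p_empirical >= p_df$band_lo &
    p_df$p_empirical <= p_df$band_hi
  structure(list(pse = pse_df, p_self = p_df,
                 n_datasets = length(simulated)), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d simulated datasets)\n",
              x$n_datasets))
  for (i in seq_len(nrow(x$pse))) {
    r <- x$pse[i, ]
    cat(sprintf("  %s: PSE empirical %.1f vs simulated %.1f [%.1f, %.1f]%s\n",
                r$condition, r$pse_empirical, r$pse_simulated, r$band_lo,
                r$band_hi, if (r$misfit) "  ** misfit" else ""))
  }
  cat(sprintf("  per-morph P(self) inside 95%% band: %d / %d cells\n",
              sum(x$p_self$inside_band), nrow(x$p_self)))
  invisible(x)
}
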
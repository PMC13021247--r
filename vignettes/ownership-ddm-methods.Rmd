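---
title: "Decomposing ownership-based self-prioritization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing ownership-based self-prioritization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ddmpse` analyzes two-choice classification of morphed images — blends of a
self-owned and an other-owned object, graded on a 0–100% "self" continuum —
with two complementary layers. The psychophysical layer asks *whether*
classification is biased: it fits each participant a cumulative logistic
psychometric function and reads off the point of subjective equality (PSE),
the morph level at which both classifications are equally likely. A PSE
below the physical midpoint (50%) means less self-related information
suffices for a self-related response. The computational layer asks *where*
the bias comes from: a hierarchical drift-diffusion model (DDM) separates a
stimulus origin (drift rate, the speed of evidence uptake) from a response
origin (the starting point of evidence accumulation, a prestimulus
preference for one response). This vignette documents the models, the
numerical choices, and the places where the design was genuinely open.

## The decision model

A trial is modeled as noisy evidence accumulating between two boundaries a
distance `a` apart, starting a fraction `z` of the way up, drifting at mean
rate `v`, with diffusion coefficient fixed at 1 (the convention of the
common hierarchical DDM software, so parameter values are directly
comparable across tools). The upper boundary is always the *self-related*
response (response coding); the observed response time adds a nondecision
time `t0`. The defective first-passage density at the lower boundary is
evaluated through the standardized process at normalized time
`tt = (rt - t0) / a^2` with two classical series expansions:

* small-time: `f(tt, w) = (2*pi*tt^3)^(-1/2) * sum_k (w + 2k) exp(-(w + 2k)^2 / (2 tt))`
* large-time: `f(tt, w) = pi * sum_k k exp(-k^2 pi^2 tt / 2) sin(k pi w)`

The number of terms is chosen adaptively so the truncation error of the
standardized density is below `1e-10` (comfortably inside the `1e-7`
target for the full density), and whichever expansion needs fewer terms is
used; the two agree to better than `1e-6` across the overlap region (this
is a test invariant). The upper-boundary density is the reflection
`v -> -v`, `z -> 1 - z`, applied exactly. No inter-trial variability
parameters (sv, sz, st) are included: the analysis this package
operationalizes never reports them, and omitting them keeps the likelihood
in closed series form. This is the main known limitation of the likelihood:
contaminant-free fast errors that inter-trial variability would absorb are
instead soaked up by the outlier mixture below.

**Outlier handling.** Empirical response-time data contain trials the
diffusion process did not generate. Following the fixed-5% convention of
the hierarchical DDM software this package parallels, each trial's density
is the mixture `(1 - p_out) * wfpt + p_out * uniform(0, t_max] / 2` with
`p_out = 0.05`, the uniform mass split equally over the two responses, and
`t_max` set to the 99th percentile of the observed response times of the
dataset being fitted. The mixture (rather than trimming) keeps the
likelihood finite for any response time, including those faster than `t0`.
Whether the original analyses removed or downweighted such trials is not
documented; the mixture is the documented convention of the software they
cite, and `p_out` is exposed for sensitivity analyses.

**Trial simulation.** The pipeline simulator draws the response from the
closed-form absorption probability
`P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))` and the response time
by numerically inverting the conditional first-passage CDF (trapezoid
integration of the series density on a 4096-point grid whose horizon is
doubled until it captures all but `1e-7` of the conditional mass). Samples
therefore follow the model's own distribution to grid accuracy —
Kolmogorov–Smirnov distance against the density-implied CDF is below 0.01
at 10^5 trials, another test invariant. A separate Euler–Maruyama
simulator (`dt = 1e-4` by default) ships as an internal function used only
as an independent brute-force oracle in the tests; it never feeds the
pipeline, so density-versus-simulation comparisons are genuinely
dual-route.

## The hierarchical models

Three nested parameter mappings are compared, all response coded, all with
one free group-level drift per condition × morph-level cell (8 levels:
0, 20, 35, 45, 55, 65, 80, 100% self) and subject-level nondecision time:

* **M1** — drift only; starting point pinned at `z = 0.5` (no response
  bias); one boundary-separation distribution. The stimulus-bias account.
* **M2** — adds a free starting point per between-subject condition: a
  prestimulus response preference. The response-bias account.
* **M3** — additionally frees boundary separation per condition: response
  caution differences.

Nondecision time never varies by condition or morph: no condition effects
on it are reported in the analyses this package reproduces, and freeing it
invites trade-offs with fast contaminants.

Estimation is hierarchical Bayesian. Subject-level parameters live on
unconstrained scales — drift raw, `logit(z)`, `log(a)`, `log(t0)` — each
drawn from a group normal with its own mean and spread (one mean/spread
pair per condition × morph drift cell, mirroring per-split group
distributions in the standard software). Because the original analyses
state no priors, the hyperpriors are weakly informative on those scales:
group means `N(0, 5^2)` for drift, `N(0, 1.5^2)` for logit-z (centred on
no bias), `N(log 1.5, 1)` for log-a, `N(log 0.3, 1)` for log-t0; group
variances inverse-gamma with shape 2.5 and rates 0.5 (v) / 0.1 (z) / 0.05
(a, t0), i.e. prior guesses of 10–40% between-subject spread with fat
tails.

The sampler is single-site Metropolis-within-Gibbs: random-walk Metropolis
for every subject-level parameter (per-parameter proposal scales adapted
toward 44% acceptance in batches of 25 during burn-in, frozen afterwards)
and conjugate normal/inverse-gamma Gibbs updates for the group means and
variances. One chain is the default, matching the 10,000-samples /
1,000-burn convention of the reference analyses; `split_rhat()` computes a
split-half potential-scale-reduction diagnostic from the stored draws and
`fit_hddm()` warns above 1.05. The documented fast mode (2,000 samples,
500 burn) is what the test suite and the calibration script use; on one
CPU a fast-mode fit of 20 subjects × 560 trials takes well under a minute.

**Model comparison** uses the deviance information criterion,
`DIC = D(θ̄) + 2 p_D`, with `D(θ̄)` evaluated at the posterior means of the
subject-level parameters on their unconstrained scales and
`p_D = mean deviance − D(θ̄)`. Two practical notes. First, this is the
conditional (subject-level) DIC, the quantity the standard hierarchical
DDM software reports. Second, DIC differences between a model and its own
superset (M2 vs M3 when the true boundary separation is
condition-invariant) are small by construction — the superset gains no fit
and pays roughly one effective parameter — so they sit inside the
Monte-Carlo noise of independently run chains at desk scale; following the
usual convention, differences below about 5 units are not treated as
decisive. The substantive comparison (M2 vs M1) is an order of magnitude
larger whenever a real starting-point bias is present.

**Directional evidence** is reported the way the reference analyses do:
`p_Bayes` is the fraction of post-burn draws violating a stated direction
(small = strong evidence), and the directional Bayes factor is
`BF10 = (1 - p) / p`, rounded to the nearest integer for reporting, with
values beyond 999 shown as the bound `"> 999"`. Condition-mean drift
summaries fold the morph cells by sign — the mean of
`v * sign(morph - 50)` — rather than taking absolute values, which would
be biased upward by posterior noise in the near-zero cells.

**The z-on-PSE regression** expresses each subject's starting point as
`z_s = plogis(b0 + b1 * PSE_std_s)`, the PSE standardized before entry.
The inverse-logit link keeps `z` in (0,1) and makes the slope scale-free;
priors are `N(0, 1.5)` on the intercept and `N(0, 1)` on the slope. A
negative slope is the signature of interest: lower PSEs (stronger
behavioral self-bias) accompanying higher starting points. There is no
subject-level residual on `z` in this model — `z` is fully determined by
the predictor — which matches the regression design it parallels and keeps
the slope identified with modest cohorts.

## The synthetic experiments

The generator reproduces the two factorial designs: two between-subject
conditions (ownership vs identity judgment; short vs long exposure), 8
morph levels shown exactly 10 times per 80-trial block, 7 blocks (560
trials per participant, 70 per morph level), around 40 participants per
condition, with object-owner and key-response counterbalancing recorded
per participant and the morph axis canonicalized to % self at generation.

Choices and response times come from the DDM itself with a linear
antisymmetric morph-to-drift map, `v = v_max (2·morph/100 − 1)` — a
generator convenience only; the fitted models still estimate one free
drift per morph cell. Default group means encode the fitted signatures of
the manipulations: `z` = 0.52 vs 0.50 for ownership vs identity judgments
and 0.53 vs 0.52 for short vs long exposures; `v_max` = 1.74 vs 1.90 and
2.10 vs 1.98, chosen so the sign-folded condition-mean drifts equal the
reported 0.87/0.95 and 1.05/0.99 under the linear map (`folded mean =
v_max / 2` on this grid). Boundary separation (1.6) and nondecision time
(0.35 s) are not reported anywhere and are set to values typical of
speeded two-choice classification; between-subject SDs default to 10% of
each mean. Recovery targets involving `a` and `t0` therefore test
self-consistency of the pipeline, not unpublished population values.
Contaminants default to 1% fast guesses (uniform 50–200 ms, coin-flip
response), sized to reproduce the ~1% exclusion rate of the 200 ms filter,
plus 2% slow uniform outliers (0.2–5 s) as material for the mixture
likelihood.

What the generator does *not* emulate: stimulus encoding (the
exposure-duration manipulation enters only through its fitted signatures —
a larger starting-point bias and a different drift scale — not through a
perceptual mechanism), sequential effects, fatigue or learning across
blocks, and lapses other than the uniform contaminants. Passing recovery
tests on these data shows the estimators are consistent and the pipeline
unbiased under the model's own assumptions; it cannot certify behavior on
real data that violate them.

## The psychophysical layer

Trials faster than 200 ms are excluded (on synthetic data with 1% injected
fast guesses this removes about 1% of trials). Each participant ×
condition is then fitted with
`P(self) = 1 / (1 + exp(-beta (morph - alpha)))` by maximum likelihood —
ordinary logistic regression, no lapse/guess asymptotes (the default of
the curve-fitting tool the reference analyses used; asymptotes cost little
at 70 trials per level but are a documented sensitivity). Under complete
separation the estimate diverges, so the fit falls back to a bounded
optimization (|slope| capped at 2 per %, location in [-100, 200]) with a
warning; the reported slope is orientation-normalized to positive and the
PSE is invariant to relabeling the response axis.

"Random responding across morph levels" — the published exclusion symptom
— is operationalized reproducibly: a likelihood-ratio test of the fitted
logistic against a constant-probability model at α = 0.01, *or* accuracy
below 60% on the unambiguous anchor images (0% and 100%), either of which
excludes the participant. A 560-trial coin-flipper is caught essentially
always; a steep monotone observer never is.

Group inference is classical, as in the source analyses: one-sample
t-tests of each condition's PSEs against the 50% midpoint with Cohen's
`d = shift / SD`, and a pooled-variance two-sample t-test between
conditions (`df = n1 + n2 - 2`) with `d` on the pooled SD. One
bookkeeping note: the published between-condition test reports one more
degree of freedom than the stated per-condition samples imply
(35 + 39 − 2 = 72, not 73); the exclusion arithmetic behind the published
counts is ambiguous, so this package simply reports the df its own counts
imply and does not force agreement.

## Posterior predictive checks

`posterior_predict()` draws one joint post-burn parameter vector per
simulated dataset (not the posterior mean — bands should reflect parameter
uncertainty) and regenerates the full design, contaminants included.
"Reproducing the key features of the data", qualitative in the source, is
made quantitative in `compare_curves()`: the empirical group-mean PSE must
fall inside the simulated 95% band (misfit is flagged otherwise), and
per-morph response probabilities are compared against their own simulated
bands. Ten datasets is the default, matching the reference procedure;
`drift_psychometric()` tabulates the group drift posterior per condition ×
morph with central 95% intervals and a monotonicity diagnostic.

## Problem sizes and test design

The package's own test suite runs everything at desk scale, with
Monte-Carlo tolerances derived from the sizes actually used rather than
copied from larger designs: recovery fits use 8–20 subjects × 240–560
trials in fast MCMC mode; the starting-point recovery check uses 20
participants (the upper end of its sanctioned 12–20 range, because the
cohort-mean sampling error at 10% between-subject spread is the binding
error source); the model-recovery study is the sanctioned 5-replicate
smoke version (6 subjects per condition × 240 trials, 3000 samples);
estimator checks at reported condition summaries average 20 seeded
cohorts. The calibration script (`scripts/acceptance.R`) recomputes all
headline quantities from scratch at these sizes in a few minutes on one
CPU.

Two calibration notes a user extending the suite should keep in mind.
First, at reported effect sizes (standardized shifts near 0.4–0.6) a
single synthetic cohort replicates "significance" with only ~70% power —
majorities across seeds, not every seed, are the right expectation.
Second, asserting *non*-significance for null generators at α = 0.05
would fail 5% of seeds by construction; the suite uses α = 0.01 together
with a 1-point bound on the mean shift for those checks.

## Known limitations

* No inter-trial variability parameters; fast-error patterns they explain
  are attributed to the contaminant mixture instead.
* Single-chain default: split-R-hat from one chain is a weaker diagnostic
  than true multi-chain R-hat; run several seeds for publication-grade
  convergence assessment.
* The conditional DIC is reported because it is the field convention for
  these models, but it penalizes subject-level parameters only
  approximately; WAIC/LOO are deliberately out of scope.
* The z-on-PSE regression uses the estimated PSE as an error-free
  predictor, as does the procedure it parallels; attenuation from PSE
  estimation noise is small at 560 trials per participant but real.
* The exposure-duration manipulation is modeled through its decision-level
  signatures, not through stimulus encoding.
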
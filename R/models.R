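# Model specifications and design construction for the hierarchical fits.

#' Parameter-mapping model specification
#'
#' The three nested models compared in the analysis. In all of them drift
#' rate varies freely over condition x morph-level cells and nondecision
#' time is subject-level only. They differ in which response/caution
#' parameters are condition-dependent:
#' \describe{
#'   \item{M1}{baseline: starting point fixed at `z = 0.5` (no response
#'     bias), one boundary-separation distribution.}
#'   \item{M2}{adds a free starting point per between-subject condition
#'     (response-selection bias).}
#'   \item{M3}{additionally lets boundary separation vary per condition
#'     (response caution).}
#' }
#'
#' @param variant `"M1"`, `"M2"` or `"M3"`.
#' @return An object of class `hddm_model`.
#' @examples
#' hddm_model("M2")
#' @export
hddm_model <- function(variant = c("M2", "M1", "M3")) {
  variant <- match.arg(variant)
  structure(list(
    variant = variant,
    z_free = variant != "M1",
    z_by_condition = variant != "M1",
    a_by_condition = variant == "M3"
  ), class = "hddm_model")
}

#' @export
print.hddm_model <- function(x, ...) {
  cat(sprintf("Model %s: v ~ condition x morph; z %s; a %s; t0 subject-level\n",
              x$variant,
              if (!x$z_free) "fixed at 0.5" else "~ condition",
              if (x$a_by_condition) "~ condition" else "pooled"))
  invisible(x)
}

# Canonical internal trial representation. Accepts the public column names
# (participant, condition, morph_pct_self, response, rt_s) or bare
# (morph, choice, rt); response may be "self"/"friend", 0/1 or logical.
normalize_trials <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  morph <- if (!is.null(trials$morph_pct_self)) trials$morph_pct_self else trials$morph
  rt <- if (!is.null(trials$rt_s)) trials$rt_s else trials$rt
  resp <- if (!is.null(trials$response)) trials$response else trials$choice
  if (is.null(morph) || is.null(rt) || is.null(resp))
    stop("trials need morph_pct_self/morph, response/choice and rt_s/rt columns",
         call. = FALSE)
  participant <- if (!is.null(trials$participant)) as.character(trials$participant)
                 else rep("p1", nrow(trials))
  condition <- if (!is.null(trials$condition)) as.character(trials$condition)
               else rep("all", nrow(trials))
  if (any(rt <= 0)) stop("response times must be > 0", call. = FALSE)
  data.frame(participant = participant, condition = condition,
             morph = as.numeric(morph), y = choice_to_upper(resp),
             rt = as.numeric(rt), stringsAsFactors = FALSE)
}

#' Build the cell design for a hierarchical fit
#'
#' Maps every trial to its drift, starting-point, boundary and nondecision
#' cells under a model specification. Drift cells are the full condition x
#' morph grid (response coded: the upper boundary is the self-related
#' response); starting point and boundary cells follow the model variant;
#' nondecision time is one cell per subject. Trials are sorted by subject
#' and morph cell and offset tables are precomputed for the sampler.
#'
#' @param trials A trial table (see [read_trials()] for the column contract).
#' @param model An [hddm_model()] object or variant string.
#' @return An object of class `hddm_design`.
#' @export
build_design <- function(trials, model = hddm_model("M2")) {
  if (is.character(model)) model <- hddm_model(model)
  d <- normalize_trials(trials)
  conditions <- sort(unique(d$condition))
  morphs <- sort(unique(d$morph))
  if (length(morphs) < 2) stop("need at least two distinct morph levels",
                               call. = FALSE)
  subjects <- unique(d$participant)
  subj_cond_chr <- vapply(subjects,
                          function(p) unique(d$condition[d$participant == p])[1],
                          character(1))
  multi <- vapply(subjects,
                  function(p) length(unique(d$condition[d$participant == p])),
                  integer(1))
  if (any(multi > 1))
    stop("between-subject design violated: participants ",
         paste(subjects[multi > 1], collapse = ", "),
         " appear in more than one condition", call. = FALSE)
  S <- length(subjects); C <- length(morphs)
  si <- match(d$participant, subjects)
  ci <- match(d$morph, morphs)
  ord <- order(si, ci, method = "radix")
  d <- d[ord, ]; si <- si[ord]; ci <- ci[ord]
  # 0-based offsets: off[s, c] .. off[s, c+1]-1 are subject s, morph cell c
  counts <- matrix(0L, S, C)
  tab <- table(factor(si, levels = seq_len(S)), factor(ci, levels = seq_len(C)))
  counts[] <- as.integer(tab)
  off <- cbind(0L, t(apply(counts, 1, cumsum)))
  base <- c(0L, cumsum(rowSums(counts)))[seq_len(S)]
  off <- off + base

  structure(list(
    model = model,
    trials = d,
    rt = d$rt, choice = as.integer(d$y),
    subjects = subjects,
    conditions = conditions,
    morphs = morphs,
    subj_cond = match(subj_cond_chr, conditions),
    off = off, counts = counts,
    S = S, C = C, K = length(conditions),
    v_labels = as.vector(outer(morphs, conditions,
                               function(m, k) sprintf("v[%s,%g]", k, m))),
    z_labels = if (model$z_free) sprintf("z[%s]", conditions) else character(0),
    a_labels = if (model$a_by_condition) sprintf("a[%s]", conditions) else "a",
    n_z_cells = if (model$z_free) length(conditions) else 0L,
    n_a_cells = if (model$a_by_condition) length(conditions) else 1L
  ), class = "hddm_design")
}

#' @export
print.hddm_design <- function(x, ...) {
  cat(sprintf("hddm_design: %d subjects, %d trials, %d conditions x %d morph levels\n",
              x$S, length(x$rt), x$K, x$C))
  cat(sprintf("  model %s: %d drift cells, %d z cell(s)%s, %d a cell(s), t0 per subject\n",
              x$model$variant, x$K * x$C, x$n_z_cells,
              if (!x$model$z_free) " (z fixed at 0.5)" else "",
              x$n_a_cells))
  invisible(x)
}
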
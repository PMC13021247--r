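# Delimited-text readers and writers tying the pipeline together.

#' Read a trial table
#'
#' Reads delimited text with one row per trial. Required columns:
#' `participant`, `condition`, `rt_s`, `response`, and either
#' `morph_pct_self` or `morph_pct_pen` together with a logical
#' `pencil_is_self` counterbalance column — in the latter case the morph
#' axis is canonicalized at ingest to % self-owned object
#' (`100 - morph_pct_pen` for pencil-owners, `morph_pct_pen` otherwise).
#' Responses may be coded `"self"`/`"friend"`, 1/0 or TRUE/FALSE (1/TRUE =
#' self-related response). Rows with unknown response codes, non-positive
#' response times or morph levels off the declared grid are rejected; the
#' rejected rows are attached as the `"row_errors"` attribute and reported
#' in a warning.
#'
#' @param path File path of the delimited text table.
#' @param sep Field separator.
#' @param morph_grid Allowed morph levels; `NULL` skips the grid check.
#' @return A validated trial data frame (participant, condition,
#'   morph_pct_self, response (0/1), rt_s).
#' @export
read_trials <- function(path, sep = ",", morph_grid = MORPH_GRID) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "rt_s", "response")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.null(raw$morph_pct_self)) {
    morph <- as.numeric(raw$morph_pct_self)
  } else if (!is.null(raw$morph_pct_pen)) {
    if (is.null(raw$pencil_is_self))
      stop("morph_pct_pen axis needs a pencil_is_self counterbalance column",
           call. = FALSE)
    pen <- as.numeric(raw$morph_pct_pen)
    cb <- as.logical(raw$pencil_is_self)
    morph <- ifelse(cb, 100 - pen, pen)
  } else {
    stop("missing column(s): morph_pct_self (or morph_pct_pen + pencil_is_self)",
         call. = FALSE)
  }

  resp_raw <- raw$response
  resp <- rep(NA_integer_, nrow(raw))
  if (is.character(resp_raw)) {
    resp[resp_raw %in% c("self", "1", "TRUE", "upper")] <- 1L
    resp[resp_raw %in% c("friend", "0", "FALSE", "lower")] <- 0L
  } else {
    resp[resp_raw %in% c(1, TRUE)] <- 1L
    resp[resp_raw %in% c(0, FALSE)] <- 0L
  }
  rt <- suppressWarnings(as.numeric(raw$rt_s))

  err <- character(nrow(raw))
  err[is.na(resp)] <- "unknown response code"
  err[is.na(rt) | rt <= 0] <- "non-positive or missing rt_s"
  err[is.na(morph)] <- "missing morph level"
  if (!is.null(morph_grid))
    err[!is.na(morph) & !morph %in% morph_grid & err == ""] <-
      "morph level off the grid"
  bad <- err != ""
  if (any(bad))
    warning(sprintf("rejected %d row(s): %s", sum(bad),
                    paste(sprintf("row %d (%s)", which(bad)[seq_len(min(5, sum(bad)))],
                                  err[bad][seq_len(min(5, sum(bad)))]),
                          collapse = "; ")), call. = FALSE)
  out <- data.frame(participant = as.character(raw$participant)[!bad],
                    condition = as.character(raw$condition)[!bad],
                    morph_pct_self = morph[!bad], response = resp[!bad],
                    rt_s = rt[!bad], stringsAsFactors = FALSE)
  attr(out, "row_errors") <- data.frame(row = which(bad), error = err[bad])
  out
}

#' Write a trial table
#'
#' Writes delimited text that [read_trials()] reads back losslessly.
#'
#' @param trials Trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export fit tables as delimited text
#'
#' Writes the posterior summary (one row per group-level parameter), the
#' post-burn group-level draws (one row per draw x parameter), and — when
#' several fits are given — the DIC comparison table.
#'
#' @param fits A named list of [fit_hddm()] results (or a single fit).
#' @param dir Output directory, created if needed.
#' @return The written file paths, invisibly.
#' @export
write_fit_tables <- function(fits, dir) {
  if (inherits(fits, "hddm_fit")) fits <- list(fit = fits)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    p1 <- file.path(dir, paste0(nm, "_summary.csv"))
    write.csv(summary(fit), p1, row.names = FALSE)
    keep <- post_idx(fit)
    draws <- data.frame(iteration = keep, fit$group$v[keep, , drop = FALSE],
                        check.names = FALSE)
    if (fit$model$z_free) {
      z <- plogis(fit$group$z[keep, , drop = FALSE])
      colnames(z) <- fit$design$z_labels
      draws <- cbind(draws, z)
    }
    p2 <- file.path(dir, paste0(nm, "_draws.csv"))
    write.csv(draws, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  if (length(fits) > 1) {
    p3 <- file.path(dir, "dic_comparison.csv")
    write.csv(compare_dic(fits), p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
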